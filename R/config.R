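# Configuration loading, validation and serialization. A model
# configuration is a plain nested list with three blocks:
#   arms$intervention / arms$comparator : label, median_pfs, median_os,
#     cost_pfs_per_cycle, cost_pd_per_cycle, optional cost_death and
#     printed_probs (externally supplied, possibly rounded probabilities)
#   global : annual_discount_rate, horizon_cycles, wtp, utility_pfs,
#     utility_pd, utility_death, half_cycle, precision (derived|fixture)
#   sensitivity : n_iter, cost_sd_frac, wtp_grid (from/to/by), ranges
#     (list of {name, base, low, high})

GLOBAL_DEFAULTS <- list(
  annual_discount_rate = 0.05, horizon_cycles = 120, wtp = 35906,
  utility_pfs = 0.89, utility_pd = 0.74, utility_death = 0,
  half_cycle = FALSE, precision = "derived"
)
SENS_DEFAULTS <- list(
  n_iter = 1000, cost_sd_frac = 0.25,
  wtp_grid = list(from = 0, to = 150000, by = 1500),
  ranges = list()
)
KNOWN_ARM_KEYS <- c("label", "median_pfs", "median_os",
                    "cost_pfs_per_cycle", "cost_pd_per_cycle",
                    "cost_death", "printed_probs")

#' Validate a model configuration, filling defaults
#'
#' Schema-checks a configuration list, fills documented defaults
#' (10-year horizon, 5% discount, WTP $35,906/QALY, utilities 0.89/0.74,
#' derived precision), and attaches a validation report. Unknown keys
#' produce a warning, not an error. When an arm carries `printed_probs`
#' whose stay probabilities disagree with the complement of the exit
#' probabilities by more than 0.005 (a row that does not sum to 1, as
#' happens with tables rounded to two decimals), a normalization warning
#' is emitted — the matrix builder will recompute the stay probability.
#'
#' @param config A configuration list (see file-level description).
#' @return The validated configuration with defaults filled and an
#'   attribute `validation` (list with `warnings` and `filled`).
#' @export
validate_config <- function(config) {
  fail <- function(...) stop(..., call. = FALSE)
  if (!is.list(config)) fail("configuration must be a list")
  warnings_seen <- character()
  note_warning <- function(msg) {
    warnings_seen <<- c(warnings_seen, msg)
    warning(msg, call. = FALSE)
  }
  unknown <- setdiff(names(config), c("arms", "global", "sensitivity"))
  if (length(unknown)) {
    note_warning(paste0("ignoring unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  if (is.null(config$arms) ||
      !all(ARM_ROLES %in% names(config$arms))) {
    fail("configuration must contain `arms$intervention` and ",
         "`arms$comparator`")
  }

  num1 <- function(x, field, lo = -Inf, hi = Inf, allow_inf = FALSE) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) != 1 || is.na(x) ||
        (!allow_inf && is.infinite(x)) || x < lo || x > hi) {
      fail("`", field, "` must be a number in [", lo, ", ", hi, "]")
    }
    x
  }

  filled <- character()
  g <- config$global %||% list()
  for (nm in names(GLOBAL_DEFAULTS)) {
    if (is.null(g[[nm]])) {
      g[[nm]] <- GLOBAL_DEFAULTS[[nm]]
      filled <- c(filled, paste0("global$", nm))
    }
  }
  unknown_g <- setdiff(names(g), names(GLOBAL_DEFAULTS))
  if (length(unknown_g)) {
    note_warning(paste0("ignoring unknown global key(s): ",
                        paste(unknown_g, collapse = ", ")))
  }
  g$annual_discount_rate <- num1(g$annual_discount_rate,
                                 "annual_discount_rate", 0, 1 - 1e-12)
  g$horizon_cycles <- num1(g$horizon_cycles, "horizon_cycles", 1, 1e6)
  if (g$horizon_cycles != round(g$horizon_cycles)) {
    fail("`horizon_cycles` must be an integer count of monthly cycles")
  }
  g$wtp <- num1(g$wtp, "wtp", 1e-9, Inf)
  for (nm in c("utility_pfs", "utility_pd", "utility_death")) {
    g[[nm]] <- num1(g[[nm]], nm, 0, 1)
  }
  g$half_cycle <- isTRUE(g$half_cycle)
  if (!g$precision %in% c("derived", "fixture")) {
    fail("`precision` must be 'derived' or 'fixture'")
  }
  config$global <- g[names(GLOBAL_DEFAULTS)]

  for (role in ARM_ROLES) {
    arm <- config$arms[[role]]
    if (!is.list(arm)) fail("arm '", role, "' must be a list")
    unknown_a <- setdiff(names(arm), KNOWN_ARM_KEYS)
    if (length(unknown_a)) {
      note_warning(paste0("arm '", role, "': ignoring unknown key(s): ",
                          paste(unknown_a, collapse = ", ")))
    }
    if (is.null(arm$label)) {
      arm$label <- role
      filled <- c(filled, paste0("arms$", role, "$label"))
    }
    arm$median_pfs <- num1(arm$median_pfs,
                           paste0(role, "$median_pfs"), 1e-9, Inf,
                           allow_inf = TRUE)
    arm$median_os <- num1(arm$median_os,
                          paste0(role, "$median_os"), 1e-9, Inf,
                          allow_inf = TRUE)
    if (arm$median_os < arm$median_pfs) {
      fail("`", role, "$median_os` must be >= `", role, "$median_pfs`")
    }
    for (nm in c("cost_pfs_per_cycle", "cost_pd_per_cycle")) {
      arm[[nm]] <- num1(arm[[nm]], paste0(role, "$", nm), 0, Inf)
    }
    if (!is.null(arm$cost_death)) {
      arm$cost_death <- num1(arm$cost_death,
                             paste0(role, "$cost_death"), 0, Inf)
    }
    if (!is.null(arm$printed_probs)) {
      p <- arm$printed_probs
      need <- c("p_pfs_pfs", "p_pfs_pd", "p_pfs_death", "p_pd_pd",
                "p_pd_death")
      for (nm in need) {
        p[[nm]] <- num1(p[[nm]], paste0(role, "$printed_probs$", nm),
                        0, 1)
      }
      stay_pfs <- 1 - p$p_pfs_pd - p$p_pfs_death
      if (abs(stay_pfs - p$p_pfs_pfs) > 0.005) {
        note_warning(sprintf(
          paste0("arm '%s': printed PFS row sums to %.2f; stay ",
                 "probability %.2f will be renormalized to its ",
                 "complement %.2f"),
          role, p$p_pfs_pfs + p$p_pfs_pd + p$p_pfs_death, p$p_pfs_pfs,
          stay_pfs))
      }
      stay_pd <- 1 - p$p_pd_death
      if (abs(stay_pd - p$p_pd_pd) > 0.005) {
        note_warning(sprintf(
          paste0("arm '%s': printed PD row sums to %.2f; stay ",
                 "probability %.2f will be renormalized to its ",
                 "complement %.2f"),
          role, p$p_pd_pd + p$p_pd_death, p$p_pd_pd, stay_pd))
      }
      arm$printed_probs <- p[need]
    }
    config$arms[[role]] <- arm
  }

  s <- config$sensitivity %||% list()
  for (nm in names(SENS_DEFAULTS)) {
    if (is.null(s[[nm]])) {
      s[[nm]] <- SENS_DEFAULTS[[nm]]
      filled <- c(filled, paste0("sensitivity$", nm))
    }
  }
  unknown_s <- setdiff(names(s), names(SENS_DEFAULTS))
  if (length(unknown_s)) {
    note_warning(paste0("ignoring unknown sensitivity key(s): ",
                        paste(unknown_s, collapse = ", ")))
  }
  s$n_iter <- num1(s$n_iter, "sensitivity$n_iter", 1, Inf)
  s$cost_sd_frac <- num1(s$cost_sd_frac, "sensitivity$cost_sd_frac",
                         0, 10)
  for (nm in c("from", "to", "by")) {
    s$wtp_grid[[nm]] <- num1(s$wtp_grid[[nm]],
                             paste0("sensitivity$wtp_grid$", nm),
                             if (nm == "by") 1e-9 else 0, Inf)
  }
  s$ranges <- lapply(s$ranges, function(r) {
    for (nm in c("base", "low", "high")) {
      r[[nm]] <- num1(r[[nm]], paste0("ranges$", r$name, "$", nm))
    }
    if (r$low > r$base || r$base > r$high) {
      fail("range '", r$name, "' must satisfy low <= base <= high")
    }
    r[c("name", "base", "low", "high")]
  })
  config$sensitivity <- s[names(SENS_DEFAULTS)]
  config <- config[c("arms", "global", "sensitivity")]
  attr(config, "validation") <- list(warnings = warnings_seen,
                                     filled = filled)
  config
}

#' Load a model configuration from JSON or YAML
#'
#' The format is chosen by file extension (`.json`, `.yaml`, `.yml`);
#' anything else is tried as JSON first, then YAML. The parsed list is
#' passed through [validate_config()].
#'
#' @param path Path to the configuration file.
#' @return A validated configuration with a `validation` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) yaml::read_yaml(path))
  }
  validate_config(raw)
}

#' Serialize a model configuration to JSON or YAML
#'
#' @param config A (validated) configuration list.
#' @param path Output path; `.yaml`/`.yml` writes YAML, anything else
#'   JSON. Numbers are written at full precision so that
#'   load -> write -> load round-trips losslessly.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  attributes(config)[setdiff(names(attributes(config)), "names")] <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path, precision = 15)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' The packaged base-case parameter set
#'
#' Loads the configuration shipped with the package: the published
#' bevacizumab+lomustine vs lomustine comparison in progressive
#' glioblastoma (arm medians 4.2/9.1 and 1.5/8.6 months; per-cycle costs
#' under the documented dosing defaults, see [drug_cost_defaults()];
#' utilities 0.89/0.74 per year; 5% annual discount; 120 monthly cycles;
#' WTP $35,906/QALY; published probability limits as sensitivity ranges).
#'
#' Loading emits one normalization warning: the published
#' intervention-arm PFS row sums to 0.99 (stay probability printed 0.77
#' vs complement 0.78), a rounding artifact that the matrix builder
#' repairs by complement.
#'
#' @return A validated configuration.
#' @export
fixture_config <- function() {
  load_config(system.file("extdata", "fixture_config.json",
                          package = "markovcea", mustWork = TRUE))
}

#' Documented per-cycle drug-cost defaults for the packaged comparison
#'
#' The published table gives unit prices but not the per-cycle dosing
#' arithmetic. The defaults reconstruct it as: bevacizumab 10 mg/kg for a
#' 65 kg patient (650 mg, i.e. 7 x 100 mg vials at $209.50), three
#' administrations (q2w) per 6-week treatment cycle; lomustine 90 mg/m2
#' (combination) or 110 mg/m2 capped at 200 mg (monotherapy) for a
#' 1.72 m2 patient, rounded up to whole 50 mg tablets at $3.25, once per
#' 6-week cycle. Costs on the 6-week schedule are converted to the
#' 1-month model cycle by the ratio (365.25/12)/42. Per-cycle adverse
#' event management and medical examination fees are already monthly and
#' enter unconverted.
#'
#' @param body_weight_kg,bsa_m2 Reference patient (65 kg, 1.72 m2).
#' @param bev_dose_mg_per_kg,bev_vial_mg,bev_vial_usd,bev_admin_per_cycle
#'   Bevacizumab dosing/pricing defaults.
#' @param lom_combo_mg_per_m2,lom_mono_mg_per_m2,lom_max_mg,lom_tablet_mg,lom_tablet_usd
#'   Lomustine dosing/pricing defaults.
#' @param ae_cost_combo,ae_cost_mono Monthly adverse-event management
#'   costs (USD).
#' @param exam_cost_combo,exam_cost_mono Monthly medical examination fees
#'   (USD).
#' @param cycle_weeks Treatment-cycle length in weeks (6).
#' @return A list with per-month drug costs and the resulting
#'   `cost_pfs_per_cycle` for each arm.
#' @export
drug_cost_defaults <- function(body_weight_kg = 65, bsa_m2 = 1.72,
                               bev_dose_mg_per_kg = 10, bev_vial_mg = 100,
                               bev_vial_usd = 209.50,
                               bev_admin_per_cycle = 3,
                               lom_combo_mg_per_m2 = 90,
                               lom_mono_mg_per_m2 = 110, lom_max_mg = 200,
                               lom_tablet_mg = 50, lom_tablet_usd = 3.25,
                               ae_cost_combo = 3.53, ae_cost_mono = 0.03,
                               exam_cost_combo = 464.67,
                               exam_cost_mono = 459.04,
                               cycle_weeks = 6) {
  months_per_cycle <- (cycle_weeks * 7) / (365.25 / 12)
  bev_dose <- bev_dose_mg_per_kg * body_weight_kg
  bev_month <- bev_vial_usd * ceiling(bev_dose / bev_vial_mg) *
    bev_admin_per_cycle / months_per_cycle
  lom_dose_combo <- lom_combo_mg_per_m2 * bsa_m2
  lom_dose_mono <- min(lom_mono_mg_per_m2 * bsa_m2, lom_max_mg)
  lom_month_combo <- lom_tablet_usd *
    ceiling(lom_dose_combo / lom_tablet_mg) / months_per_cycle
  lom_month_mono <- lom_tablet_usd *
    ceiling(lom_dose_mono / lom_tablet_mg) / months_per_cycle
  list(
    bev_usd_per_month = bev_month,
    lom_usd_per_month_combo = lom_month_combo,
    lom_usd_per_month_mono = lom_month_mono,
    cost_pfs_per_cycle_intervention = bev_month + lom_month_combo +
      exam_cost_combo + ae_cost_combo,
    cost_pfs_per_cycle_comparator = lom_month_mono + exam_cost_mono +
      ae_cost_mono
  )
}
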