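# Synthetic trial data and random configurations. Event times are
# exponential, matching the constant-hazard assumption under which the
# model converts medians to monthly probabilities — so median estimation
# and parameter recovery are well-posed end-to-end checks.

#' Generate one synthetic trial arm with exponential event times
#'
#' Progression times are exponential with rate `log(2) / median_pfs`;
#' post-progression survival is exponential with rate
#' `log(2) / (median_os - median_pfs)`; overall survival is their sum,
#' so `os_months > pfs_months` for every patient by construction. (The
#' sum of the two phases has median close to, but not exactly,
#' `median_os`; the construction targets the two phase medians the model
#' actually consumes.)
#'
#' @param n Number of patients (>= 1).
#' @param median_pfs,median_os True medians in months,
#'   `median_os > median_pfs`.
#' @param rng_seed Optional integer seed.
#' @param arm_label Arm label carried through to estimation.
#' @return A data frame of class `synthetic_trial_arm` with columns
#'   `patient_id`, `pfs_months`, `os_months`; attributes `arm_label`,
#'   `true_median_pfs`, `true_median_os`.
#' @export
generate_trial_arm <- function(n, median_pfs, median_os, rng_seed = NULL,
                               arm_label = "synthetic") {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(median_pfs) || median_pfs <= 0 ||
      !is.numeric(median_os) || median_os <= median_pfs) {
    stop("medians must satisfy 0 < median_pfs < median_os", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pfs <- stats::rexp(n, rate = log(2) / median_pfs)
  post <- stats::rexp(n, rate = log(2) / (median_os - median_pfs))
  out <- data.frame(patient_id = seq_len(n), pfs_months = pfs,
                    os_months = pfs + post)
  class(out) <- c("synthetic_trial_arm", "data.frame")
  attr(out, "arm_label") <- arm_label
  attr(out, "true_median_pfs") <- median_pfs
  attr(out, "true_median_os") <- median_os
  out
}

#' Estimate arm medians from individual-level trial data
#'
#' Sample medians of the progression and survival times (no censoring),
#' packaged as [arm_clinical_inputs()] so the estimate feeds directly
#' into [derive_arm_transitions()].
#'
#' @param arm A `synthetic_trial_arm` (or any data frame with
#'   `pfs_months` and `os_months` columns).
#' @return An [arm_clinical_inputs()] object.
#' @export
estimate_medians <- function(arm) {
  if (!is.data.frame(arm) || nrow(arm) == 0 ||
      !all(c("pfs_months", "os_months") %in% names(arm))) {
    stop("`arm` must be a non-empty data frame with `pfs_months` and ",
         "`os_months` columns", call. = FALSE)
  }
  arm_clinical_inputs(
    arm_label = attr(arm, "arm_label") %||% "estimated",
    median_pfs = stats::median(arm$pfs_months),
    median_os = stats::median(arm$os_months)
  )
}

#' Generate a random but structurally valid model configuration
#'
#' Draws a complete two-arm configuration uniformly within the given
#' constraints. Every generated configuration passes [validate_config()]
#' and runs end-to-end through [evaluate_model()].
#'
#' @param rng_seed Optional integer seed.
#' @param constraints Named list of `c(low, high)` ranges:
#'   `median_pfs`, `os_gap` (post-progression median), `cost_pfs`,
#'   `cost_pd`, `utility_pfs`, `utility_pd_frac` (PD utility as a
#'   fraction of the PFS utility), `discount`, `wtp`. Defaults span
#'   plausible oncology cost-effectiveness inputs.
#' @return A validated model configuration list.
#' @export
generate_random_config <- function(rng_seed = NULL, constraints = list()) {
  defaults <- list(
    median_pfs = c(1, 12), os_gap = c(0.5, 24),
    cost_pfs = c(50, 5000), cost_pd = c(20, 2000),
    utility_pfs = c(0.5, 1), utility_pd_frac = c(0.4, 1),
    discount = c(0, 0.1), wtp = c(10000, 200000)
  )
  bad <- setdiff(names(constraints), names(defaults))
  if (length(bad)) {
    stop("unknown constraint(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cn <- utils::modifyList(defaults, constraints)
  for (nm in names(cn)) {
    if (length(cn[[nm]]) != 2 || cn[[nm]][1] > cn[[nm]][2]) {
      stop("constraint '", nm, "' must be c(low, high) with low <= high",
           call. = FALSE)
    }
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  u <- function(r) stats::runif(1, r[1], r[2])
  mk_arm <- function(label) {
    pfs <- u(cn$median_pfs)
    list(label = label,
         median_pfs = pfs,
         median_os = pfs + u(cn$os_gap),
         cost_pfs_per_cycle = u(cn$cost_pfs),
         cost_pd_per_cycle = u(cn$cost_pd))
  }
  upfs <- u(cn$utility_pfs)
  cfg <- list(
    arms = list(intervention = mk_arm("intervention"),
                comparator = mk_arm("comparator")),
    global = list(annual_discount_rate = u(cn$discount),
                  horizon_cycles = 120,
                  wtp = u(cn$wtp),
                  utility_pfs = upfs,
                  utility_pd = upfs * u(cn$utility_pd_frac),
                  utility_death = 0,
                  half_cycle = FALSE,
                  precision = "derived"),
    sensitivity = list(n_iter = 1000, cost_sd_frac = 0.25,
                       wtp_grid = list(from = 0, to = 150000, by = 1500),
                       ranges = list())
  )
  validate_config(cfg)
}
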