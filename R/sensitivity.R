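# One-way deterministic (tornado) and probabilistic (Monte Carlo)
# sensitivity analyses. Both re-enter the model exclusively through
# evaluate_model(config, overrides), so no state leaks between
# evaluations.

Z95 <- stats::qnorm(0.975)

#' Default sensitivity ranges for a configuration
#'
#' Combines the explicit ranges in `config$sensitivity$ranges` (typically
#' published low/high limits for transition probabilities) with automatic
#' ranges for parameters lacking them: costs and utilities get +/-20%
#' around base (utilities capped at 1, probabilities kept in `[0, 1]`),
#' and the annual discount rate ranges over `[0, 0.08]` (the span of
#' common pharmacoeconomic guideline rates).
#'
#' @param config A validated model configuration.
#' @return Data frame with columns `name`, `base`, `low`, `high`; bases
#'   are the resolved model parameters (see [resolve_parameters()]).
#' @export
default_ranges <- function(config) {
  params <- resolve_parameters(config)
  explicit <- config$sensitivity$ranges
  rows <- list()
  for (r in explicit) {
    if (!r$name %in% names(params)) {
      stop("sensitivity range names unknown parameter '", r$name, "'",
           call. = FALSE)
    }
    rows[[r$name]] <- param_range(r$name, params[[r$name]],
                                  min(r$low, params[[r$name]]),
                                  max(r$high, params[[r$name]]))
  }
  for (nm in setdiff(names(params), names(rows))) {
    base <- params[[nm]]
    if (nm == "annual_discount_rate") {
      lo <- min(0, base); hi <- max(0.08, base)
    } else if (grepl("^utility_", nm) || grepl("^p_", nm)) {
      lo <- max(0, base * 0.8); hi <- min(1, base * 1.2)
    } else {
      lo <- base * 0.8; hi <- base * 1.2
    }
    rows[[nm]] <- param_range(nm, base, lo, hi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Clamp a probability override to keep its transition row feasible
# (exit mass <= 1), holding the row's other exit probability at base.
# Returns list(value, clamped).
clamp_feasible <- function(name, value, params) {
  clamped <- FALSE
  if (grepl("^p_", name)) {
    new <- min(max(value, 0), 1)
    role <- sub("^p_[a-z]+_[a-z]+_", "", name)
    partner <- if (grepl("^p_pfs_pd_", name)) {
      paste0("p_pfs_death_", role)
    } else if (grepl("^p_pfs_death_", name)) {
      paste0("p_pfs_pd_", role)
    } else {
      NA_character_
    }
    if (!is.na(partner)) {
      room <- 1 - params[[partner]]
      if (new > room) {
        new <- room
        clamped <- TRUE
      }
    }
    if (new != value) clamped <- TRUE
    value <- new
  } else if (grepl("^utility_", name)) {
    new <- min(max(value, 0), 1)
    if (new != value) clamped <- TRUE
    value <- new
  } else if (grepl("^cost_", name) && value < 0) {
    value <- 0
    clamped <- TRUE
  }
  list(value = value, clamped = clamped)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full pipeline at each parameter's low and high bound,
#' holding all other parameters at base, and reports the resulting ICERs
#' and their span, sorted by span descending (tornado order).
#'
#' ICERs here are the signed raw ratio `delta_cost / delta_qalys`, which
#' stays defined (and plottable) when an evaluation crosses into a
#' dominance quadrant; the per-evaluation decision is also reported. An
#' evaluation whose perturbed probability would make a transition row's
#' exit mass exceed 1 is clamped to the feasible boundary and flagged,
#' never dropped.
#'
#' @param config A validated model configuration.
#' @param ranges Optional data frame of ranges (`name`, `base`, `low`,
#'   `high`); defaults to [default_ranges()].
#' @return Data frame of class `dsa_result`: `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`, `decision_at_low`,
#'   `decision_at_high`, `clamped`; attribute `base_icer` holds the
#'   base-case raw ratio.
#' @export
one_way_dsa <- function(config, ranges = NULL) {
  if (is.null(ranges)) ranges <- default_ranges(config)
  params <- resolve_parameters(config)
  base_run <- evaluate_model(config)
  eval_at <- function(name, value) {
    cl <- clamp_feasible(name, value, params)
    ov <- stats::setNames(cl$value, name)
    run <- evaluate_model(config, overrides = ov)
    list(icer = run$comparison$cost_per_qaly_ratio,
         decision = run$comparison$decision, clamped = cl$clamped)
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- eval_at(r$name, r$low)
    hi <- eval_at(r$name, r$high)
    data.frame(parameter = r$name, low = r$low, high = r$high,
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               span = abs(hi$icer - lo$icer),
               decision_at_low = lo$decision,
               decision_at_high = hi$decision,
               clamped = lo$clamped || hi$clamped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("dsa_result", "data.frame")
  attr(out, "base_icer") <- base_run$comparison$cost_per_qaly_ratio
  attr(out, "base_decision") <- base_run$comparison$decision
  out
}

# Beta draw with mean m and a 95% interval (low, high) interpreted via a
# normal approximation sd = (high - low) / (2 * 1.96); method-of-moments
# shapes. Falls back to uniform(low, high) with a warning when the
# implied variance is infeasible for a Beta.
rbeta_interval <- function(n, m, low, high) {
  sd <- (high - low) / (2 * Z95)
  if (sd <= 0 || m <= 0 || m >= 1) return(rep(m, n))
  v <- sd^2
  if (v >= m * (1 - m)) {
    warning("Beta moment matching infeasible for mean ", signif(m, 4),
            "; falling back to uniform(", signif(low, 4), ", ",
            signif(high, 4), ")", call. = FALSE)
    return(stats::runif(n, low, high))
  }
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, shape1 = m * k, shape2 = (1 - m) * k)
}

# Gamma draw with mean m and sd = sd_frac * m.
rgamma_meansd <- function(n, m, sd_frac) {
  if (m <= 0 || sd_frac <= 0) return(rep(m, n))
  shape <- 1 / sd_frac^2
  stats::rgamma(n, shape = shape, rate = shape / m)
}

#' Draw one sampled parameter set for probabilistic sensitivity analysis
#'
#' Distribution policy (`"default"`): transition probabilities and
#' utilities are drawn from Beta distributions with mean at base and the
#' low/high range treated as a 95% interval (method-of-moments shapes;
#' infeasible moment matching falls back to uniform(low, high) with a
#' warning); costs are drawn from Gamma distributions with mean at base
#' and SD equal to `config$sensitivity$cost_sd_frac` (default 25%) of the
#' mean. The discount rate is held fixed. The `"degenerate"` policy
#' returns the base parameters unchanged (zero-variance draws).
#'
#' PFS exit probabilities of the same arm are sampled independently and
#' the stay probability is renormalized downstream; draws whose exit mass
#' exceeds 1 are rejected and resampled (count in the `"rejections"`
#' attribute).
#'
#' @param config A validated model configuration.
#' @param dist_policy `"default"` or `"degenerate"`.
#' @param rng_seed Optional integer; when supplied, seeds the RNG before
#'   drawing (leave `NULL` inside a seeded loop).
#' @return Named numeric vector of sampled parameters (same names as
#'   [resolve_parameters()]), with attribute `"rejections"`.
#' @export
sample_params <- function(config, dist_policy = c("default", "degenerate"),
                          rng_seed = NULL) {
  dist_policy <- match.arg(dist_policy)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  base <- resolve_parameters(config)
  if (dist_policy == "degenerate") {
    return(structure(base, rejections = 0L))
  }
  ranges <- default_ranges(config)
  rng <- function(nm) ranges[ranges$name == nm, ]
  sd_frac <- config$sensitivity$cost_sd_frac %||% 0.25
  draw <- base
  rejections <- 0L
  for (nm in names(base)) {
    if (nm == "annual_discount_rate") next
    r <- rng(nm)
    if (grepl("^p_", nm) || grepl("^utility_", nm)) {
      draw[[nm]] <- rbeta_interval(1, base[[nm]], r$low, r$high)
    } else {
      draw[[nm]] <- rgamma_meansd(1, base[[nm]], sd_frac)
    }
  }
  for (role in ARM_ROLES) {
    nm1 <- paste0("p_pfs_pd_", role)
    nm2 <- paste0("p_pfs_death_", role)
    tries <- 0
    while (draw[[nm1]] + draw[[nm2]] > 1) {
      tries <- tries + 1
      if (tries > 1000) {
        stop("could not sample a feasible PFS row for arm '", role,
             "' after 1000 attempts", call. = FALSE)
      }
      r1 <- rng(nm1); r2 <- rng(nm2)
      draw[[nm1]] <- rbeta_interval(1, base[[nm1]], r1$low, r1$high)
      draw[[nm2]] <- rbeta_interval(1, base[[nm2]], r2$low, r2$high)
    }
    rejections <- rejections + tries
  }
  structure(draw, rejections = rejections)
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Runs `n_iter` full pipeline evaluations on parameter sets drawn by
#' [sample_params()], producing the cost-effectiveness-plane scatter of
#' incremental costs and QALYs. A draw that fails to evaluate is recorded
#' with status `"invalid"` and `NA` results; it never aborts the batch.
#'
#' @param config A validated model configuration.
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param rng_seed Integer seed (required for reproducibility).
#' @param dist_policy Passed to [sample_params()].
#' @return Data frame of class `psa_draws` with one row per draw:
#'   `draw`, `delta_cost`, `delta_qalys`, `icer` (`NA` under dominance),
#'   `dominance`, `decision`, plus the sampled parameters in `par_*`
#'   columns. Attributes: `wtp`, `rejections`.
#' @export
run_psa <- function(config, n_iter = 1000, rng_seed = NULL,
                    dist_policy = "default") {
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop("`n_iter` must be a positive count", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  base <- resolve_parameters(config)
  rejections <- 0L
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    sp <- sample_params(config, dist_policy = dist_policy)
    rejections <- rejections + attr(sp, "rejections")
    res <- tryCatch(evaluate_model(config, overrides = sp),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row <- data.frame(draw = i, delta_cost = NA_real_,
                        delta_qalys = NA_real_, icer = NA_real_,
                        dominance = "invalid", decision = "invalid",
                        stringsAsFactors = FALSE)
    } else {
      cmp <- res$comparison
      row <- data.frame(draw = i, delta_cost = cmp$delta_cost,
                        delta_qalys = cmp$delta_qalys, icer = cmp$icer,
                        dominance = cmp$dominance %||% NA_character_,
                        decision = cmp$decision,
                        stringsAsFactors = FALSE)
    }
    pars <- as.data.frame(as.list(sp))
    names(pars) <- paste0("par_", names(sp))
    rows[[i]] <- cbind(row, pars)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("psa_draws", "data.frame")
  attr(out, "wtp") <- config$global$wtp %||% 35906
  attr(out, "rejections") <- rejections
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' that the intervention is cost-effective is the fraction of PSA draws
#' with positive incremental net monetary benefit,
#' `lambda * delta_qalys - delta_cost > 0`. Invalid draws are excluded
#' from the denominator.
#'
#' @param draws A `psa_draws` data frame from [run_psa()].
#' @param wtp_grid Numeric grid of WTP values (USD/QALY); default 0 to
#'   150,000 in steps of 1,500.
#' @return Data frame of class `ceac_curve` with columns `wtp`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 150000, by = 1500)) {
  if (!is.data.frame(draws) || nrow(draws) == 0) {
    stop("`draws` must be a non-empty data frame of PSA draws",
         call. = FALSE)
  }
  if (length(wtp_grid) == 0 || any(wtp_grid < 0)) {
    stop("`wtp_grid` must be a non-empty grid of non-negative WTP values",
         call. = FALSE)
  }
  ok <- !is.na(draws$delta_qalys) & !is.na(draws$delta_cost)
  dc <- draws$delta_cost[ok]
  de <- draws$delta_qalys[ok]
  if (!length(dc)) stop("no valid draws", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

# WTP grid from a configuration's sensitivity block.
config_wtp_grid <- function(config) {
  g <- config$sensitivity$wtp_grid
  if (is.null(g)) return(seq(0, 150000, by = 1500))
  seq(g$from, g$to, by = g$by)
}
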