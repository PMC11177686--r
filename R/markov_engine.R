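#' Run a Markov cohort simulation
#'
#' Propagates a cohort occupancy vector through the monthly transition
#' matrix for `n_cycles` cycles. The whole cohort starts in PFS by default
#' (the decision point for a newly progressing patient population).
#'
#' @param matrix A validated `transition_matrix`
#'   (see [build_matrix()]).
#' @param n_cycles Number of monthly cycles; default 120 (10 years).
#' @param init Initial occupancy over (PFS, PD, Death); must sum to 1.
#' @return A data frame of class `cohort_trace` with columns `cycle`
#'   (0..`n_cycles`), `pfs`, `pd`, `death`.
#' @export
run_cohort <- function(matrix, n_cycles = 120, init = c(1, 0, 0)) {
  validate_transition_matrix(matrix)
  if (!is.numeric(init) || length(init) != 3 || any(init < 0) ||
      abs(sum(init) - 1) > 1e-9) {
    stop("`init` must be 3 non-negative occupancy fractions summing to 1",
         call. = FALSE)
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  }
  occ <- base::matrix(0, nrow = n_cycles + 1, ncol = 3)
  occ[1, ] <- init
  m <- unclass(matrix)
  for (t in seq_len(n_cycles)) {
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  out <- data.frame(cycle = 0:n_cycles, pfs = occ[, 1], pd = occ[, 2],
                    death = occ[, 3])
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "arm_label") <- attr(matrix, "arm_label")
  out
}

#' Economic inputs for one arm
#'
#' Per-cycle, per-state costs in USD; per-year health-state utilities
#' (QALY weights, converted to per-cycle by dividing by 12); the annual
#' discount rate; and the willingness-to-pay threshold.
#'
#' @param cost_pfs_per_cycle,cost_pd_per_cycle State costs in USD per
#'   monthly cycle.
#' @param cost_death Per-cycle cost of the Death state (USD), default 0
#'   (no terminal-care cost).
#' @param utility_pfs,utility_pd,utility_death QALY weights per year,
#'   each in `[0, 1]`.
#' @param annual_discount_rate Annual discount rate as a fraction in
#'   `[0, 1)`; default 0.05.
#' @param wtp Willingness-to-pay threshold in USD/QALY; default 35906
#'   (three times China's 2022 per-capita GDP).
#' @return An object of class `economic_inputs`.
#' @export
economic_inputs <- function(cost_pfs_per_cycle, cost_pd_per_cycle,
                            cost_death = 0,
                            utility_pfs = 0.89, utility_pd = 0.74,
                            utility_death = 0,
                            annual_discount_rate = 0.05, wtp = 35906) {
  for (fld in c("cost_pfs_per_cycle", "cost_pd_per_cycle", "cost_death")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("`", fld, "` must be a single non-negative cost (USD)",
           call. = FALSE)
    }
  }
  for (fld in c("utility_pfs", "utility_pd", "utility_death")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("`", fld, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(annual_discount_rate) || length(annual_discount_rate) != 1 ||
      is.na(annual_discount_rate) || annual_discount_rate < 0 ||
      annual_discount_rate >= 1) {
    stop("`annual_discount_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(wtp) || length(wtp) != 1 || is.na(wtp) || wtp <= 0) {
    stop("`wtp` must be a positive USD/QALY threshold", call. = FALSE)
  }
  structure(
    list(cost_pfs_per_cycle = cost_pfs_per_cycle,
         cost_pd_per_cycle = cost_pd_per_cycle,
         cost_death = cost_death,
         utility_pfs = utility_pfs, utility_pd = utility_pd,
         utility_death = utility_death,
         annual_discount_rate = annual_discount_rate, wtp = wtp),
    class = "economic_inputs"
  )
}

# Monthly discount factors d(t) = (1 + r)^(-t/12) for cycles t = 1..n:
# the continuous-equivalent of an annual rate applied to monthly cycles.
discount_factors <- function(n_cycles, annual_rate) {
  (1 + annual_rate)^(-(seq_len(n_cycles)) / 12)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Accrual convention: each cycle `t = 1..N` accrues
#' `occupancy(t) * state_cost * d(t)` in cost and
#' `occupancy(t) * (state_utility / 12) * d(t)` in QALYs, with
#' `d(t) = (1 + annual_discount_rate)^(-t/12)`. Cycle 0 (the decision
#' point) accrues nothing. With `half_cycle = TRUE` the standard half-cycle
#' correction is applied: each cycle uses the average of its entry
#' (`t - 1`) and exit (`t`) occupancy instead.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param econ An [economic_inputs()] object.
#' @param half_cycle Apply the half-cycle correction? Default `FALSE`.
#' @return An object of class `arm_result`: `total_cost`, `total_qalys`
#'   (both discounted), `cost_by_state`, `qalys_by_state`,
#'   `state_months` (discounted person-months per state), plus the arm
#'   label and accounting flags.
#' @export
accrue <- function(trace, econ, half_cycle = FALSE) {
  if (!inherits(trace, "cohort_trace")) {
    stop("`trace` must be a `cohort_trace`", call. = FALSE)
  }
  if (!inherits(econ, "economic_inputs")) {
    stop("`econ` must be an `economic_inputs` object", call. = FALSE)
  }
  n <- nrow(trace) - 1
  occ <- as.matrix(trace[, c("pfs", "pd", "death")])
  o <- occ[-1, , drop = FALSE]
  if (isTRUE(half_cycle)) {
    o <- (o + occ[-(n + 1), , drop = FALSE]) / 2
  }
  d <- discount_factors(n, econ$annual_discount_rate)
  costs <- c(econ$cost_pfs_per_cycle, econ$cost_pd_per_cycle,
             econ$cost_death)
  utils_yr <- c(econ$utility_pfs, econ$utility_pd, econ$utility_death)
  disc_months <- as.numeric(crossprod(o, d))      # discounted months/state
  cost_by_state <- disc_months * costs
  qalys_by_state <- disc_months * utils_yr / 12
  names(disc_months) <- names(cost_by_state) <- names(qalys_by_state) <-
    STATES
  structure(
    list(arm_label = attr(trace, "arm_label"),
         total_cost = sum(cost_by_state),
         total_qalys = sum(qalys_by_state),
         cost_by_state = cost_by_state,
         qalys_by_state = qalys_by_state,
         state_months = disc_months,
         n_cycles = n, half_cycle = isTRUE(half_cycle)),
    class = "arm_result"
  )
}

#' Closed-form discounted expected time in a transient state
#'
#' Analytic counterpart of trace-based accrual for the 3-state chain with
#' no PD -> PFS reversion, used as an independent oracle. Writing `p` for
#' the PFS stay probability, `q` for the PD stay probability and `a` for
#' the monthly discount factor, the discounted expected months counted at
#' cycles `1..N` are
#' \deqn{PFS: \sum_{t=1}^{N} (ap)^t}
#' \deqn{PD: p_{PFS \to PD} \sum_{k=1}^{N} p^{k-1} a^k
#'   \frac{1 - (aq)^{N-k+1}}{1 - aq}}
#' (the PD occupancy at cycle `t` is a convolution of the geometric PFS
#' survivor mass with the geometric PD holding time).
#'
#' @param matrix A validated `transition_matrix`.
#' @param state `"PFS"` or `"PD"`.
#' @param monthly_discount Per-cycle discount factor `a` in `(0, 1]`
#'   (1 = undiscounted).
#' @param n_cycles Horizon; `Inf` gives the infinite-horizon limit.
#' @return Discounted expected months spent in `state` over cycles
#'   `1..n_cycles`, for a cohort starting wholly in PFS.
#' @export
expected_state_time_closed_form <- function(matrix, state = c("PFS", "PD"),
                                            monthly_discount = 1,
                                            n_cycles = 120) {
  state <- match.arg(state)
  validate_transition_matrix(matrix)
  a <- monthly_discount
  if (!is.numeric(a) || length(a) != 1 || a <= 0 || a > 1) {
    stop("`monthly_discount` must lie in (0, 1]", call. = FALSE)
  }
  p <- matrix[1, 1]
  q <- matrix[2, 2]
  p_pd <- matrix[1, 2]
  geom_sum <- function(x, n) {
    # sum_{t=1}^{n} x^t, stable at x = 1 and n = Inf (requires x < 1)
    if (is.infinite(n)) {
      if (x >= 1) stop("infinite-horizon sum diverges for ratio >= 1",
                       call. = FALSE)
      return(x / (1 - x))
    }
    if (abs(x - 1) < 1e-14) return(n)
    x * (1 - x^n) / (1 - x)
  }
  if (state == "PFS") {
    return(geom_sum(a * p, n_cycles))
  }
  if (is.infinite(n_cycles)) {
    if (a * p >= 1 || a * q >= 1) {
      stop("infinite-horizon PD time diverges (non-absorbing chain)",
           call. = FALSE)
    }
    return(p_pd * a / ((1 - a * p) * (1 - a * q)))
  }
  k <- seq_len(n_cycles)
  inner <- if (abs(a * q - 1) < 1e-14) {
    n_cycles - k + 1
  } else {
    (1 - (a * q)^(n_cycles - k + 1)) / (1 - a * q)
  }
  sum(p_pd * p^(k - 1) * a^k * inner)
}

#' @export
print.arm_result <- function(x, ...) {
  cat("Discounted arm result - '", x$arm_label, "' (", x$n_cycles,
      " cycles", if (x$half_cycle) ", half-cycle corrected", ")\n",
      sep = "")
  cat(sprintf("  total cost:  $%.2f\n", x$total_cost))
  cat(sprintf("  total QALYs: %.4f\n", x$total_qalys))
  invisible(x)
}
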