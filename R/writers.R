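# CSV writers for every pipeline artifact. All outputs are plain
# comma-separated UTF-8 with a header row and '.' decimal; monetary
# columns are suffixed `_usd`.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write derived transition probabilities as CSV
#'
#' Columns: `arm`, `transition`, `value`, `source`
#' (`"derived"`/`"fixture"`).
#'
#' @param tps A `transition_probs` object or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transitions_csv <- function(tps, path) {
  if (inherits(tps, "transition_probs")) tps <- list(tps)
  write_csv_plain(do.call(rbind, lapply(tps, transitions_table)), path)
}

#' Write a cohort trace as CSV
#'
#' Columns: `cycle`, `pfs`, `pd`, `death`, `discount_factor` (the
#' factor applied to accrual in that cycle; 1 at cycle 0).
#'
#' @param trace A `cohort_trace`.
#' @param annual_discount_rate Annual discount rate used for the
#'   `discount_factor` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, annual_discount_rate = 0.05) {
  n <- nrow(trace) - 1
  trace$discount_factor <- c(1, discount_factors(n, annual_discount_rate))
  write_csv_plain(as.data.frame(trace), path)
}

#' Write an arm result (by-state and total cost/QALYs) as CSV
#'
#' @param result An `arm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arm_result_csv <- function(result, path) {
  df <- data.frame(
    arm = result$arm_label,
    state = c(STATES, "total"),
    cost_usd = c(result$cost_by_state, result$total_cost),
    qalys = c(result$qalys_by_state, result$total_qalys),
    discounted_months = c(result$state_months, sum(result$state_months)),
    stringsAsFactors = FALSE
  )
  write_csv_plain(df, path)
}

#' Write a two-arm comparison as CSV
#'
#' Mirrors the conventional cost-effectiveness results table: per-state
#' costs and QALYs, totals, increments, per-arm C/E ratios, ICER and NMB.
#'
#' @param run A `cea_model_run` from [evaluate_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(run, path) {
  df <- comparison_table(run$intervention$result, run$comparator$result,
                         run$comparison)
  write_csv_plain(df, path)
}

#' Write a tornado (one-way DSA) table as CSV
#'
#' @param dsa A `dsa_result` from [one_way_dsa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(dsa, path) {
  write_csv_plain(as.data.frame(dsa), path)
}

#' Write PSA draws as CSV
#'
#' @param draws A `psa_draws` from [run_psa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(draws, path) {
  write_csv_plain(as.data.frame(draws), path)
}

#' Write a CEAC as CSV
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  write_csv_plain(as.data.frame(curve), path)
}

#' Write a synthetic trial arm as CSV
#'
#' Columns: `patient_id`, `pfs_months`, `os_months`, `arm`.
#'
#' @param arm A `synthetic_trial_arm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(arm, path) {
  df <- as.data.frame(arm)
  df$arm <- attr(arm, "arm_label") %||% "synthetic"
  write_csv_plain(df, path)
}
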