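#' Compare two arm results: incremental cost-effectiveness
#'
#' Computes incremental cost and effectiveness (intervention minus
#' comparator), the incremental cost-effectiveness ratio (ICER), per-arm
#' cost-effectiveness ratios and net monetary benefit (NMB), and the
#' decision at a willingness-to-pay (WTP) threshold.
#'
#' Dominance handling: when the increments have opposite favourable signs
#' the ICER is not interpretable and is reported as `NA` with a dominance
#' flag — `"dominant"` (cheaper and more effective) or `"dominated"`
#' (costlier and less effective). The raw ratio
#' `delta_cost / delta_qalys` is always retained in `cost_per_qaly_ratio`
#' for diagnostics such as tornado diagrams. Identical arms yield the
#' `"equivalent"` decision; `delta_qalys == 0` with nonzero `delta_cost`
#' yields a signed-infinite ICER with the corresponding dominance
#' annotation.
#'
#' The decision is `"cost-effective"` iff the incremental NMB
#' `wtp * delta_qalys - delta_cost` is positive (equivalently
#' `ICER < wtp` with `delta_qalys > 0`, or dominance of the intervention).
#'
#' @param intervention,comparator `arm_result` objects from [accrue()].
#' @param wtp Willingness-to-pay threshold in USD/QALY.
#' @return An object of class `cea_comparison`.
#' @export
compare_arms <- function(intervention, comparator, wtp = 35906) {
  for (a in list(intervention, comparator)) {
    if (!inherits(a, "arm_result")) {
      stop("arms must be `arm_result` objects", call. = FALSE)
    }
  }
  if (!is.numeric(wtp) || length(wtp) != 1 || wtp <= 0) {
    stop("`wtp` must be a positive USD/QALY threshold", call. = FALSE)
  }
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qalys - comparator$total_qalys
  ratio <- if (de != 0) dc / de else sign(dc) * Inf   # NaN-free raw ratio
  inmb <- wtp * de - dc

  dominance <- NA_character_
  icer <- ratio
  if (dc == 0 && de == 0) {
    dominance <- "equivalent"
    icer <- NA_real_
  } else if (de > 0 && dc <= 0) {
    dominance <- "dominant"
    icer <- NA_real_
  } else if (de < 0 && dc >= 0) {
    dominance <- "dominated"
    icer <- NA_real_
  } else if (de == 0) {
    dominance <- if (dc > 0) "dominated" else "dominant"
  }

  decision <- if (identical(dominance, "equivalent")) {
    "equivalent"
  } else if (identical(dominance, "dominant")) {
    "dominant"
  } else if (identical(dominance, "dominated")) {
    "dominated"
  } else if (inmb > 0) {
    "cost-effective"
  } else {
    "not-cost-effective"
  }

  nmb <- c(intervention = wtp * intervention$total_qalys -
             intervention$total_cost,
           comparator = wtp * comparator$total_qalys -
             comparator$total_cost)
  ce_ratio <- c(
    intervention = intervention$total_cost / intervention$total_qalys,
    comparator = comparator$total_cost / comparator$total_qalys)

  structure(
    list(intervention_label = intervention$arm_label,
         comparator_label = comparator$arm_label,
         delta_cost = dc, delta_qalys = de,
         icer = icer, cost_per_qaly_ratio = ratio,
         dominance = dominance, decision = decision,
         nmb = nmb, incremental_nmb = inmb,
         ce_ratio = ce_ratio, wtp = wtp),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Cost-effectiveness comparison: '", x$intervention_label, "' vs '",
      x$comparator_label, "' (WTP $", format(x$wtp, big.mark = ","),
      "/QALY)\n", sep = "")
  cat(sprintf("  incremental cost:  $%.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs: %.4f\n", x$delta_qalys))
  if (is.na(x$icer)) {
    cat("  ICER: not reported (", x$dominance, ")\n", sep = "")
  } else {
    cat(sprintf("  ICER: $%.2f/QALY\n", x$icer))
  }
  cat(sprintf("  incremental NMB:   $%.2f\n", x$incremental_nmb))
  cat("  decision: ", x$decision, "\n", sep = "")
  invisible(x)
}

# Comparison in the row layout used by the CSV writer: per-state and total
# costs/QALYs per arm, increments, per-arm C/E ratios, ICER.
comparison_table <- function(res_int, res_comp, cmp) {
  row <- function(parameter, int, comp) {
    data.frame(parameter = parameter, intervention = int,
               comparator = comp, stringsAsFactors = FALSE)
  }
  rbind(
    row("cost_pfs_usd", res_int$cost_by_state[["PFS"]],
        res_comp$cost_by_state[["PFS"]]),
    row("cost_pd_usd", res_int$cost_by_state[["PD"]],
        res_comp$cost_by_state[["PD"]]),
    row("qalys_pfs", res_int$qalys_by_state[["PFS"]],
        res_comp$qalys_by_state[["PFS"]]),
    row("qalys_pd", res_int$qalys_by_state[["PD"]],
        res_comp$qalys_by_state[["PD"]]),
    row("total_cost_usd", res_int$total_cost, res_comp$total_cost),
    row("total_qalys", res_int$total_qalys, res_comp$total_qalys),
    row("incremental_cost_usd", cmp$delta_cost, NA),
    row("incremental_qalys", cmp$delta_qalys, NA),
    row("ce_ratio_usd_per_qaly", cmp$ce_ratio[["intervention"]],
        cmp$ce_ratio[["comparator"]]),
    row("icer_usd_per_qaly", cmp$icer, NA),
    row("nmb_usd", cmp$nmb[["intervention"]], cmp$nmb[["comparator"]])
  )
}
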