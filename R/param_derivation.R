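# Health-state labels, in transition-matrix order. PD (progressed disease)
# is non-reversible and Death is absorbing.
STATES <- c("PFS", "PD", "Death")

#' Monthly transition probability from a median time-to-event
#'
#' Converts a median time-to-event (in months) into a per-cycle (monthly)
#' transition probability under a constant-hazard assumption:
#' \deqn{p = 1 - 0.5^{1/m} = 1 - e^{-\ln(2)/m}}
#' where `m` is the median in months. The two forms are algebraically
#' identical because the exponential hazard satisfying \eqn{S(m) = 0.5} is
#' \eqn{R = \ln(2)/m}.
#'
#' @param median Median time-to-event in months. Must be strictly positive;
#'   `Inf` is accepted and maps to probability 0 (no events).
#' @return A probability per monthly cycle in `[0, 1)`, strictly decreasing
#'   in `median`. `median = 1` gives exactly 0.5 (half the cohort has the
#'   event within one median).
#' @examples
#' monthly_prob_from_median(1.5)  # 0.3700...
#' monthly_prob_from_median(4.2)  # 0.1522...
#' @export
monthly_prob_from_median <- function(median) {
  if (!is.numeric(median) || length(median) == 0 || anyNA(median)) {
    stop("`median` must be a numeric time-to-event in months", call. = FALSE)
  }
  if (any(median <= 0)) {
    stop("`median` must be strictly positive (months); got ",
         paste(median[median <= 0], collapse = ", "), call. = FALSE)
  }
  ifelse(is.infinite(median), 0, 1 - 0.5^(1 / median))
}

#' Clinical inputs for one treatment arm
#'
#' Bundles the two trial summary statistics the model consumes per arm:
#' median progression-free survival (PFS) and median overall survival (OS),
#' both in months.
#'
#' @param arm_label Character label for the arm (e.g. `"BEV+LOM"`).
#' @param median_pfs Median PFS in months, strictly positive (`Inf` allowed).
#' @param median_os Median OS in months, strictly positive (`Inf` allowed);
#'   must satisfy `median_os >= median_pfs`.
#' @return An object of class `arm_clinical_inputs`.
#' @export
arm_clinical_inputs <- function(arm_label, median_pfs, median_os) {
  stopifnot(is.character(arm_label), length(arm_label) == 1)
  for (fld in c("median_pfs", "median_os")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop("`", fld, "` must be a single strictly positive number of months",
           call. = FALSE)
    }
  }
  if (median_os < median_pfs) {
    stop("`median_os` (", median_os, ") must be >= `median_pfs` (",
         median_pfs, ")", call. = FALSE)
  }
  structure(
    list(arm_label = arm_label, median_pfs = median_pfs,
         median_os = median_os),
    class = "arm_clinical_inputs"
  )
}

#' Construct a validated set of monthly transition probabilities
#'
#' Stay probabilities, when not supplied, are computed as complements of the
#' exit probabilities (`p_pfs_pfs = 1 - p_pfs_pd - p_pfs_death`,
#' `p_pd_pd = 1 - p_pd_death`).
#'
#' @param arm_label Character label for the arm.
#' @param p_pfs_pd,p_pfs_death,p_pd_death Exit probabilities per cycle.
#' @param p_pfs_pfs,p_pd_pd Optional stay probabilities; default complements.
#' @param source `"derived"` (computed from medians) or `"fixture"`
#'   (externally supplied, e.g. a published rounded table).
#' @return An object of class `transition_probs`.
#' @export
transition_probs <- function(arm_label, p_pfs_pd, p_pfs_death, p_pd_death,
                             p_pfs_pfs = NULL, p_pd_pd = NULL,
                             source = "derived") {
  for (fld in c("p_pfs_pd", "p_pfs_death", "p_pd_death")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("`", fld, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p_pfs_pd + p_pfs_death > 1 + 1e-12) {
    stop("PFS exit probabilities sum to ", p_pfs_pd + p_pfs_death,
         " > 1; no valid stay probability exists", call. = FALSE)
  }
  if (is.null(p_pfs_pfs)) p_pfs_pfs <- 1 - p_pfs_pd - p_pfs_death
  if (is.null(p_pd_pd)) p_pd_pd <- 1 - p_pd_death
  structure(
    list(arm_label = arm_label,
         p_pfs_pd = p_pfs_pd, p_pfs_death = p_pfs_death,
         p_pd_death = p_pd_death,
         p_pfs_pfs = p_pfs_pfs, p_pd_pd = p_pd_pd,
         source = source),
    class = "transition_probs"
  )
}

#' Derive monthly transition probabilities from arm medians
#'
#' Maps the three constant hazards of the three-state model to the arm's
#' trial medians:
#' * PFS -> PD uses the median PFS;
#' * PFS -> Death uses the median OS;
#' * PD -> Death uses the post-progression median, `median_os - median_pfs`.
#'
#' Each median is converted with [monthly_prob_from_median()]; stay
#' probabilities are complements, computed at full floating-point precision
#' (published tables typically print these rounded to two decimals).
#'
#' @param arm An [arm_clinical_inputs()] object with
#'   `median_os > median_pfs` (when both are finite; an infinite
#'   `median_os` encodes an arm with no deaths).
#' @return A [transition_probs()] object with `source = "derived"`.
#' @export
derive_arm_transitions <- function(arm) {
  if (!inherits(arm, "arm_clinical_inputs")) {
    stop("`arm` must be an `arm_clinical_inputs` object", call. = FALSE)
  }
  if (is.infinite(arm$median_os)) {
    p_death <- 0
    p_pd_death <- 0
  } else {
    if (arm$median_os <= arm$median_pfs) {
      stop("`median_os` must exceed `median_pfs` (arm '", arm$arm_label,
           "'): the post-progression median median_os - median_pfs, which ",
           "sets the PD->Death hazard, is otherwise undefined",
           call. = FALSE)
    }
    p_death <- monthly_prob_from_median(arm$median_os)
    p_pd_death <- monthly_prob_from_median(arm$median_os - arm$median_pfs)
  }
  transition_probs(
    arm_label = arm$arm_label,
    p_pfs_pd = monthly_prob_from_median(arm$median_pfs),
    p_pfs_death = p_death,
    p_pd_death = p_pd_death,
    source = "derived"
  )
}

#' Assemble a validated 3x3 transition matrix
#'
#' Builds the row-stochastic monthly transition matrix over the states
#' PFS, PD, Death from a set of transition probabilities. Death is
#' absorbing and PD cannot revert to PFS.
#'
#' When the supplied stay probabilities are inconsistent with the exit
#' probabilities (typical for published tables rounded to two decimals,
#' whose rows may not sum to 1), the `"complement"` policy recomputes each
#' stay probability as the complement of its row's exit probabilities and
#' records a provenance note (exit probabilities carry the clinical signal;
#' the stay probability is the residual). The `"strict"` policy errors
#' instead.
#'
#' @param tp A [transition_probs()] object.
#' @param policy `"complement"` (default) or `"strict"`.
#' @param tol Discrepancy above which an adjustment is noted / rejected.
#' @return A 3x3 matrix of class `transition_matrix` with a `notes`
#'   attribute (character vector of adjustments, possibly empty) and an
#'   `arm_label` attribute.
#' @export
build_matrix <- function(tp, policy = c("complement", "strict"),
                         tol = 1e-9) {
  policy <- match.arg(policy)
  if (!inherits(tp, "transition_probs")) {
    stop("`tp` must be a `transition_probs` object", call. = FALSE)
  }
  if (tp$p_pfs_pd + tp$p_pfs_death > 1 + 1e-12) {
    stop("PFS exit probabilities sum to more than 1; cannot normalize by ",
         "complement", call. = FALSE)
  }
  notes <- character()
  stay_pfs <- 1 - tp$p_pfs_pd - tp$p_pfs_death
  stay_pd <- 1 - tp$p_pd_death
  if (abs(stay_pfs - tp$p_pfs_pfs) > tol) {
    msg <- sprintf(
      "PFS row: supplied stay probability %.4f replaced by complement %.4f (row summed to %.4f)",
      tp$p_pfs_pfs, stay_pfs, tp$p_pfs_pfs + tp$p_pfs_pd + tp$p_pfs_death)
    if (policy == "strict") stop(msg, call. = FALSE)
    notes <- c(notes, msg)
  }
  if (abs(stay_pd - tp$p_pd_pd) > tol) {
    msg <- sprintf(
      "PD row: supplied stay probability %.4f replaced by complement %.4f (row summed to %.4f)",
      tp$p_pd_pd, stay_pd, tp$p_pd_pd + tp$p_pd_death)
    if (policy == "strict") stop(msg, call. = FALSE)
    notes <- c(notes, msg)
  }
  m <- rbind(
    c(stay_pfs, tp$p_pfs_pd, tp$p_pfs_death),
    c(0,        stay_pd,     tp$p_pd_death),
    c(0,        0,           1)
  )
  dimnames(m) <- list(from = STATES, to = STATES)
  structure(m, class = c("transition_matrix", "matrix"),
            notes = notes, arm_label = tp$arm_label)
}

#' Validate a 3x3 transition matrix
#'
#' Checks row-stochasticity (each row sums to 1 within `tol`), entries in
#' `[0, 1]`, an absorbing Death state, and no PD -> PFS reversion.
#'
#' @param m A 3x3 numeric matrix (rows = from-state, order PFS, PD, Death).
#' @param tol Row-sum tolerance.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_transition_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || !is.numeric(m)) {
    stop("transition matrix must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(m) - 1) > tol)) {
    stop("transition matrix rows must sum to 1 (within ", tol, ")",
         call. = FALSE)
  }
  if (any(abs(m[3, ] - c(0, 0, 1)) > tol)) {
    stop("Death must be absorbing: last row must be [0, 0, 1]",
         call. = FALSE)
  }
  if (abs(m[2, 1]) > tol) {
    stop("PD -> PFS transitions are not allowed (progression is ",
         "non-reversible)", call. = FALSE)
  }
  invisible(m)
}

#' A named parameter range for sensitivity analysis
#'
#' @param name Parameter name (see [resolve_parameters()] for the registry
#'   of perturbable names).
#' @param base,low,high Base-case value and range bounds,
#'   `low <= base <= high`.
#' @return A one-row data frame with columns `name`, `base`, `low`, `high`.
#' @export
param_range <- function(name, base, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  if (!all(is.finite(c(base, low, high)))) {
    stop("range for '", name, "' must be finite", call. = FALSE)
  }
  if (low > base || base > high) {
    stop("range for '", name, "' must satisfy low <= base <= high (got ",
         low, " / ", base, " / ", high, ")", call. = FALSE)
  }
  data.frame(name = name, base = base, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' @export
print.transition_probs <- function(x, ...) {
  cat("Monthly transition probabilities (", x$source, ") - arm '",
      x$arm_label, "'\n", sep = "")
  v <- unlist(x[c("p_pfs_pfs", "p_pfs_pd", "p_pfs_death", "p_pd_pd",
                  "p_pd_death")])
  print(round(v, 4))
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Monthly transition matrix - arm '", attr(x, "arm_label"), "'\n",
      sep = "")
  print(unclass(x)[, , drop = FALSE])
  for (n in attr(x, "notes")) cat("note: ", n, "\n", sep = "")
  invisible(x)
}

# Tidy table of transition probabilities, one row per transition; the
# shape used by the CSV writer.
transitions_table <- function(tp) {
  data.frame(
    arm = tp$arm_label,
    transition = c("PFS->PFS", "PFS->PD", "PFS->Death", "PD->PD",
                   "PD->Death"),
    value = c(tp$p_pfs_pfs, tp$p_pfs_pd, tp$p_pfs_death, tp$p_pd_pd,
              tp$p_pd_death),
    source = tp$source,
    stringsAsFactors = FALSE
  )
}
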