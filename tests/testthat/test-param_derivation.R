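test_that("median-to-probability conversion matches both closed forms and limits", {
  # m = 1: half the cohort has the event by the median
  expect_identical(monthly_prob_from_median(1), 0.5)
  # the two printed forms are the same function of m
  m <- c(0.1, 0.5, 1, 1.5, 4.2, 4.9, 7.1, 8.6, 9.1, 25, 1000)
  expect_equal(monthly_prob_from_median(m), 1 - exp(-log(2) / m),
               tolerance = 1e-12)
  # strictly decreasing in m; limits 1 (m -> 0) and 0 (m -> Inf)
  grid <- sort(stats::runif(200, 0.01, 200))
  expect_true(all(diff(monthly_prob_from_median(grid)) < 0))
  expect_gt(monthly_prob_from_median(1e-9), 1 - 1e-6)
  expect_identical(monthly_prob_from_median(Inf), 0)
  # domain errors name the offending input
  expect_error(monthly_prob_from_median(0), "median")
  expect_error(monthly_prob_from_median(-2), "median")
  expect_error(monthly_prob_from_median("a"), "median")
})

test_that("derived arm transitions reproduce the published 2-dp baselines", {
  lom <- derive_arm_transitions(arm_clinical_inputs("LOM", 1.5, 8.6))
  # independent closed form: exponential hazard ln2/m per transition
  p <- function(m) 1 - exp(-log(2) / m)
  expect_equal(lom$p_pfs_pd, p(1.5), tolerance = 1e-12)
  expect_equal(lom$p_pfs_death, p(8.6), tolerance = 1e-12)
  expect_equal(lom$p_pd_death, p(8.6 - 1.5), tolerance = 1e-12)
  expect_equal(
    round(unlist(lom[c("p_pfs_pd", "p_pfs_death", "p_pd_death",
                       "p_pfs_pfs", "p_pd_pd")]), 2),
    c(p_pfs_pd = 0.37, p_pfs_death = 0.08, p_pd_death = 0.09,
      p_pfs_pfs = 0.55, p_pd_pd = 0.91))

  bev <- derive_arm_transitions(arm_clinical_inputs("BEV+LOM", 4.2, 9.1))
  expect_equal(
    round(unlist(bev[c("p_pfs_pd", "p_pfs_death", "p_pd_death",
                       "p_pd_pd")]), 2),
    c(p_pfs_pd = 0.15, p_pfs_death = 0.07, p_pd_death = 0.13,
      p_pd_pd = 0.87))
  # the full-precision complement is 0.7744, which rounds to the printed
  # 0.77 even though the printed row's own 2-dp entries sum to 0.99
  # (1 - 0.15 - 0.07 = 0.78): the inconsistency is a rounding artifact of
  # the printed exits, not of the derivation
  expect_equal(round(bev$p_pfs_pfs, 2), 0.77)

  # complements are exact, not read from a table
  expect_equal(bev$p_pfs_pfs, 1 - bev$p_pfs_pd - bev$p_pfs_death,
               tolerance = 1e-15)
  expect_equal(bev$p_pd_pd, 1 - bev$p_pd_death, tolerance = 1e-15)
})

test_that("degenerate and invalid medians are handled explicitly", {
  # no-death arm: infinite OS maps both death hazards to zero
  arm <- derive_arm_transitions(arm_clinical_inputs("x", 3, Inf))
  expect_identical(arm$p_pfs_death, 0)
  expect_identical(arm$p_pd_death, 0)
  # OS <= PFS leaves the post-progression hazard undefined
  expect_error(derive_arm_transitions(arm_clinical_inputs("x", 5, 5)),
               "median_os")
  expect_error(arm_clinical_inputs("x", 5, 4), "median_os")
  expect_error(arm_clinical_inputs("x", -1, 4), "median_pfs")
})

test_that("matrix assembly is row-stochastic with Death absorbing", {
  for (arm in list(c(1.5, 8.6), c(4.2, 9.1))) {
    m <- build_matrix(derive_arm_transitions(
      arm_clinical_inputs("a", arm[1], arm[2])))
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-15)
    expect_identical(unname(unclass(m)[3, ]), c(0, 0, 1))
    expect_identical(unclass(m)[2, 1], 0)
    expect_length(attr(m, "notes"), 0)
  }
})

test_that("externally supplied rounded rows follow the normalization policy", {
  # published intervention PFS row sums to 0.99
  printed <- transition_probs("BEV+LOM", p_pfs_pd = 0.15,
                              p_pfs_death = 0.07, p_pd_death = 0.13,
                              p_pfs_pfs = 0.77, p_pd_pd = 0.87,
                              source = "fixture")
  m <- build_matrix(printed, policy = "complement")
  expect_equal(unclass(m)["PFS", "PFS"], 0.78, tolerance = 1e-12)
  expect_length(attr(m, "notes"), 1)
  expect_match(attr(m, "notes"), "0.7700.*0.7800")
  # the PD row (0.87 = 1 - 0.13) needs no repair
  expect_equal(unclass(m)["PD", "PD"], 0.87, tolerance = 1e-12)
  # strict policy refuses to repair
  expect_error(build_matrix(printed, policy = "strict"), "replaced")
  # exit mass > 1 cannot be normalized by complement
  expect_error(transition_probs("x", p_pfs_pd = 0.6, p_pfs_death = 0.6,
                                p_pd_death = 0.1),
               "sum")
})

test_that("parameter ranges enforce low <= base <= high", {
  r <- param_range("u", 0.5, 0.4, 0.6)
  expect_identical(r$name, "u")
  expect_error(param_range("u", 0.3, 0.4, 0.6), "low <= base <= high")
  expect_error(param_range("u", 0.7, 0.4, 0.6), "low <= base <= high")
  expect_error(param_range("u", Inf, 0.4, 0.6), "finite")
})
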