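test_that("a cohort with no exit hazards never moves", {
  m <- build_matrix(transition_probs("static", 0, 0, 0))
  tr <- run_cohort(m, n_cycles = 12)
  expect_equal(nrow(tr), 13)
  expect_true(all(tr$pfs == 1) && all(tr$pd == 0) && all(tr$death == 0))
})

test_that("one cycle of the comparator matrix moves the cohort by one row of probabilities", {
  tp <- derive_arm_transitions(arm_clinical_inputs("LOM", 1.5, 8.6))
  tr <- run_cohort(build_matrix(tp), n_cycles = 3)
  expect_equal(tr$pfs[2], tp$p_pfs_pfs, tolerance = 1e-15)
  expect_equal(tr$pd[2], tp$p_pfs_pd, tolerance = 1e-15)
  expect_equal(tr$death[2], tp$p_pfs_death, tolerance = 1e-15)
})

test_that("occupancy is conserved and monotone over random chains", {
  set.seed(101)
  for (i in 1:1000) {
    tr <- run_cohort(random_matrix(), n_cycles = 24)
    occ <- tr$pfs + tr$pd + tr$death
    expect_true(all(abs(occ - 1) <= 1e-12))
    expect_true(all(diff(tr$death) >= -1e-15))   # absorbing state
    expect_true(all(diff(tr$pfs) <= 1e-15))      # no re-entry into PFS
  }
})

test_that("input validation rejects bad matrices and occupancies", {
  m <- build_matrix(transition_probs("x", 0.2, 0.1, 0.3))
  expect_error(run_cohort(m, init = c(0.5, 0.2, 0.2)), "sum")
  expect_error(run_cohort(m, n_cycles = 0), "positive integer")
  bad <- unclass(m); bad[3, ] <- c(0.1, 0, 0.9)
  expect_error(validate_transition_matrix(bad), "absorbing")
  bad2 <- unclass(m); bad2[2, 1] <- 0.1; bad2[2, 2] <- bad2[2, 2] - 0.1
  expect_error(validate_transition_matrix(bad2), "non-reversible")
})

test_that("undiscounted accrual at full utility counts months alive", {
  m <- build_matrix(transition_probs("static", 0, 0, 0))
  tr <- run_cohort(m, n_cycles = 120)
  econ <- economic_inputs(0, 0, utility_pfs = 1, utility_pd = 1,
                          annual_discount_rate = 0)
  # 120 months alive at weight 1/year -> 10 QALYs
  expect_equal(accrue(tr, econ)$total_qalys, 10, tolerance = 1e-12)
})

test_that("accrual convention matches the geometric closed form", {
  tp <- derive_arm_transitions(arm_clinical_inputs("LOM", 1.5, 8.6))
  m <- build_matrix(tp)
  tr <- run_cohort(m, n_cycles = 120)
  econ0 <- economic_inputs(1, 0, utility_pfs = 1, utility_pd = 0,
                           annual_discount_rate = 0)
  res <- accrue(tr, econ0)
  # person-months in PFS counted at cycles 1..N: sum p^t = p/(1-p)
  p <- tp$p_pfs_pfs
  expect_equal(res$state_months[["PFS"]], p / (1 - p), tolerance = 1e-9)
  # discounting can only shrink totals
  econ5 <- economic_inputs(1, 0, annual_discount_rate = 0.05)
  expect_lte(accrue(tr, econ5)$total_cost, res$total_cost)
})

test_that("totals decompose into their by-state components", {
  cfg <- make_test_config()
  run <- evaluate_model(cfg)
  for (role in c("intervention", "comparator")) {
    r <- run[[role]]$result
    expect_equal(r$total_cost, sum(r$cost_by_state), tolerance = 1e-9)
    expect_equal(r$total_qalys, sum(r$qalys_by_state), tolerance = 1e-9)
    expect_true(all(r$cost_by_state >= 0) && all(r$qalys_by_state >= 0))
  }
})

test_that("trace accrual equals the closed-form expected-state-time oracle", {
  set.seed(202)
  for (i in 1:100) {
    m <- random_matrix()
    n <- sample(c(60, 120), 1)
    rate <- stats::runif(1, 0, 0.1)
    a <- (1 + rate)^(-1 / 12)
    tr <- run_cohort(m, n_cycles = n)
    econ <- economic_inputs(1, 1, utility_pfs = 1, utility_pd = 1,
                            annual_discount_rate = rate)
    res <- accrue(tr, econ)
    expect_equal(res$state_months[["PFS"]],
                 expected_state_time_closed_form(m, "PFS", a, n),
                 tolerance = 1e-9)
    expect_equal(res$state_months[["PD"]],
                 expected_state_time_closed_form(m, "PD", a, n),
                 tolerance = 1e-9)
  }
})

test_that("half-cycle correction averages entry and exit occupancy", {
  m <- build_matrix(transition_probs("x", 0.3, 0.1, 0.2))
  tr <- run_cohort(m, n_cycles = 60)
  econ <- economic_inputs(100, 50, annual_discount_rate = 0)
  full <- accrue(tr, econ, half_cycle = FALSE)
  half <- accrue(tr, econ, half_cycle = TRUE)
  # PFS occupancy is non-increasing, so averaging in the (higher) entry
  # occupancy raises PFS person-months by half the total decline
  expect_equal(half$state_months[["PFS"]] - full$state_months[["PFS"]],
               (tr$pfs[1] - tr$pfs[61]) / 2, tolerance = 1e-12)
})

test_that("accrual is deterministic: equal inputs give identical results", {
  cfg <- make_test_config()
  cfg$arms$comparator <- cfg$arms$intervention
  run <- evaluate_model(cfg)
  expect_identical(run$intervention$result$total_cost,
                   run$comparator$result$total_cost)
  expect_identical(run$intervention$result$total_qalys,
                   run$comparator$result$total_qalys)
  expect_identical(run$comparison$decision, "equivalent")
})

test_that("extending the horizon adds only a small undiscounted tail", {
  m <- build_matrix(derive_arm_transitions(
    arm_clinical_inputs("LOM", 1.5, 8.6)))
  econ <- economic_inputs(0, 0, annual_discount_rate = 0)
  q120 <- accrue(run_cohort(m, 120), econ)$total_qalys
  q600 <- accrue(run_cohort(m, 600), econ)$total_qalys
  expect_gte(q600, q120)
  expect_lt((q600 - q120) / q600, 0.01)
})
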