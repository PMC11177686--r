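test_that("one-way DSA re-runs cleanly and leaves no state behind", {
  cfg <- make_test_config()
  base_before <- evaluate_model(cfg)$comparison$cost_per_qaly_ratio
  dsa <- one_way_dsa(cfg)
  base_after <- evaluate_model(cfg)$comparison$cost_per_qaly_ratio
  expect_identical(base_before, base_after)
  expect_identical(attr(dsa, "base_icer"), base_before)
  # tornado order: spans sorted descending
  expect_true(all(diff(dsa$span) <= 1e-12))
  expect_setequal(dsa$parameter, names(resolve_parameters(cfg)))
})

test_that("degenerate ranges produce a flat tornado", {
  cfg <- make_test_config()
  params <- resolve_parameters(cfg)
  ranges <- do.call(rbind, lapply(names(params), function(nm) {
    param_range(nm, params[[nm]], params[[nm]], params[[nm]])
  }))
  dsa <- one_way_dsa(cfg, ranges)
  expect_true(all(dsa$span == 0))
  expect_true(all(dsa$icer_at_low == attr(dsa, "base_icer")))
})

test_that("a range that breaks row feasibility is clamped and flagged", {
  cfg <- make_test_config()
  ranges <- param_range("p_pfs_pd_comparator",
                        resolve_parameters(cfg)[["p_pfs_pd_comparator"]],
                        0.1, 0.999)
  dsa <- one_way_dsa(cfg, ranges)
  expect_true(dsa$clamped[1])
  expect_true(is.finite(dsa$icer_at_high))
})

test_that("degenerate distributions reproduce the base case bit-identically", {
  cfg <- make_test_config()
  base <- resolve_parameters(cfg)
  sp <- sample_params(cfg, dist_policy = "degenerate", rng_seed = 1)
  expect_identical(unname(sp[names(base)]), unname(base))
  base_cmp <- evaluate_model(cfg)$comparison
  draws <- run_psa(cfg, n_iter = 3, rng_seed = 5,
                   dist_policy = "degenerate")
  expect_identical(draws$delta_cost, rep(base_cmp$delta_cost, 3))
  expect_identical(draws$delta_qalys, rep(base_cmp$delta_qalys, 3))
})

test_that("sampled parameters respect their supports and the seed", {
  cfg <- load_fixture_quietly()
  set.seed(99)
  draws <- replicate(200, sample_params(cfg))
  probs <- draws[grepl("^p_|^utility_", rownames(draws)), ]
  expect_true(all(probs >= 0 & probs <= 1))
  costs <- draws[grepl("^cost_", rownames(draws)), ]
  expect_true(all(costs >= 0))
  # PFS rows stay feasible after renormalization by complement
  expect_true(all(draws["p_pfs_pd_intervention", ] +
                    draws["p_pfs_death_intervention", ] <= 1))
  # identical seeds give identical draw sequences
  expect_identical(sample_params(cfg, rng_seed = 123),
                   sample_params(cfg, rng_seed = 123))
})

test_that("PSA batches are seed-reproducible and robust per draw", {
  cfg <- make_test_config()
  d1 <- run_psa(cfg, n_iter = 40, rng_seed = 11)
  d2 <- run_psa(cfg, n_iter = 40, rng_seed = 11)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 40)
  # every draw is resolved: a result or an explicit invalid flag
  expect_true(all(d1$decision %in%
    c("cost-effective", "not-cost-effective", "dominant", "dominated",
      "equivalent", "invalid")))
})

test_that("the CEAC is a probability curve with the right limits", {
  # synthetic draws, all with positive incremental effectiveness
  set.seed(33)
  draws <- data.frame(draw = 1:500,
                      delta_cost = stats::rnorm(500, 12000, 4000),
                      delta_qalys = stats::runif(500, 0.05, 0.4))
  grid <- seq(0, 300000, by = 5000)
  curve <- ceac(draws, grid)
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))
  # all dE > 0 -> monotone non-decreasing in lambda
  expect_true(all(diff(curve$prob_cost_effective) >= 0))
  # lambda = 0: fraction of cost-saving draws
  expect_equal(curve$prob_cost_effective[1], mean(draws$delta_cost < 0))
  # lambda large: fraction with dE > 0 (here, all)
  expect_equal(ceac(draws, 1e9)$prob_cost_effective, 1)
  expect_error(ceac(draws[0, ], grid), "non-empty")
})

test_that("CEAC curves from different seeds agree within Monte Carlo error", {
  cfg <- load_fixture_quietly()
  grid <- c(0, 35906, 75000, 150000)
  c1 <- ceac(run_psa(cfg, n_iter = 300, rng_seed = 21), grid)
  c2 <- ceac(run_psa(cfg, n_iter = 300, rng_seed = 22), grid)
  # 4 sigma on a binomial fraction at n = 300 is < 0.116
  expect_true(all(abs(c1$prob_cost_effective -
                        c2$prob_cost_effective) < 0.12))
})
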