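# Shared fixtures, built in code.

# A small, fully explicit two-arm configuration (not the packaged one):
# intervention with longer PFS but higher costs.
make_test_config <- function() {
  validate_config(list(
    arms = list(
      intervention = list(label = "A", median_pfs = 5, median_os = 10,
                          cost_pfs_per_cycle = 2000,
                          cost_pd_per_cycle = 300),
      comparator = list(label = "B", median_pfs = 2, median_os = 9,
                        cost_pfs_per_cycle = 400,
                        cost_pd_per_cycle = 250)
    ),
    global = list(annual_discount_rate = 0.05, horizon_cycles = 120,
                  wtp = 50000, utility_pfs = 0.85, utility_pd = 0.7,
                  utility_death = 0, half_cycle = FALSE,
                  precision = "derived"),
    sensitivity = list(n_iter = 100, cost_sd_frac = 0.25,
                       wtp_grid = list(from = 0, to = 100000, by = 5000),
                       ranges = list())
  ))
}

# Random valid 3-state chain (PD non-reversible, Death absorbing).
random_matrix <- function() {
  exits <- stats::runif(2, 0, 0.5)
  build_matrix(transition_probs("rand",
                                p_pfs_pd = exits[1],
                                p_pfs_death = exits[2],
                                p_pd_death = stats::runif(1, 0.01, 0.9)))
}

# Minimal arm_result for economics tests that do not need a trace.
fake_arm_result <- function(cost, qalys, label = "arm") {
  structure(
    list(arm_label = label, total_cost = cost, total_qalys = qalys,
         cost_by_state = c(PFS = cost, PD = 0, Death = 0),
         qalys_by_state = c(PFS = qalys, PD = 0, Death = 0),
         state_months = c(PFS = NA_real_, PD = NA_real_, Death = NA_real_),
         n_cycles = 120, half_cycle = FALSE),
    class = "arm_result"
  )
}

load_fixture_quietly <- function() suppressWarnings(fixture_config())
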