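# markovcea

Markov cohort cost-effectiveness analysis for two-arm oncology
treatment comparisons.

Health-economic evaluations of new cancer regimens often have to work
from published trial summaries — a median progression-free survival
(PFS) and median overall survival (OS) per arm — plus unit costs and
health-state utilities. `markovcea` turns those inputs into a complete
cost-utility analysis for decision makers and health-economics
researchers: a three-state (PFS, progressed disease, death) Markov
cohort simulation with discounted cost and QALY accrual, incremental
cost-effectiveness ratios against a willingness-to-pay (WTP)
threshold, and deterministic (tornado) plus probabilistic (Monte
Carlo, CEAC) sensitivity analyses.

## The model

Monthly transition probabilities come from trial medians under a
constant-hazard assumption,

> p(1 month) = 1 − 0.5^(1/m) = 1 − e^(−ln2/m),  m = median in months,

mapped as PFS→PD from median PFS, PFS→Death from median OS, and
PD→Death from the post-progression median (OS − PFS). The cohort
starts in PFS and is propagated through the row-stochastic matrix

```
        PFS          PD           Death
PFS     1−p_FP−p_FD  p_FP         p_FD
PD      0            1−p_PD       p_PD
Death   0            0            1
```

for 120 monthly cycles (10 years). Cycle t accrues
`occupancy · cost` and `occupancy · utility/12`, discounted by
`(1+r)^(−t/12)` (5%/year default; optional half-cycle correction).
Arms are compared by incremental cost ΔC, incremental effectiveness
ΔE (QALYs), ICER = ΔC/ΔE, and net monetary benefit `λ·E − C` at
WTP λ (default $35,906/QALY). The ships-with parameter set is a
published comparison of bevacizumab plus lomustine (BEV+LOM) versus
lomustine (LOM) in progressive glioblastoma.

## Worked example

```r
library(markovcea)

cfg <- fixture_config()        # packaged parameter set (one expected
                               # warning: a published probability row
                               # sums to 0.99 and is renormalized)
run <- evaluate_model(cfg)
run
#> Discounted arm result - 'BEV+LOM' (120 cycles)
#>   total cost:  $13959.61
#>   total QALYs: 0.5520
#> Discounted arm result - 'LOM' (120 cycles)
#>   total cost:  $2014.03
#>   total QALYs: 0.6134
#> Cost-effectiveness comparison: 'BEV+LOM' vs 'LOM' (WTP $35,906/QALY)
#>   incremental cost:  $11945.58
#>   incremental QALYs: -0.0614
#>   ICER: not reported (dominated)
#>   incremental NMB:   $-14149.04
#>   decision: dominated
```

Reading: at these transition probabilities the combination costs
$11,946 more and yields 0.061 *fewer* discounted QALYs than lomustine
alone — the comparator's lower monthly PD→Death probability (0.09 vs
0.13) gives it a longer progressed-disease tail. The combination is
therefore dominated, i.e. not cost-effective at any threshold,
consistent with the published conclusion at $35,906/QALY (the
published analysis reports a positive QALY increment instead; see the
methods vignette for why that is not derivable from its own
transition probabilities). Uncertainty:

```r
draws <- run_psa(cfg, n_iter = 1000, rng_seed = 1)
curve <- ceac(draws)
curve[curve$wtp == 36000, ]
#>     wtp prob_cost_effective
#> 25 36000                   0
tornado <- one_way_dsa(cfg)
head(as.data.frame(tornado)[, c("parameter", "span")], 3)
#>                 parameter      span
#> 1 p_pd_death_intervention 3490105.0
#> 2   p_pd_death_comparator  790175.7
#> 3              utility_pd  581500.7
```

At a WTP of $36,000/QALY the intervention is cost-effective in none of
1,000 Monte-Carlo draws; the tornado ranks the two post-progression
death probabilities and the PD utility as the most influential
parameters (spans are on the signed cost-per-QALY ratio, which is
large in magnitude near the dominance boundary). `write_*_csv()` functions export every
artifact (traces, results, comparison, tornado, draws, CEAC), and
`inst/cli/cea.R` provides the same pipeline as a command-line tool
(`derive`, `run`, `compare`, `dsa`, `psa`, `ceac`, `simulate-trial`).

A synthetic-trial module (`generate_trial_arm()`,
`estimate_medians()`, `generate_random_config()`) generates
individual-level exponential event times and random valid
configurations for end-to-end validation.

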