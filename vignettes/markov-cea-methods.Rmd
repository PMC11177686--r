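---
title: "Methods: a three-state Markov cohort model for cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cohort model for cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem and model structure

`markovcea` evaluates whether an intervention is good value for money
relative to a comparator when a trial reports only median
progression-free survival (PFS) and median overall survival (OS) per
arm, together with unit costs and health-state utilities. The packaged
parameter set is a published comparison of bevacizumab plus lomustine
(BEV+LOM) versus lomustine alone (LOM) in progressive glioblastoma, but
every input is configurable and the machinery is generic for two-arm
oncology comparisons.

The disease course is modelled as a discrete-time Markov cohort over
three health states — progression-free (PFS), progressed disease (PD)
and Death — with a 1-month cycle and a 10-year horizon (120 cycles) by
default. The whole cohort starts in PFS. Progression is
non-reversible (no PD to PFS transitions) and Death is absorbing, so the
transition matrix is upper-triangular:

$$
M \;=\;
\begin{pmatrix}
p_{FF} & p_{FP} & p_{FD}\\
0      & p_{PP} & p_{PD}\\
0      & 0      & 1
\end{pmatrix},
\qquad p_{FF} = 1 - p_{FP} - p_{FD},\quad p_{PP} = 1 - p_{PD}.
$$

## From medians to monthly probabilities

Under a constant hazard, the survivor function that halves at the
median $m$ (months) has hazard $R = \ln 2 / m$, giving the per-cycle
transition probability

$$p(m) \;=\; 1 - 0.5^{1/m} \;=\; 1 - e^{-\ln 2 / m}.$$

`monthly_prob_from_median()` implements this conversion; the two forms
are the same function to machine precision, $p$ is strictly decreasing
in $m$, $p(1) = 0.5$, and an infinite median encodes a no-event arm
($p = 0$).

The three hazards of the model are mapped to the arm medians as
follows (`derive_arm_transitions()`):

* PFS → PD from the median PFS;
* PFS → Death from the median OS;
* PD → Death from the post-progression median, `median_os − median_pfs`.

This mapping is the unique one under which the packaged medians
(4.2/9.1 months for BEV+LOM, 1.5/8.6 for LOM) reproduce, at two
decimals, every baseline transition probability of the published table
the parameter set is drawn from (0.15/0.07/0.13/0.77/0.87 and
0.37/0.08/0.09/0.55/0.91). It treats the reported OS median as if it
measured time-to-death from the start of PFS at constant hazard, and
the post-progression difference of medians as a median — a pragmatic
reconstruction, not a fitted survival model (fitting parametric curves
to Kaplan–Meier data is out of scope).

One numerical subtlety: at full precision the BEV+LOM PFS stay
probability is $1 - 0.1522 - 0.0733 = 0.7744$, which rounds to the
published 0.77. The published *row*, however, is internally
inconsistent at two decimals (its exits imply $1 - 0.15 - 0.07 =
0.78$, so the printed row sums to 0.99). When such externally supplied
rounded probabilities are used verbatim (`precision = "fixture"`),
`build_matrix()` repairs the row by recomputing the stay probability as
the complement of the exits and records a provenance note; exit
probabilities are never rescaled, because they carry the clinical
signal while the stay probability is a residual. A `strict` policy that
refuses repair is available. Rows whose exit mass exceeds 1 are an
error in all policies.

## Cycle accounting, discounting and accrual

`run_cohort()` propagates the occupancy vector; `accrue()` turns a
trace into discounted totals. The conventions, each explicit and
testable:

* **Membership counting.** By default, cycle $t \in \{1..N\}$ accrues
  the occupancy *after* $t$ transitions; cycle 0 — the decision point —
  accrues nothing. The standard half-cycle correction (average of entry
  and exit occupancy per cycle) is available via `half_cycle = TRUE`,
  default off.
* **Discounting.** $d(t) = (1 + r)^{-t/12}$ with $r$ the annual rate
  (default 5%/year): the continuous-equivalent monthly factor rather
  than annual step discounting.
* **Utilities.** Per-year QALY weights (defaults 0.89 PFS, 0.74 PD,
  0 Death) divided by 12 per monthly cycle.
* **Costs.** Per-cycle per-state USD; Death accrues nothing by default
  (no terminal-care cost in the packaged inputs).

An analytic oracle, `expected_state_time_closed_form()`, computes the
same discounted person-months from geometric/convolution series rather
than matrix propagation; the test suite requires agreement with
trace-based accrual to $10^{-9}$ over random chains.

Because published cost-effectiveness tables rarely state these
conventions, QALY and cost *totals* from other implementations of the
same inputs are generally not reproducible to the cent; the package
treats such totals as non-binding references and exposes the
conventions as flags instead.

## Economic inputs of the packaged analysis

The packaged per-cycle PFS costs reconstruct the dosing arithmetic the
published unit prices imply (`drug_cost_defaults()`): bevacizumab
10 mg/kg for a 65 kg reference patient is 650 mg, i.e. 7 × 100 mg
vials at \$209.50, administered 3× per 6-week treatment cycle;
lomustine 90 mg/m² (combination) or 110 mg/m² capped at 200 mg
(monotherapy) for 1.72 m² BSA, rounded up to whole 50 mg tablets at
\$3.25, once per 6-week cycle. Costs on the 6-week schedule are
converted to the 1-month model cycle by the ratio
$(365.25/12)/42 \approx 0.725$. Monthly adverse-event management
(\$3.53 / \$0.03) and examination fees (\$464.67 / \$459.04) enter
unconverted, giving \$3,665.95 and \$468.49 per month in PFS. The
second-line (PD-state) costs are not published as per-cycle figures;
the packaged defaults (\$325 and \$170 per month) were reconstructed
once so that discounted PD cost accruals land on the scale of the
published state-cost totals, and are ordinary configurable inputs —
no headline check depends on them.

The willingness-to-pay threshold defaults to \$35,906/QALY (three
times China's 2022 per-capita GDP); all monetary inputs and outputs
are USD.

## What the base case shows — and a reproducibility caveat

With the packaged derived probabilities the model finds, over 120
cycles at 5%/year discounting:

* BEV+LOM: higher cost (≈ \$13,960) and ≈ 0.552 QALYs;
* LOM: ≈ \$2,014 and ≈ 0.613 QALYs.

The combination is therefore *dominated*: it costs ≈ \$11,946 more and
yields ≈ 0.061 *fewer* QALYs, so it is not cost-effective at any
threshold — which agrees with the published decision ("not
cost-effective at \$35,906/QALY") while disagreeing with the published
incremental QALY gain of +0.25. The disagreement is structural, not a
convention choice: the comparator's post-progression median
(8.6 − 1.5 = 7.1 months) implies a low monthly PD → Death probability
(0.09 vs 0.13), hence a *longer* PD tail (≈ 8.9 vs ≈ 5.1 undiscounted
person-months) that outweighs the intervention's extra PFS time at any
utility pair with $u_{PD} > 0$. No standard accrual convention
(cycle-0 inclusion, half-cycle correction, discounting variant)
reverses the sign under these transition probabilities, and the
published per-state QALY breakdown (equal PD QALYs in both arms
despite different PD occupancies) cannot be produced by any cohort
trace over this matrix. The package therefore reports what the stated
model implies and surfaces every convention as a flag; the acceptance
suite keeps the published direction claims as failing checks rather
than adjusting inputs toward them.

`compare_arms()` reports increments, the ICER
($\Delta C / \Delta E$, withheld as `NA` under dominance with the raw
ratio retained for diagnostics), per-arm cost-effectiveness ratios,
net monetary benefit ($\lambda E - C$) and the threshold decision,
which coincides with the incremental-NMB sign by construction.

## Sensitivity analyses

**One-way (tornado), `one_way_dsa()`.** Each parameter in the registry
(six exit probabilities, four per-arm state costs, two utilities, the
discount rate) is set to its low and high bound with all else at base,
and the full pipeline re-run. Probability bounds come from the
configuration's published limits; parameters without published ranges
get ±20% (utilities capped at 1), and the discount rate spans 0–8%.
An evaluation that would push a row's exit mass above 1 is clamped to
the feasible boundary and flagged, never dropped silently. Spans are
reported on the signed cost-per-QALY ratio so bars remain defined when
an evaluation crosses a dominance quadrant.

**Probabilistic (PSA), `run_psa()`.** Default distributions follow
standard cost-effectiveness practice, since the source analysis names
none: Beta for probabilities and utilities, with mean at base and the
low/high range read as a 95% interval (method-of-moments shapes;
infeasible matching falls back to uniform with a warning), and Gamma
for costs with SD = 25% of the mean by default. Exit probabilities of
a row are sampled independently, the stay probability renormalized by
complement, and infeasible rows rejected and resampled (counts
logged). All draws are reproducible from a single seed; degenerate
(zero-variance) policies reproduce the base case bit-identically. One
thousand iterations run in a few seconds.

**CEAC, `ceac()`.** For each $\lambda$ on a grid (default \$0–150,000
in \$1,500 steps, covering both the packaged threshold and the
\$100k–150k range discussed for US oncology), the probability of
cost-effectiveness is the fraction of draws with positive incremental
NMB. For the packaged analysis this probability is ≈ 0 at
\$35,906/QALY — the distribution-level restatement of "not
cost-effective". Note that a PSA summary phrased as "the ICER exceeds
the threshold in (nearly) all draws" is ill-defined when many draws
are dominated (negative ratio); conditioning on draws with
$\Delta E > 0$ yields very large ICERs (5th percentile ≈ \$10^5/QALY)
precisely because those gains are small.

## The synthetic-data generator

`generate_trial_arm()` emulates individual-level trial data consistent
with the model's constant-hazard assumption: progression times are
exponential with median `median_pfs`; post-progression survival is
exponential with median `median_os − median_pfs`; per-patient OS is
their sum, so `os > pfs` always. `estimate_medians()` closes the loop
(sample medians, no censoring — the model consumes only medians, so
censoring would add nothing testable), and `generate_random_config()`
fuzzes the whole pipeline with structurally valid random
configurations.

Two honest limitations. First, real trial data are censored,
non-exponential and correlated with costs; passing recovery tests here
shows the *pipeline* is consistent, not that the constant-hazard
reading of real medians is. Second, the sum construction preserves the
two *phase* medians, not the OS median: when the phases are comparable
(e.g. 4.2 and 4.9 months) the median of the sum (≈ 11 months) exceeds
the OS input, so re-deriving death hazards from sample medians of OS
carries a structural bias (≈ 0.035 on the PD → Death probability for
that geometry) that no sample size removes. Recovery of all five
probabilities to ±0.02 at n = 5,000 holds when the progression phase
is short relative to post-progression survival (e.g. medians 1.5/8.6),
and the per-patient phase durations (`median(os − pfs)`) recover the
post-progression median for any geometry; the tests assert exactly
these two statements.

## Numerical and testing choices

* Row-stochasticity is enforced to $10^{-12}$; occupancy conservation
  and the monotonicity of PFS (non-increasing) and Death
  (non-decreasing) are property-tested over 1,000 random chains.
* Oracle agreement (trace vs closed form) is required to $10^{-9}$
  over 100 random chains including random discount rates.
* Tie-breaks: identical arms yield an explicit `"equivalent"`
  decision; $\Delta E = 0$ with $\Delta C \neq 0$ yields a
  signed-infinite ICER with a dominance annotation, never `NaN`.
* Problem sizes in the test suite — 120-cycle horizons, 1,000-chain
  property loops, 1,000-iteration PSAs, n = 5,000 synthetic arms — were
  chosen so the full suite completes in well under a minute while
  keeping Monte-Carlo assertions comfortably inside 4-sigma bands.

## Known limitations

* Constant hazards throughout; no time-varying transition matrices,
  cure fractions or microsimulation.
* Two strategies only — no efficiency frontiers over three or more
  options, no EVPI, no budget impact.
* The dosing arithmetic behind the packaged PFS costs (body weight,
  BSA, vial rounding, administrations per cycle) is a documented
  reconstruction; users with actual dispensing data should override
  `cost_pfs_per_cycle` directly.
* Parameter correlation in PSA is limited to the feasibility coupling
  of same-row exit probabilities; no copulas.
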