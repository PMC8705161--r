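---
title: "Methods: a five-state Markov cost-effectiveness model of BNP-guided heart-failure care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-state Markov cost-effectiveness model of BNP-guided heart-failure care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnpcea)
```

## The decision problem

Outpatients with heart failure with reduced ejection fraction (HFrEF) can be
managed on standard clinical assessment (history and physical examination)
or with monthly B-type natriuretic peptide (BNP) measurement guiding
therapy. Serial BNP monitoring does not change mortality but reduces
heart-failure hospitalisation (relative risk 0.81 in the model's default
bundle). The package asks whether BNP-guided care is good value for money
from a societal perspective, in 2019 US dollars, using quality-adjusted
life-years (QALYs) as the effectiveness measure.

## The cohort model

Disease progression is proxied by the number of previous heart-failure
rehospitalisations. Five states: no rehospitalisation (NRH), first to third
rehospitalisation (RH1--RH3), and death. Each month a patient either stays
in the current state, is readmitted and moves one state up the ladder
(re-admissions past the third collapse into RH3), or dies. Death combines
two hazards treated as independent competing risks:

* a state-specific monthly heart-failure death probability
  (0.067--0.095/month in the default bundle), and
* age-banded all-cause background mortality from an Iranian life table
  (annual probabilities 0.002 at 45--49 up to 0.218 at 85+), converted to
  monthly via the constant-rate transform `1 - (1 - p)^(1/12)`.

The relative risk applies to the hospitalisation transitions of the BNP arm
only (capped so hospitalisation + death never exceeds 1), never to
mortality — consistent with the evidence that BNP-guided therapy reduces
hospitalisation, not death.

The cohort starts with everyone in NRH and is propagated by
`run_cohort()`; per cycle `t`, costs accrue as occupancy times the arm- and
state-specific monthly cost with discount factor `(1.058)^(-t/12)`, and
QALYs as occupancy times the state utility times 1/12 with
`(1.03)^(-t/12)`. The run stops at a fixed horizon if configured, at age
100, or when less than `1e-8` of the cohort is alive. Results are per
patient; the cohort size only scales absolute outputs.

### Deliberately configurable ambiguities

Several modelling semantics are underdetermined by the available summary
inputs; each is an explicit switch on the bundle so their influence can be
examined rather than buried:

* **`transition_label_mode`** (default `"next-state"`): the tabulated
  per-state probabilities such as 0.168/month for NRH are read as the
  probability of the *next rehospitalisation* (NRH→RH1 and so on). This is
  the reading consistent with a model in which patients "stay or move to
  the next state": a literal self-transition probability would be redundant
  (the stay probability is the residual), and the upstream transition
  evidence parameterises hospitalisation events. The alternative
  `"literal-stay"` mode treats the printed value as the stay probability
  with the move probability as residual.
* **`cost_semantics`** (default `"per-cycle"`): state costs accrue for
  every month of occupancy. The `"event"` mode instead charges a
  rehospitalisation state's cost once on entry (NRH cost still per cycle),
  since a cost labelled "rehospitalisation" could plausibly be an admission
  cost. Printed summary outputs do not discriminate between the readings.
* **`half_cycle_correction`** (default off): when on, accruals use the
  average of start- and end-of-cycle occupancy (transitions mid-cycle on
  average).
* **`start_age`** (default 60): the cohort's starting age is not fixed by
  the source inputs; 60 sits centrally in the 45+ outpatient population and
  in the middle age band of the subgroup analysis. Subgroup runs use 50,
  60, 70 for the 45--55, 55--65, 65--75 bands.

### Validation

`microsim_oracle()` is an individual-level Monte-Carlo simulation using the
same transition matrices and discounting; it is an independent check of
the deterministic trace (agreement within three standard errors at 20,000
individuals is part of the test suite), exact on degenerate chains.
Structural invariants — occupancy conservation to `1e-9` per cycle,
monotone death absorption, equality of discounted and undiscounted totals
at zero rates, bit-identical arms under a neutral relative risk with equal
costs, and a geometric-series closed form for a two-state reduction — are
property-tested over randomised valid bundles.

## Incremental analysis

`incremental()` and `icer()` implement the standard quadrant logic: lower
cost with higher effect is *dominant*, higher cost with lower effect
*dominated*, otherwise the incremental cost-effectiveness ratio
ΔC/ΔE applies; with ΔE = 0 the cost sign decides. The integer display of an
ICER truncates toward zero, matching the convention of the published
subgroup ratios the tests reproduce (140/0.30 → 466; 650/0.22 → 2954).
Net monetary benefit is `λ·ΔE − ΔC` at willingness-to-pay λ, defaulting to
20,800 USD/QALY (three times per-capita GDP).

Under the default bundle the deterministic model makes BNP-guided care
dominant: cheaper (the expensive late-rehospitalisation states cost less in
the BNP arm and are reached less often) and more effective (slower
progression into low-utility, high-mortality states). The absolute totals
are far larger than the roughly two QALYs per patient a much lower-risk
cohort would accrue — the default monthly heart-failure death probabilities
imply a life expectancy near one year — so the package treats published
absolute totals as calibration references and asserts the qualitative
headline plus internal consistency instead; the printed per-arm tables are
still reproduced exactly as arithmetic identities by `incremental()` and
`icer()`.

## Uncertainty analysis

**Distribution fits.** Probabilities and utilities get Beta distributions
fitted by the method of moments; costs get Gamma (`shape = (mean/sd)^2`,
`scale = sd^2/mean`); the relative risk is log-normal with
`meanlog = log(mean) − sdlog^2/2` so its *arithmetic* mean equals the
requested value. The tabulated dispersion printed for the relative risk
("5") is not usable as a standard deviation; the log-scale sd is a
configuration input defaulting to 0.1 and flagged in every run manifest.

**Feasibility repair.** A Beta fit needs `sd^2 < mean(1 − mean)`. Several
tabulated dispersions sit at or beyond that bound (0.32 on mean 0.085,
0.33 on 0.095), and several more sit just inside it, where the fitted
shapes fall far below 1 and the distribution degenerates toward a
two-point mass on {0, 1}. Fits with `sd > 0.95 × sqrt(mean(1 − mean))` are
therefore repaired by shrinking the sd to 0.95 of the bound, and flagged;
repaired fits keep the requested mean but not the requested sd, and are
excluded from moment-recovery tests. Silent failure or dropping parameters
would change the analysis, so repair-and-flag is the only behaviour.

**PSA.** `run_psa()` samples every uncertain parameter independently from
its fitted distribution (the relative risk once per draw, applied to the
BNP arm only), renormalises any transition row that independent sampling
made infeasible — reserving headroom for the largest monthly background
mortality, since the engine later folds background death into the same
row — and reruns the full two-arm model per draw. The (seed, bundle, n)
triple fully determines all outputs.

A consequence worth stating plainly: even after repair, the
hospitalisation-probability fits have Beta shapes of order 0.02--0.3, so a
large share of draws places essentially zero hospitalisation risk in both
arms. In those draws the arms differ only in the NRH cost (higher under
BNP), so they count against BNP at any threshold, and the acceptability
curve plateaus near the fraction of draws with positive incremental QALYs
(≈0.4) instead of approaching 1. The deterministic dominance result and the
PSA summary therefore tell different stories by construction of the input
dispersions, not through a model defect; the acceptability probability at
20,800 USD/QALY is reported as computed (≈0.44 at 1000 draws) rather than
forced toward the deterministic result.

**Tornado.** Each parameter is moved ±20% (probabilities and utilities
clipped into their valid range, with the clip recorded), with two full
model runs per parameter. The default outcome is NMB at the threshold
because the ICER is sign-unstable around dominance; an ICER mode exists for
convention's sake. Bars are sorted by width; under the defaults the widest
bars are the RH3 state costs and the relative risk.

**Bootstrap.** `bootstrap_ci()` is the percentile bootstrap (resamples of
the original size, mean per resample, percentile interval) — the plain
non-parametric choice when nothing stronger is claimed. Coverage on
standard-normal data (n = 200, B = 1000) is verified at 95% ± 2% over 500
replications in the test suite.

## The synthetic cohort

No patient-level data accompany the published summaries, so
`generate_cohort()` fabricates a cohort of 200 patients per arm with the
statistical structure the analysis assumes, and is labelled synthetic
throughout:

* **Itemised costs** are independent Gamma draws (right-skewed,
  non-negative; coefficient of variation 0.6 — typical of itemised
  healthcare cost data) for ten items: physician visits, heart medications,
  BNP test (zero in the standard arm), diagnostics/laboratory,
  (re)hospitalisation, nursing, special equipment, private service,
  accommodation, traveling, plus lost workdays × daily wage (human-capital
  indirect cost). Arm means are calibrated so the expected per-patient
  total is exactly 682 USD (BNP) and 649 USD (standard) with medications
  (255/196) and diagnostics (189/141) fixed at their observed means and the
  remainder split evenly across the other items; the true itemised
  breakdown beyond those figures is not public.
* **EQ-5D-3L responses** are per-dimension multinomials whose level
  probabilities depend on the patient's prior-rehospitalisation stratum.
  For a target stratum utility `u`, the per-dimension expected decrement
  `(1 − u)/5` is split half to level 2 and half to level 3, which makes the
  expected scored utility equal the target *exactly* under the tariff —
  the simplest structure matching the stated stratum means
  (0.85/0.828/0.809/0.777).
* **The value set** is a replaceable coefficient table (dimension, level,
  decrement, optional once-per-response level-3 interaction). The shipped
  default is a documented toy tariff (0.05 at level 2, 0.15 at level 3, no
  interaction); it makes no claim to equal any published national tariff,
  which should be supplied via `read_value_set_csv()` for real scoring.
* **Ages** are 45 + Gamma(4, 4) years (mean 61), matching an over-45
  outpatient population; stratum occupancy defaults to
  (0.40, 0.30, 0.20, 0.10).

What passing tests show: the generator is internally consistent
(reproducible under a seed, cost identity exact, arm means within 5% of the
targets, per-stratum utilities recovered within three standard errors, and
bootstrap intervals on generated totals covering the design mean at close
to nominal rate). What they cannot show: anything about the real interview
data beyond the published summary statistics the generator was pointed at —
correlation between items, within-patient cost-utility dependence, and
non-Gamma tails are all assumptions, not inferences.

## Problem sizes and numerical choices

Default analysis sizes are the ones a desk analysis of this model needs:
1000 PSA draws, 1000 bootstrap resamples, 20,000 individuals for the
microsimulation check, 200 patients per synthetic arm. Lifetime horizon
runs terminate on cohort extinction (alive fraction below `1e-8`, reached
after roughly 15 years under the defaults). Occupancy conservation is
asserted at `1e-9` per cycle; moment round-trips at `1e-9`; transition-row
feasibility violations raise errors naming the state rather than being
silently renormalised outside the PSA path. Ties in ICER classification
(ΔE = 0) fall back to the cost sign, and `icer()` retains the
full-precision ratio alongside the truncated display.

## Known limitations

* The default transition probabilities come from an external HF cohort
  model and carry dispersions that are implausible as Beta standard
  deviations; the PSA inherits that (see above) and should be read
  accordingly.
* Background mortality is all-cause, so heart-failure death is mildly
  double-counted in the competing-risk combination.
* No tunnel states beyond RH3; no treatment switching, adherence, or test
  characteristics (sensitivity/specificity) of BNP measurement.
* Costs are 2019 USD with no inflation or currency adjustment by design.
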