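---
title: "Modelling thyroid nodule natural history with thyronod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thyroid nodule natural history with thyronod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyronod)
```

## The model

`thyronod` is an individual-level, annual-cycle microsimulation of the
natural history of thyroid nodules — benign and malignant — in women
followed from birth to age 100 or death. It exists to quantify the
pre-clinical reservoir of disease: papillary thyroid carcinoma is heavily
overdiagnosed, autopsy and ultrasound series show large numbers of
undetected nodules in the living population, and any assessment of
screening, active surveillance or treatment policy needs a model of what
is there *before* detection.

Each simulated woman carries a list of nodules. Every year she faces, in
fixed order:

1. an all-cause death draw from an age-indexed life table (`age,qx` CSV;
   a Gompertz–Makeham synthetic stand-in for US female period mortality
   ships with the package);
2. possible initiation of one new nodule, with age-stratified annual
   probability `dev_rate_i`; the nodule is malignant with probability
   `1 - p_benign = 0.10`, starts as a single cell (volume
   $10^{-6}\,\mathrm{mm}^3$, diameter 0.012407 mm), and receives a growth
   rate drawn from a lognormal whose parameters depend on malignancy and
   on the age stratum at onset;
3. a volume update of every nodule by its closed-form law;
4. a clinical-detection draw at annual rate $r_i(V) = B_{1i} + B_{2i} V$,
   where $V$ is the volume of the largest nodule and $i$ the age stratum —
   permitted only if that nodule's diameter is at least 3 mm, the
   conservative limit of sonography. The rate is converted to a per-cycle
   probability as $1 - e^{-r}$ and clamped at zero from below.

On detection the person leaves the natural-history model, classed
`malignant_found` if any malignant nodule of at least 3 mm is present and
`benign_only` otherwise — benign work-up incidentally finds co-located
cancers, which is why benign nodules must be modelled at all.

### Nodule kinetics

Volumes follow three closed forms. Growth is logistic,
$$V(t) = \frac{K V_0 e^{rt}}{K + V_0\,(e^{rt}-1)},$$
with a single global carrying capacity $K$, the volume of a 20 cm sphere;
growth data observed over short windows look exponential, but
extrapolation over decades needs the biological size ceiling. Five years
after onset each nodule's subsequent behavior is decided once: keep
growing (malignant 0.301, benign 0.111), shrink (0.252 / 0.131), or stay
stable (0.447 / 0.758). Shrinking nodules decay exponentially,
$V(t) = V_0 e^{-rt}$ with $r \sim N(0.0170, 0.0016)$ truncated at zero;
stable nodules drift linearly, $V(t) = V_0 + rt$ with
$r \sim N(0.0094, 0.0096)$ mm\(^3\)/yr, deliberately untruncated (the sd
exceeds the mean, so mild shrinkage is allowed). In both cases $V_0$ is
the volume at the five-year switch and the clock restarts there. The
shrink rate and stable slope are treated as *volume*-domain quantities,
since the kinetic laws are volume equations; this is flagged here because
the convention matters when comparing with diameter-based reports.

Two numerical guards: every trajectory is clamped below at the one-cell
volume (a nodule cannot be smaller than one cell, and stable nodules with
negative slope would otherwise go negative), and above at $K$.

### Randomness

The compiled cohort engine draws every uniform as a pure function of
(cohort seed, person index, purpose, cycle counter) through a splitmix64
hash — named substreams for death, initiation, malignancy, growth rate,
behavior, shrink rate, slope, side and detection. Two consequences:
results are reproducible independent of evaluation order, and two
parameter sets simulated at the same seed share their random numbers, so
calibration optimises a *deterministic* objective (common random
numbers). The pure-R per-person engine (`annual_cycle()`,
`simulate_person()`) instead uses R's own RNG stream — simpler to read
and to step through, still replayable from its seed; the two engines are
compared distributionally in the test suite, not trace-by-trace.

## Calibration

The unknowns — `dev_rate`, the two lognormal growth-rate parameter pairs,
and the detection coefficients `B1`, `B2`, each per 5-year age stratum
from 15 to 85 (ages outside clamp to the boundary strata; 98 scalars in
all) — are fitted to binned targets: age-binned detected-cancer incidence
proportions, the 1-cm size distribution of tumors at detection per age
bin, a benign-only share of detections (base case $1 - 0.164 = 0.836$),
and a benign size table assumed to equal the malignant one but
down-weighted (default weight 0.1 against 1.0 / 1.0 / 0.5) because the
underlying data are weak.

The goodness of fit is a weighted chi-squared,
$$\mathrm{GOF} = \sum_\text{tables} w_t \sum_\text{bins}
\frac{(m_b - t_b)^2}{\max(t_b, 10^{-6})},$$
not normalised by bin count. The $\varepsilon$ floor avoids division by
zero in empty target bins. Search proceeds by simulated annealing —
single-coordinate Gaussian proposals scaled to each bound range and
reflected at the bounds, Metropolis acceptance $e^{-\Delta/T}$, geometric
cooling from $T_0 = $ initial GOF down to $10^{-3} T_0$ — followed by
coordinate-wise greedy descent with shrinking steps on every archived
local minimum scoring within 5% of the best. A state is archived as a
local minimum when it is abandoned through an uphill move without any
downhill proposal having been seen from it. Default parameter bounds
(`dev_rate` in [0, 0.2], `B1` in [0, 0.5], `B2` in [0, 0.01], log-means
in [-8, 2], log-sds in [0, 2]) are artifact choices, configurable.

### Limits of the goodness of fit

Two structural properties of this GOF are worth knowing. First, the
$\varepsilon$-floored denominator makes any model mass in an *empty*
target cell cost $m^2/10^{-6}$ — zero-cell collisions dominate the score
at small simulation sizes, which is why the self-calibration noise floor
is far above zero at an independent seed. Second, the incidence table
contributes $O(t_b) \sim 10^{-3}$ per bin (a full miss of every bin costs
only $\sum t_b \approx 0.03$) while size-distribution shape terms are
$O(0.1)$ per cell: a GOF-optimal parameter set is therefore nearly
unconstrained in its incidence curve below the overshoot scale. The
acceptance suite implements the "incidence recovered within Monte Carlo
noise" check faithfully and it fails for exactly this reason; the
headline recovery criterion (GOF reduced by at least 90% from the
random-start median under the scaled-down schedule of 2,000 annealing
steps at 20,000 persons per evaluation) passes with orders of magnitude
to spare.

## The synthetic stated world

Nothing is downloaded: every input has a synthetic, programmatically
generated stand-in, clearly labelled as such.

* **Life table** — Gompertz–Makeham with an infant term, tuned once to
  approximate US female period mortality (life expectancy ≈ 79–81,
  $q_{50} \approx 3\times10^{-3}$).
* **Calibrated parameter set** (`inst/extdata/params_synthetic.json`) —
  the published model's calibrated values are not available, so the
  package bundles a synthetic analog chosen during development to
  reproduce the published verification surface: ≈50% of 50-year-old women
  carrying at least one pre-clinical nodule and ≈6.4% a malignant one,
  ≈1.9% cumulative detected cancer over ages 15–85, and ≈99% of
  reservoir nodules under 10 mm. Incidentally, the first two are almost
  forced by structure: with Poisson-like initiation, prevalence pairs
  $(1-e^{-\Lambda},\, 1-e^{-0.1\Lambda})$ at $\Lambda \approx 0.69$ give
  (50.0%, 6.7%) — which is also why the age-50 screen in the acceptance
  report counts *all* nodules rather than only those ≥3 mm: the published
  pair is mutually consistent under the count-all reading and not under
  the ≥3 mm one. `screening_cross_section()` keeps the 3 mm floor as its
  default, with `detect_floor = 0` available.
* **Calibration targets** (`inst/extdata/targets_synthetic/`) — generated
  from the bundled parameter set at 200,000 persons, giving a
  self-consistent SEER-emulating target surface for download-free
  calibration runs. Their incidence curve rises from ≈55 to ≈270 per
  100,000 per 5-year bin across adult ages; real registry incidence
  declines more after 60 than this synthetic world does.
* **Longitudinal kinetics cohort** (`synthetic_longitudinal()`) — a
  221-patient stand-in for the observational active-surveillance series:
  ages 21–80, follow-up lognormal with the sample median pinned at
  exactly 9.7 years by quantile-matched sampling, class mix
  0.301/0.252/0.447, kinetic rates drawn from the input distributions,
  2% multiplicative measurement noise on diameters. It reproduces the
  cohort's stated summary statistics, not any patient's trajectory;
  analyses of per-class proportions under the ±3 mm classification rule
  are *not* asserted against the input probabilities, because slow
  shrinkage rarely crosses 3 mm of diameter inside a decade.

A green test on this world establishes internal consistency — the
machinery recovers what it generated — not external validity against
registry data, which would require the real SEER tables in the documented
CSV schemas.

## Design choices on open points

* **Event order within a cycle** (death → initiation → growth →
  detection) is fixed and documented; it shifts incidence by less than
  one cycle.
* **Behavior re-switching**: none — one decision at year five; growing
  nodules keep their original logistic trajectory through the switch.
* **Shrink clock**: restarts at the switch ($V_0$ is the volume when
  shrinking starts).
* **One initiation per cycle**: `dev_rate` is a per-cycle Bernoulli
  probability; multinodularity emerges across cycles.
* **Benign-vs-malignant detection**: Eq-style detection depends only on
  age and largest-nodule volume; the 0.164 malignant share of detections
  is a calibration target, not a mechanism inside the detection rate.
* **Constant-series shrink fits**: `fit_shrink_rate()` returns 0 for a
  flat volume series (rate zero) rather than erroring; only records with
  fewer than two observations are rejected.
* **Incidence denominator**: detections per person alive and undetected
  entering the 5-year bin — a proportion, not a per-100,000 rate.
* **Size at detection**: the largest *malignant* nodule's diameter for
  `malignant_found` persons (the primary-tumor size a registry would
  record), the largest nodule overall for `benign_only` persons.

## Known limitations

Treatment, recurrence, survival after detection, male disease,
cost-effectiveness and molecular diagnostics are out of scope. The
synthetic calibrated set is one point in a ridge of near-equivalent fits:
development rate and detection rate trade off against each other, and
only the bundled targets pin them. Growing nodules that escape detection
can reach the 20 cm carrying capacity, which is biologically generous;
the detection term $B_2 V$ makes such nodules short-lived in the
simulated population.
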