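---
title: "Methods: consensus, agreement and non-inferiority for region-level burn assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus, agreement and non-inferiority for region-level burn assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnagree)
```

## The design this package analyses

A diagnostic accuracy and agreement study of burn assessment compares three
sources of judgement on the same material: an automated model (one rating per
case), a group of emergency physicians (here 18), and a small expert panel
(here 3) whose consensus is the reference standard. The analytic unit is the
*region-case* — one anatomically distinct burn region on one patient — and
patients can contribute several region-cases, so observations are clustered
by patient and all inference must respect that clustering. Each rating is a
TBSA contribution in percentage points and an ordinal depth class
(superficial partial = 1 < deep partial = 2 < full thickness = 3, with
`non_assessable` allowed for the panel).

Two analysis populations are built: the Full Analysis Set (cases with a
usable model rating, at least one physician rating and an assessable panel
rating) and a Per-Protocol set that further drops cases rated non-assessable
by two or more panelists. TBSA values outside [0, 100] are never used
silently: they stay in the data with an entry-error flag and are excluded
from every computation. The conservative flag-and-exclude rule is a package
decision; carrying the flagged value keeps the audit trail intact.

## Consensus rules

Panel consensus is the median TBSA and the majority depth class. A full
three-way depth tie defaults to deep partial; a two-way tie is broken toward
the deeper class, the clinically safer direction. The case is auto-accepted
when the panel TBSA range (max − min) is at most 2 percentage points *and* a
strict majority (> n/2) depth class exists; otherwise the case is flagged
`needs_adjudication`. In the live study that flag triggers a human re-score
round, which software cannot re-execute; the package therefore still reports
the median/majority consensus for flagged cases and exposes the flag so
users can audit which cases would have been adjudicated.

Physician-group consensus uses the same median (midpoint convention for the
even 18-rater group) and the modal depth class with the same deeper-class
tie-break, flagged when a tie-break fired. Two caveats are deliberate
choices and remain overridable: "majority" in the auto-acceptance test means
strict majority, not plurality; and the deeper-class tie-break is provably
monotone in each vote for a 3-member panel (verified exhaustively in the
tests) but *not* for larger groups, where raising a non-modal vote can
dissolve a tie in favour of a lower class — a structural property of modal
rules, documented rather than hidden.

Pre-consensus agreement is summarised by ICC(2,1) for TBSA and, for depth,
the mean pairwise quadratically weighted kappa across rater pairs: no
standard multi-rater generalisation of weighted kappa is canonical enough to
assume, so the transparent pairwise mean is used.

## The primary endpoint

For region-case $i$, let $\Delta_i$ be the model's absolute TBSA error minus
the physician-median absolute error, both against the panel. The location of
the $\Delta_i$ is estimated by the Hodges–Lehmann estimator, the median of
all Walsh averages $(\Delta_i + \Delta_j)/2$ over $i \le j$ (self-pairs
included), which is robust to the heavy right tail that absolute errors
produce. Its one-sided 95% upper confidence bound comes from a patient-level
cluster bootstrap: patients are resampled with replacement and each drawn
patient contributes *all* its region-cases (so replicate sample sizes vary —
no re-balancing). The decision rule on the upper bound $u$ with margin
$\Delta^\* = 3$ pp is: superior if $u < 0$; non-inferior if $u \le \Delta^*$
(superiority implies non-inferiority; the strongest label is reported);
otherwise not demonstrated. With all-zero deltas the bootstrap distribution
is degenerate at 0, giving $u = 0$: non-inferior but, by the strict
inequality, not superior.

Bootstrap details, all fixed and documented rather than tunable defaults
hiding in code paths:

* percentile intervals with the inclusive type-7 quantile convention
  (basic/BCa intervals are deliberately out of scope for v1);
* 5000 resamples for the primary endpoint, 2000 for agreement-metric
  intervals;
* clusters are sorted canonically (by id, then value) before sampling and a
  single seeded RNG stream drives all replicates, so the replicate vector is
  reproducible from the seed and invariant to input row order; per-replicate
  counter substreams would buy parallelism the package does not use;
* a statistic may be undefined on degenerate resamples (kappa on an all-one-
  class replicate of a 64-case study); such replicates are recorded and
  tolerated up to 1% of the total, beyond which the bootstrap aborts with
  diagnostics rather than silently quoting quantiles of a censored
  distribution.

## The secondary battery

All follow their standard definitions; the numerically consequential
choices are:

* **Tolerance bands are inclusive** (error ≤ 3 pp counts as "within 3 pp").
* **Lin's CCC** uses population $1/n$ moments, per the original definition;
  at $n \approx 64$ the $1/(n-1)$ variant changes the third decimal, so the
  convention matters and is pinned by tests.
* **Bland–Altman** limits are bias ± 1.96 sd of the differences with the
  sample $(n-1)$ SD.
* **Weighted kappa** uses agreement weights $w_{ij} = 1-(i-j)^2/(k-1)^2$;
  the unweighted scheme reduces exactly to Cohen's kappa (property-tested to
  1e-12). On a 3-class table with one dominant category this statistic can
  sit near zero while raw agreement is high — the kappa paradox; the package
  computes both so the dissociation is visible instead of puzzling.
* **ICC(2,1)** is computed from the two-way ANOVA mean squares and requires
  a complete cases × raters matrix (complete-case restriction upstream);
  the studies this package targets have complete physician data.
* **DeLong's test** for paired AUCs is computed from placement values, with
  midrank (half-credit) tie handling; a class with a single member
  contributes no estimable covariance and identical score vectors return
  $z = 0$, $p = 1$ by convention.
* **Threshold discrimination** applies whole-body cut-points (adults ≥ 20%
  TBSA, pediatrics ≥ 10%, both configurable — the pediatric literature spans
  10–15 and the scalar default is the conservative low end) at the patient
  level by summing each patient's regional TBSA per method, because the
  clinical cut-points refer to whole-body burden; region-level evaluation is
  selectable. An absent class yields an explicit undefined result with
  count diagnostics, not a crash or a fabricated AUC.
* **Confusion-matrix reconstruction** from margins and diagonal is an
  exhaustive integer search over the four free cells; it returns a matrix
  only when the solution is unique and otherwise reports the solution count,
  since an ambiguous reconstruction silently resolved would fabricate data.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every simulation property in the test suite is evaluated.

Structure: 52 patients contribute 1/2/3 regions with probabilities
43/52, 6/52, 3/52 (64 expected region-cases); region-level pediatric share
35/64 (the 18-year boundary splits age groups); anatomical sites
face-head/torso/upper/lower at 7/6/21/30 per 64; true depth prevalence
47/16/1 per 64. Patient-level covariates are shared by all regions of a
patient, which is what induces the clustering the bootstrap exists for.

True regional TBSA follows $15 \cdot \mathrm{Beta}(1.5, 5)$ — right-skewed
on (0, 15] pp, small regions dominating. No published per-region TBSA
distribution constrains this family; it is a modelling choice, exposed in
the configuration, and simulation conclusions should be read as conditional
on it.

Rater error model: a group's rating of a case with true TBSA $t$ is
$\alpha + \beta t + b_r + \varepsilon$, clipped to [0, 100], with
$b_r \sim N(0, \sigma^2_{rater})$ shared across cases and
$\varepsilon \sim N(0, \sigma^2_{resid})$. Under $\beta = 1$ the theoretical
single-rater ICC is $\sigma^2_{case}/(\sigma^2_{case} + \sigma^2_{rater} +
\sigma^2_{resid})$, so target ICCs pin the noise totals in closed form
(`icc_noise_sd()`): physicians are calibrated to ICC 0.71 and panelists to
0.97 against the Beta family's case variance ($\approx 5.33$). The model
rater uses $\alpha = 1.05$, $\beta = 0.71$ (calibration compression) and
residual SD 2 pp. Depth errors are drawn per rater from a true-class
confusion row, conditionally independently given the true class. The model
rater's confusion rows are the empirical rates of the reconstructed depth
table (e.g. 13/16 of true deep-partial cases reported as superficial
partial, full thickness never reported); the panel confusion was calibrated
analytically — via the closed-form expected pairwise kappa at the default
prevalence — so that pre-consensus depth κw is ≈ 0.86.

What the generator does *not* emulate: case-difficulty random effects (depth
errors are independent across raters given truth, so real studies where hard
cases fool everyone will show more correlated errors than simulated ones),
within-patient correlation of true TBSA beyond shared covariates,
skin-tone/illumination effects, and any quality–error dependence (image
quality is drawn independently, which is exactly what makes it a negative
control for the quality-sensitivity analysis). Clipping at 0 slightly
shrinks noise for the smallest regions, which nudges empirical ICCs a few
thousandths above their closed-form targets; recovery tests use tolerances
wide enough to be honest about that, and the exact-recovery tests draw from
the unclipped linear model where the closed form is exact.

## Simulation sizes and numerical tolerances

Monte-Carlo test sizes are the package's own accuracy/runtime trade-offs:
500 outer replicates for the bootstrap coverage check (93–97% acceptance
band at nominal 95%) and the exchangeable-null false-superiority check
(bounded by 5% plus the binomial 95% allowance), 200 replicates for ICC and
calibration parameter recovery (judged within two Monte-Carlo standard
errors of the mean), 1000 bootstrap resamples per simulated study inside the
null check and the one-region-per-patient sensitivity default — the rate
and stability conclusions these support are insensitive to the resample
count, unlike a single study's quoted bound, which uses the full 5000.
Exact identities (kappa against its double-sum oracle, AUC against
exhaustive pair counting, Hodges–Lehmann against Walsh-average enumeration)
are asserted at 1e-12.

## Known limitations

* The adjudication flag marks, but cannot emulate, the human re-score round.
* ICC requires complete rating matrices (v1); incomplete designs need a
  complete-case restriction first.
* The modal depth tie-break is non-monotone for large rater groups (above).
* Percentile bootstrap bounds can be slightly anticonservative at 52
  clusters; the coverage test quantifies this under the generator's
  conditions, not under all real-world error distributions.
* Decision labels follow the strongest-claim convention; a study wanting
  separate superiority and non-inferiority claims should read the bound and
  margin directly from `tidy()`.
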