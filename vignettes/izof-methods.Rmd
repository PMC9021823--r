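---
title: "Individual optimal-functioning zones: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual optimal-functioning zones: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izofr)
```

## The problem and the model

The individual zone of optimal functioning (IZOF) framework holds that the
anxiety level at which a performer does best is a personal constant, not a
population one: the same pre-performance state that energises one pianist
derails another. `izofr` operationalises this for multidimensional state
anxiety measured with the CSAI-2 inventory, whose three subscales —
cognitive anxiety (CA), somatic anxiety (SA) and self-confidence (SC) —
each sum nine items rated 1–4 into a 9–36 total.

For participant $i$ and subscale $k$, given recalled occasions
$t = 1,\dots,n_i$ with intensities $x_{ikt}$ and judged performance scores
$S_{it}$, the zone is

$$\mathrm{IZOF}_{ik} = M_{ik} \pm \tfrac{1}{2}\,\mathrm{SD}_{ik},$$

where $M_{ik}$ is the mean intensity over the occasion(s) achieving the
participant's *personal best* score and $\mathrm{SD}_{ik}$ is the standard
deviation of the subscale over **all** recalled occasions. The model's key
assumptions are (a) that the recalled best performances are informative
about the optimum, (b) that within-person fluctuation is roughly symmetric
around that optimum so that $\pm\mathrm{SD}/2$ is a sensible bandwidth, and
(c) that performance declines with distance from the zone, which motivates
the prospective statistics: membership combinations before an upcoming
jury, and the rank correlation between the distance to the closest zone
border (defined as 0 inside the zone) and the eventual score.

## Estimation choices

Several points are underdetermined by the verbal definition; the package's
resolutions are:

* **Tied personal bests.** All occasions tied for the maximum score
  contribute to $M$ (`best_rule = "all-tied-best"`). With four recalled
  occasions and integer-ish trimmed panel scores, ties are common, and
  averaging over them uses strictly more information than an arbitrary
  tie-break. `"top1"`, `"topk"` and `"quantile"` rules are provided for
  sensitivity analysis.
* **SD convention.** Population (divide-by-$n$) SD is the default: the
  recalled occasions are the complete set of occasions the zone refers to,
  a fixed design rather than a sample from a larger occasion population.
  `sd_method = "sample"` switches to $n-1$.
* **Inclusive bounds.** Membership uses $l \le x \le u$. This makes the two
  prospective views consistent by construction:
  `classify_zone(x, l, u) == "in"` exactly when
  `zone_distance(x, l, u) == 0`.
* **Degenerate zones.** Zero within-person variance collapses the zone to
  a point $[M, M]$; classification and distance remain well defined.
* **Precision.** Bounds are carried at full floating precision; rounding to
  one decimal happens only in display and reports.

The retrospective validity statistics follow directly. The outstanding
threshold is pooled mean + 1 SD of all recalled scores, rounded to the
nearest integer for reporting (`threshold_round = "nearest"`); the
comparison uses `>=`, so with an integer threshold an exactly-threshold
performance counts as outstanding — `>` would misclassify it. The
$D$ statistic (mean in-zone score minus mean out-of-zone score) is
*undefined*, not zero, when a participant's occasions fall entirely on one
side; undefined values are excluded from cohort averages rather than
zero-filled, which would bias $D$ toward the null. Cohort summaries weight
participants equally, not occasions, so a participant with unusual occasion
counts cannot dominate the classification report.

Judge panels are aggregated by removing exactly one occurrence of the
maximum and one of the minimum (sort, drop one from each end) and averaging
the rest — the 7-judge panel keeps five scores. With tied extremes,
removing *all* tied copies would change the retained count and is not what
a trim-one-per-end grading rule does. Panels generalise to $N \ge 3$
(trim 2, average $N-2$).

The published CSAI-2 item wording and key are deliberately not bundled;
item-level data are scored through a user-supplied JSON/YAML key mapping
each of the 27 items to a subscale, nine per subscale.

## The rank correlation

Zone distances are zero for every in-zone performer, so ties are the rule,
not the exception. `spearman_cor()` therefore computes $\rho$ as the
Pearson correlation of midranks, with a two-sided $p$ from the $t$
approximation on $n-2$ degrees of freedom — appropriate at the cohort sizes
(dozens) this analysis targets. An exact permutation option enumerates all
$n!$ permutations for $n \le 8$ (40,320 at the cap, instantaneous; beyond
that enumeration grows uselessly large and the $t$ approximation is already
accurate). A constant vector (e.g. every performer in-zone) leaves $\rho$
undefined and is reported as `NA` rather than coerced.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per participant, a latent optimal triplet
$\mu_i$ from independent per-subscale normals (defaults: CA $18.0 \pm 4.9$,
SA $17.3 \pm 4.8$, SC $20.9 \pm 5.5$, instrument units, clipped to
$[9, 36]$ — the cohort scale a conservatory-sized study reports). Observed
occasion intensities are $\mathrm{round}(\mu_i + \varepsilon)$ with state
noise SD 2.6 (about twice the typical reported zone half-width, so that
estimated zones have realistic widths); the latent zone half-width defaults
to 1.3 = state SD/2, which makes $M \pm \mathrm{SD}/2$ a consistent
estimator of the latent band and parameter recovery a fair test. Occasion
performance is `base_score` (93) minus `penalty_beta` (2 score-units per
intensity-unit) times the *mean* zone distance over the three subscales,
plus residual noise (SD 1); each of 7 judges adds independent noise (SD 2)
before rounding, and the recorded score is the trimmed panel aggregate.
The default design is 4 recalled + 1 predicted occasion for 30
participants. All draws flow from one seed; the same seed and configuration
reproduce the cohort bit-for-bit, and the caller's RNG state is restored.

The generator emulates the *structure* the analysis assumes — personal
optima, symmetric state fluctuation, distance-penalised performance, panel
noise — not the full texture of real jury data: no drift or learning across
occasions, no recall bias in retrospective self-ratings, no cross-subscale
correlation by default (a correlation-matrix hook exists but defaults to
identity), and no judge-specific severity or halo effects (judge errors are
independent and exchangeable). Passing parameter-recovery tests on this
generator therefore shows the estimator recovers what the model plants, not
that real recalled ratings satisfy the model.

Two behaviours of the generator are worth knowing when interpreting
simulated output. First, because the performance penalty acts through the
mean distance across the three subscales, any single subscale's distance
carries only about a third of the signal; single-subscale rank correlations
in simulated 30-participant cohorts are modest and noticeably noisier than
the pooled relationship, and their sign can flip in a nontrivial fraction
of seeds at the default noise levels. Second, with state fluctuation (2.6)
about twice the latent half-width (1.3), in-zone predicted occasions are
relatively rare, so the all-three-in combination is sparser in simulated
cohorts than in cohorts whose members regulate themselves toward their
zones.

## Problem sizes used in the test suite

The oracle-equivalence checks compare zone estimation, judge aggregation,
classification accuracy and the rank correlation against brute-force
reimplementations on 1,000 random small instances at $10^{-12}$ tolerance.
Parameter recovery uses 20 seeded cohorts of 500 participants (recovery of
cohort-level center means, and MAE shrinkage when recalled occasions grow
from 4 to 32); sign and null calibration of the distance–performance
correlation use 100 seeded cohorts of 30. These sizes give Monte-Carlo
error well inside the asserted tolerances while keeping the default test
run in minutes.

## Known limitations

Zones estimated from four occasions are wide-variance objects; the MAE
reported by `recovery_error()` quantifies this directly, and it shrinks
slowly ($\propto 1/\sqrt{n}$ at best) with more occasions. The pipeline
deliberately stops at rank correlation for the distance–performance
relationship — no regression modelling of scores on distance — and performs
no inferential testing on the descriptive tables. Missing values are
rejected rather than imputed, and reverse-scored items are unsupported: the
item key asserts a direct sum per subscale.
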