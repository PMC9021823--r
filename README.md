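# izofr

Individual zones of optimal functioning (IZOF) for performance-anxiety data.

Performers differ in how much pre-performance anxiety helps or hurts them:
some play their best keyed-up, others only when calm. The IZOF model makes
this individual difference measurable. From repeated observations of a
performer's multidimensional state anxiety — the three CSAI-2 subscales:
cognitive anxiety (CA), somatic anxiety (SA) and self-confidence (SC), each
scored 9–36 — linked to judged performance scores, it estimates a personal
optimal *band* per subscale and uses band membership to explain and predict
performance. `izofr` implements that analysis as a reusable, tested pipeline
for psychometric repeated-measures data: conservatory juries, sport
competitions, or any setting with a panel-scored outcome and a state
inventory.

## The model

For participant *i* and subscale *k*, with recalled occasions
*t = 1…n<sub>i</sub>*, anxiety intensities *x<sub>ikt</sub>* and performance
scores *S<sub>it</sub>*:

- **Zone**: IZOF<sub>ik</sub> = *M<sub>ik</sub>* ± ½ *SD<sub>ik</sub>*, where
  *M<sub>ik</sub>* is the mean of *x<sub>ikt</sub>* over the occasion(s)
  attaining the participant's best score (ties all included) and
  *SD<sub>ik</sub>* is the (population) standard deviation of
  *x<sub>ikt</sub>* over all recalled occasions. Bounds are inclusive.
- **Judge aggregation**: a panel of *J* ≥ 3 scores (1–100) is trimmed —
  one highest and one lowest removed — and averaged (*J* = 7 by default).
- **Outstanding threshold**: pooled mean + 1 SD of all recalled scores,
  reported to the nearest integer.
- **Validity**: per participant and subscale, *D* = mean(*S* | in-zone) −
  mean(*S* | out-of-zone); correct classification = % of occasions that are
  outstanding-and-in-zone or less-than-outstanding-and-out-of-zone.
- **Prediction**: a pre-performance triplet is classified below/in/above per
  subscale; the 8 In/Out combinations over (SA, CA, SC) are tabulated
  against actual scores, and Spearman's ρ (midranks, *t* approximation;
  exact permutation for small *n*) relates the distance from the closest
  zone border (0 inside the zone) to the score.

A seeded generator (`simulate_cohort()`) produces cohorts with known latent
zones — state fluctuation around a personal optimum, distance-penalised
performance, judge noise — for parameter-recovery and calibration testing.

## Worked example

```r
library(izofr)

sim <- simulate_cohort(cohort_config(), seed = 7)  # 30 pianists, 4+1 occasions
fit <- izof(sim$cohort)
fit
#> Individual zones of optimal functioning
#>
#>   Participants: 30   recalled occasions: 120   predicted occasions: 30
#>   Zone rule: M (all-tied-best) +/- SD/2 (population SD)
#>   Outstanding threshold: 93 (mean + 1 SD = 92.98)
#>   All three subscales in-zone: 0.0%
```

The outstanding threshold (93) is the pooled mean + 1 SD of the 120 recalled
scores. Each participant's zone bounds are in `coef(fit)`:

```r
round(coef(fit)[1:3, 1:6], 2)
#>      ca_center ca_lower ca_upper sa_center sa_lower sa_upper
#> P001        31    30.39    31.61        13    12.11    13.89
#> P002        10     9.06    10.94        21    19.81    22.19
#> P003        14    13.17    14.83        21    19.66    22.34
```

P001 performs best keyed-up (CA optimum 31 of 36), P002 when calm (CA 10) —
the individual differences the zone analysis exists to capture. The
prospective stage classifies each pre-jury triplet and correlates zone
distance with the actual score:

```r
predict(fit)[1:3, c("participant_id", "pattern", "n_in", "score")]
#>   participant_id     pattern n_in score
#> 1           P001   Out/In/In    2  93.4
#> 2           P002  In/Out/Out    1  89.6
#> 3           P003 Out/Out/Out    0  92.4

summary(fit)$phase2$correlations
#>   subscale         rho    p_value  n
#> 1       ca -0.34692229 0.06034843 30
#> 2       sa  0.02275778 0.90498369 30
#> 3       sc -0.42703517 0.01859476 30
```

Negative ρ means performances degrade with distance from the personal zone.
`at_least_k_in(fit$phase2$combinations, 2, score_floor = 90)` gives the
headline percentage of performers with ≥ 2 subscales in-zone who also scored
at least 90. `run_pipeline()` chains the whole analysis and writes the
report CSVs (`zones.csv`, `classification_report.csv`,
`combination_table.csv`, …); `inst/scripts/izof.R` wraps it for the shell.

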