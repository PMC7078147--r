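# lesiondyn

Lesion-level tumor heterogeneity from the dynamics of individual target
lesions, and its link to overall survival.

Oncology trials measure a handful of *individual target lesions* (iTLs) per
patient — at most 5 per organ and 10 in total — then collapse them into one
total tumor size per visit (SLD in mm under RECIST, SOPD in mm² under the
modified WHO criteria). `lesiondyn` keeps the lesions apart and asks whether
they move together: it classifies each lesion into an organ class from its
free-text location, quantifies the similarity of every within-patient pair
of size trajectories as a lagged cross-correlation coefficient (CC),
clusters the CCs, and carries a per-patient heterogeneity metric — the
median zero-shift inter-class CC — into Kaplan-Meier, log-rank and Cox
proportional-hazards analyses of overall survival. It is aimed at
pharmacometricians and biostatisticians deciding whether a tumor-size model
(or a survival model) needs to account for between-lesion heterogeneity.

## The method in brief

For two aligned size series \(x, y\) on their common assessment visits, the
CC at visit-index shift \(k\) is the Pearson correlation on the overlap:

```
CC(k) = sum_i (x_i - xbar)(y_{i+k} - ybar) /
        sqrt( sum_i (x_i - xbar)^2 * sum_i (y_{i+k} - ybar)^2 )
```

evaluated for |k| ≤ 12 (and never beyond what the overlap allows), so every
defined value lies in [−1, 1]: 1 = parallel dynamics, −1 = opposite
dynamics. The *inter-class* analysis compares per-organ lesion aggregates
(cTLs) inside each multi-organ patient; the *intra-class* analysis compares
lesion pairs within one organ. CC values are grouped by 1-D K-means
(elbow-diagnosed, conventionally k = 3) and clusters are labeled by their
centroid: *different* below −0.35, *similar* above 0.35, *undefined*
between. Each patient's median zero-shift inter-class CC, dichotomized at
0.35, is tested as a survival predictor next to ECOG status, baseline tumor
size, the week-8 shrinkage ratio (TS0 − TS8)/TS0 and KRAS status.

Because real lesion-level trial data are proprietary, the package ships a
synthetic multi-lesion mCRC-like trial generator (`simulate_trial()`) with
controllable heterogeneity (probability an organ class follows divergent
growth-dominant dynamics, delayed-response classes) and survival tied to the
true class concordance — every pipeline stage is testable end to end, with
a truth log for parameter-recovery checks.

## Worked example

```r
library(lesiondyn)

sim <- simulate_trial(sim_config(n_patients = 500, seed = 20260920))
res <- run_pipeline(validate_lesion_records(sim$records), sim$covariates,
                    k = 3, seed = 11)
res$report_zero$table
```

```
 cluster centroid n_pairs pct_pairs n_patients pct_patients     label
       1   -0.870     175      31.4        117         38.6 different
       2   -0.710      74      13.3         60         19.8 different
       3    0.959     308      55.3        228         75.2   similar
```

55% of inter-class cTL pairs (75% of multi-organ patients) show similar
dynamics; the rest sit in negative-centroid clusters — those patients'
organs respond differently. The realized divergent-pair fraction in the
generator's truth log is 46.9%, matching the 31.4 + 13.3 = 44.7% of pairs in
the negative clusters.

```r
res$logrank          # chi-square 24.00, p = 9.6e-07
res$cox_continuous$table
```

```
      term    hr hr_lower hr_upper     p
      ecog 1.742    1.260    2.409 0.001
       ts0 1.003    1.000    1.005 0.038
 ts_ratio8 1.103    0.329    3.704 0.874
      kras 1.315    0.951    1.817 0.097
 median_cc 0.646    0.538    0.777 0.000
```

Patients whose organs move together live longer: each unit of median CC
multiplies the hazard by 0.65 (the generator's true value is 0.74, inside
the 95% CI), and the Kaplan-Meier median is 63.1 weeks for median CC > 0.35
versus 33.7 weeks at or below it.

The numbered scripts under `analysis/` run the same workflow stepwise —
`01_simulate.R` → `05_survival.R` — printing what each stage found and
writing tables under `results/tables/` (bulk intermediates go to
`scratch/`).

## Package layout

- `R/trial_data.R` — readers, validation, exclusion rules, series assembly,
  total tumor size at landmarks
- `R/lesion_classifier.R` — keyword ruleset (editable YAML in
  `inst/extdata/organ_classes.yaml`), rare-class merging, class summaries
- `R/crosscorr.R` — lagged cross-correlation of lesion pairs
- `R/heterogeneity.R` — cTL aggregation, pair enumeration, 1-D K-means,
  elbow selection, cluster reports and lag histograms
- `R/survival_link.R` — median CC, dichotomization, KM / log-rank / Cox
- `R/synthetic_trial.R` — trial generator, truth log, canned fixtures
- `R/pipeline.R` — end-to-end orchestration and CSV export
- `vignettes/lesion-heterogeneity.Rmd` — the methods vignette: model
  assumptions, numerical choices, generator design, limitations
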