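# limbkin

Limb kinematics clustering for post-stroke gait analysis.

Post-stroke gait disorders change how the paretic lower limb moves as a
whole. `limbkin` analyses sagittal-plane hip/knee/ankle joint-center
trajectories (e.g. markerless pose-estimation output at 120 Hz) in terms of
two limb endpoint variables:

- **limb extension angle** — the cycle minimum of the signed angle θ between
  the downward vertical and the hip→ankle vector (flexion positive, so the
  extension peak is negative), reached in terminal stance;
- **effective limb length** — the swing-phase minimum of
  r = |hip − ankle| / (|hip − knee| + |knee − ankle|) ∈ (0, 1],
  which quantifies limb shortening for ground clearance.

From those per-participant features the package

1. segments gait cycles from the shank angular velocity (swing peak flanked
   by toe-off and heel-contact minima), time-normalises strides onto a
   201-point cycle basis, trims the first/last 3 strides and averages 10;
2. clusters participants with a full-covariance Gaussian mixture fitted by
   EM, the number of components K ∈ {4..7} selected by BIC
   (−2 log L + p log n, p = 6K − 1) with ICL (BIC + 2·entropy) reported
   alongside, and 95% confidence ellipses
   (semi-axes √(χ²₂(0.95)·eigenvalues));
3. compares clinical and gait variables across clusters with Kruskal–Wallis
   tests (effect size ε² = H/(n−1)), Steel–Dwass all-pairs post-hoc tests
   (standardized pairwise Wilcoxon statistic referred to the studentized
   range), Spearman correlations with Fisher-z CIs, and chi-squared tests
   for categorical demographics.

Because cohorts of this kind are not publicly deposited, the package ships a
synthetic-data generator that plants known cluster structure at every level
— feature pairs from a configurable mixture, explicit walking trajectories
whose extracted features equal the planted values, and cluster-conditional
ordinal clinical scores — so the entire pipeline is testable end to end.
It is intended for gait researchers and biostatisticians who want a
reproducible, scriptable version of this analysis for their own keypoint
data, and for methodologists studying the pipeline itself.

## Worked example

Simulate a 67-participant cohort from the default five-cluster scenario,
extract features from the raw trajectories, select and fit the mixture, and
compare clinical variables across clusters:

```r
library(limbkin)

scenario <- default_scenario(n_participants = 67, seed = 7)
cohort   <- simulate_cohort(scenario)            # features, walks, clinical
features <- do.call(rbind, lapply(cohort$walks, function(w)
  analyze_walk(w, meters_per_pixel = 9e-4)))
head(features[, 1:4], 3)
#>      limb_angle_ext_peak limb_length_min_swing gait_speed  cadence
#> P001           -28.88890             0.9619293  0.7347185 108.1893
#> P002           -18.44654             0.9418613  0.6071829 109.5057
#> P003           -15.30619             0.8467343  0.5312151 103.1519

sel <- select_model(as.matrix(features[, c("limb_angle_ext_peak",
                                           "limb_length_min_swing")]),
                    K_range = 4:7, seed = 11)
sel
#> <gmm_selection> K selected by BIC: 5 (ICL minimum at K = 5)
#>  K log_likelihood n_params      BIC      ICL
#>  4     -26.992460       23 150.6929 150.6930
#>  5      -6.313125       29 134.5623 134.5624
#>  6       3.835952       35 139.4923 140.4438
#>  7       4.436558       41 163.5193 165.2465
```

Five components minimise both criteria; the hard labels recover the five
planted clusters exactly (one-to-one up to label permutation). The two
features correlate across the cohort (extension is a negative angle, so a
negative rho means stronger extension goes with longer effective length):

```r
spearman_ci(features$limb_angle_ext_peak, features$limb_length_min_swing)
#>      rho ci_low ci_high     p  n
#>   -0.377 -0.566   -0.15 0.002 67
```

Cluster-wise comparison of clinical and gait variables:

```r
tab <- cbind(cohort$clinical, features)
cmp <- compare_clusters(tab, sel$model$hard_labels,
                        ordinal_vars = c("fms", "mas", "sf_bbs", "gait_speed",
                                         "cadence", "gait_stability_ratio"))
cmp$kw[, c("variable", "H", "df", "epsilon_sq", "p", "stars")]
#>              variable     H df epsilon_sq        p stars
#>                   fms 43.23  4     0.6550 9.27e-09   ***
#>                   mas 43.83  4     0.6640 6.97e-09   ***
#>                sf_bbs 50.84  4     0.7703 2.41e-10   ***
#>            gait_speed 52.50  4     0.7954 1.08e-10   ***
#>               cadence  2.83  4     0.0429 5.86e-01
#>  gait_stability_ratio 60.40  4     0.9152 2.39e-12   ***
```

The motor-synergy score (`fms`), plantar-flexor spasticity (`mas`), balance
(`sf_bbs`) and gait strategy differ strongly across clusters while cadence
alone does not — the structure the generator planted. The Steel–Dwass
matrix for spasticity separates the two low-spasticity clusters from the
three high-spasticity ones:

```r
round(cmp$posthoc_matrices$mas$p, 3)
#>       1     2     3     4     5
#> 1    NA 0.907 0.000 0.000 0.000
#> 2 0.907    NA 0.002 0.001 0.001
#> 3 0.000 0.002    NA 0.969 0.999
#> 4 0.000 0.001 0.969    NA 0.881
#> 5 0.000 0.001 0.999 0.881    NA
```

`run_all(run_config(seed = 7), "out/")` performs the same workflow end to
end and writes `features.csv`, `selection_table.csv`, `clusters.csv`,
`ellipses.csv`, `kw_results.csv`, per-variable Steel–Dwass matrices and a
run log; reruns with the same seed are byte-identical. Real data enter
through `read_openpose_dir()` (BODY_25 per-frame JSON),
`read_keypoint_csv()` and `read_clinical_csv()`.

## Package layout

- `R/synth.R` — scenario definitions, mixture sampling, walk synthesis,
  clinical-score generation
- `R/io.R` — OpenPose JSON / CSV keypoint readers and writers, clinical
  table validation
- `R/kinematics.R` — filtering, limb angle/length, event detection, cycle
  normalisation, feature extraction
- `R/gmm.R` — EM, BIC/ICL, model selection, confidence ellipses
- `R/stats.R` — Spearman CI, Kruskal–Wallis + ε², Steel–Dwass, chi-squared,
  cluster comparison report
- `R/pipeline.R` — configuration and the end-to-end `run_all()`
- `vignettes/limb-kinematics.Rmd` — the model, parameter choices and their
  rationale, and known limitations
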