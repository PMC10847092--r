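---
title: "Limb kinematics clustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limb kinematics clustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbkin)
```

## The problem

Post-stroke gait disorders alter the kinematics of the paretic lower limb.
Rather than tracking each joint separately, the *limb endpoint* view treats
the whole limb as one segment connecting the hip and ankle joint centers and
summarises its configuration with two variables:

- **limb angle** — the signed angle between the downward vertical and the
  hip-to-ankle vector in the sagittal plane, in degrees, flexion (ankle
  anterior to hip) positive. Its cycle minimum — the peak in the extension
  direction, a negative number — is the *limb extension angle*, reached in
  terminal stance and tied to propulsion.
- **effective limb length** — the hip-to-ankle distance divided by the sum of
  the hip-to-knee and knee-to-ankle distances. Dimensionless in (0, 1], equal
  to 1 only with the knee fully extended. Its minimum during the swing phase
  quantifies how much the limb shortens to clear the ground.

Participants occupy different regions of this two-dimensional feature space
(e.g. strong extension with little shortening versus weak extension with
strong shortening), and those regions go with different clinical profiles —
spasticity, motor paralysis, balance, gait strategy. The package models that
heterogeneity with a Gaussian mixture over the per-participant feature pairs,
selects the number of components by information criteria, and compares
clinical and gait variables across the resulting clusters with nonparametric
statistics.

## Signal processing

Input is a per-frame 2-D trajectory of the hip, knee and ankle joint centers
of the paretic side (markerless pose output or CSV), sampled uniformly —
120 Hz by default. The processing chain per trial is:

1. derive the limb angle, effective limb length and shank angle
   (knee-to-ankle vector, same sign convention) per frame;
2. low-pass filter the derived angle and length series with a zero-lag
   Butterworth filter, cutoff 6 Hz, order 4 per directional pass. The
   stated order is interpreted as per-pass; the forward-backward pass
   doubles the effective order, the convention most common in biomechanics.
   Filtering the *derived series* rather than the raw coordinates follows
   the usual wording of angle-data filtering; a `filter_coords` switch
   allows the other order for sensitivity analysis. The filter starts each
   pass in steady state at the first sample and pads by odd reflection, so
   constants pass through exactly and edge transients are below 1e-4 of the
   signal amplitude;
3. differentiate the filtered shank angle (central differences) into a
   shank angular velocity;
4. detect gait events with the standard shank-gyroscope heuristic: the
   swing phase appears as a dominant positive peak of shank angular
   velocity; heel contact is the local minimum immediately after that peak
   and toe off the local minimum immediately before it. Peaks are screened
   by topographic prominence at 20% of the largest prominence
   (`min_prominence_frac`, exposed in the configuration);
5. resample each heel-contact-to-heel-contact stride onto a 201-point
   gait-cycle basis by cubic spline (knots are preserved exactly; strides
   under 4 frames are dropped with a warning);
6. extract per-stride features — the limb-angle minimum over the full cycle
   (ties resolve to the earliest frame) and the limb-length minimum over
   the detected swing window (toe off to next heel contact) — then remove
   the first and last 3 strides and average up to 10 retained strides. If
   fewer than 10 remain, all are used and a warning is logged rather than
   failing the trial.

Cadence comes from the retained heel-contact times (two steps per stride);
gait speed from the net hip displacement when a meters-per-pixel calibration
is available (limb angle and length themselves are scale-free, so no
calibration is otherwise needed); and the gait stability ratio is cadence
divided by speed, in steps per meter — higher values indicate a
cadence-favouring strategy.

Two conventions had to be fixed where common practice varies: the swing
window for the limb-length minimum uses the *detected* toe off rather than a
fixed percent-cycle window, and the peak extension is the global cycle
minimum rather than a stance-restricted one. Both are configuration-visible
choices, not facts about any particular cohort.

## The synthetic cohort generator

No public dataset accompanies this problem, so the package ships a generator
that plants known structure at every level:

- **Features.** Each participant's (extension angle, limb length) pair is
  drawn from one component of a configurable bivariate Gaussian mixture.
  The default five-component scenario mirrors the qualitative layout
  reported for post-stroke cohorts — high/high, mid/high, low/high,
  high/low, mid/low in extension-magnitude-by-length space — with weights
  10/17/11/10/19 out of 67. The means are illustrative, not estimated from
  data; components are well separated (between 3.5 and 7 Mahalanobis units
  pairwise) so that cluster-count recovery is a meaningful test.
  Draws falling outside the feasible region (angle in (-60, 0) degrees,
  length in (0.5, 1]) are rejected and redrawn.
- **Walks.** Each feature pair is realised as an explicit hip/knee/ankle
  trajectory: the hip advances at constant speed with a small sinusoidal
  bob; the limb angle follows a smooth two-harmonic cycle whose minimum
  equals the planted extension angle exactly; and the knee flexes in swing
  by an amount *calibrated numerically* so that the limb-length minimum
  *after the 6 Hz analysis filter* equals the planted length (the filter
  slightly attenuates the swing dip, so an uncalibrated generator would be
  recovered a few thousandths too shallow). A loading-response knee-flexion
  wave with a steep rise and slow decay, its amplitude scaled to the
  limb-angle excursion, reproduces the post-swing braking minimum of shank
  angular velocity that event detectors key on; ground-truth event frames
  are computed from the closed-form profiles on a fine grid, independent of
  the detector code path. Isotropic Gaussian keypoint jitter (default SD
  1 px at a nominal 1000 px leg) emulates markerless-capture noise.
- **Clinical scores.** Ordinal scales (motor synergy 0-22, sensory 0-12,
  spasticity 0-5, short-form balance 0-28, ambulation category 0-5) are
  drawn as binomial-discretised variables with cluster-specific logit
  shifts — bounded by construction, ordinal, and friendly to rank-based
  tests. The default shifts encode the qualitative clinical profile of each
  cluster (spasticity high where limb length stays high, balance reduced in
  the low-extension clusters, mild profiles in the short-limb-length
  clusters); they are stand-ins, not calibrated to any cohort.

Noise-free round trips over a 10 x 10 grid of planted pairs recover the
extension angle to well under 0.1 degrees and the limb length to under
0.005; detected heel contacts match the generator's ground truth within 2
frames. The generator's accuracy domain for limb length is (0.5, 0.99]: in
walks whose knee essentially never flexes during swing, the loading-response
wave itself becomes the shortest configuration inside the swing window and
the round trip degrades to about 0.004.

What passing these tests does *not* show: the generator uses constant
stride periods within a trial, a single gait pattern family, no dropped or
swapped keypoints, no occlusions, and isotropic noise. Real markerless data
fail in ways the generator does not model; the io layer's confidence
handling and gap interpolation are tested separately on constructed
fixtures.

## Mixture model and model selection

The mixture is fitted by expectation-maximisation with full, unequal
covariances per component ("the distribution parameters are not equally
distributed"); spherical or tied structures are deliberately excluded from
the default search. Implementation choices:

- k-means++ seeding with 10 restarts (best final log-likelihood wins);
- convergence when the relative log-likelihood change falls below 1e-6
  (tighter tolerances are accepted where an equivalence test needs them);
- near-singular covariances receive a 1e-6 trace-scaled ridge; a run whose
  components still collapse is retried once with a stronger ridge and
  otherwise discarded, and an error is raised only if every restart
  collapses;
- hard labels are the responsibility argmax, ties to the lowest index.

Model selection scans K = 4..7 and reports both criteria in the
lower-is-better convention:

- BIC = -2 logLik + p log n, with p = 6K - 1 parameters in two dimensions;
- ICL = BIC + 2 EN, where EN is the total entropy of the responsibilities —
  an assignment-uncertainty penalty, so ICL >= BIC with equality for a hard
  partition.

The default selection is the BIC minimum; when ICL disagrees, both minima
are reported and the disagreement is logged, because adjudicating between
close models on substantive grounds is an analyst's judgment that the
package does not mechanise. Note that published selection tables of this
kind sometimes carry ICL values on a different scale than BIC + entropy can
produce; this package implements the standard definition and makes no
attempt to match any particular table's ICL magnitudes. Clustering operates
on one point per participant (stride-averaged features), not on stride-level
points.

The 95% confidence ellipse of a component has semi-axes
`sqrt(qchisq(0.95, 2) * eigenvalues)` of its covariance (chi-squared
quantile 5.9915) and rotation given by the leading eigenvector.

## Statistics

- **Spearman correlation** with average ranks for ties; the two-sided
  p-value uses the t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2
  degrees of freedom and the CI the Fisher z-transform with standard error
  `1/sqrt(n-3)`. These conventions reproduce a published
  (rho, p, CI) triple at n = 67 exactly to printed precision, which is how
  they were identified among the common alternatives.
- **Kruskal-Wallis** delegates the tie-corrected H and chi-squared p-value
  to `stats::kruskal.test()` and adds the epsilon-squared effect size
  `H/(n-1)` — the definition that reproduces both published effect sizes
  from their printed H values at n = 67. All-identical input returns H = 0,
  p = 1 by convention.
- **Steel-Dwass** all-pairs comparisons: each pair is ranked jointly
  (average ranks), the tie-corrected standardized Wilcoxon statistic z is
  formed, and `|z| sqrt(2)` is referred to the studentized range
  distribution with k groups and infinite degrees of freedom. This
  large-sample form is checked in the test suite against an exhaustive
  permutation oracle (all 34,650 arrangements of three groups of four) and
  agrees within 0.02. No additional multiplicity adjustment is applied
  beyond the procedure's built-in family-wise control.
- **Chi-squared** tests for categorical demographics use the Pearson
  statistic without continuity correction; expected counts below 5 raise a
  warning.
- Significance stars follow the 0.05 / 0.01 / 0.001 convention.

## Reproducibility and problem sizes

Every stochastic step draws from a sub-seed derived from one root seed
(`derive_seed()`), so a full pipeline run — simulate, extract, cluster,
compare — is byte-reproducible from a single integer, which the test suite
asserts on the emitted CSVs. The validation suite uses a 67-participant
default cohort, 16 strides per trial at 120 Hz, 20 seeds of n = 300 for
cluster-count recovery, a 10 x 10 planted feature grid for the kinematics
round trip, and 10^4 replicates for the null calibration of the
Kruskal-Wallis stage; these sizes were chosen to keep the whole suite
comfortably under a few minutes on a single core while leaving Monte-Carlo
error well below the tolerances being checked.

## Known limitations

- The event detector assumes the shank-gyro signature (one dominant
  positive swing peak per stride); heavily disordered signals without that
  signature are reported as "no strides detected" rather than guessed at.
- Gait speed requires an external meters-per-pixel calibration; without it,
  speed and the gait stability ratio are `NA` while the scale-free features
  remain valid.
- The mixture operates in two dimensions by design; the internal EM handles
  arbitrary dimension but that surface is not part of the tested contract.
- Clinical score generation is a structural stand-in (shifted binomials),
  suitable for calibration and power checks of the rank-based statistics,
  not for emulating any specific instrument's distribution.
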