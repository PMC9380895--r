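---
title: "Methods: assessing Big Five traits from gait keypoint sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing Big Five traits from gait keypoint sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfive)
```

## The measurement problem

Personality questionnaires are impractical in settings with deception
incentives or repeated measurement. Gait — a natural, stable, easily
filmed behaviour — carries personality-relevant signal: walking speed,
arm-swing vigour and limb coordination all co-vary with Big Five traits.
`gaitfive` implements a complete pipeline that turns a 2-D body-keypoint
recording of a walking person into predicted Big Five subscale scores, and
then evaluates those predictions the way a psychometrician evaluates a new
scale: criterion validity against an established inventory, split-half
reliability, and a multitrait-multimethod (MTMM) analysis of convergent and
discriminant validity.

The pipeline assumes front-view walking recorded by a fixed camera and
pose-estimated to the OpenPose BODY_25 skeleton (25 keypoints per frame,
pixel coordinates plus detection confidence). It does not perform pose
estimation, multi-person tracking or 3-D lifting.

## Preprocessing

**Ingestion and window unification.** Sequences arrive as per-frame OpenPose
JSON or flat CSV. Undetected keypoints (confidence below a threshold,
default 0.1, or the OpenPose `(0, 0, 0)` sentinel) are filled by linear
interpolation over the frame index, with nearest-value extension at the
ends. All subjects are then unified to a common 75-frame window so that
every feature is computed on identical temporal support. Where the original
protocol selected gait cycles manually, `unifyFrames()` substitutes an
automatic rule: the contiguous 75-frame window with the highest mean
detection confidence (ties to the earliest window). Sequences shorter than
75 frames are refused rather than resampled — up-sampling would change the
temporal sampling that the difference and wavelet features assume.

**MidHip translation.** Raw pixel coordinates confound gait with body
position in the image. Every frame is re-expressed relative to MidHip
(keypoint 8, the pelvis centre and a good proxy for the body's centre of
gravity): $x'_i = x_i - x_8$, $y'_i = y_i - y_8$. MidHip itself becomes
identically zero and is eliminated, leaving 24 keypoints. All downstream
features are therefore invariant to global translation of the walker.

**Smoothing.** Each of the 48 remaining coordinate series is convolved with
the unit-sum binomial kernel $[1, 4, 6, 4, 1]/16$. The boundary policy is
half-sample symmetric (reflect) padding — chosen because it preserves
constant series, leaves the interior of linear trends untouched, and keeps
the output at 75 frames. Smoothing is applied after translation, matching
the order in which the coordinate series visibly acquire their periodic
structure. Smoothing is linear and never increases a series' variance
(both properties are asserted in the test suite).

## Feature construction

From each preprocessed sequence a *feature data pool* of 132 named time
series is built:

* 48 **coordinate series** (24 keypoints × x, y) — static posture signal;
* 48 **interframe difference series**, $\Delta f_j = f_{j+1} - f_j$ —
  frame-to-frame motion;
* 26 **joint distance series** — per-axis distances $|x'_a - x'_b|$,
  $|y'_a - y'_b|$ over 13 joint pairs (head swing, upper-arm/arm swings,
  thigh/leg swings, relative swings of elbows, hands, knees and feet).
  Distances are magnitudes by default; a `signed = TRUE` flag preserves
  signs for users who want directional swings;
* 10 **joint angle series** — the angle at vertex $b$ of each triple
  $(a, b, c)$ (neck, shoulder, elbow, hip and knee angles bilaterally),
  computed as $\arccos$ of the normalised dot product, clipped to
  $[-1, 1]$ before $\arccos$ so rounding can never produce `NaN`, reported
  in degrees in $[0, 180]$. Zero-length rays (coincident keypoints) yield
  angle 0 with a warning. Because MidHip is eliminated, the hip angles use
  the opposite hip as the third point.

Each of the 48 coordinate series is additionally decomposed with a 5-level
Haar discrete wavelet transform into detail coefficient arrays
$D_1 \dots D_5$ and the approximation $A_5$, satisfying
$X = D_1 + \dots + D_5 + A_5$ when the bands are reconstructed — an
identity the test suite verifies to $10^{-8}$ relative tolerance on random
series. The transform uses half-sample symmetric extension (odd-length
levels repeat their final sample), so both 75-frame full sequences and
37-frame halves decompose cleanly; the implementation was cross-checked
against an independent reference decomposition frozen into the tests.

**Feature extraction.** Ten time-domain functions (maximum, minimum, mean,
median, variance, root mean square, skewness, kurtosis, absolute energy
$\sum x_j^2$, coefficient of variation) are applied to each of the 132
series: $132 \times 10 = 1320$ time-domain features. Four frequency-domain
statistics (absolute maximum, mean, variance, absolute energy) are applied
to each of the 6 coefficient arrays of each coordinate series:
$48 \times 6 \times 4 = 1152$ frequency-domain features. Total: **2472**
features, in a fixed deterministic order, with identical names for full and
half sequences. Time-domain functions are applied to the 132 time series
only, and frequency statistics to coordinate-series bands only — the only
assignment consistent with the 1320/1152 split.

Numerical conventions, chosen once and asserted in tests: moments are
*population* moments (variance divides by $n$), matching common
signal-feature practice; kurtosis is *excess* (Fisher) kurtosis; the
coefficient of variation is defined as 0 when the mean is exactly 0; and
skewness/kurtosis of a constant series are defined as 0 so feature vectors
stay finite.

## Modeling

With 2472 features and cohort-scale subject counts, regression directly on
features would overfit badly. Models are therefore fit through a transform
stack:

1. **Standardisation** per feature (zero-variance features get scale 1 and
   become zero columns);
2. **PCA**, retaining all `min(n − 1, rank)` components — the
   least-assuming choice, giving selection the full decorrelated space;
3. **Sequential forward selection (SFS)** of 40 components: greedily add
   the component that maximises the mean 5-fold inner cross-validation
   score (negative RMSE) of the estimator refit on the candidate subset,
   ties to the lowest index. Negative RMSE was chosen as the inner score
   because RMSE is the pipeline's headline error metric.

Seven regression algorithms are available: Gaussian process regression
(RBF kernel; the bandwidth is fixed by the median pairwise-distance
heuristic and the white-noise term at 0.1 var(y), so fits are
deterministic), linear regression, random forest regression (100 trees,
seeded), and epsilon-SVR with linear, polynomial, RBF and sigmoid kernels.
Targets are raw subscale sums, so RMSE is in score points. For the linear
estimator, SFS candidate scoring runs through an exact batched
normal-equations/Cholesky path (identical model to refitting OLS per
candidate — verified against a brute-force greedy oracle in the tests);
other estimators use a generic fit/predict loop. An `sfsEstimator` override
lets users score SFS with the fast linear path while fitting a kernel
regressor, since generic-path SFS over ~150 components with a kernel
estimator is computationally prohibitive; the default keeps estimator and
scorer identical.

**Three data streams.** Besides the full 75-frame stream, each sequence is
split into odd frames (1, 3, …, 73) and even frames (2, 4, …, 74) — 37
frames each from the first 74. The stack and regressor are always fitted on
all-frames features and merely *applied* to the odd/even features, so the
halves are measured by the identical instrument.

**Evaluation protocol.** 10 repetitions of 10-fold cross-validation. The
whole stack is refit inside every training fold, so held-out subjects never
influence standardisation, PCA or selection (asserted in tests). A
`stackMode = "global"` option fits one stack on the full cohort instead —
the literal reading of a single-stack flow diagram — but leaks feature
information across folds and is provided for comparison only. Each subject
receives one out-of-fold prediction per stream per repetition; the
aggregated prediction is the mean over the 10 repetitions (pooling choice:
the mean is the natural point estimate, and the per-repetition matrices are
retained for inspection).

## Psychometric evaluation

* **Criterion validity** $r_1$: Pearson correlation between aggregated
  all-frames predictions and the BFI-44 subscale scores, with
  $t$-distribution ($n-2$ df) p-values; RMSE alongside.
* **Split-half reliability** $r_2$: correlation between the odd-frame and
  even-frame predictions. With 74 frames, enumerating all half-splits is
  infeasible; the odd-even split is the standard approximation.
* **MTMM matrix**: the 10 × 10 Pearson matrix over five traits × two
  methods (model, scale). Convergent validity = mono-trait hetero-method
  entries; discriminant structure = hetero-trait mono-method triangles.
  No sign reflection is applied to neuroticism; negative correlations are
  reported as-is. `validitySummary()` reports mean convergent and mean
  absolute discriminant coefficients and a permutation test (subject
  labels of the model method permuted, default 1000 draws) of whether
  convergent entries exceed the hetero-trait hetero-method entries — the
  comparison is reported with an explicit permutation p-value because no
  standard closed-form test exists for this contrast.

## Keypoint contribution mapping

To interpret what the models use, the 40 selected components are mapped
back to body keypoints by inverting feature construction: each component
distributes one unit of mass over raw features in proportion to its
absolute PCA loadings (squared loadings available as an option), and each
feature passes its mass to the keypoints it was built from — wholly for
coordinate/difference/wavelet features, half/half for distance pairs,
thirds for angle triples (the construction-rule weights). Total keypoint
mass therefore equals the number of selected components, a conservation law
asserted to $10^{-9}$. Ranking keypoints by mass and intersecting the top
half across two models shows which joints both models rely on.

## The synthetic cohort

Recorded gait-video datasets of this kind cannot be redistributed, so the
package ships a generator that emulates the study conditions and makes
every stage testable:

* **Kinematics.** 75-frame, 25-keypoint sequences: a plausible front-view
  rest pose plus sinusoidal oscillation at a 25-frame gait period
  (three cycles per window) — antiphase arm swing (elbows at half wrist
  amplitude), antiphase stride (knees at half, toes/heels riding the
  ankles), lateral upper-body sway, and vertical head bob at twice the
  step frequency — plus Gaussian pixel noise (SD 1 px, the jitter scale of
  pose estimation on clean video).
* **Traits.** Latent Big Five vectors are multivariate normal with the
  qualitative BFI inter-trait pattern (extraversion, agreeableness,
  conscientiousness, openness mutually positive at ρ = 0.3, all negative
  with neuroticism), so MTMM discriminant structure is exercisable.
  Subscale scores are midpoint + subscale-SD × latent + noise (SD 2),
  rounded and clipped to the legal ranges (E/N 8–40, A/C 9–45, O 10–50).
* **Trait→kinematics effects.** Each trait modulates one kinematic
  parameter (extraversion → arm swing, agreeableness → torso sway,
  conscientiousness → stride, neuroticism → cadence negatively,
  openness → head bob), with effect sizes of roughly half the baseline
  amplitude per latent SD — a strong, recoverable signal.

What the generator does **not** emulate: pose-estimation dropouts and
outliers, view changes and turns, within-subject gait variability across
cycles, non-sinusoidal waveforms, and realistic trait–kinematics effect
sizes (real effects are far weaker than the generator's defaults). Passing
the recovery tests therefore demonstrates that the pipeline is correct and
leak-free — that planted signal of stated strength is recovered and absent
signal is not hallucinated — not that comparable validity would be attained
on real recordings.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: cohorts of 150 subjects
(10 × 10-fold CV, all five traits) for recovery and null checks; 60
subjects for structural checks; 200 random series for wavelet
reconstruction (tolerance 1e−8 relative, achieved at ~1e−15); 50 random
instances for the SFS-oracle equivalence; 1000 subjects for score-marginal
and MTMM sign-pattern checks. Cholesky scoring guards against collinear
candidates with a 1e−10 pivot floor; keypoint mass conservation is checked
at 1e−9.

## Known limitations

* Front-view, single-walker input is assumed; view classification and
  tracking are out of scope.
* The 75-frame unification crops rather than resamples; recordings shorter
  than 75 frames are rejected.
* Whether smoothing preceded MidHip elimination in the original protocol
  is unknowable from the outside; this package smooths the 48
  post-translation series.
* SFS selects PCA components, not raw features; the keypoint mapping's
  |loading| propagation is one defensible inversion of that choice, and
  the exact weights practitioners used elsewhere may differ.
* Generic-path SFS with kernel estimators at full component counts is
  slow; use `sfsEstimator = "lr"` for large problems.
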