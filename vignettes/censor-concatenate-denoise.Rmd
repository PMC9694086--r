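---
title: "Censor, concatenate, denoise: methods and design notes"
author: "motionscrub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censor, concatenate, denoise: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Resting-state fMRI of young children is dominated by head motion. A single
fidgety minute can contaminate functional-connectivity estimates far beyond
the frames in which the head actually moved: motion leaves rigid-body
misalignment, spin-history intensity modulation, slice-periodic artifacts
tied to the multiband/interleaved acquisition, and bright rings at the
brain edge. Left in the data, these artifacts inflate short-range
connectivity and couple every quality metric to how much the subject moved.

`motionscrub` implements a deliberately simple preprocessing recipe for
this situation — volume censoring by framewise displacement (FD), run
concatenation, field-of-view (FOV) screening, rigid realignment,
per-volume intensity normalization, spatial ICA with rule-based
signal/noise labeling, and "aggressive" regression of the noise
time courses — together with the quantitative QC battery used to judge it
(temporal SNR, parcel connectivity, edge-wise QC–FD correlations and their
distance profile, DVARS–FD regressions, subject retention by threshold),
and a synthetic multi-subject BOLD phantom generator so that every stage
can be validated against exact ground truth.

# The pipeline

For each subject (one or more runs):

1. **Dummy discard.** The first `nDummy = 3` volumes of each run are
   dropped (pre-steady-state magnetization at short TR).
2. **FD.** From the six rigid-body parameters,
   $\mathrm{FD}_t = \sum |\Delta d_t| + R \sum |\Delta \theta_t|$ with
   $R = 50$ mm converting rotations to arc length; $\mathrm{FD}_1 = 0$, so
   the first frame is never censored by FD. When no motion traces are
   supplied they are estimated by realignment (below).
3. **Censoring.** A frame survives iff $\mathrm{FD} \le$ the threshold
   (default 0.3 mm; the comparison grid is 0.25 / 0.3 / 0.4 / 0.5 mm).
   Boundary frames are kept — the rule removes frames that *exceed* the
   threshold — neighbours are not expanded, and no minimum segment length
   is imposed by default (`minSegment` exists but defaults off).
4. **Concatenation.** Surviving frames of all runs are joined in
   acquisition order; a `CensorPlan` ledger records, for every acquisition
   frame, whether it survived and why it was dropped
   (`dummy`/`fd`/`fov`/`trim`), so frames are accounted for exactly once.
5. **FOV screening.** Per-volume brain extraction (voxels above 0.35 of
   the volume's 98th-percentile intensity, largest 6-connected component)
   gives a brain-voxel count per frame; frames deviating from the
   all-frame mean by more than 4 SD are dropped. The mean/SD pass is
   single-pass by default (`iterative = TRUE` re-estimates after
   exclusion; with clean data the two agree).
6. **Motion correction.** Each surviving frame is resampled under the
   inverse of its rigid transform (trilinear).
7. **Normalization.** Every volume is scaled so its in-brain mean is
   10,000 units, removing run-to-run scanner scale.
8. **ICA + labeling + aggressive cleanup.** Spatial ICA with a fixed model
   order (60 components by default) decomposes the data; per-component
   features feed a rule-based classifier; all noise time courses (plus an
   intercept) are regressed out of every voxel and intercept + residual is
   kept, so cleaned data share no variance with any noise time course.
9. **Trim.** The first $\lfloor 240\,\mathrm{s} / TR \rfloor$ frames are
   kept (never more than the stated duration). A subject whose surviving
   data fall short of 240 s is *excluded* — a normal status, the
   subject-exclusion event, not an error.

`runCohort()` applies this per subject and assembles the QC battery;
passing `thresholds =` sweeps the censoring threshold.

# Rigid realignment

Realignment minimises the masked mean-squared intensity difference to the
reference frame. Two choices matter, both standard in intensity-based
registration but worth stating:

* **Smoothed images.** The cost is evaluated on Gaussian-smoothed images
  (FFT convolution, $\sigma = 1.2$ voxels). Trilinear interpolation loss
  is high-frequency; unsmoothed, it drowns the rotation signal of a
  smooth phantom.
* **Symmetric cost.** Frame and reference are each resampled by *half*
  the candidate transform. With a one-sided cost, the interpolation loss
  grows with the magnitude of the candidate transform and biases the
  minimum toward zero rotation (we measured minima at roughly half the
  true rotation); resampling both sides makes the loss nearly equal on
  both sides of the comparison, cancelling the bias.

The optimizer is damped Gauss–Newton (Levenberg–Marquardt) with a
central-difference Jacobian (steps: $10^{-3}$ rad, 0.05 mm), optionally
seeded by a coarse 2 mm translation grid. On noise-free planted motions up
to 2 mm / 0.035 rad it recovers parameters to ~0.003 rad / ~0.05 mm,
comfortably inside the tenth-of-a-voxel targets (0.005 rad / 0.25 mm).
Frames whose estimates exceed the search bounds are flagged, not failed.

The apply→invert round trip loses ~3 % RMS of the robust maximum intensity
to double trilinear interpolation on the default phantom. That is the
price of the cheap interpolant; sinc fidelity is not needed for the QC
logic this package exists to evaluate.

# Spatial ICA and component labeling

The decomposition is PCA reduction (temporal covariance eigendecomposition)
to the model order, then a symmetric fixed-point iteration with the tanh
contrast on the whitened *spatial* matrix — i.e. spatial ICA, components
are spatial maps with maximally independent weight distributions and the
mixing matrix holds their time courses. Conventions: time courses have unit
variance (maps absorb scale), map skewness is made positive, components are
ordered by explained variance, and the random initial rotation is seeded —
a decomposition is bit-reproducible given its seed. The convergence
tolerance (1e-4 on the rotation update) and iteration cap (200) follow
common FastICA practice; hitting the cap yields a warning and a flagged,
still-usable partial result.

Per-component features mirror the hand-labeling guidance for ICA cleanup:

| feature | meaning | noise rule |
|---|---|---|
| `edgeFraction` | share of absolute map mass on the brain rim | > 0.45 |
| `slicePeriodicity` | normalized spectral peak of the slice-wise mean absolute weight at a period of 4 slices | > 0.30 |
| `highfreqFraction` | share of off-DC temporal power above 0.1 Hz | > 0.50 |
| `jumpScore` | max time-course step over the robust SD of steps | > 6 |
| `gmOverlap` | share of map mass on grey matter | ≥ 0.68 **protects** |

A component is noise iff any noise rule fires *and* grey-matter overlap is
below the override. Spatial fractions are computed on robustly thresholded
maps (mass above median + 2 MAD), the analogue of mixture-model map
thresholding: without it, the flat noise floor pulls every fraction toward
the mask-wide base rate and the features stop discriminating. The override
threshold (0.68) was placed in the empirical gap between artifact-matched
components (≤ 0.60) and network components (≥ 0.76) on a training set of
eight synthetic subjects disjoint from all test seeds; the other four
thresholds are the package defaults that already satisfied the ≥ 90 %
planted-component classification contract. All five are configurable.

"Aggressive" cleanup is full regression: noise time courses are centred,
collinear columns dropped (with a warning), and each in-mask voxel is
replaced by intercept + residual of the joint fit. Consequences that the
tests assert: cleaned voxel variance never exceeds the input variance, and
residual correlation with every regressed time course is zero to numerical
precision.

# The QC battery

* **tSNR** — primary mode is voxelwise (temporal mean / temporal SD,
  averaged over the brain mask; zero-SD voxels excluded with a warning). A
  "global" mode (mean over SD of the mean in-mask series) exists because
  the verbal definition "mean whole-brain signal divided by the standard
  deviation across time" is ambiguous; comparisons must use one mode
  consistently, and the pipeline uses voxelwise.
* **Connectivity** — parcel-mean time series (parcels under 5 voxels
  dropped), Pearson correlations for all node pairs, centroid Euclidean
  distances per edge.
* **QC–FD edges** — per-edge Pearson correlation across subjects between
  edge value and subject mean FD, two-sided t-test p-values, the
  proportion with p < 0.05 (uncorrected; the benchmark is the 5 % chance
  level, so no multiplicity correction is applied), and a lowess profile
  (span 2/3) of correlation against internodal distance. Raw r, not
  Fisher z, is correlated with FD by default (`fisherZ` flag available).
* **Subject mean FD** is computed over the retained frames of the trimmed
  data, using each frame's original FD value.
* **DVARS–FD** — OLS of DVARS on FD per subject and pooled, frame 1
  dropped. *After censoring*, each surviving frame keeps its original FD
  value (the x-axis is capped at the threshold) while DVARS is computed on
  the spliced data. Re-deriving FD across splice gaps was rejected: the
  position jumps across removed segments correlate mechanically with the
  DVARS splice jumps and the regression tightens instead of relaxing.
* **Retention** — a subject is retained at a threshold iff frames with
  FD ≤ threshold add up to ≥ 240 s; monotone in the threshold by
  construction. Scanner-side monitoring (`accumulateGoodTime`) instead
  uses a *strict* inequality (< 0.4 mm), reflecting its different origin.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

* **Phantom** (`makePhantom`): 32 × 32 × 24 grid at 2.5 mm. An ellipsoid
  with deliberately unequal semi-axes (a rotationally symmetric phantom
  leaves rotations unidentifiable), a smooth intensity profile with an
  off-centre dark "ventricle" and a handful of broad bright/dark blobs
  (the non-radial structure realignment needs), a ~2-voxel soft edge (an
  EPI-like point-spread roll-off that also keeps trilinear losses small),
  a thin grey-matter shell (~26 % of brain volume, cortical-ribbon-like —
  grey-matter overlap must be a *selective* feature for the override rule
  to mean anything), and 12 disjoint parcels (≥ 5 voxels each, by
  construction; too many nodes for the shell is an error) seeded by
  farthest-point sampling with capped Voronoi growth.
* **Motion** (`simulateMotionTrace`): Gaussian jitter plus sparse
  log-normal jump events — the simplest generator with the cohort-like
  right-skewed FD distribution (mean well above median). After drawing,
  all six step series are rescaled by one factor so the realized mean FD
  *equals* the target (FD is 1-homogeneous in the steps): subject mean FD
  is an exact design variable, the shape stays random.
* **Artifacts** (`makeGroundTruth` / `renderRun`): each frame is the
  template plus network signal resampled under that frame's motion, then
  (a) a rim ring scaled by FD, (b) an every-4th-slice pattern gated by
  FD > 0.3 mm whose sign alternates frame-to-frame (a high-frequency
  flicker, which also decorrelates it from the rim time course so ICA can
  separate them), (c) a spin-history slice-wise multiplicative gain scaled
  by FD with a static part (a removable rank-1 artifact) and a voxel-level
  frame-varying part at 0.35 of its amplitude (irreducible motion-scaled
  intensity instability — this is what keeps tSNR coupled to motion even
  after perfect component removal; it must stay a *minority* of the
  motion-locked variance, because the cohort being emulated shows cleanup
  *weakening* the tSNR–FD coupling and raising tSNR substantially, i.e.
  most motion-locked variance in such data is structured and removable),
  and (d) Gaussian thermal noise
  (SD 15 on a ~1000-unit brain, ≈ 1.5 %). Artifact amplitude saturates at
  FD = 1.5 mm; frames that bad are censored anyway and unbounded
  amplitudes are unphysical. Amplitudes (rim 250/mm, slice 150/mm, spin
  gain SD 0.1/mm) put sub-threshold artifact variance on the order of the
  thermal noise — the regime in which censoring alone cannot finish the
  job and ICA cleanup has something real to do.
* **Networks**: 3 networks, each a sum of three sinusoids in
  0.01–0.08 Hz, painted on disjoint node groups with weights jittered
  around 1; amplitude 15 units (≈ 1.5 % "BOLD").
* **Connectivity confound** (`confoundStrength`): FD-spike-locked shared
  signal (gate: FD above 0.25 mm, capped at 1.5 mm, times white noise per
  source) painted on parcels with source weights decaying with distance
  (scale 25 mm) and amplitude proportional to subject mean FD. It lives in
  grey matter, so the classifier's override correctly protects it — it is
  *censoring*, not component regression, that removes it, which is exactly
  the mechanism the threshold comparison is meant to expose. Its base
  amplitude (15 intensity units, i.e. comparable to the network signal at
  the highest subject FD) keeps edge inflation in the linear regime: much
  stronger and the no-censor arm pins every mover's edges near the
  shared-signal ceiling, compressing exactly the cross-subject differences
  the QC–FD statistic measures.
* **FOV dropout**: flagged frames are rendered with an extra out-of-plane
  translation computed to push a stated fraction (default 30 %) of brain
  voxels off the grid. The shift is *not* written into the motion trace:
  it emulates slow drift whose frame-to-frame FD signature is negligible,
  so dropout frames survive FD censoring and must be caught by the
  brain-voxel-count screen — the scenario that screen exists for.
* **Cohort** (`simulateCohort`): per-subject target mean FD uniform on
  0.2–0.65 mm plus a +0.08 mm offset for group "B" (emulating a sex
  difference in head motion); ages uniform on 6–8 years, independent of
  FD. With `render = FALSE` the cohort carries traces, truths, analytic
  node-level series and per-run render seeds only; `runCohort()` renders
  one subject at a time (`renderSubject`), keeping peak memory to a single
  subject. The analytic node series contain networks + confound +
  parcel-level measurement noise but no imaging artifacts; they represent
  ideal post-cleanup data and are what the null-calibration checks use.

What the generator does **not** emulate: real anatomy, EPI distortion,
cardiac/respiratory physiology, multiband reconstruction artifacts beyond
the slice-periodic pattern, slice-to-volume motion, or respiratory
contamination of the motion parameters. Tests passing on this phantom show
the pipeline's logic and its directional behaviour under motion-locked
artifacts with known truth; they do not certify performance on real
pediatric data.

# Numerical choices and degenerate inputs

* FD of the first frame is 0 by convention; censor masks therefore always
  keep frame 1 at any positive threshold.
* `detectFovOutliers` with all counts equal (SD 0) warns and flags
  nothing; it requires ≥ 8 frames for the SD to mean anything.
* `trimToDuration` uses `floor()` (never exceed the stated duration) and
  is idempotent; insufficient data signals a typed condition
  (`msInsufficientData`) that the pipeline converts into the `excluded`
  status.
* Constant nodes give NA edges with a warning; constant FD within a
  subject skips that subject's DVARS regression with a warning.
* ICA requires the model order to be below both the frame count and mask
  size; the pipeline caps it at (frames − 2) when censoring leaves little
  data, recording that in the stage log.
* Ties and signs in ICA are fixed deterministically (explained-variance
  order, positive map skewness), so reruns are byte-identical.

# Problem sizes used by the test-suite and acceptance runs

Cohort-level checks run 30 subjects × 2 runs × 300 frames at TR 0.78 s on
the default phantom, with a threshold sweep {none, 0.5, 0.3} mm; null
calibration uses 20 (tests) or 10 (acceptance script) node-level cohorts
of 30 subjects; classification recovery uses 10 single-run subjects of
300 frames. These sizes give stable directional statistics while keeping a
full run in the minutes range on one CPU.

# Known limitations

* The rule-based classifier is tuned to this phantom's artifact
  vocabulary; it is a stand-in for a trained classifier, not a
  re-implementation of one, and its thresholds should be re-examined on
  any new artifact model.
* Trilinear interpolation loses ~3 % RMS per resample on this phantom;
  analyses that need sub-percent intensity fidelity through resampling
  would need a better interpolant.
* The DVARS–FD "after censoring" pairing convention (original FD, spliced
  DVARS) is one of several defensible choices; it is stated here and used
  consistently.
* Group-level ICA across subjects and anatomical/standard-space
  registration are out of scope.
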