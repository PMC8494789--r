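---
title: "Delineating thalamocortical networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating thalamocortical networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`thalnet` maps the functional coupling between the thalamus and large-scale
cortical networks in resting-state fMRI. For every voxel of a thalamus mask
it computes the Pearson correlation of that voxel's time series with every
brain voxel, Fisher-transforms the maps to z, and stacks them across all
thalamic voxels and all subjects. Spatial ICA of this stack yields
"network ROIs": spatially independent whole-brain maps that are coherently
connected to common thalamic territory across subjects. Dual regression then
localizes, per subject, the thalamic voxels associated with each network —
the functional thalamic subdivisions. Group differences (e.g. patients vs
controls) are tested nonparametrically: the primary analysis compares the
thalamic subdivision maps between groups; the secondary analysis extracts a
thalamic seed per subdivision, computes seed-to-whole-brain betas per
subject, and compares those. Unlike winner-takes-all parcellation, a
thalamic voxel may belong to several subdivisions; overlap is a feature of
the model, not an error, and no hard parcellation is offered anywhere.

## Preprocessing

Three stages run in a fixed order per subject: dropping the first `trim`
frames (default 4, the usual dummy scans before steady-state magnetization),
highpass temporal filtering, and confound regression.

* **Highpass filter** (`highpassFilter`): frequency-domain with a
  raised-cosine transition band (width 0.002 Hz) centred on the cutoff
  (default 0.01 Hz). Any implementation that removes fluctuations slower
  than the cutoff while preserving the passband would do; the
  frequency-domain form makes the attenuation contract easy to verify by
  FFT. The voxel mean is restored after filtering so a constant series
  passes unchanged.
* **Confound regression** (`regressConfounds`): OLS residuals on an
  intercept plus the confound columns (six motion parameters, mean
  white-matter and CSF signals). The intercept is included even when all
  confounds are centred — otherwise the voxel mean would be treated as
  signal. The projection is idempotent, and all-zero confound columns are
  dropped, so a table of zeros reduces the operation to demeaning.
* **Ordering**: whether filtering should precede or follow confound
  regression is genuinely open; the package fixes filter-then-regress so
  that slow drifts do not leak into the confound betas. This is a package
  convention, not a claim about the only valid order.

No spatial smoothing stage exists anywhere in the package, deliberately:
the connectivity maps feed ICA at native resolution.

## Seed maps and the group stack

Correlations are computed between every thalamic voxel and every brain
voxel (`thalamicSeedMaps`), then Fisher-transformed,
z = artanh(r) = ½·ln((1+r)/(1−r)). Two numerical conventions:

* r is clipped to ±(1 − 1e−7) before the transform; the seed's
  self-correlation of exactly 1 would otherwise map to infinity.
* Zero-variance series (masked edge voxels in real data) yield r = 0 with
  a warning instead of an error, keeping the pipeline total.

Thalamic voxels are ordered by ascending column-major linear index. The
choice is arbitrary but fixed, which makes the frame order of the
concatenated group stack (`concatenateGroup`, subject-major) reproducible
bit for bit. Voxel indices are 1-based everywhere, the natural R
convention; world coordinates are reached only through the NIfTI affine,
which keeps its own 0-based convention internally.

## Spatial ICA

`fitSpatialICA` treats frames as observations and brain voxels as
variables. Each frame is scaled to unit standard deviation within the
brain first (equalizing subjects' global correlation levels), rows are
centred, the dimension is reduced to `nComponents` by SVD, and the
whitened spatial modes are rotated to maximal independence by a symmetric
fixed-point iteration with a tanh contrast — tolerance 1e−6, at most 1000
iterations, and up to 5 fresh random initializations before the fit fails
with the iteration count in the error. Determinism: the initialization is
drawn from the user's seed, so the same seed gives identical maps.

Post-processing conventions:

* Component maps are converted to z by subtracting the median and dividing
  a robust (MAD-based) spread estimate — the usual "z-scored IC map" one
  thresholds visually. When a map is mostly exact zeros (a perfectly
  recovered sparse source) the MAD degenerates and the plain SD is used.
* Sign is fixed so each map's largest-magnitude voxel is positive;
  components are ordered by explained mixing variance. Both are pure
  conventions to stabilize output across runs.
* The default of 20 components matches the dimensionality commonly used
  for whole-brain network ROIs; it is a config value, not a detected
  quantity. Model-order estimation and split-half repeatability analysis
  are out of scope.
* The display threshold for component maps is a parameter with no claimed
  canonical value.

`matchComponents` pairs fitted components with reference maps by exact
one-to-one assignment maximizing total |spatial r| (a small bitmask dynamic
program, up to 16 references), reporting signed correlations so inverted
matches are visible.

## Dual regression

Stage 1 regresses each timepoint's image on the component maps plus an
intercept, over the whole brain — the components are whole-brain objects,
and restricting the fit to the thalamus would discard the cortical signal
that defines them. Whether a mask should be used here is an open question;
whole-brain is the package's answer. Stage-1 time courses are
variance-normalized (the "des-norm" convention) so stage-2 betas are
comparable across subjects; the group analyses require that.

Stage 2 regresses each voxel's series jointly on all time courses plus an
intercept. Joint, not marginal: with correlated time courses the two differ,
and the tests pin the joint solution to a direct least-squares oracle.
Collinear time courses (condition number above 1e8) are refused with the
worst-correlated pair named. The thalamus-restricted beta stack is the
subject's set of functional thalamic subdivisions.

## Permutation inference

`permutationTest` fits the voxelwise GLM contrast (t = c'β/SE,
df = n − rank), enhances the map, and compares the observed enhanced values
against the permutation distribution of the maximum enhanced statistic —
family-wise error control by the max-statistic argument.

* **Nuisance covariates** (age, sex) are handled by Freedman–Lane:
  residualize the data against the nuisance regressors, permute (or
  sign-flip) the residuals, re-add the nuisance fit, refit the full model.
  With no covariates this reduces exactly to simple label permutation — a
  property the tests check numerically against an independent
  implementation.
* **p-values** follow the (1 + count)/(nPerm + 1) convention, so the
  smallest attainable corrected p is 1/(nPerm + 1) and p is never 0. For
  sign flipping with 2^n ≤ nPerm the full flip space is enumerated and p
  is exact.
* **TFCE** defaults: E = 0.5, H = 2, dh = h_max/100, 26-connectivity — the
  enhancement's standard parameterization. The integration step is fixed
  from the observed map and shared by all permutations so enhanced values
  are comparable. Two-sided tests enhance |t|; merging of adjacent
  opposite-sign clusters is therefore possible in principle and accepted
  for the simplicity and exact calibration it buys.
* **Cluster extent**: the forming threshold default is t = 2.3. No
  principled value exists for the primary analysis — the choice cannot be
  recovered from first principles — so a common default is exposed and
  overridable.
* Degenerate voxels: zero residual variance with zero effect gives t = 0;
  a saturated effect is capped at a large finite value rather than ±Inf so
  enhancement stays well-defined.
* Per-component analyses are reported per component; correction across
  components is left to the user (the alpha parameter is exposed), since
  stacking a second correction layer is a study-level decision.

The seed analysis (`extractSeed`) runs a one-sample sign-flip test with
TFCE on each component's thalamic betas, pooled across *all* subjects —
pooling is the default (a controls-only decomposition flag exists at the
ICA stage for the related concern that patient abnormalities could leak
into the data reduction). The seed is every voxel with corrected p below
alpha; several disjoint significant clusters stay one seed, since nothing
in the model distinguishes them. The statistic carried to the group level
is the raw seed-regressor beta — the GLM-native effect — not a correlation
transform of it.

## The synthetic cohort generator

`makeGroundTruth`/`simulateSubject`/`simulateCohort` plant a fully known
truth: a central ellipsoidal thalamus inside an ellipsoidal brain; K
peripheral Gaussian cortical blobs, spatially well separated (pairwise
map correlation < 0.2); per network a Gaussian thalamic weight blob plus a
small baseline (2% of peak) so subdivisions overlap, as real thalamic
functional anatomy does. Each network is driven by an AR(1) time course
(coefficient 0.3 — resting-state signals are autocorrelated, which
exercises the highpass and correlation stages realistically; white noise
would not). A voxel's amplitude for component k is the thalamic weight
inside the thalamus and the cortical map value outside. Patients differ
only multiplicatively: designated components' thalamic weights are scaled
by a factor (default 0.5), which is precisely a change in thalamo-cortical
coupling, the effect the pipeline is built to detect. White Gaussian noise
(SD 1, against signal amplitudes of order 1) and a small confound leak
(15% of the noise SD) complete the simulation; the leak scales with the
noise so noiseless simulations are exactly low-rank. Demographics default
to a young-adult two-group cohort (ages near 23 years, patients slightly
more dispersed, near-balanced sex).

What the generator does *not* emulate: hemodynamic response shapes,
scanner noise spectra (drift, spikes, physiological aliasing), head
motion, registration error, and the spatial autocorrelation of real BOLD
data. Passing tests therefore demonstrate that the implementation is
correct and well calibrated under the stated generative model — not that
any specific real-data finding would replicate.

## Validation scales

The test-suite and acceptance-script problem sizes are package choices
balancing statistical resolution against run time: planted-source ICA on a
12³ grid with 40 frames; dual-regression recovery on a 14×16×14 grid;
permutation calibration with 1000 simulated null datasets of 8 vs 8
subjects at 500 permutations each (a family-wise error rate with binomial
standard error ≈ 0.007); and an end-to-end cohort of 12 vs 12 subjects on
an 18×22×18 grid, 150 timepoints, with a factor-0.5 decrease planted on
one component. The full-scale stack arithmetic (606 thalamic voxels × 80
subjects = 48,480 frames) is exercised through the real concatenation code
with shared dummy map arrays.

## Known limitations

* The ICA dimensionality is user-set; components split or merge as it
  changes, and no stability analysis is built in.
* Two-sided TFCE on |t| can merge adjacent opposite-sign clusters.
* The permutation engine supports whole-sample exchangeability only — no
  exchangeability blocks, variance smoothing, or F contrasts.
* Masks are resampled nearest-neighbour only; partial-volume weighting of
  the thalamus boundary is not modelled.
* The pipeline consumes already-aligned volumes; registration quality is
  upstream of everything here.
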