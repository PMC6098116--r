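---
title: "Methods: tensor-metric registration and zero-shot transfer decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor-metric registration and zero-shot transfer decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tensorxfer)
```

This vignette is the package's own account of its models, numerical choices
and limitations. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The registration model

### Metric

Diffusion tensors are symmetric 3×3 matrices in mm²/s, stored as their six
unique components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz),
the common NIfTI convention. The registration similarity between two tensors
is the deviatoric distance

\[
\|D_1 - D_2\|_D = \sqrt{8\pi/15}\,\|\mathrm{dev}(D_1)-\mathrm{dev}(D_2)\|_F,
\qquad \mathrm{dev}(D) = D - \tfrac{\mathrm{tr}\,D}{3} I,
\]

algebraically equal to
\(\sqrt{8\pi/15\,(\|D_1-D_2\|_F^2 - \mathrm{Tr}^2(D_1-D_2)/3)}\).
Both routes are implemented and tested against each other; the distance is a
*pseudo*-metric (isotropic differences score zero), which is the point: it
aligns fibre architecture, not mean diffusivity. Numerically, a difference
whose anisotropic part is at the floating-point cancellation floor (relative
threshold \(10^{-13}\) of the input scale) is snapped to exactly zero, so
`tensor_distance(D + cI, D)` is identically 0 at any magnitude of `c`.

FA uses the Frobenius form \(\sqrt{3/2}\,\|\mathrm{dev}(D)\|_F/\|D\|_F\),
clamped to [0, 1], with FA(0) = 0 by convention; it needs no
eigendecomposition, so slightly negative fitted eigenvalues are handled
without clipping. Tensor fitting is per-voxel log-linear least squares of
\(\log S = \log S_0 - b\,g^\top D g\) (one QR factorization shared by all
voxels); weighted or robust refitting is out of scope. Non-positive signals
inside the mask flag the voxel, zero its tensor and emit a warning. Repeated
acquisitions are averaged in signal space before fitting (a flag disables
averaging and concatenates volumes instead), since the protocol-level choice
is not observable downstream at our noise levels.

### Transform model

A `piecewise_affine` transform is a regular lattice of block centres over the
template domain, one affine (A, t, world mm) per block, blended with
trilinear weights between the 8 nearest centres; outside the centre lattice
the weights clamp, extending the map affinely. A single block is exactly a
global affine. The blended map is continuous; its analytic Jacobian includes
the blend-weight gradient term, so `jacobian_map()` agrees with central
finite differences away from the (measure-zero) cell faces. Warping is
pull-back: output voxel x samples the source at Φ(x) with component-wise
trilinear interpolation, then reorients the tensor by the finite-strain
rotation R of the local linear part (polar factor computed by Higham's
Newton iteration, ~10× cheaper than an SVD per voxel; inputs with
determinant below 1e−12 skip reorientation). Out-of-field samples yield zero
and are excluded from the output mask.

### Optimizer

The objective is the masked sum of squared deviatoric distances between the
warped source and the target (sum of squared intensity differences for the
scalar T1-style baseline, without reorientation). It is minimized
coarse-to-fine (block-mean pyramid) by a derivative-free coordinate-wise
pattern search over each block's 12 parameters, marching in a direction while
it improves, halving steps when a sweep stalls. Three hardening choices
matter on noisy data and are exposed in `reg_config()`:

* **Out-of-foreground penalty** (`oob_weight`, default 0.3× the mean target
  signal power per voxel): without it the search can *reduce* the objective
  by pushing weakly anisotropic gray matter into empty background, because a
  zero tensor can be closer to a noisy gray-matter tensor than another noisy
  sample is.
* **Determinant guard**: a block update is rejected if its linear part's
  determinant leaves [0.1, 10], maintaining orientation-preserving,
  well-conditioned blocks (the scalar objective otherwise admits collapsed,
  near-singular minima).
* **Exhaustive translation initialization** at the coarsest level (±2
  coarse voxels, half-voxel steps) to land in the right basin before local
  refinement; blocks supported by fewer than `min_support` foreground voxels
  keep their inherited affine.

Objective trajectories are recorded per pyramid level and are non-increasing
within each level (asserted in the tests); `converged = FALSE` means the
final level exhausted its sweep cap while still improving. The default
schedule (pyramid /4, /2, /1 with 1³ → 2³ → 4³ blocks) reflects brain-sized
volumes (the method's native grid is 128×128×64 at 1.75×1.75×2.5 mm). On the
32³ phantoms used throughout the tests a two-level global-affine chain
(`pyramid c(2, 1)`, single block) is both faster and more accurate: the /4
level loses the thin tissue band, and fine block lattices overfit
acquisition noise. `cohort_pipeline()` therefore uses the two-level chain by
default, and the Jacobian-feature analyses re-register with a 2³ final level
where spatially varying determinants are required.

### Common space

`build_common_space()` follows the template-then-average construction:
register every subject to a designated template subject, average the warped
volumes (Euclidean, component-wise — matching the L2 objective;
log-Euclidean averaging is a non-goal), then re-register each original
subject to the mean, yielding Φₛ mapping common-space world coordinates onto
that subject. The template subject anchors the coordinates and is excluded
from decoding analyses. With identical input subjects the construction is a
fixed point: the mean equals the template and every Φₛ is identity to within
a tenth of a voxel.

## 2. Functional preprocessing and decoders

`preprocess_run()` converts a time×voxel run into one pattern per trial, in
this order: drop the first 5 volumes; shift phase windows by the hemodynamic
delay (2 TRs = 4 s, configurable — the generator simulates the same delay);
per-voxel linear detrend; winsorize samples beyond 4 MADs of the voxel
median (the outlier rule is otherwise unquantified); average volumes within
the Attention phase; subtract the same trial's Control-phase mean (the
baseline-correction reading we adopt; both steps are individually
switchable); z-score each voxel across the run's trials (run-scoped, which
respects leave-one-run-out hygiene). Zero-variance voxels yield 0 and are
flagged; trials whose shifted windows overrun the run are dropped with a
warning.

`extract_roi()` warps each trial image through Φₛ (trilinear pull-back,
evaluated only at ROI voxels) and indexes the mask in ascending voxel order,
so feature columns align across subjects. `select_voxels()` implements
supervised transfer-safe selection: per reference subject a Welch two-sample
t per voxel (left vs right trials; Welch chosen for robustness, the flavour
being otherwise unspecified), summed |t| over reference subjects, top
⌈fraction·n⌉ kept with ties broken by ascending index. The target subject's
data never enters.

Decoders are linear soft-margin SVMs (libSVM via e1071; C = 1, tolerance
1e−6, no scaling beyond the upstream z-scores, no class weights). The fitted
hyperplane is extracted to an explicit (w, b) with the sign normalized so
positive decisions mean attend-left, making decision values reproducible
without the solver. The conjunction decoder pools all reference trials; the
voting decoder takes the majority of per-reference-classifier votes and
counts exact ties as errors (taken verbatim from the decoding rule it
implements); self-decoding averages leave-one-run-out fold accuracies.
Whether pooled data should be re-z-scored across subjects before conjunction
training is left as emitted by preprocessing (no re-scoring).

## 3. Discordance, tails, and resampling statistics

The discordance map is the voxel-wise mean over subjects of
|FA∘Φ^A − FA∘Φ^B| for two registration routes, with the per-subject signed
subtraction maps retained. Tissue classes are operationalized from template
FA: white matter is FA ≥ 0.25 inside the brain mask, the edge of gray matter
is the gray-matter voxels 6-adjacent to white matter, and the reported
gray-matter class excludes that edge so the three classes are disjoint
(threshold and connectivity are config-exposed; an anatomically validated
segmentation is a non-goal). The exponential tail `exp(-a x)` is fitted by
maximum likelihood on exceedances over a threshold — `a = 1/mean(excess)` —
with the threshold defaulting to the per-class median (where the fit begins
is otherwise unspecified) and a seeded bootstrap standard error.

`wilcoxon_paired()` wraps the exact signed-rank distribution for ≤ 25
non-zero untied differences and the normal approximation otherwise, dropping
zeros. `jackknife_area_test()` deletes one subject at a time, fits OLS lines
to both methods' (self, transfer) scatters, and records the signed difference
of areas under the lines over the observed x-range of the retained points;
the p-value is a one-sided jackknife-t on those leave-one-out differences
(the construction is this package's choice — the raw differences are always
returned so other constructions can be applied). A uniform vertical shift of
Δ changes every difference by exactly Δ×range, giving a closed-form check.
`surrogate_distance_test()` compares the mean pairwise Euclidean distance of
a selected subject subset against the same statistic on uniformly drawn
subsets (which may re-draw the observed subset — the simplest exchangeable
null), with `p = (1 + #{surrogate ≤ observed}) / (1 + n_surrogates)`.
`pca_embed()` is mean-centred PCA with the largest-magnitude loading of each
component made positive for cross-platform reproducibility.

## 4. The synthetic cohort: what it emulates and what it does not

`phantom_spec()` defines the study conditions; `make_cohort()` is
deterministic given its seed. The template brain is a curved white-matter
tract (tube of radius 4 mm around an arc) wrapped in a 6 mm gray-matter
band on a 32³ grid of 2 mm voxels: WM tensors have eigenvalues
(1.7, 0.3, 0.3)×10⁻³ mm²/s along the tract tangent, GM (0.9, 0.7, 0.7)×10⁻³
radially — literature-typical values. DWI follows the target protocol: 1 b0
+ 30 Fibonacci-sphere directions at b = 1000 s/mm², S0 = 1000, Gaussian
noise SD 20 (Rician by flag), two acquisitions averaged in signal space;
subject tensor volumes are *fitted from these signals*, so registration sees
realistic estimation noise. A pseudo-T1 (WM 1.0, GM 0.6, noise SD 0.02)
exercises the scalar baseline route on the same anatomy.

Each subject is the template warped by a ground-truth piecewise-affine
deformation (2³ blocks): rotations ≤ 8°, per-axis translations ≤ 6 mm
(3 voxels), scales within ±8%, per-block translation jitter ≤ 2 mm,
resampled if it folds. These magnitudes were chosen once so that
inter-subject misalignment (1–3 voxels) exceeds the one-voxel thickness of
the informative band — the regime in which anatomical registration is the
binding constraint, which is the phenomenon the package exists to study. The
informative voxels are the gray-matter voxels adjacent to white matter
(edge-of-GM), lateralized by hemisphere, and they *follow each subject's
anatomy* through the ground-truth warp. Task runs (TR 2 s; 10 trials/run, 5
runs; Rest 8–16 s, Control 4 s, Attention 8 s; 5 dummy volumes) add
+effect/−effect (0.5 noise-SD units, a realistic single-trial amplitude) at
informative voxels with the sign set by attention side × hemisphere, a
symmetric half-amplitude response in Control, linear drift, and Gaussian
noise; the simulated response lags stimulus onset by the same 2-TR
hemodynamic delay the preprocessing corrects.

What passing tests show: the geometric and statistical machinery is correct,
and under boundary-localized signal with realistic misalignment the
registered conjunction decoder recovers transfer performance that collapses
without registration. What they do not show: performance on real brains —
the phantom has no cortical folding, no physiological noise or motion, a
single tract, piecewise-affine (not diffeomorphic) ground truth, and
deformations drawn from the same family the registration fits. The scalar
baseline here registers the phantom nearly as well as the tensor route at
default SNR; the tissue-level contrasts (edge-of-GM discordance, the
transfer-vs-self comparison) are therefore asserted directionally, not at
real-data effect sizes.

## 5. Problem sizes and degenerate inputs

The shipped tests and the acceptance script use 32³ phantoms (16³ for unit
fixtures), cohorts of 6 subjects, 10-seed recovery batteries, 200-replicate
null calibrations and 999-surrogate tests; these sizes make the full battery
reproducible in minutes on a single core while leaving every assertion
statistically meaningful. Degenerate inputs are contracts, not crashes:
empty masks, single-class training folds, all-zero difference vectors,
degenerate x-ranges, empty tissue classes and folding deformations all raise
informative errors or flagged warnings, as exercised in the test suite.
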