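---
title: "Simulated CT acquisitions for radiomics stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated CT acquisitions for radiomics stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Purpose and scope

Radiomics features — quantitative intensity and texture statistics computed
inside a region of interest (ROI) of a medical image — are sensitive to how
the image was acquired: projection count, reconstruction algorithm, dose.
Physical test–retest studies with printed anthropomorphic phantoms quantify
that sensitivity but are slow and costly. `radphantom` implements the
in-silico alternative: a virtual abdominal phantom is pushed through a
simulated CT acquisition chain (helical or circular cone-beam projection,
Poisson sinogram noise, FBP or SIRT reconstruction), 86 standard radiomics
features are extracted per ROI, and feature *stability* (intra-class) and
*discriminative power* (inter-class) are scored with a standardized
rank-sum statistic.

This vignette documents the model, the tunable parameters and their
defaults, the numerical choices, and what the synthetic world does and does
not establish.

# The phantom

`generate_phantom()` realises a `phantom_spec()`: an elliptical soft-tissue
body on a background fixed at −100 HU, containing six ellipsoidal ROIs in
four tissue classes — two normal liver regions (mean 60 HU), two cysts
(5 HU), one hemangioma (140 HU), one metastasis (33 HU). All values are
confined to [−100, 1000] HU, the contrast range a paper-based printed
phantom can represent; the generator rejects specs whose mean ± amplitude
leave that range and clamps the rare Gaussian tail excursions of the
realised field.

Tissue texture is the one component with no physical counterpart in the
pipeline's inputs (a real study would use a measured high-dose CT volume),
so it is stated explicitly: each region receives a seeded Gaussian random
field, smoothed by FFT to a configurable correlation length (default 3 mm,
the scale of visible low-contrast liver texture at 1 mm voxels), scaled to
the region's amplitude (its texture standard deviation in HU). Cysts are
nearly homogeneous (amplitude 6 HU), lesions more heterogeneous
(15–20 HU). Because the fields are smoothed periodically and renormalised
empirically, the realised standard deviation matches the requested
amplitude only approximately; the test suite checks the first moment
tightly and the second loosely.

Two default grids exist: `default_phantom_spec()` (128×128×64 voxels, 1 mm
isotropic — the slice thickness equals the pixel size) and
`fast_phantom_spec()` (64×64×1), the "2D mode" used by the test suite and
the scaled study. Voxel convention everywhere: indices are 0-based in the
compiled code and world position of a voxel centre is
`origin + (index + 0.5) * spacing`.

# Acquisition model

`build_helical_geometry()` produces explicit per-view vectors: source
position, detector centre, and detector axes scaled by the pixel pitch.
The source-to-isocenter distance is 500 mm and source-to-detector 1000 mm
(magnification 2) — we read the stated "target and detector at 500 mm and
1000 mm" as source-centred distances; the detector is a flat square
512×512 array of 1 mm pixels by default. Views are uniform in gantry angle
on a half-open grid, and the source advances in z so that one rotation
covers `pitch × rows × pixel × sod/sdd` (256 mm at the defaults, pitch 1).
`build_circular_geometry()` is the pitch-0 special case; with a one-row
detector and a single-slice volume it is a fan-beam fast mode, and all the
statistical machinery downstream is geometry-agnostic.

Projection is Joseph's method (bilinear interpolation on slices
perpendicular to the ray's dominant axis), chosen over Siddon because its
adjoint is clean: `apply_adjoint()` is the exact matrix transpose of
`forward_project()` — the same traversal with the same weights, scattering
instead of gathering — which the tests verify against a dense system
matrix built by projecting basis vectors. HU are converted to linear
attenuation by `mu = mu_water (1 + HU/1000)` with `mu_water = 0.0192/mm`,
clamped at zero; the reconstruction inverts the same map, so air
reconstructs to −1000 HU even though the phantom background is −100 HU.

# Noise model and calibration

Noise enters at the projection level. With noise level `A = 1/I0` (`I0`
the background photon count), each pixel with clean line integral `I`
yields `k ~ Poisson(I0 e^{-I})` and the noisy integral is `−log(k/I0)`.
`A = 0` is an exact passthrough. Sampled counts of zero are clamped to one
before the log — the paper-trail convention in low-dose CT simulation; the
alternative (discarding rays) would bias the sinogram. The delta method
gives `Var ≈ e^I A`, which the tests verify at 10% on 10^5 pixels, and the
study default is `A = 1e-4` (the level equated with roughly a 10 mGy
dose).

Seeding: each repetition uses `base_seed + 100·group + repetition`; draws
are taken pixel-by-pixel in column-major order from one generator, so runs
are bit-reproducible across platforms, and the caller's RNG state is
restored afterwards.

`calibrate_noise()` reconstructs repeated noisy realisations over a grid
of `A` values, computes the mean per-voxel variance over a support mask
(the phantom support by default — the choice of averaging region is not
dictated by anything physical, so it is a parameter), fits the
approximately linear `sigma² = slope·A + intercept` relation, and
`solve_A_for_variance()` inverts it. The absolute variance targets of a
real scanner (e.g. 2.5×10⁻³–2.8×10⁻³ HU² per pixel) depend on data we do
not have; targets are therefore user-supplied, and the multi-center preset
(`build_multicenter_preset()`) maps its stated variance range
(2.5×10⁻³–2.9×10⁻³) through whatever calibration the user fitted.

# Reconstruction

`fbp_reconstruct()` is FDK-style filtered back-projection: cosine
weighting, row-wise convolution with the band-limited Ram-Lak ramp (no
apodization — the simulated scanner's kernel is fixed and explicit),
voxel-driven distance-weighted backprojection with detector coordinates
rescaled to the isocenter plane, and a `Δβ/2` full-scan normalisation. For
helical data at pitch 1 this is the short-object FDK approximation; no
exact helical inversion is attempted. On a noiseless anti-aliased cylinder
the interior reconstruction error is below 5% of contrast.

`sirt_reconstruct()` iterates
`x ← x + C Pᵀ R (b − P x)` with `R` and `C` the inverse row and column
sums of the projector, zero initialisation, and a fixed iteration count
(default 500, the published setting). The iteration runs entirely in
compiled code; residual norms are recorded per iteration and a greater
than tenfold residual growth aborts with a diagnostic. There is no
nonnegativity constraint by default (an optional flag exists). On tiny
dense instances SIRT's fitted values approach the least-squares fitted
values, as the tests check against an SVD pseudoinverse.

# Feature extraction

`extract_features()` computes exactly 86 features: 18 first-order, 22
grey-level co-occurrence (GLCM), 14 grey-level dependence (GLDM), 16
run-length (GLRLM) and 16 size-zone (GLSZM), in a frozen canonical order
(`feature_names()`). Settings mirror the standard defaults: fixed bin
width 25 HU anchored at the ROI minimum
(`level = floor((x − min)/25) + 1`), neighbour distance 1 voxel, symmetric
co-occurrence accumulation over the 13 unique 3D directions, dependence
tolerance α = 0, voxel array shift 0, and no normalisation, resampling or
resegmentation. Because binning is anchored at the ROI minimum, adding a
constant to the ROI leaves every texture feature unchanged — a property
the tests assert.

Design decisions worth recording:

* **GLCM manifest.** The 22 co-occurrence features are the standard
  24-feature list minus the two deprecated linear duplicates
  (dissimilarity = 2 × difference average, sum average = 2 × joint
  average). The maximal-correlation coefficient (MCC) is not implemented;
  it is not required to reach the 86-feature census.
* **GLDM dependence.** The matrix stores raw dependence counts, so an
  isolated voxel has dependence 0; the feature formulas index columns as
  `j = dependence + 1`, keeping small-dependence emphases finite. With
  α = 0 a neighbour counts only when its grey level is equal ("always
  considered independent" otherwise).
* **Direction aggregation.** GLCM and GLRLM accumulate counts over the 13
  directions and compute features once from the summed matrix (rather than
  averaging per-direction features). Run percentage is normalised by
  `13 × N_voxels` accordingly.
* **Degenerate ROIs.** A single-grey-level ROI triggers a warning and
  features whose formulas would divide by zero return 0 — including GLCM
  correlation, where other toolkits return 1; the convention is uniform
  here and documented.
* **Percentiles** use linear interpolation (R `type = 7`, the numpy
  default); skewness and kurtosis use biased moments and kurtosis is not
  excess-corrected.

All four texture matrices are validated against brute-force enumeration
oracles (exhaustive pair counting, naive run walking, flood fill,
neighbour counting) on randomized small ROIs.

# Stability and discriminative power

`wilcoxon_W()` computes `W = |z|`, the tie-corrected normal-approximation
standardization of the Mann–Whitney rank-sum statistic (average ranks, no
continuity correction; `W = 0` when the pooled sample is constant). The
source material uses a threshold of `W < 1` for "same distribution"
without printing the statistic's formula; a unit threshold is only
meaningful for a standardized statistic, which motivates this definition —
it is a documented choice, not a reproduction of an unpublished formula.
On [1,2,3] vs [4,5,6] this yields W ≈ 1.964.

`stability_percentage()` compares, per feature and per ROI, all C(8,2)=28
pairs of parameter-variation groups (168 comparisons over 6 ROIs);
success is `W < 1`. `discriminative_percentage()` compares, per feature
and per group, all C(4,2)=6 tissue-class pairs (48 comparisons over 8
groups), pooling the ROIs of a class; success is `W > 1`. The two
duplicated-class ROI pairs are kept separate in the stability axis (each
ROI is its own test-retest series). No multiple-testing correction is
applied — the procedure thresholds a statistic, not a p-value. Note the
null behaviour: for identically distributed samples `P(W > 1) ≈ 0.32`, so
"no discrimination" empirically means percentages near 30%, not near zero.

`rank_features()` sorts descending with canonical-name tie-break;
`topk_overlap()` uses round-half-up so that 10% of 86 features is a top
group of 9, with the random-expectation baseline `f × 100`.

# The scaled study and what it establishes

`build_table2_design()` reproduces the 8-group design — SIRT and FBP at
150, 200, 250, 300 projections, `A = 1e-4`, 10 noise seeds per group —
and `run_study()` executes it end to end (480 feature vectors), caching
noiseless sinograms per projection count. Two runtime scale-downs apply in
the default `study_config()`: the single-slice 64×64 phantom with a
192-column one-row detector, and 100 SIRT iterations instead of 500 (the
`recon_spec()` default remains 500). Both are documented scale-downs for a
1-CPU budget, not tuned values.

On this synthetic world the published qualitative headline reproduces:
mean stability across the 86 features is low while mean discriminative
power is high, because reconstruction-parameter changes (algorithm, view
count) shift feature distributions between groups while the constructed
class separations dominate within any fixed group. A green acceptance test
establishes exactly that ordering on the synthetic phantom — it does *not*
establish the paper's absolute percentages, which depend on a real printed
phantom, a real scanner's noise, and ADMIRE-class vendor kernels, none of
which are modelled. Likewise the PCA machinery (`fit_pca()`,
`pca_project()`, `compare_variability()`) is validated on constructed
clusters (shift detection, spread ratios, 95% covariance ellipse), not on
empirical acquisitions.

`replicate_empirical_design()` enumerates the physical protocol's 240
records (8 groups × 20 fixed + 10 repositioned repetitions); repositioning
is realised as a seeded rigid pose perturbation (±1 mm, ±1°,
`perturb_pose()`) — an addition of this package, since noise seeds alone
cannot stand in for physically moving a phantom.

# Numerical notes and limitations

* The projector clips each ray to the segment between source and detector
  pixel; line integrals are exact for rays through an axis-aligned box up
  to bilinear interpolation error.
* The FBP field of view must cover the object: the CLI sizes detectors at
  3× the grid extent by default; truncated projections produce severe
  cupping (this is physics, not a bug).
* Binary rasterized test objects have jagged edges whose line integrals
  deviate by a few percent at oblique angles; analytic-oracle tests use
  supersampled (anti-aliased) cylinders.
* Scatter, beam hardening, polychromatic spectra, detector blur, tube
  current modulation and vendor iterative kernels are all out of scope;
  the noise is uncorrelated Poisson only.
* The NIfTI-1 reader/writer is deliberately minimal (little-endian,
  axis-aligned, single-file); it round-trips this package's volumes
  exactly and is cross-checked against nibabel, but it is not a general
  NIfTI implementation.
* At small view counts FBP noise amplification is strong (the ramp filter
  integrates white sinogram noise across frequency); SIRT images are
  visibly smoother at the same `A` — the expected ordering between the
  two algorithm families.
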