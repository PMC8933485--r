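# radphantom

Simulated CT acquisitions for radiomics stability analysis.

## The problem

Radiomics features — intensity and texture statistics extracted from a
region of interest (ROI) of a CT image — are used as image biomarkers, but
they are sensitive to acquisition details: projection count, dose,
reconstruction algorithm. The gold standard for quantifying that
sensitivity is a test–retest study with a printed anthropomorphic phantom,
which is expensive and slow. `radphantom` provides the in-silico
counterpart for researchers who develop or vet radiomics features: a
virtual abdominal phantom, a cone-beam CT acquisition simulator, standard
feature extraction, and the statistics to score feature **stability**
(intra-class repeatability across acquisition settings) and
**discriminative power** (inter-class tissue separation).

## What it computes

* **Phantom** — an elliptical body with six ROIs in four tissue classes
  (2 normal liver, 2 cysts, hemangioma, metastasis), HU confined to the
  printable range [−100, 1000], texture as seeded correlated Gaussian
  fields. NIfTI-1 I/O for volumes and masks.
* **Acquisition** — helical (pitch 1, source/detector at 500/1000 mm,
  512×512 1 mm detector) or circular cone-beam geometries as explicit
  per-view vectors; Joseph-method forward projection with an exact
  adjoint; Poisson sinogram noise `k ~ Poisson(I₀ e^{−I})`,
  `I_final = −log(k/I₀)`, noise level `A = 1/I₀`; variance-vs-A
  calibration `σ² = slope·A + intercept`.
* **Reconstruction** — FDK-style filtered back-projection (Ram-Lak) and
  SIRT `x ← x + C Pᵀ R (b − P x)` (default 500 iterations), both back to
  HU.
* **Radiomics** — exactly 86 features (18 first-order, 22 GLCM, 14 GLDM,
  16 GLRLM, 16 GLSZM), fixed bin width 25 HU anchored at the ROI minimum,
  13-direction 3D texture matrices, IBSI-style formulas.
* **Statistics** — standardized rank-sum magnitude `W = |z|`
  (tie-corrected Mann–Whitney); a comparison is *stable* iff `W < 1` and
  *discriminative* iff `W > 1`; per-feature percentages over the 8-group ×
  10-seed study design; rankings and top-k overlap curves (10% of 86 →
  top 9); PCA variability comparison between acquisition sets.

## Worked example

```r
library(radphantom)

ph <- generate_phantom(fast_phantom_spec(seed = 1))
ph$volume
#> <voxel_volume> 64 x 64 x 1 voxels, spacing 1 x 1 x 1 mm
#>   HU range [-100.0, 146.3], origin (-32, -32, -0.5) mm
ph$masks[[5]]
#> <roi_mask> 'hemangioma' (hemangioma): 80 voxels

geom  <- build_circular_geometry(300, detector = c(1, 192, 1))
sino  <- forward_project(hu_to_mu(ph$volume), geom)
noisy <- add_poisson_noise(sino, noise_model(A = 1e-4, seed = 42))
noisy
#> <sinogram> 300 views of 1 x 192 (noisy), range [-0.03652, 1.752]

rec <- reconstruct(noisy, recon_spec("SIRT", n_iterations = 100),
                   grid = ph$volume)
fv  <- extract_features(rec, ph$masks[[5]])
round(unclass(fv)[c("firstorder_Mean", "firstorder_Entropy",
                    "glcm_Contrast", "glszm_ZoneEntropy")], 3)
#>    firstorder_Mean firstorder_Entropy      glcm_Contrast  glszm_ZoneEntropy
#>            126.248              2.298              2.626              3.808

wilcoxon_W(c(1, 2, 3), c(4, 5, 6))
#> <wilcoxon_result> W = 1.9640 (n = 3, 3)
```

The hemangioma (true mean 140 HU) reconstructs to a mean of ~126 HU at
this dose and view count; texture features quantify the reconstructed
heterogeneity. The `W` value 1.964 is the fully separated 3-vs-3 case —
above the stability threshold of 1.

The full study (8 groups: SIRT/FBP × 150–300 projections, `A = 1e-4`, 10
noise seeds, 6 ROIs → 480 feature vectors) runs with:

```r
res <- run_study(study_config(out_dir = "study_out"))
res$report   # per-feature stability % and discriminative power %
```

On this synthetic phantom the mean discriminative power across the 86
features is far above the mean stability — the qualitative pattern seen in
physical phantom studies (features sensitive to acquisition parameters yet
still separating tissue classes); the acceptance suite asserts this
ordering.

## Command line

A thin CLI wraps the same pipeline (see `inst/cli/radphantom`):

```sh
Rscript inst/cli/radphantom generate-phantom --out ph/ --fast --seed 1
Rscript inst/cli/radphantom project --phantom ph/phantom.nii.gz --nproj 300 --out sino/
Rscript inst/cli/radphantom add-noise --sino sino/ --A 1e-4 --seed 7 --out noisy/
Rscript inst/cli/radphantom reconstruct --sino noisy/ --algo sirt --iters 100 --out rec.nii
Rscript inst/cli/radphantom extract --vol rec.nii --masks ph/masks/ --out features.csv
Rscript inst/cli/radphantom stability --features features.csv --out report/
```

## Documentation

The methods vignette (`vignettes/simulated-ct-radiomics.Rmd`) documents
the phantom and noise models, the projector/adjoint pair, reconstruction
and feature-definition conventions, the `W` statistic, the scaled study
design, and known limitations.
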