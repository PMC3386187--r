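# ilpcitex

Texture analysis of in-line (propagation-based) X-ray phase-contrast
projection images of liver tissue bearing staged hepatic tumors.

In-line phase-contrast imaging (ILPCI) records, after free-space
propagation, an intensity pattern whose contrast is proportional to the
Laplacian of the X-ray phase shift — soft-tissue interfaces appear
edge-enhanced without any contrast agent. On such projections, normal
liver parenchyma and tumor tissue differ in *texture*: early tumors show
a diffuse fine grain, later ones develop necrotic lumps with sharp rims.
This package implements, end to end, the quantitative pipeline that
exploits this:

* a **synthetic phantom generator** with ground-truth masks and stage
  labels (6/9/12/15 days after tumor-cell inoculation), imaged through a
  paraxial Fresnel forward model
  (`exp(ikz)·exp(−iπλz(u²+v²))` in the frequency domain), its weak-object
  TIE limit `I ≈ I₀(1 − (λz/2π)∇²φ)`, and a detector model (Gaussian
  PSF, Poisson counts, 16-bit quantization) — real images of this kind
  were never deposited, so the generator is first-class, tested code;
* **ROI sampling** (20 patches of 60×60 px per region) and per-ROI
  min–max quantization to 16 gray levels;
* **GLCM texture**: symmetric co-occurrence matrices at distance 1,
  averaged over 0°/45°/90°/135°, summarized by nine parameters (angular
  second moment, inertia, inverse difference moment, entropy,
  correlation, sum/difference average, sum/difference entropy);
* a **dual-tree complex wavelet transform** (two levels, CDF 9/7 level-1
  filters + 14-tap Q-shift beyond, perfect reconstruction to ~1e−11)
  whose subbands yield two low-frequency (LF1, LF2) and two
  high-frequency (HF1, HF2) images, re-analyzed with the same texture
  parameters;
* a **PCA discriminant**: correlation-matrix PCA of the standardized
  feature matrix, components kept up to 80% cumulative contribution rate
  (`CRᵢ = λᵢ/Σλ`), first component sign-oriented so that **F₁ > 0 reads
  "normal" and F₁ < 0 "tumor"**;
* **stage monotonicity** of the pooled LF1 tumor texture (Spearman ρ of
  the per-stage mean scores) and **SVM staging** (radial-basis kernel,
  stratified 5-fold cross-validation over a small cost/γ grid, with a
  label-permutation baseline).

It is aimed at researchers in phase-contrast imaging and biomedical
image analysis who need a reproducible, fully testable reference
implementation of this GLCM + DTCWT + PCA + SVM methodology.

## Worked example

Simulate the default four-stage study (one 1024×1024 projection per
stage at 15 keV, 0.5 m, 9 µm pixels; 20 normal + 20 tumor ROIs per
image) and run every analysis:

```r
library(ilpcitex)

cfg <- pipeline_config(n_per_stage = 1, master_seed = 1)
res <- run_pipeline(cfg, "runs/demo")

d6 <- res$discriminant[["6d"]]
round(c(cr1 = d6$cr1, agreement = d6$agreement), 3)
res$lf1_trend$stage_means
res$svm$accuracy
```

With master seed 1 this prints (the numbers the code produced):

```
6d: CR1 = 80.8%, normal F1 = +2.58 ± 0.84, tumor F1 = -2.58 ± 0.49, agreement = 98%
LF1 stage means: -2.76 -0.82 +0.92 +2.66 | rho = 1
SVM: accuracy 72.5% (baseline 32.5%), best cost 100 gamma 0.01
```

Reading it: for the 6-day image the first principal component carries
80.8% of the standardized texture variance, and its oriented sign
separates the tissues — normal ROIs score positive (+2.58 on average),
tumor ROIs negative (−2.58), classifying 98% of ROIs correctly. The
pooled low-frequency (LF1) tumor texture score increases strictly with
tumor age (Spearman ρ = 1), and the cross-validated SVM assigns the
stage of unseen tumor ROIs with 72.5% accuracy against a 32.5%
permutation baseline. `runs/demo/` holds the images, masks,
`features.csv`, `features_dtcwt.csv`, both JSON reports and a run log;
rerunning with the same master seed reproduces every file byte for
byte.

A command-line front end over the same functions is installed with the
package (`system.file("scripts", "ilpci.R", package = "ilpcitex")`),
with subcommands `simulate`, `extract-rois`, `texture`, `texture-dtcwt`,
`discriminate`, `stage-classify` and `run`.

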