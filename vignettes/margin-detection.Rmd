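---
title: "Hyperspectral tumor-margin detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral tumor-margin detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hsimargin)
```

## The problem

Surgical resection of head-and-neck squamous cell carcinoma (SCC) fails to
achieve clean margins in a substantial fraction of cases, and intraoperative
frozen-section consultation is slow and sampling-limited. Label-free
hyperspectral imaging (HSI) of excised specimens offers a fast alternative:
a reflectance hypercube (here 450–900 nm in 5 nm bands, 91 bands) or an
autofluorescence cube (500–720 nm in 10 nm bands, 23 bands) is acquired per
specimen, and a classifier maps each pixel or patch to a cancer
probability. `hsimargin` implements the full analysis chain for this
problem — calibration, two training protocols, heat-map reconstruction,
margin-distance-stratified evaluation, and spectral saliency — and a
synthetic tissue-phantom generator so that every stage is testable without
patient data.

## Calibration model

Raw counts are flat-field normalized per band:

$$R = \frac{\mathrm{raw} - \mathrm{dark}}{\mathrm{white} - \mathrm{dark}}$$

with `dark` a closed-shutter frame and `white` a white-reference disk.
Whether an instrument's white normalization was itself dark-subtracted is
often unrecorded, so `calibrate()` also offers the
$(\mathrm{raw}-\mathrm{dark})/\mathrm{white}$ convention behind a switch;
the difference is a per-band gain. Pixels with a nonpositive denominator
are returned as an explicit flagged set, never as silent `NaN`s.
Reflectance above 1 — specular glare — is *retained*: glare handling is a
property of the downstream classifier in this design, and clipping is
offered for visualization only. Negative numerators (shot noise below the
dark level) are clamped to zero.

Tissue free edges curve away from the imaging surface and give unreliable
spectra, so a rim of the tissue mask is discarded from every performance
calculation (`trim_tissue_edge()`, 10 px = 0.25 mm at the instrument's
25 µm/px). The erosion uses a square (Chebyshev) structuring element with
image borders treated as background — deterministic and exactly matched by
the brute-force oracle in the tests.

## Margin-distance evaluation

The registered histology mask provides tumor/normal labels, but
registration, sectioning depth and photon penetration make labels within
roughly a millimetre of the tumor–normal interface uncertain. Performance
is therefore reported as a function of margin distance: the interface is
the set of tissue pixels with a 4-neighbor of the opposite class
(`find_interface()`); an exact Euclidean distance transform from that set,
scaled by the pixel pitch, gives a distance map in mm
(`distance_to_margin()`; at 25 µm/px, 40 px = 1 mm).

Two readings of "performance at *d* mm" exist. The implemented default
**excludes** pixels closer than *d* to the interface (on both sides) and
evaluates the remainder, so masks are nested in *d* and *d* = 0 is the
"actual" margin using every trimmed tissue pixel; accuracy rising with *d*
is the expected signature of removing the ambiguous zone. The alternative
reading — evaluate *only* pixels within *d* — is available via
`mode = "include"` for sensitivity analysis. Distances that leave a
patient without both classes are marked unattainable and dropped from that
distance's aggregate, which is why the per-distance sample size shrinks.

## Intra-patient protocol (ensemble LDA)

The personalized protocol trains on a patient's own primary-tumor (T) and
all-normal (N) specimens and tests on the same patient's tumor-involved
margin (TN). Features are raw calibrated pixel spectra (no derivatives or
projections — the simplest reading consistent with per-specimen training,
and the 91-dimensional spectrum is already a strong feature for LDA).
The ensemble is 500 linear discriminant learners in 5 stratified
pixel-level folds: the learner budget is split across folds, each fold's
learners are fit on bootstrap bags (`bag_fraction` 0.632) of the remaining
folds' rows, and the fold's own rows provide held-out validation scores.
Bagging is the standard way to make a learner-count ensemble out of a
deterministic base learner; boosting or feature subsampling would be
equally consistent with "an ensemble of 500 learners" but bagging is the
documented choice here.

Each learner is a two-class Gaussian discriminant with shrunk pooled
covariance $\hat\Sigma = (1-\gamma)S + \gamma\,\mathrm{diag}(S)$
(default $\gamma = 0.1$). At $C = 91$ bands and small specimens the pooled
covariance can be near-singular; diagonal shrinkage is the minimal guard
and $\gamma = 0.1$ is far from both the identity and the raw MLE. Class
priors are empirical. The ensemble score is the mean posterior over
learners.

## Inter-patient protocol (patch CNN)

The fully-independent protocol splits *patients* into 5 folds; all scenes
of a patient share a fold. For each fold, a patch classifier is trained on
T and N scenes of the other folds' patients (one of those folds held out
for early stopping and operating-point selection) and deployed once on the
held-out fold — so every patient receives exactly one set of test-level
predictions and the provenance record allows a leakage audit.

Patches are 25×25×C windows on a stride-12 lattice (window overlap 13 px),
plus a flush window at each image edge so border tissue is covered; full
coverage matters because the margin metrics need whole-tissue heat maps.
Training patches must be at least half tissue and are labeled cancer when
the tumor fraction of their tissue pixels is ≥ 0.5; patches with purity in
(0.2, 0.8) are dropped from training by default (T and N specimens are
near-pure, so this mainly affects phantoms). At inference every
tissue-intersecting patch is scored and overlapping patch scores are
averaged exactly per pixel (`reconstruct_heatmap()`), with the coverage
count retained.

The classifier is a compact inception-style network — a 1×1 spectral-mixing
convolution (accepting any C ∈ {3, 23, 91}), inception blocks with parallel
1×1/3×3/5×5 branches, global average pooling and a linear logit — trained
with Adam on binary cross-entropy, majority-class undersampling per epoch,
and early stopping on validation AUC (≤ 50 epochs). The forward/backward
passes are written directly on BLAS matrix products (shift-and-multiply
convolutions), which is exact and fast at these patch sizes and keeps
training fully deterministic under a seed. The network is deliberately
sized to train on a CPU at phantom scale; the protocol — patient-level
folds, patch geometry, validation-threshold semantics, overlap averaging —
is the fidelity target, not any specific large architecture, and the block
widths are configurable if a larger topology is wanted.

## Evaluation

`roc_curve()` sweeps thresholds over the unique scores (ties cross
simultaneously, contributing half); its trapezoidal area provably equals
Mann–Whitney pair counting, which the acceptance suite checks exhaustively
at small n. The operating point is chosen on *validation* data only, by
maximizing Youden's J (ties broken toward higher specificity); "optimal
operating point" is not otherwise defined in common usage, and the
closest-to-corner alternative differs only in tie-regions. The threshold
is then applied unchanged to test data.

Sensitivity and specificity are reported with their standard definitions
(TP/(TP+FN), TN/(TN+FP)) together with PPV and NPV. A common prose
formulation — "ratio of true positives to total positive predictions" —
literally describes PPV; reporting all four quantities keeps either
reading available. Modality comparisons use a paired one-tailed t-test per
patient, implemented in closed form so zero-variance differences are
flagged (t = 0, p = 0.5 for all-zero differences) instead of erroring; no
multiple-testing correction is applied across modality pairs, matching the
reporting style of the underlying study design. Specimen-type calls
(T/TN/N) are scored by decomposing margins into tumor and normal
components on both sides; the counting rules for all nine truth/prediction
combinations extend the two canonical cases (true TN predicted T → TP+FP;
true T predicted TN → TP+FN) in the unique way that scores pure-specimen
errors once and never penalizes a correct TN call.

## Spectral saliency

`gradcam_spectral()` turns the trained patch CNN into a per-wavelength
importance profile by applying the grad-CAM construction with the input's
spectral bands as channels: the channel weight is the spatial mean of the
class-score gradient at the input, pooled over the correctly classified
patches of the target class, and it multiplies the equally pooled mean of
the standardized input; the rectified product, min-max scaled, is the
profile. Two aspects of this reduction were forced by experiments on the
phantoms rather than free choices. First, activations must be averaged
across patches *before* the product and, when correctly classified patches
of the other class are available, centered on the pooled two-class mean:
without centering, class-independent structure (the tissue-vs-background
offset, the shared pixel-brightness field that the network cancels against
high-reflectance NIR reference bands) dominates the profile, because pure
sensitivity is not class evidence. Second, the profile is only meaningful
for a fully trained network — early-stopped networks whose validation AUC
saturates in the first epochs retain near-initialization weights, and
their gradients attribute to arbitrary bands; the saliency analyses
therefore train to convergence with substantive weight decay (0.1).
Weighting the spatial means by the grad-CAM map of the last inception
block is available (`spatial_weighting = "gradcam"`) but is not the
default, because CAM weights differ between the two classes' patch sets
and spoil the cancellation. The reduction is validated by parameter
recovery — on phantoms whose class separation is injected only at
560/565 nm, those two bands are the profile's top-2 for both classes
across seeds — rather than by any claim of uniqueness.

## The phantom generator: what it emulates, and what it does not

`generate_cohort()` produces T/N/TN specimen triples per patient with the
statistical structure the analysis assumes:

* **Spectra** are phenomenological: a smooth reflectance baseline with
  Gaussian oxygenated-hemoglobin absorption dips at 560 and 565 nm (deeper
  in SCC), stronger near-infrared attenuation in normal tissue (fat,
  collagen, water), and a small broad SCC brightening so the classes
  differ at every band — the qualitative features reported for real SCC
  spectra, not a radiative-transfer simulation. A fluorescence variant
  puts Gaussian emission peaks on an emission-shaped baseline.
* **Sensor model**: raw counts are reflectance × (white − dark) + dark,
  rounded, under a band-dependent white reference with mild vignetting, a
  flat dark level, additive per-band noise (σ = 0.02 reflectance), a
  per-pixel lognormal brightness field (σ = 0.08) for spatial texture, and
  ~2% flat near-saturation glare pixels. Calibration recovers the
  generating reflectance to within the noise level by construction.
* **Geometry**: elliptical tissue blobs with harmonic boundary roughness;
  TN scenes contain one contiguous tumor blob with a single interface and
  both classes ≥ 10% of tissue.
* **Margin uncertainty**: the labeled TN boundary is exact, but the
  *spectral* boundary is displaced by a smooth random field and blurred by
  partial-volume mixing over a 1 mm scale — chosen to match the ~1 mm
  registration error plus margin-depth uncertainty described for
  histology-to-HSI registration. This is the feature that makes AUC rise
  as the exclusion distance grows; with a hard spectral boundary the
  distance stratification would be vacuous.

Default phantom scale: 64×64 px scenes at 100 µm/px (6.4 mm extent,
matching the ~9 × 6 mm median size of real excised specimens at coarser
sampling), 10-patient cohorts, `class_separation = 1` as the
high-separation condition. These sizes were chosen once so the full
pipeline — cohort simulation, 10 personalized LDA ensembles, a 5-fold CNN
experiment and saliency extraction — runs end to end on a single CPU in
minutes while every protocol element (fold structure, patch lattice,
distance strata up to ~1.5 mm) remains non-trivially exercised.

What the phantoms deliberately do **not** model: real registration
deformation (masks are exact by construction; uncertainty enters only
through the spectral-boundary displacement), dye chemistry, wavelength-
dependent point-spread, camera nonlinearity, and inter-patient biological
variability beyond random geometry and pixel fields. Passing the
parameter-recovery tests therefore shows the *pipeline* is correct and
sensitive under its stated assumptions — it does not certify clinical
performance on patient data, and no claim about patient-data performance
is made here.

## Numerical choices and degenerate inputs

* Band grids must divide exactly (checked to 1e-8 relative); degenerate
  single-band grids are legal.
* RGB composites default to 650/550/450 nm Gaussian kernels with
  σ = 30 nm — canonical R/G/B centers inside the 450–900 nm grid; σ = 0
  degenerates to single-band selection and requires the center to sit on
  the grid.
* `fit_lda()` refuses single-class input and singular covariances (with
  guidance to raise `shrinkage`); an ensemble of one full-bag learner
  reduces exactly to a single LDA fit.
* Ties in operating-point selection resolve toward higher specificity,
  then higher threshold, making the choice deterministic.
* Empty evaluation masks warn and yield `NA` metrics rather than erroring,
  so per-distance aggregation can simply drop unattainable rows.
* All randomness flows from explicit seeds; per-scene, per-patient and
  per-fold seeds derive from a master seed by a counter scheme
  (`derive_seed()`), so cohorts are reproducible regardless of evaluation
  order.

## Known limitations

* The inception-style network is a compact stand-in sized for CPU phantom
  studies; porting a specific large topology is possible through
  `cnn_config()` but not attempted.
* Glare pixels are generated and retained but not segmented or inpainted.
* The ensemble's 500 learners are bagged; if the original ensemble used a
  different resampling scheme, absolute scores would differ while the
  protocol-level conclusions tested here would not.
* Fluorescence phantoms reuse the reflectance machinery with emission
  peaks; they share its simplifications.
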