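# hsimargin

Delineating squamous-cell-carcinoma margins in hyperspectral images of
excised head-and-neck tissue specimens.

Surgeons resecting head-and-neck SCC rely on slow intraoperative
frozen-section consultation to judge whether margins are clean, and 10–30%
of cases still end with close or positive margins. Label-free hyperspectral
imaging (HSI) of the excised specimen — a reflectance cube of 91 bands over
450–900 nm, or an autofluorescence cube of 23 bands over 500–720 nm — can
be classified into per-pixel cancer probability in minutes. `hsimargin`
implements that analysis chain for imaging scientists and computational
pathologists:

* **Calibration**: per-band flat-field normalization
  R = (raw − dark)/(white − dark) against closed-shutter and
  white-reference frames, with glare retained, flagged bad pixels, ENVI
  raster I/O, Gaussian-kernel RGB composites, and edge trimming
  (10 px = 0.25 mm at 25 µm/px).
* **Margin geometry**: the tumor–normal interface from registered
  histology masks, an exact Euclidean distance-to-margin map (40 px = 1 mm
  at 25 µm/px), and nested millimeter-increment evaluation masks —
  performance at "TN at d mm" excludes the ambiguous zone within d of the
  interface.
* **Intra-patient protocol**: a personalized ensemble of 500 shrinkage-LDA
  learners trained in 5 folds on one patient's tumor (T) and normal (N)
  specimens, tested on the same patient's margin specimen (TN), with the
  ensemble score the mean posterior w'x + b passed through the two-class
  Gaussian formula.
* **Inter-patient protocol**: patient-level 5-fold cross-validation of a
  compact inception-style CNN on 25×25×C patches (sliding window, overlap
  13 px), overlap-averaged heat-map reconstruction, and a leakage-auditable
  provenance record.
* **Evaluation**: trapezoidal ROC/AUC (≡ Mann–Whitney pair counting),
  Youden-J operating points chosen on validation data only,
  accuracy/sensitivity/specificity/PPV/NPV, distance-stratified
  per-patient reports, and paired one-tailed t-tests for modality
  comparisons; specimen-type (T/TN/N) confusion with TN decomposed into
  components.
* **Saliency**: grad-CAM spectral profiles — per-wavelength importance of
  the trained CNN, scaled to [0, 1].
* **Synthetic phantoms**: a generator producing T/N/TN triples per patient
  with hemoglobin absorption dips at 560/565 nm (deeper in SCC), stronger
  NIR absorption in normal tissue, sensor noise, specular glare, and a
  ~1 mm spectral uncertainty zone at the TN margin, so the whole pipeline
  is testable without patient data.

See `vignettes/margin-detection.Rmd` for the model details and design
rationale.

## Worked example

```r
library(hsimargin)

# a 10-patient phantom cohort under the default study conditions
cohort <- generate_cohort(10, scene_spec(), seed = 101)

# personalized protocol for one patient
pat <- cohort$scenes
ens <- train_intra_patient(pat$P001_T, pat$P001_N,
                           ensemble_config(n_learners = 100, seed = 1),
                           trim_px = 3)
roc_val <- roc_curve(ens$val_scores, ens$val_labels)
roc_val
#> <roc_curve> 2343 thresholds, AUC = 0.9997
op <- optimal_operating_point(roc_val)
pm <- predict_map(ens, pat$P001_TN)

report <- distance_report(list(P001_TN = pm), cohort,
                          d_grid = c(0, 0.5, 1), threshold = op$threshold,
                          trim_px = 3)
report[, c("d_mm", "auc", "accuracy", "n_pixels")]
#>   d_mm       auc  accuracy n_pixels
#> 1  0.0 0.9369662 0.8679847     1568
#> 2  0.5 0.9967755 0.9631966      951
#> 3  1.0 0.9968102 0.9742991      428
```

Held-out validation AUC on the patient's own T/N pixels is 0.9997 (the
default phantom separation is high), while AUC on the margin specimen is
0.94 at the registered margin (`d = 0`) because labels within the ~1 mm
uncertainty zone conflict with the underlying spectra; excluding that zone
(`d = 0.5`, `1`) recovers near-perfect AUC on fewer pixels — the same
qualitative signature the margin-distance framework is designed to expose
on real specimens.

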