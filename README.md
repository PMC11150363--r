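# brainage

Brain age estimation from T1-weighted structural MRI with an
attention-augmented 3D residual network, and Alzheimer's-vs-normal
classification from the resulting brain-age gap.

## What it does, and for whom

The brain ages in structurally measurable ways — the ventricles enlarge and
grey matter declines.  A regression model trained on cognitively normal (CN)
subjects predicts a **brain age** from a scan; the **brain-age gap**

    BAG = predicted brain age − chronological age

is elevated when brain aging is accelerated, as in Alzheimer's disease (AD),
making it a compact, interpretable biomarker.  This package is for
neuroimaging researchers who want a complete, dependency-light, fully
testable implementation of that pipeline:

* **Preprocessing**: brain extraction (mask, external tool hook, or
  threshold fallback), smooth multiplicative bias-field correction (robust
  log-polynomial fit, N4-substitutable via a hook), trilinear resampling to
  the network grid, within-mask z-scoring.
* **Regression network**: three residual blocks (8, 32, 128 features)
  interleaved with two dot-product self-attention blocks (16, 64), 3×3×3
  convolutions, 1×1×1 shortcut projections, ELU(α = 1), 2×2×2 max-pooling,
  a 128-unit L2-regularised dense layer with dropout 0.2, and subject sex
  fused before the final linear age unit.  A residual block computes
  `H(x) = shortcut(x) + F(x)` (pointwise sum); an attention block computes
  query/value embeddings, softmax attention over all spatial positions,
  concatenates query and attention output, and projects back to the block
  width.  Forward *and* backward passes are implemented in
  Rcpp/RcppArmadillo — no deep-learning framework required — and trained
  with Adam (lr 0.0007) on MSE loss.
* **SVR head**: epsilon-insensitive RBF support-vector regression on the
  fused penultimate features `F_l ⊕ G` for the final age estimate.
* **AD detection**: brain-age gaps feed four classifiers — logistic
  regression, SVM, AdaBoost, XGBoost — combined by majority voting
  (2–2 ties broken by mean predicted probability), reported with precision,
  recall, F1, accuracy, ROC and AUC.
* **Interpretability**: 3D Grad-CAM saliency maps over the age output.
* **Synthetic phantoms**: an age-encoded ellipsoid generator (growing
  ventricle, sex-scaled brain volume, bright skull shell, noise, bias
  field, AD-as-accelerated-aging) so the entire pipeline is testable
  without clinical data.

Volumes are NIfTI (`.nii`/`.nii.gz`); cohorts are CSV manifests with columns
`subject_id, scan_path, age, sex, diagnosis`.  Train/validation/test splits
are always by subject, never by scan.

## Worked example

The one-command demonstration generates a phantom cohort, trains the reduced
network, fits the SVR head, and runs the BAG-based AD classification:

```r
library(brainage)
r <- run_demo(seed = 5, scale = "test")
print(r$metrics)
#> Regression metrics on 12 scans:
#>   MAE   5.555 years
#>   RMSE  7.329 years
#>   PCC   0.948   SRCC  0.762   R2  0.835
#>   95% CI of mean signed error: [-8.099, 0.017]
print(r$svr_metrics)
#> Regression metrics on 12 scans:
#>   MAE   4.120 years
#>   RMSE  5.141 years
#>   PCC   0.974   SRCC  0.846   R2  0.919
#>   95% CI of mean signed error: [-4.690, 1.873]
print(r$ad$ensemble)
#> Classifier report (6 samples, AD positive):
#>   TP 3  FP 1  FN 0  TN 2
#>   precision 0.750  recall 1.000  F1 0.857  accuracy 0.833
#>   AUC 1.000 (7 ROC points)
```

Reading this: on the 12 held-out phantom scans the network predicts age with
a mean absolute error of 5.6 years versus 18.0 years for the mean-age
baseline, and the SVR head improves it to 4.1 years; on the held-out CN/AD
phantoms the majority-vote ensemble classifies 5 of 6 correctly from the
brain-age gap alone.  (This is the seconds-scale 16×16×8 demo; the
32×32×16 study in `scripts/acceptance.R` reaches MAE ≈ 1.5 years.)

The step-by-step equivalent:

```r
params <- phantom_params(shape = c(32, 32, 16), noise_sd = 0.01)
gen    <- make_cohort(240, age_range = c(20, 80), params = params, seed = 11)
ch     <- split_subjects(gen$cohort, test_fraction = 0.25, seed = 12)
vols   <- lapply(gen$volumes, \(v) normalize_intensity(extract_brain(v, v$mask)))

cfg    <- network_config(features = c(4, 8, 16), types = c("res", "att", "res"),
                         input_shape = c(32, 32, 16))
model  <- build_network(cfg, seed = 13)
model  <- train_network(model, train_set, val_set, train_spec(epochs = 12, seed = 14))
head   <- fit_svr(extract_features(model, train_set))
ages   <- predict_svr(head, extract_features(model, test_set))

bag    <- compute_bag(chronological, ages)
report <- detect_ad(bag, diagnosis, seed = 16)
cam    <- gradcam(model, volume, sex = 1)     # saliency over the age output
```

A thin command-line interface covering `simulate`, `split`, `preprocess`,
`train`, `predict`, `evaluate`, `classify-ad`, `gradcam` and `demo` is
installed at `inst/cli/brainage` (run it with `Rscript` or directly).

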