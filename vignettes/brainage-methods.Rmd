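---
title: "Brain age from structural MRI: model, assumptions and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age from structural MRI: model, assumptions and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The brain changes structurally throughout life: ventricles enlarge, grey
matter volume declines, white-matter integrity degrades.  A regression model
trained to predict chronological age from T1-weighted structural MRI of
cognitively normal (CN) subjects learns what *typical* aging looks like.
Applied to a new scan, its prediction is the subject's **brain age**, and the
difference

$$\mathrm{BAG} = \widehat{\mathrm{age}}_{\mathrm{brain}} - \mathrm{age}_{\mathrm{chronological}}$$

— the **brain-age gap** — is a compact biomarker of deviation from typical
aging.  Neurodegeneration manifests as accelerated brain aging, so
Alzheimer's disease (AD) patients show systematically positive gaps.  This
package implements the full pipeline: preprocessing, an attention-augmented
3D residual regression network with a support-vector-regression (SVR) head,
Grad-CAM saliency, and BAG-based AD-vs-CN classification by a four-classifier
majority-vote ensemble.

## The regression model

The network input is a preprocessed volume $x$ (default $64 \times 64
\times 32$) plus the subject's sex code $G \in \{0, 1\}$.  Five blocks
alternate residual and attention types — `R(8), A(16), R(32), A(64), R(128)`
— each halving all three spatial dimensions with $2^3$ max-pooling, so the
terminal feature map is $2 \times 2 \times 1 \times 128$.

**Residual blocks.**  With stride-1, zero-padded $3^3$ convolutions and a
$1^3$ shortcut projection $s(\cdot)$,

$$H(x) = s(x) + \mathrm{BN}(\mathrm{conv}(\mathrm{ELU}(\mathrm{BN}(\mathrm{conv}(x))))), \qquad
\mathrm{out} = \mathrm{maxpool}(\mathrm{ELU}(H(x))).$$

The shortcut projection exists precisely so the pointwise sum is well
defined when the channel count changes.  All activations are ELU with
$\alpha = 1$.

**Attention blocks.**  Two independent $3^3$ convolutions produce query and
value embeddings $Q, V$; spatial positions are flattened to a sequence of
length $N = DHW$ with $C$ channels and

$$S_{ij} = Q_i \cdot V_j, \qquad W = \mathrm{softmax}_{\mathrm{rows}}(S), \qquad
\mathrm{att}_i = \textstyle\sum_j W_{ij} V_j .$$

Keys equal values (no separate key embedding) and scores are unscaled by
default (`use_scale` adds the $1/\sqrt{C}$ variant) — matching the stock
dot-product attention layer of the framework family this architecture comes
from.  The query and attention maps are concatenated along channels and a
third $3^3$ convolution projects back to the block's stated feature count,
so the widths 16 and 64 remain meaningful as output widths; then BN, ELU and
max-pooling as usual.  Because softmax weights form a probability vector,
every attention output lies in the convex hull of the value rows — one of
the package's property tests.

**Head.**  Flatten $\to$ dense(128, L2 $10^{-4}$) $\to$ ELU $\to$
dropout(0.2) $\to$ concatenate $G$ $\to$ a final linear unit producing the
age estimate.  After training, the post-ELU dense activation $F_l$ (dropout
off) is extracted per scan and an epsilon-insensitive RBF SVR is fitted on
$F_l \oplus G$:

$$\hat y = \mathrm{SVR}(F_l \oplus G).$$

Sex therefore enters twice — once fused inside the network and once in the
SVR input — which is how the design is stated; the redundancy is harmless
and keeping both preserves the stated interfaces.

Training uses Adam (learning rate $7\times10^{-4}$), mean-squared-error
loss, batch size 8 (unstated in the design; 8 is a conventional choice at
this volume size) and a fixed epoch budget with the best-validation-loss
parameters checkpointed — no early stopping, but desk-scale runs are
protected against late-epoch noise.

### Numerical choices

* **Everything differentiable is hand-authored** (C++ kernels for
  convolution, pooling and attention; R for BN, ELU, dense, dropout, Adam)
  and verified end-to-end by central-difference gradient checks (max
  relative error $\approx 4\times10^{-8}$ across all parameter groups).
* **Attention memory**: scores are computed in row chunks (default 256
  queries at a time), bounding memory at $O(N \cdot \mathrm{chunk})$; at the
  full-scale first attention block $N = 16{,}384$, so materialising all
  $N^2$ scores would need 2 GB.  Chunking changes neither results nor
  determinism.
* **Batch-norm momentum** defaults to 0.9 rather than the framework-typical
  0.99.  With only ~20 mini-batches per desk-scale epoch, a 0.99 decay
  leaves the inference-mode running statistics far behind the batch moments
  for most of a short schedule, which wrecks held-out evaluation while
  training loss looks fine.  0.9 converges within a few dozen updates; long
  runs may raise it.
* **Max-pooling ties** resolve to the first maximum in scan order —
  deterministic.
* **SVR scaling**: the age target is standardised by its training moments
  (an $\epsilon$-tube regression with $C = 1$ is only well scaled for an
  O(1) response; `epsilon` is specified in years and converted internally).
  Feature columns are centred per column but scaled by a single *pooled*
  standard deviation by default: the 128 dense activations are homogeneous
  quantities, and per-column z-scoring would inflate near-dead,
  noise-dominated units to unit variance, distorting the RBF metric.
  Classic per-column scaling is available via
  `svr_params(standardize = "column")`.  Statistics always come from
  training rows only and are stored with the head.
* **Majority voting** over the four base classifiers (logistic regression,
  RBF-SVM, AdaBoost on decision stumps, XGBoost) breaks 2–2 ties by the
  mean predicted AD probability against 0.5 — deterministic and
  information-preserving; the ensemble ROC uses that mean probability as its
  score.  AdaBoost is implemented in-package (discrete AdaBoost with
  `rpart` stumps), since the surrounding stack provides gradient boosting
  but no AdaBoost learner.

## Preprocessing chain

Fixed order, each stage switchable: **brain extraction** (supplied mask
first, then an external tool hook, then an Otsu-threshold fallback that
seals the bright skull/scalp shell with a morphological closing and takes
its enclosed interior), **bias-field correction**, **resampling** to the
network grid, and **within-mask z-scoring**.

The bias corrector estimates the smooth multiplicative
intensity-inhomogeneity field by a robust (Huber M-estimate) polynomial fit
of configurable order (default 2) to log-intensities inside the mask and
divides it out, preserving the mean in-mask intensity.  Robustness plays the
role histogram sharpening plays in N4-style correctors: genuine dark
structure (ventricles) must not leak into the field estimate.  A hook
(`n4_hook`) substitutes an external N4 implementation where available.
The overall intensity scale is fundamentally unidentifiable in this model
(any global factor can move between tissue and field); the package resolves
it by preserving the input's in-mask mean.

Resampling is trilinear for intensities (half-pixel centre alignment),
nearest-neighbour for masks, with a Gaussian anti-aliasing prefilter
(sigma $(f-1)/2$ per axis) when an axis is downsampled by more than a
factor of 2.  Axes are stretched independently: anisotropic inputs are
distorted onto the target grid.  This is acceptable here because every
scan — training and test — passes through the identical mapping; it would
matter for morphometry, which this package does not do.

## The synthetic phantom generator

Clinical MRI collections cannot ship with a package, so every downstream
stage is validated on **age-encoded phantoms**: concentric ellipsoids with
zero background, a bright "skull/scalp" shell, a "brain" compartment whose
overall volume differs between the sexes by `sex_scale` (default 8%,
roughly the adult intracranial-volume sex difference), and a central dark
"ventricle" whose radius grows linearly with age
(`ventricle_base_radius + ventricle_growth × age`; defaults scale with the
grid, 1.5 voxels + 0.07 voxels/year on a 32-voxel axis).  Additive Gaussian
noise and a multiplicative exponentiated-quadratic bias field emulate
scanner artifacts — the latter is exactly the model class the bias
corrector assumes, which makes field recovery testable with a known ground
truth.  AD subjects are rendered at `age + Δ` with
`Δ ~ N(ad_delta_mean, ad_delta_sd)` truncated at zero while their manifest
age stays chronological: AD *is* accelerated aging in this world, which is
the premise of the BAG biomarker.  The default Δ ~ N(5, 2) years creates a
recoverable but non-trivial separation, consistent with the ~4-year CN/AD
gap difference reported for real cohorts; the BAG recovery study uses
Δ = 8.

What the phantoms deliberately do **not** model: anatomy (no gyri,
hippocampus, tissue classes), MRI physics (no Rician noise, no partial
volume), registration error, or motion.  A passing synthetic suite
therefore demonstrates that the *pipeline mechanics* are correct — the
architecture learns a monotone structure–age mapping, the gap separates
accelerated agers, preprocessing recovers known corruptions — not that any
particular clinical accuracy will be achieved on real data.

## Desk-scale study conditions

The acceptance-style tests and `scripts/acceptance.R` run one fixed study:
240 single-scan CN subjects, ages uniform on 20–80, phantoms on a
$32 \times 32 \times 16$ grid with noise 0.01, a subject-level 25% test /
10% validation split, and the reduced `R(4), A(8), R(16)` network (dense
128) trained 12 epochs — about five minutes on one CPU.  A second cohort of
80 subjects (half AD, Δ = 8, ages 50–75) feeds the BAG classification with
a stratified 85/15 split.  The demonstration command `run_demo(scale =
"test")` shrinks further to a $16 \times 16 \times 8$ grid and 48 subjects
for a seconds-scale smoke run; `scale = "full"` configures the full
$64 \times 64 \times 32$ architecture and 100 epochs for unattended runs.

Typical desk-scale results (seed-dependent): network test MAE ≈ 1.5 years
against a mean-age-baseline MAE ≈ 13.6; SVR head MAE at or slightly below
the network's; CN/AD gap difference ≈ 6–7 years for Δ = 8 (regression
dilution compresses the gap slightly, as it does in real BAG studies);
ensemble hold-out accuracy ≥ 0.9.  The numbers your machine produces are
written by `scripts/acceptance.R` and the test suite — the package makes no
claims beyond what those runs compute.

## Design choices where the design was genuinely open

* **Residual-block combination**: the defining equation is a pointwise sum;
  an alternative reading mentioning concatenation inside residual blocks is
  rejected in favour of the sum, which the $1^3$ shortcut projection exists
  to enable.
* **Attention block third convolution**: interpreted as the projection of
  the query/attention concatenation back to the block's feature count.
* **Sequence construction**: a 3D feature map becomes an attention sequence
  by flattening all spatial positions, channels as the feature dimension.
* **F_l**: the 128-unit dense activation (the last feature vector before
  the output), not the 512-long flattened convolutional map; the latter is
  available via `extract_features(..., layer = "flatten")`.
* **Validation fraction**: 10% of subjects by default (only "training and
  validation sets" is stated upstream).
* **Repeated scans** of one subject are evaluated per scan; subject-level
  splitting already prevents leakage, and scan-level metrics match how the
  combined-cohort numbers are reported.
* **Confidence interval**: `ci95` is the t-based interval of the mean
  signed error — one defensible reading of an otherwise undefined interval
  column.
* **Tie rule and ensemble score**: see above; both are undefined upstream.

## Known limitations

* The network is trained and validated on phantoms at desk scale; clinical
  use requires full-scale training on real, preprocessed cohorts.
* No noise robustness: like the design it follows, the model expects
  artifacts to be removed beforehand.
* Brain extraction is a pluggable interface; the built-in fallback is a
  threshold/morphology heuristic adequate for phantoms and clean heads, not
  a learned skull stripper.
* The bias corrector is a log-polynomial surrogate satisfying the same
  contract as N4 (smooth multiplicative field, mean preservation); true N4
  can be substituted through the hook.
* Grad-CAM's source layer defaults to the final residual block's pre-pool
  activation (configurable).  At desk scale that map is only
  $8 \times 8 \times 4$, too coarse to resolve a ventricle a few voxels
  wide; localisation claims on small grids should use an earlier block
  (`source_block = 1`), which is what the saliency test does.
* MCI conversion, multi-modal inputs and atlas-space localisation of
  saliency are out of scope.
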