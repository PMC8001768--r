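---
title: "histopatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histopatch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models behind each stage, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the known limitations. Everything quantitative
stated here is computed by the test suite or by `scripts/acceptance.R`;
nothing is quoted from elsewhere.

## 1. The synthetic H&E image model

The generator exists so that every downstream stage — stain separation,
descriptors, classifiers, fine-tuning, explanation — can be exercised on
data whose ground truth is known exactly.

**Color.** A patch is composed in optical-density space under the
Beer–Lambert law: `RGB = 255 · 10^(−W c)`, where the columns of the 3×2
matrix `W` are unit-norm stain color vectors (hematoxylin-like
`≈ (0.65, 0.70, 0.29)` and eosin-like `≈ (0.07, 0.99, 0.11)` before
normalization — widely used reference values) and `c(x, y)` are per-pixel
concentrations. Nuclei carry high hematoxylin concentration (0.85 ± 0.12
chromatin texture); stroma carries band-pass textured eosin
(0.35 ± 0.18). Two choices matter for identifiability of the stain model:
the stromal hematoxylin wash is faint (≈ 0.015) and *statistically
independent* of the eosin texture field, and chromatin largely excludes
eosin (8% of the stromal level). If instead the two concentration maps
were proportional, the factorization `V = W H` would be unidentifiable in
principle — no solver could recover `W`. `stain_jitter` perturbs the
entries of `W` with Gaussian noise per image (then renormalizes), which is
what stain normalization is meant to undo.

**Morphology.** Each class specification controls nucleus count, radius,
eccentricity, margin irregularity, and clustering. Margins are rendered as
`r(θ) = r₀ (1 + a Σ_{k=2..5} c_k sin(kθ + φ_k))` with random phases —
a cheap, parameterizable model of irregular, spiculated nuclear outlines.
The benign default is few (5–10), small (2.5–4.5 px), round, smooth
nuclei; the malignant default is many (9–16), large (6–10 px), elongated,
irregular, clustered nuclei — the direction pathologists describe.
Magnification is realized purely as a nuclear-scale multiplier
(40×: 1.0, 100×: 1.6, 200×: 2.5, 400×: 4.0) at fixed patch size, keeping
one knob per magnification without resampling artifacts.

**Ground truth.** The union of rendered nuclei is returned as a binary
mask with center coordinates. When `signal_quadrant` is set, *entire
nucleus bodies* (not just centers) are confined to the requested quadrant
— the center range is inset by each nucleus's outer radius — so the
class-discriminative signal is planted in a known region for the
localization checks.

**What the generator does not emulate.** Real histology has lumina,
stromal fibers, overlapping nuclei with shared chromatin structure,
scanner point-spread functions, compression artifacts, and inter-patient
variation far richer than stain jitter. Passing tests on this generator
shows the pipeline's machinery is correct and sensitive to the planted
effects; it does not certify clinical performance.

**The separability contract.** On the defaults, a threshold on mean
nucleus area from ground truth classifies benign vs malignant at ~98%
(n = 200). That guarantees downstream classifiers have real signal — and
it also means the binary desk-scale task *saturates* strong classifiers
(see §7).

## 2. Stain normalization

Images are mapped to optical density `OD = −log₁₀(max(I,1)/I₀)`,
`I₀ = 255` (log base 10 is a convention; any base is equivalent up to
scale). Tissue pixels are those with max-channel OD above `β = 0.15`;
images with fewer than 100 such pixels raise a typed "no tissue" error
that pipeline mode converts into pass-through.

Stain separation solves

`min ‖V − W H‖² + λ Σ H,  W ≥ 0 (unit columns), H ≥ 0, λ = 0.1`

over tissue pixels. The package solves this by **block coordinate
descent in the dictionary-learning style**: an exact per-pixel active-set
solve for `H` (with two stains the four active sets have closed forms and
vectorize across pixels) alternating with the projected atom update
`w_j ← normalize(max(R_j h_jᵀ, 0))`. We tried the multiplicative-update
NMF first and rejected it on evidence: with unit-column renormalization
and the L1 term, the update map is not monotone — started *at the true
basis* it walks away (the objective climbs) and settles on a degenerate
basis whose hematoxylin cosine with truth is ≈ 0.71. The coordinate
solver recovers both stain columns at cosine ≥ 0.999 from any seeded
random start (200 iterations, tolerance 1e-6, deterministic per seed).

Normalization decomposes the source in its own basis, rescales each
concentration row by the ratio of robust (99th-percentile) maxima, and
recomposes in the reference basis. The L1 penalty serves *identification*;
the concentrations used for recomposition are re-solved with λ = 0
(plain non-negative least squares), since lasso shrinkage would uniformly
brighten the output (self-normalization error drops from ≈ 7 to < 0.5
intensity levels). The reference image is an operator choice supplied by
path; the package does not auto-select a template.

## 3. Handcrafted descriptors

All three extractors are implemented in the package and are checked
against independent brute-force oracles in the tests (agreement to 1e-8
on 16×16 random images).

**Zernike moments** (shape/margin). The image grid is mapped onto the
unit disk centered at the image center with radius `min(H, W)/2`; pixels
outside contribute nothing. For each valid pair (n, m) with n ≤ 8, m ≥ 0,
n − m even (25 pairs), the discrete projection onto the conjugate basis
`R_{n,m}(ρ) e^{−imθ}` is scaled by `(n+1)/α_N`, where `α_N` is the number
of in-disk pixels — this makes the (0,0) magnitude the disk-mean intensity
and bounds all magnitudes. Magnitudes (not complex values) are returned:
only magnitudes are rotation invariant, which the tests verify under
90°/180°/270° rotations (exact-resampling rotations; observed error
~1e-13, asserted < 1e-2). Grayscale conversion uses ITU-R BT.601 luma.

**Haralick texture.** Gray levels are quantized to 32 uniform bins over
[0, 255]; co-occurrence matrices are accumulated at displacements
`(round(d cos α), −round(d sin α))` for d ∈ {1, 2, 4} and the eight
multiples of 45°, symmetrized and normalized; the first 13 Haralick
statistics are computed per matrix and averaged element-wise over all 24.
The 14th statistic (maximal correlation coefficient) is excluded for its
numerical instability. Distances and level count are configurable; the
defaults span fine-to-coarse texture at patch scale. Numerical guards:
log base 2 with ε = 1e-12 inside entropy terms; correlation-type terms
return 0 when a denominator (variance or marginal entropy) vanishes, as
on constant images; "sum variance" is centered on the sum average (the
statistically meaningful centring of that distribution).

**Color histogram.** The joint 8×8×8 histogram over (R, G, B) — 512 bins,
R-major flattening — normalized to frequencies so the feature is
resolution independent. The joint (rather than per-channel) form is what
yields a 512-length vector.

Fusion concatenates the three blocks in a fixed order (25 + 13 + 512 =
550) with layout-stable names. By default images are resized to 224×224
before extraction so both study arms see identical inputs; the desk-scale
experiments in the tests extract at native size (`resize_to = NULL`)
because upsampling 32-px synthetic patches adds no information.

## 4. Classical classification protocol

Stratified 10-fold cross-validation: each class is dealt round-robin into
folds (remainders go to the currently smallest folds, so fold sizes never
differ by more than one record and per-fold class counts stay within one
of the global proportion); within each fold's training portion a
stratified 30% is set aside as a validation set (used for MLP monitoring
only). Feature standardization (zero mean, unit variance) is fitted on
the training portion only — the fused vector mixes scales (moments vs
frequencies), and KNN/SVM/MLP are scale sensitive.

Hyperparameters are fixed at the study's values: KNN k = 3 (Euclidean;
ties in the vote broken deterministically by smallest class index, which
is why KNN is implemented directly rather than through a library whose
tie-break is random); RF 100 trees; MLP one hidden layer of 100 rectified
units trained by Adam (L2 1e-4, lr 1e-3, up to 2000 epochs with plateau
stopping), implemented on the package's own network core since no
installed R MLP offers ReLU + Adam; AdaBoost as SAMME over depth-1
`rpart` stumps (50 rounds, learning rate 1), written here because no
AdaBoost package is available in the environment; linear SVM with C = 5
via `e1071`. Macro averaging is used for multiclass recall/precision (the
standard choice under class imbalance). Splitting is image-level,
mirroring the study protocol; patient IDs are carried in the manifest so
group-aware splits remain possible.

## 5. The network and block-wise fine-tuning

The network is the classic 19-weight-layer VGG design: conv blocks of
(2, 2, 4, 4, 4) 3×3 convolutions with 2×2 max-pools, then dense layers of
4096, 4096, and `num_classes` width, partitioned into blocks B1–B5 (conv)
and B6 (dense). `apply_blockwise_schedule(net, "B3")` trains B3–B6 and
freezes B1–B2; `B1` is full fine-tuning; `B6` trains the head only.
Trainable-parameter counts increase strictly from B6 to B1 (verified for
all six schedules), and frozen parameters are bit-identical before and
after training (the freeze contract).

Training follows the fixed protocol: SGD with momentum 0.9, constant
learning rate 0.001, dropout 0.5 on the two hidden dense layers, weight
decay 0.001 applied to weights (not biases), batch size 32. The five
augmentations (horizontal/vertical flip, rotations by 90/180/270) are
drawn uniformly — one per sample per epoch — together with identity;
all six are pixel permutations. The final-epoch model is kept (no early
stopping), matching the fixed-epoch protocol; per-epoch test metrics are
logged when a held-out set is supplied.

Desk-scale instances use `scale_factor`, which divides every channel
width (and the 4096-wide dense layers) while preserving the layer count,
pattern and partition — every structural claim is testable at scale 8 on
32–96 px inputs in seconds. Inputs are normalized per channel to mean
0.5 / std 0.5; initialization is seeded He-style. Pretrained weights can
be supplied from a file but are never required by any test. The conv and
pool kernels are compiled (Rcpp/RcppArmadillo, im2col + BLAS per sample);
everything else is base R matrix algebra.

**Optimization failure and restarts.** A 19-layer stack trained from
random initialization without normalization layers sometimes never leaves
chance level — under the fixed constant-lr protocol a substantial
fraction of seeds stall at miniature scale, and neither a larger learning
rate nor more epochs reliably rescues a stalled draw.
`train_network(..., max_restarts = k)` retrains with freshly drawn
weights and a derived seed whenever the final training accuracy falls
below `restart_threshold`. The `restart_scope` matters: when a schedule
freezes early blocks and the whole network started from random weights, a
degenerate draw in a frozen block starves every downstream attempt, so
from-scratch experiments restart with `restart_scope = "all"` (redraw
everything); `"trainable"` is for networks whose frozen blocks carry
pretrained weights worth keeping. This is deterministic multi-start over
the optimization randomness, not a change to the training protocol; the
comparative experiment of §7 does *not* use it, so its numbers reflect
the raw protocol.

## 6. Visual explanation

**Embeddings.** `pca_2d` projects mean-centred features onto the top-2
covariance eigenvectors, with each component's sign fixed so its
largest-magnitude loading is positive (signs are mathematically
arbitrary; fixing them makes plots reproducible). `kpca_2d`
eigendecomposes the double-centred kernel matrix and scales the top-2
eigenvectors by √λ, under which the linear kernel reproduces PCA exactly
(verified to 1e-6; PCA itself is verified against an eigendecomposition
oracle to 1e-8, and against an independent kernel-PCA implementation up
to each component's arbitrary scale and sign). Kernel defaults: γ = 1/p
for rbf and sigmoid, degree 3 / coefficient 1 for the polynomial. One
subtlety found while testing: as γ → 0 the *uncentred* rbf kernel
approaches the rank-one all-ones matrix, but the double-centred spectrum
shrinks proportionally to γ with a *constant* eigenvalue ratio (the limit
is classical metric scaling); the tests assert the true limit.
Embeddings are fitted per data subset (e.g., per magnification), matching
how the comparison is visualized.

**Grad-CAM.** For a target class, the pre-softmax class score is
backpropagated to the activations A_k of the last convolutional layer
(always the last conv of the whole network, regardless of the freeze
schedule); channel weights α_k are spatial means of those gradients; the
map `relu(Σ α_k A_k)` is bilinearly upsampled to the input size and
min-max normalized to [0, 1] (identically-zero maps stay zero). A
hand-built single-feature-map network has a closed form — heat
proportional to the rectified activation — which the implementation
matches to 1e-8. The localization experiment plants all nuclei of one
class in the top-left quadrant against a nucleus-free contrast class:
with 96-px inputs (3×3 final feature maps), fine-tuning from B3 for 40
epochs on 175 images, the planted quadrant receives the highest mean heat
on 50/50 held-out signal images. Input size matters here: at 32 px the
final conv layer is 2×2 with near-global receptive fields and the dense
head can encode the class in any cell, so no faithful attribution method
can localize — a structural limit, not an implementation one.

## 7. The desk-scale comparison, and what it can show

`run_experiment()` orchestrates generate → (normalize) → features + CML
arms → DL arms → report, with per-arm error isolation, stage skipping on
re-run with an unchanged configuration, and a master seed fanned out to
per-stage seeds. `select_best()` picks the arm with maximum accuracy,
breaking ties by higher macro recall — in diagnostic use a false negative
is costlier than a false positive, so between equally accurate models the
more sensitive one is preferred — then lexicographically.

The comparative experiment in the acceptance tests uses the synthetic
benign/malignant set (n = 400 at 32 px), the scale-8 network, 15 epochs
and 3 seeds against all five classical arms under 10-fold CV. Two
qualitative findings reproduce at desk scale: deeper fine-tuning beats
head-only training from random initialization (≈ 97% vs ≈ 61% mean test
accuracy — with random frozen convolutions the head sees uninformative
features), and the deep arm comes close to the classical ceiling. The
second comparison has a structural caveat stated honestly: the generator
contract makes the binary task so separable that every classical arm
reaches 100.0% CV accuracy, so "deep ≥ best classical" would require
literally perfect test classification from ~135 SGD updates from scratch
— the measured deep arm reaches ≈ 97.5% mean. At full scale the deep
arm's advantage rests on ImageNet pretraining and long training, neither
of which desk scale reproduces; the package reports the comparison as
measured rather than tuning the generator after the fact to manufacture
the inequality.

## 8. Problem sizes and runtimes

Chosen so the full suite runs comfortably on one CPU: module tests use
patches of 32–96 px and datasets of 24–400 images; the comparative
experiment trains 6 miniature networks (≈ 10 s each); the localization
experiment trains one 96-px network (≈ 2 min) and evaluates 50 heatmaps;
`scripts/acceptance.R` completes in ≈ 4–7 minutes (depending on restarts),
and the full test suite in ≈ 5 minutes.

## 9. Known limitations

- The generator's realism limits (§1): results demonstrate mechanism, not
  clinical accuracy.
- Stain separation assumes exactly two stains and benefits from pixels
  near each pure-stain ray; heavily mixed or necrotic tissue would weaken
  identifiability.
- From-scratch training of the full-depth architecture is fragile at
  miniature scale (§5); restarts mitigate but the comparative numbers
  keep the raw protocol.
- Grad-CAM localization requires final conv maps with usable spatial
  resolution (§6).
- The AdaBoost weak learner is an `rpart` stump with the default split
  search; exotic tie-breaks inside `rpart` are not replicated from any
  particular reference implementation.
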