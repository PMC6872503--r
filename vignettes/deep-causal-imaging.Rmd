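---
title: "From voxels to causes: classification, occlusion relevance, and CGAN causal discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voxels to causes: classification, occlusion relevance, and CGAN causal discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neurocausal` implements an interpretable deep-learning pipeline for
case/control neuroimaging studies — the motivating application is Alzheimer's
disease (AD) classification from registered diffusion tensor images — and
carries the analysis past classification into *where* the discriminative
signal lives and *whether* those image regions stand in a causal relationship
to disease and to genetic variation. This vignette is the package's own
account of the methods, their assumptions, the defaults, and what the
synthetic-data tests do and do not establish.

## The pipeline at a glance

1. **Classification.** A VGG-style 3D convolutional network with global
   average pooling (GAP) maps a whole-brain volume to a case probability.
2. **Relevance.** Occlusion (prediction-difference) analysis slides a small
   patch over the volume, replaces its contents with draws from a
   multivariate normal estimated from training images, and scores each
   window by the log-odds change in the case probability. Top-decile voxels
   form connected regions of interest (ROIs).
3. **Summaries.** Each ROI's voxel intensities — and, on the genetics side,
   each gene's positional genotype profile — are reduced to functional
   principal component (FPC) scores.
4. **Causal screening.** For each (ROI, outcome) or (gene, ROI) pair, a
   conditional GAN (CGAN) is fitted in both candidate directions and the two
   fits are compared by K-nearest-neighbour classifier two-sample tests
   (C2ST); the accuracy difference is tested against its asymptotic normal
   null and screened with Bonferroni correction.

## The classifier

The default architecture follows the published schedule: five convolutional
layers with cubic filters of size 11, 5, 3, 3, 3 and strides 4, 1, 1, 1, 1,
a 2×2×2 max pool after each convolution, GAP, and a two-node softmax.
Channel counts are not part of the published schedule; the defaults are
16/32/64/64/64 and configurable. Two published descriptions of the head
disagree (a GAP-plus-softmax figure versus "three fully connected layers" in
the text); the GAP form is the default because GAP is what supports the
regularisation-and-localisation argument, and `hidden_fc` restores the
fully connected variant.

Convolutions are zero-padded ("same", the VGG convention) and pools use
ceil-mode partial windows; with valid padding the native 91×109×91 grid
exhausts the five-pool schedule before GAP, so padding is the only reading
under which the published layer table processes the published grid. With
`padding = "valid"` an undersized input raises an error naming the offending
layer.

Training is mini-batch Adam on the softmax cross-entropy. The study does not
print optimiser settings; defaults are learning rate `1e-4`, 30 epochs,
batch 8, recorded in the training log so any deviation from unstated
settings is visible. The implementation is deliberately dependency-free
(Rcpp kernels for the convolution and pooling passes): no R deep-learning
backend is assumed, training is single-threaded and bit-reproducible under a
fixed seed, and backpropagation is verified against numerical gradients in
the test suite.

Augmentation mirrors the published scheme: Gaussian blurs with kernel sizes
3, 5, 7 and spreads 0.7, 0.7, 0.6 (implemented as separable 3D kernels with
border renormalisation); ±1-voxel translations along each axis (zero-filled,
mimicking registration jitter); then a left-right flip of *every* image.
Composition order is pinned — flips apply after blurs and translations — so
one original yields 2 × (1 + 3 + 6) = 20 images, and minority-class
duplication then balances the classes. On a 51-case / 100-control cohort
this produces 4000/151 ≈ 26.5 times the input count, consistent with the
published "over 20 times" figure. Cross-validation applies augmentation
inside each training fold only; augmented copies inherit their source
subject id, and the suite asserts that no derived image of a held-out
subject enters training.

Evaluation reports accuracy, sensitivity and specificity with the case
class positive, and the rank-statistic (Mann–Whitney) AUC on the predicted
case probability; metrics whose denominator class is absent are reported as
missing rather than zero.

## Occlusion relevance

For a window at location $w$, with $p_0$ the case probability of the intact
image and $p_1$ the mean case probability over `n_draws` occluded copies,
the relevance score is the log-odds difference

$$d = \log\frac{p_0/(1-p_0)}{p_1/(1-p_1)},$$

positive where the window's contents carried evidence *for* the case class.
Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ first, since softmax
saturation is routine on confident models. The replacement distribution at
each location is a multivariate normal with the marginal mean and covariance
of that patch across training volumes — the simplest faithful reading of
"sampled from multivariate normal distributions"; conditional (surround-aware)
replacement is deliberately out of scope. Scores are accumulated into every
voxel of the window, overlapping windows are averaged by coverage count, and
per-subject maps are averaged over subjects. Draws are seeded per window
location, which makes the map independent of subject order and lets a
per-window brute-force loop reproduce it exactly (an oracle the tests
exploit). Defaults: 3×3×3 patch, `n_draws = 10`, stride 1.

ROI extraction keeps voxels at or above the chosen percentile of the map
(default 90, i.e. the top decile; boundary ties are all retained — a
constant map therefore returns an empty set with a warning rather than the
whole volume), labels connected components (26-connectivity by default) and
orders them by size. The published count of 23 regions is a data outcome,
never an input.

## FPC summaries

Region summaries treat the subjects × voxels matrix (columns in
lexicographic voxel order) as discretised functional data: columns are
centred, an optional 3D Gaussian pre-smoothing can be applied within the
ROI's bounding box (off by default — planted-signal tests showed no need),
and the leading eigenvectors of the sample covariance are taken via SVD.
Gene summaries rescale SNP positions to $[0,1]$, project each subject's
genotype profile onto a B-spline basis (df = min(#SNPs, 8), ridge-stabilised),
and decompose the smoothed profiles; single-SNP genes bypass the
decomposition and return the centred genotype. One published passage calls
the region summaries "2D" and another "three-dimensional"; the package
treats all region summaries uniformly as FPCA on the ROI voxel matrix.

Component count defaults to the smallest number explaining 80% of variance,
capped at 5. Eigenvector signs are fixed by making each component's
largest-magnitude loading positive, so scores are deterministic. The suite
checks the decomposition against dense eigendecompositions, planted
two-component spectra, and latent-structure genotype simulations.

## CGAN causal discovery

For a candidate direction $X \to Y$ the generator approximates
$Y = f_Y(X, N_Y)$ with noise independent of the cause. The default generator
is **restricted to the additive-noise form** $\hat y = g(x) + h(z)$ — an MLP
on the cause plus a learnable linear map of the Gaussian noise vector. This
is a deliberate design decision: an unrestricted conditional generator can
represent *any* conditional distribution, including the anticausal one, so
in the large-capacity limit both directions fit equally well and the
direction signal vanishes; experiments during development confirmed exactly
that. The additive restriction is the model class whose asymmetry the
additive-noise framework actually licenses. `generator_form = "general"`
remains available. Both networks train with Adam ($\beta_1 = 0.5$, the
standard GAN setting), non-saturating generator loss, and a retry-once rule
on divergence.

The two-sample comparison classifies the real pairs $(x_i, y_i)$ against the
generated pairs $(x_i, \hat y_i)$ (coordinates jointly standardised), with a
KNN classifier ($K = \lfloor\sqrt{n_\text{train}}\rfloor$ by default) on a
50/50 subject-level split shared by both directions; the held-out accuracy
is $t^{X\to Y}$, and symmetrically $t^{Y\to X}$. The published procedure
nominally lists only the effect values in this comparison, but it defines
the generated dataset as the pair set, and only the joint comparison carries
the additive-noise asymmetry — the package follows the joint reading
(`features = "marginal"` implements the literal one). The statistic

$$T = t^{X\to Y} - t^{Y\to X}, \qquad
  \sigma^2 = \tfrac{0.5}{n_\text{test}} - 2\,\mathrm{cov}(t^{X\to Y}, t^{Y\to X})$$

is referred to $N(0, \sigma^2)$; $n_\text{test}$ is the number of held-out
subjects, as published. The covariance is not given an estimator in the
publication; here it is the sample covariance of the two accuracies over 20
repeated random splits of the *same* fitted generators (refitting per split
is not desk-scale, and splits dominate the shared noise), and $\sigma^2$ is
floored at $0.1/n_\text{test}$ to guard against noisy covariance estimates.
The reported $t$ statistics come from the first split (split-averaged
variants are also returned). A significantly negative $T$ — the $X \to Y$
generator fools the classifier better — calls $X \to Y$; the publication
never states the sign convention, so this one is documented and pinned by an
exact antisymmetry test: swapping the arguments flips $T$ bit-exactly,
because both direction fits share one seed and the splits are shared.

Bonferroni screening divides the family-wise level by the number of tests
(0.05/23 → 0.0022 for the ROI screen; 0.05/61 → 0.00082 for the candidate
genes), and sub-resolution table entries like "<0.00005" are treated as
intervals: significant at any threshold at or above the bound, not
significant below it. Gene–region association (distinct from causation) is
measured by the first canonical correlation between the two FPC score sets
with a subject-permutation null.

## The synthetic-data module

No public accession exists for the study's images or genotypes, so the
package generates what the pipeline needs, with ground truth:

* **Volumes** — Gaussian background noise, optionally smoothed (default
  simulations use `smoothness_sigma = 1` voxel) to mimic the spatial
  correlation of registered diffusion images — occlusion analysis is only
  meaningful on spatially correlated inputs — then rescaled to `noise_sd`
  and, for cases, shifted by `effect_size` inside planted axis-aligned
  boxes. The test cohorts mirror the study's 51/100 class imbalance where
  the claim under test concerns cohort structure.
* **Genotypes** — per-SNP minor-allele frequencies drawn uniformly from
  `maf_range`, Hardy–Weinberg genotypes, independent SNPs (no linkage
  disequilibrium: no pipeline stage depends on it).
* **Cause–effect pairs** — additive-noise mechanisms restricted to three
  named forms (`linear`, `quadratic`, `sigmoid`: $u$, $u^2$, $\tanh 2u$)
  with standard-normal causes, so direction-recovery experiments are
  reproducible.

Everything is a pure function of (spec, seed); regeneration is bit-identical.

What these simulations do **not** capture: anatomy, tract structure,
registration artefacts, intensity non-stationarity, linkage disequilibrium,
or realistic genetic architectures. Passing tests demonstrate that the
algorithms recover planted structure under their own assumptions at desk
scale — not that the published biological findings replicate.

## Problem sizes, numerical choices, defaults

The test suite and the examples run on one CPU core; sizes were chosen as
the smallest that leave the tested signals comfortably above their noise
floors:

* classifier tests use 32³ (and smaller) grids with a two-layer
  configuration (`conv_specs = list(c(5,2,2,8), c(3,1,1,16))`), learning
  rate `3e-3`, 15 epochs — a strong planted signal separates perfectly;
* planted-region recovery runs ten seeded 32³ cohorts (10 cases / 10
  controls, 12³ signal box), relevance stride 3 with 2 draws, and asks for
  Dice ≥ 0.3 between the top-decile mask and the true box in at least 8.
  The map is evaluated on case subjects: a positive score marks evidence
  *for* a subject's case classification, so for controls the planted region
  carries negative relevance and a mixed-subject average partially cancels —
  which experiments showed clearly;
* causal power uses 20 quadratic pairs ($n = 500$, noise sd 0.3 — "strong"
  in the sense that the mechanism dominates the noise), CGAN width 16,
  noise dimension 2, 800 epochs; null calibration uses 100 independent
  pairs at 150 epochs, where fit quality matters less;
* the C2ST calibration check runs 200 replicates at $n = 500$.

Other numerical choices worth knowing: the relevance map computes log-odds
directly from the network's output logits and averages occluded copies on
the log-odds scale — algebraically the same score, but it survives softmax
saturation, which on confident models pushes probabilities within
double-precision distance of 1 and silently flattens probability-space maps;
probabilities clipped before log-odds in the probability-facing scorer; percentile thresholds computed with R's default quantile
definition and boundary ties retained; covariance matrices for patch
replacement factorised by symmetric eigendecomposition with negative
eigenvalues clipped at zero (sampling degenerate normals is legitimate);
B-spline projections ridge-stabilised at `1e-10`; 0-based, half-open voxel
coordinates everywhere on the R side of file formats.

## Known limitations

* The CNN and CGAN are plain single-threaded implementations; they are
  meant for method-level validation and modest grids, not GPU-scale imaging
  studies.
* The causal test's null variance follows the published formula; its
  covariance estimator (and hence the test's exact level) is a
  reconstruction, and the type-I error band asserted in the tests
  (1%–10% at nominal 5%) reflects that uncertainty honestly.
* Direction identification rests on the additive-noise restriction; with
  `generator_form = "general"` the test degenerates by design, and
  linear-Gaussian pairs are unidentifiable in principle.
* Cross-timepoint designs (train at baseline, predict at a later visit) are
  supported by evaluating a trained model on another cohort, with both
  subject-disjoint and subject-shared evaluation possible; the original
  study does not state which it used.
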