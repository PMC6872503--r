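# neurocausal

Interpretable deep-learning analysis for case/control neuroimaging-genetics
studies, built for the Alzheimer's-disease setting: classify registered 3D
brain volumes with a VGG-style convolutional network, locate the image
regions the classifier relies on by occlusion (prediction-difference)
analysis, summarise regions and genes by functional principal component
(FPC) scores, and screen region–disease and gene–region pairs for *causal*
(not merely associative) relationships with conditional-GAN fits compared by
classifier two-sample tests.

Who it is for: methodologists and imaging-genetics analysts who want the
full pipeline — classification, relevance mapping, dimension reduction,
bivariate causal screening — as composable, tested R functions that run at
desk scale, with a synthetic-data module providing ground-truthed inputs.

## The methods in brief

**Classifier.** A 3D CNN with five convolutional layers (cubic filters
11, 5, 3, 3, 3; strides 4, 1, 1, 1, 1), a 2×2×2 max pool after each, global
average pooling, and a two-node softmax. Augmentation: Gaussian blurs
(kernels 3/5/7, spreads 0.7/0.7/0.6), ±1-voxel translations per axis, a
left–right flip of every image (20 images per original), then random
minority-class duplication to balance — ≈26.5× a 51/100 cohort.

**Relevance.** Each 3×3×3 window is replaced by draws from a multivariate
normal estimated at that location from training volumes; the window's score
is the log-odds difference

d = log[ (p₀/(1−p₀)) / (p₁/(1−p₁)) ],

with p₀ the case probability of the intact image and p₁ the mean over
occluded copies. Scores accumulate into a whole-image relevance matrix W;
voxels in the top decile of W form connected ROIs.

**Causal screening.** For variables X, Y (FPC scores of an ROI, disease
status, or gene FPC scores), fit conditional GANs X→Y and Y→X restricted to
the additive-noise form ŷ = g(x) + h(z), classify real pairs against
generated pairs with a KNN classifier two-sample test in each direction, and
test T = t^{X→Y} − t^{Y→X} against N(0, σ²), σ² = 0.5/n_test −
2·cov(t^{X→Y}, t^{Y→X}). Significantly negative T calls X→Y. Screening uses
Bonferroni thresholds (e.g. 0.05/23 → 0.0022, 0.05/61 → 0.00082).

## Worked example

```r
library(neurocausal)

spec <- image_cohort_spec(grid_shape = c(32, 32, 32),
                          n_cases = 15, n_controls = 15,
                          signal_regions = list(rbind(c(8, 8, 8), c(20, 20, 20))),
                          effect_size = 5, noise_sd = 1,
                          smoothness_sigma = 1, seed = 7)
cohort <- generate_image_cohort(spec)

arch <- architecture_config(conv_specs = list(c(5, 2, 2, 8), c(3, 1, 1, 16)),
                            n_maxpool = 2)
model <- build_classifier(arch, spec$grid_shape, seed = 3)
model <- train_classifier(model, cohort$volumes, cohort$labels,
                          list(lr = 3e-3, epochs = 15, batch_size = 8), seed = 4)
evaluate(model, cohort$volumes, cohort$labels)
#> accuracy 1.0000 | sensitivity 1.0000 | specificity 1.0000 | AUC 1.0000

sampler <- patch_sampler(cohort$volumes, n_draws = 2)
map <- compute_relevance_map(model, cohort$volumes[c(1, 2, 16, 17)],
                             sampler, stride = 3, seed = 5)
rois <- select_top_regions(map, percentile = 90)
head(rois$rois[, 1:5], 3)
#>   roi_index size centroid_x centroid_y centroid_z
#> 1         1 2916   12.91667   13.22222   16.63889
#> 2         2   81    5.00000   21.00000   28.00000
#> 3         3   54   28.00000   26.50000   14.50000
dice_overlap(rois$labels > 0, cohort$truth$signal_mask)
#> [1] 0.41

scores <- fpca_region(region_signal_matrix(cohort$volumes, rois, 1))
causal_test(scores$scores[, 1], as.numeric(cohort$labels),
            cgan_config(epochs = 150, batch_size = 30, noise_dim = 2,
                        gen_hidden = c(16, 16), disc_hidden = c(16, 16)),
            n_covariance_splits = 10, seed = 6)
#> t_xy = 0.7667, t_yx = 0.7667, T = +0.0000, sigma2 = 2.63e-02, p = 1 -> inconclusive

bonferroni_threshold(0.05, nrow(rois$rois))
#> [1] 0.004545455
```

Reading the output: the trained network separates the planted cohort
perfectly; the largest top-decile ROI (2916 voxels, centroid ≈ (13, 13, 17))
overlaps the planted 12³ signal box with Dice 0.41; at n = 30 subjects the
region–status causal test is — correctly — inconclusive (direction calls need
the larger samples used in the test suite, where 500-sample quadratic pairs
orient correctly in ≥ 70% of runs).

The bundled ROI screening example reproduces published filtering arithmetic:

```r
scr <- screen_results(roi_ad_screen_table(), bonferroni_threshold(0.05, 23))
scr$counts
#> baseline      m06      m12      m24
#>        1        1        2        4
```

`run_pipeline()` chains synth → train → relevance → fpca → causal → screen
with per-stage derived seeds and a hash manifest; `inst/cli/neurocausal.R`
is a thin command-line front end over the same functions
(`Rscript inst/cli/neurocausal.R run --config cfg.yaml --seed 1 --out out/`).

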