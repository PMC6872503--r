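## Bivariate causal discovery under additive-noise asymmetry: fit a
## conditional GAN in each direction, compare each direction's synthetic
## effect sample against the real one with a K-nearest-neighbour classifier
## two-sample test (C2ST), and test the accuracy difference
## T = t_xy - t_yx against its asymptotic normal null
## sigma^2 = 0.5 / n_test - 2 cov(t_xy, t_yx).

#' Conditional GAN configuration
#'
#' The generator maps (cause, noise vector) to a synthetic effect; the
#' discriminator scores (cause, effect) pairs. Sizes default to a deliberately
#' small network — the conditional distributions being modelled are
#' one-dimensional.
#'
#' @param gen_hidden,disc_hidden Hidden-layer widths.
#' @param noise_dim Noise input dimension of the generator.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate (both networks).
#' @param generator_form `"additive"` (default) restricts the generator to
#'   the additive-noise form `effect = g(cause) + h(noise)` — the model class
#'   whose directional asymmetry the causal test exploits; `"general"` lets
#'   cause and noise mix freely, which can represent any conditional
#'   distribution (including the anticausal one) and therefore weakens
#'   direction identification.
#' @param seed Default seed used by [fit_cgan()] when none is supplied.
#' @return An object of class `cgan_config`.
#' @export
cgan_config <- function(gen_hidden = c(32, 32), disc_hidden = c(32, 32),
                        noise_dim = 5L, epochs = 500L, batch_size = 64L,
                        lr = 1e-3, generator_form = c("additive", "general"),
                        seed = 1L) {
  generator_form <- match.arg(generator_form)
  for (f in c("noise_dim", "epochs", "batch_size"))
    assign(f, check_count(get(f), f))
  if (any(gen_hidden < 1) || any(disc_hidden < 1))
    stop_field("gen_hidden", "layer widths must be positive")
  lr <- check_number(lr, "lr", lower = 0, strict_lower = TRUE)
  structure(list(gen_hidden = as.integer(gen_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 noise_dim = noise_dim, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 generator_form = generator_form,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cgan_config")
}

## Generator forward/backward for both forms. For "additive" the effect is
## g(cause) + h(noise) with separate subnetworks; for "general" a single MLP
## sees (cause, noise) jointly.
gen_new <- function(cfg) {
  if (cfg$generator_form == "additive")
    list(form = "additive",
         gx = mlp_new(c(1L, cfg$gen_hidden, 1L), "relu", "linear"),
         ## linear noise path: a learnable linear map of the Gaussian noise
         ## vector, i.e. additive Gaussian noise with trainable scale
         gz = mlp_new(c(cfg$noise_dim, 1L), "relu", "linear"))
  else
    list(form = "general",
         g = mlp_new(c(1L + cfg$noise_dim, cfg$gen_hidden, 1L), "relu", "linear"))
}

gen_fwd <- function(G, xb, z, cache = FALSE) {
  if (G$form == "additive") {
    fx <- mlp_fwd(G$gx, cbind(xb), cache = cache)
    fz <- mlp_fwd(G$gz, z, cache = cache)
    if (cache) list(out = fx$out + fz$out, fx = fx, fz = fz)
    else fx + fz
  } else {
    mlp_fwd(G$g, cbind(xb, z), cache = cache)
  }
}

## Returns per-subnet grads; dOut is the gradient at the generated effect.
gen_bwd <- function(G, fw, dOut) {
  if (G$form == "additive")
    list(gx = mlp_bwd(G$gx, fw$fx, dOut), gz = mlp_bwd(G$gz, fw$fz, dOut))
  else
    list(g = mlp_bwd(G$g, fw, dOut))
}

gen_params_finite <- function(G) {
  nets <- if (G$form == "additive") list(G$gx, G$gz) else list(G$g)
  all(vapply(nets, function(nn)
    all(vapply(nn$W, function(w) all(is.finite(w)), logical(1))), logical(1)))
}

cgan_train_once <- function(xs, ys, cfg, seed) {
  n <- length(xs)
  withr::with_seed(seed, {
    G <- gen_new(cfg)
    ## D emits a logit; sigmoid and the cross-entropy gradient are applied
    ## here so the backward pass stays numerically simple.
    D <- mlp_new(c(2L, cfg$disc_hidden, 1L), "lrelu", "linear")
    sD <- adam_new(D)
    sG <- lapply(G[-1], adam_new)
    t_step <- 0L
    d_loss <- g_loss <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      dl <- gl <- 0; nb <- 0L
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, n)]
        m <- length(bi)
        xb <- xs[bi]; yb <- ys[bi]
        z <- matrix(rnorm(m * cfg$noise_dim), m)
        gfw <- gen_fwd(G, xb, z, cache = TRUE)
        yfake <- as.numeric(gfw$out)
        ## Discriminator step: real pairs labelled 1, generated 0.
        Xd <- rbind(cbind(xb, yb), cbind(xb, yfake))
        lab <- c(rep(1, m), rep(0, m))
        dfw <- mlp_fwd(D, Xd, cache = TRUE)
        p <- 1 / (1 + exp(-as.numeric(dfw$out)))
        dl <- dl - mean(log(pmax(ifelse(lab == 1, p, 1 - p), 1e-12)))
        dgr <- mlp_bwd(D, dfw, matrix((p - lab) / (2 * m), ncol = 1))
        t_step <- t_step + 1L
        up <- adam_step(D, dgr, sD, cfg$lr, t_step, beta1 = 0.5)
        D <- up$net; sD <- up$state
        ## Generator step (non-saturating): push D(x, G(x, z)) toward 1.
        dfw2 <- mlp_fwd(D, cbind(xb, yfake), cache = TRUE)
        p2 <- 1 / (1 + exp(-as.numeric(dfw2$out)))
        gl <- gl - mean(log(pmax(p2, 1e-12)))
        dgr2 <- mlp_bwd(D, dfw2, matrix((p2 - 1) / m, ncol = 1))
        ggr <- gen_bwd(G, gfw, dgr2$dX[, 2, drop = FALSE])
        for (nm in names(ggr)) {
          up <- adam_step(G[[nm]], ggr[[nm]], sG[[nm]], cfg$lr, t_step,
                          beta1 = 0.5)
          G[[nm]] <- up$net; sG[[nm]] <- up$state
        }
        nb <- nb + 1L
      }
      d_loss[ep] <- dl / nb; g_loss[ep] <- gl / nb
    }
  })
  list(G = G, D = D, d_loss = d_loss, g_loss = g_loss)
}

#' Fit a conditional GAN for one causal direction
#'
#' Trains a generator approximating `effect = f(cause, noise)` with noise
#' independent of the cause, then pairs every observed cause with one
#' generated synthetic effect. Cause and effect are standardised internally;
#' generated effects are returned on the original scale. A run whose
#' parameters diverge to non-finite values is retried once from a derived
#' seed before erroring.
#'
#' @param cause,effect Equal-length finite numeric vectors (n >= 20).
#' @param cfg A [cgan_config()].
#' @param direction Label recorded on the fit (`"x_to_y"` when `cause` is X).
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return Object of class `direction_fit`: `direction`, `generated`
#'   (data.frame `cause`, `effect_hat`, same row count as the input),
#'   `generator` (weights and scaling), `diagnostics` (loss traces).
#' @export
fit_cgan <- function(cause, effect, cfg = cgan_config(),
                     direction = c("x_to_y", "y_to_x"), seed = NULL) {
  direction <- match.arg(direction)
  if (length(cause) != length(effect))
    stop_field("cause", "cause and effect must have equal length")
  if (length(cause) < 20) stop_field("cause", "need n >= 20")
  if (any(!is.finite(cause)) || any(!is.finite(effect)))
    stop_field("cause", "inputs must be finite")
  if (sd(cause) == 0 && sd(effect) == 0)
    stop_field("cause", "degenerate input: both variables are constant")
  if (is.null(seed)) seed <- cfg$seed
  mu_x <- mean(cause); sd_x <- if (sd(cause) > 0) sd(cause) else 1
  mu_y <- mean(effect); sd_y <- if (sd(effect) > 0) sd(effect) else 1
  xs <- (cause - mu_x) / sd_x; ys <- (effect - mu_y) / sd_y
  fit <- cgan_train_once(xs, ys, cfg, seed)
  if (!gen_params_finite(fit$G)) {
    fit <- cgan_train_once(xs, ys, cfg, derive_seed(seed, "cgan-retry"))
    if (!gen_params_finite(fit$G))
      stop("CGAN training diverged twice; adjust cgan_config()", call. = FALSE)
  }
  z <- withr::with_seed(derive_seed(seed, "cgan-gen"),
                        matrix(rnorm(length(xs) * cfg$noise_dim), length(xs)))
  yhat <- as.numeric(gen_fwd(fit$G, xs, z)) * sd_y + mu_y
  structure(list(direction = direction,
                 generated = data.frame(cause = cause, effect_hat = yhat),
                 generator = list(net = fit$G, mu_x = mu_x, sd_x = sd_x,
                                  mu_y = mu_y, sd_y = sd_y,
                                  noise_dim = cfg$noise_dim),
                 diagnostics = list(d_loss = fit$d_loss, g_loss = fit$g_loss,
                                    seed = seed)),
            class = "direction_fit")
}

#' K-nearest-neighbour classifier two-sample test
#'
#' Pools two samples with labels 0 (`real`) and 1 (`synthetic`), splits into
#' train/test halves with equal label counts per split, and reports the
#' held-out KNN accuracy `t`. Under the null of equal distributions the
#' accuracy is centred at 0.5.
#'
#' @param real,synthetic Numeric vectors or matrices (points in rows, same
#'   number of columns).
#' @param K Neighbour count; default `floor(sqrt(train size))`.
#' @param split_fraction Fraction of each sample used for training.
#' @param seed Integer seed (split and KNN tie-breaking).
#' @param split_train Optional 1-based row indices (shared by both samples,
#'   which must then have equal row counts) forming the training half; used
#'   by [causal_test()] to split subjects rather than points.
#' @return Object of class `c2st_result`: `t` (accuracy), `n_test` (held-out
#'   points), `K`, `seed`.
#' @export
knn_c2st <- function(real, synthetic, K = NULL, split_fraction = 0.5,
                     seed = 1L, split_train = NULL) {
  Xr <- as.matrix(real); Xs <- as.matrix(synthetic)
  if (nrow(Xr) == 0 || nrow(Xs) == 0)
    stop_field("real", "both samples must be non-empty")
  if (ncol(Xr) != ncol(Xs))
    stop_field("synthetic", "samples must have the same dimensionality")
  if (is.null(split_train)) {
    tr_r <- withr::with_seed(derive_seed(seed, "c2st-r"),
                             sample(nrow(Xr), floor(nrow(Xr) * split_fraction)))
    tr_s <- withr::with_seed(derive_seed(seed, "c2st-s"),
                             sample(nrow(Xs), floor(nrow(Xs) * split_fraction)))
  } else {
    if (nrow(Xr) != nrow(Xs))
      stop_field("split_train", "shared splits need equal sample sizes")
    tr_r <- tr_s <- split_train
  }
  train <- rbind(Xr[tr_r, , drop = FALSE], Xs[tr_s, , drop = FALSE])
  test <- rbind(Xr[-tr_r, , drop = FALSE], Xs[-tr_s, , drop = FALSE])
  ytrain <- factor(c(rep(0L, length(tr_r)), rep(1L, length(tr_s))), levels = 0:1)
  ytest <- c(rep(0L, nrow(Xr) - length(tr_r)), rep(1L, nrow(Xs) - length(tr_s)))
  if (is.null(K)) K <- max(1L, floor(sqrt(nrow(train))))
  if (K >= nrow(train))
    stop_field("K", "must be smaller than the training size")
  pred <- withr::with_seed(derive_seed(seed, "c2st-knn"),
                           class::knn(train, test, ytrain, k = K))
  structure(list(t = mean(as.integer(as.character(pred)) == ytest),
                 n_test = nrow(test), K = as.integer(K), seed = seed),
            class = "c2st_result")
}

#' CGAN + C2ST bivariate causal test
#'
#' Fits conditional GANs in both directions (both from the same seed, so the
#' procedure is exactly antisymmetric in its arguments), then classifies real
#' effect values against generated ones in each direction with the KNN C2ST
#' over shared subject-level train/test splits. The reported statistics use
#' the first split; the covariance entering the null variance
#' `sigma^2 = 0.5/n_test - 2 cov(t_xy, t_yx)` is estimated over
#' `n_covariance_splits` further random splits of the same fitted generators,
#' and `sigma^2` is floored at `0.1/n_test`. A significantly negative
#' `T = t_xy - t_yx` (the x->y generator fools the classifier better) calls
#' `x_to_y`; significantly positive calls `y_to_x`; otherwise the result is
#' inconclusive.
#'
#' @param x,y Equal-length finite numeric vectors (n >= 20).
#' @param cfg A [cgan_config()].
#' @param n_covariance_splits Splits used for the covariance estimate.
#' @param seed Integer seed.
#' @param alpha Two-sided significance level for the direction call.
#' @param K Neighbour count passed to the C2ST (default sqrt rule).
#' @param features `"joint"` (default) classifies the generated pair dataset
#'   `(x, y-hat)` against the real pairs `(x, y)` — the comparison that
#'   carries the additive-noise asymmetry; `"marginal"` classifies generated
#'   effect values against real ones alone.
#' @return Object of class `causal_test_result`: `t_xy`, `t_yx`, `T`,
#'   `sigma2`, `z`, `p_value`, `call`, plus split-averaged accuracies
#'   (`t_xy_avg`, `t_yx_avg`), `n_test` and `K`.
#' @export
causal_test <- function(x, y, cfg = cgan_config(), n_covariance_splits = 20L,
                        seed = 1L, alpha = 0.05, K = NULL,
                        features = c("joint", "marginal")) {
  features <- match.arg(features)
  n_covariance_splits <- check_count(n_covariance_splits, "n_covariance_splits",
                                     min = 2L)
  n <- length(x)
  s_fit <- derive_seed(seed, "cgan")
  fit_xy <- fit_cgan(x, y, cfg, direction = "x_to_y", seed = s_fit)
  fit_yx <- fit_cgan(y, x, cfg, direction = "y_to_x", seed = s_fit)
  yhat <- fit_xy$generated$effect_hat
  xhat <- fit_yx$generated$effect_hat
  ## Put both coordinates on a common scale so the KNN metric treats them
  ## symmetrically (the same transform serves both directions).
  sx <- if (sd(x) > 0) sd(x) else 1; sy <- if (sd(y) > 0) sd(y) else 1
  if (features == "joint") {
    real_xy <- cbind(x / sx, y / sy); synth_xy <- cbind(x / sx, yhat / sy)
    real_yx <- real_xy;               synth_yx <- cbind(xhat / sx, y / sy)
  } else {
    real_xy <- cbind(y / sy); synth_xy <- cbind(yhat / sy)
    real_yx <- cbind(x / sx); synth_yx <- cbind(xhat / sx)
  }
  n_train <- floor(n / 2); n_test <- n - n_train
  t_xy <- t_yx <- numeric(1L + n_covariance_splits)
  for (s in seq_len(1L + n_covariance_splits)) {
    idx <- withr::with_seed(derive_seed(seed, paste0("split", s)),
                            sample(n, n_train))
    t_xy[s] <- knn_c2st(real_xy, synth_xy, K = K,
                        seed = derive_seed(seed, paste0("kxy", s)),
                        split_train = idx)$t
    t_yx[s] <- knn_c2st(real_yx, synth_yx, K = K,
                        seed = derive_seed(seed, paste0("kxy", s)),
                        split_train = idx)$t
  }
  cov_hat <- cov(t_xy[-1], t_yx[-1])
  sigma2 <- max(0.5 / n_test - 2 * cov_hat, 0.1 / n_test)
  T_stat <- t_xy[1] - t_yx[1]
  z <- T_stat / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  call <- if (p < alpha && T_stat < 0) "x_to_y"
          else if (p < alpha && T_stat > 0) "y_to_x"
          else "inconclusive"
  Ktr <- if (is.null(K)) max(1L, floor(sqrt(2 * n_train))) else as.integer(K)
  structure(list(t_xy = t_xy[1], t_yx = t_yx[1], T = T_stat,
                 t_xy_avg = mean(t_xy), t_yx_avg = mean(t_yx),
                 sigma2 = sigma2, z = z, p_value = p, call = call,
                 n_test = n_test, K = Ktr, cov_hat = cov_hat, seed = seed),
            class = "causal_test_result")
}

#' @export
print.causal_test_result <- function(x, ...) {
  cat(sprintf("t_xy = %.4f, t_yx = %.4f, T = %+.4f, sigma2 = %.2e, p = %.4g -> %s\n",
              x$t_xy, x$t_yx, x$T, x$sigma2, x$p_value, x$call))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  alpha <- check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop_field("alpha", "must lie in (0, 1)")
  m <- check_count(m, "m", min = 1L)
  alpha / m
}

## Parse a p-value entry that is either numeric or a "<bound" token.
parse_p_entry <- function(p, row) {
  if (is.numeric(p)) {
    if (is.na(p) || p < 0 || p > 1)
      stop(sprintf("row %d: p-value %s outside [0, 1]", row, format(p)),
           call. = FALSE)
    return(list(value = p, upper = FALSE))
  }
  p <- trimws(as.character(p))
  if (grepl("^<", p)) {
    v <- suppressWarnings(as.numeric(sub("^<", "", p)))
    if (is.na(v) || v < 0 || v > 1)
      stop(sprintf("row %d: malformed p-value token '%s'", row, p), call. = FALSE)
    return(list(value = v, upper = TRUE))
  }
  v <- suppressWarnings(as.numeric(p))
  if (is.na(v) || v < 0 || v > 1)
    stop(sprintf("row %d: malformed p-value token '%s'", row, p), call. = FALSE)
  list(value = v, upper = FALSE)
}

#' Screen causal-test results at a significance threshold
#'
#' Filters a results table to rows significant at the threshold and counts
#' them per timepoint. Interval entries like `"<0.00005"` are treated as
#' lying below any threshold at or above the stated bound (and as
#' non-significant below it).
#'
#' @param results Data frame with columns `timepoint` and `p_value` (numeric
#'   or `"<bound"` strings); other columns pass through.
#' @param threshold Significance threshold (e.g. a
#'   [bonferroni_threshold()]).
#' @return List of class `screen_result`: `significant` (filtered rows),
#'   `counts` (named per-timepoint counts over all timepoints present),
#'   `threshold`.
#' @export
screen_results <- function(results, threshold) {
  stopifnot(is.data.frame(results))
  if (!all(c("timepoint", "p_value") %in% names(results)))
    stop_field("results", "must contain columns 'timepoint' and 'p_value'")
  threshold <- check_number(threshold, "threshold", lower = 0, upper = 1)
  tp_levels <- unique(as.character(results$timepoint))
  sig <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    e <- parse_p_entry(results$p_value[i], i)
    sig[i] <- if (e$upper) e$value <= threshold else e$value < threshold
  }
  counts <- vapply(tp_levels, function(tp)
    sum(sig[as.character(results$timepoint) == tp]), integer(1))
  structure(list(significant = results[sig, , drop = FALSE],
                 counts = counts, threshold = threshold),
            class = "screen_result")
}

#' Permutation test of association between two FPC score sets
#'
#' Measures association as the first canonical correlation between the two
#' score matrices and assesses it against the permutation null obtained by
#' shuffling subjects of one set.
#'
#' @param gene_scores,region_scores `fpc_scores` objects or numeric matrices
#'   with matching row (subject) counts (>= 3).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `p_value` (in `[1/(n_permutations+1), 1]`), `statistic`
#'   (observed first canonical correlation) and `n_permutations`.
#' @export
association_test <- function(gene_scores, region_scores,
                             n_permutations = 999L, seed = 1L) {
  X <- if (inherits(gene_scores, "fpc_scores")) gene_scores$scores
       else as.matrix(gene_scores)
  Y <- if (inherits(region_scores, "fpc_scores")) region_scores$scores
       else as.matrix(region_scores)
  if (nrow(X) != nrow(Y)) stop_field("region_scores", "subject sets must match")
  if (nrow(X) < 3) stop_field("gene_scores", "need at least 3 subjects")
  n_permutations <- check_count(n_permutations, "n_permutations")
  first_cc <- function(a, b) cancor(a, b)$cor[1]
  obs <- first_cc(X, Y)
  perm <- withr::with_seed(seed, vapply(seq_len(n_permutations), function(i)
    first_cc(X, Y[sample(nrow(Y)), , drop = FALSE]), numeric(1)))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_permutations + 1)
  list(p_value = p, statistic = obs, n_permutations = n_permutations)
}
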