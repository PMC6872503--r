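## VGG-style 3D convolutional classifier with global average pooling.
## The network is built from scratch on Rcpp kernels: stacked 3D convolutions
## (ReLU), 2x2x2 max pools, a GAP layer collapsing each final feature channel
## to its spatial mean, optional fully connected hidden layers, and a softmax
## output. Training is plain Adam on the cross-entropy.

#' 3D CNN architecture configuration
#'
#' The default follows the VGG-GAP layout used for whole-brain diffusion
#' images: five convolutional layers with filter sizes 11, 5, 3, 3, 3 and
#' strides 4, 1, 1, 1, 1 (equal in-plane and through-plane), a 2x2x2 max pool
#' after each of the five convolutions, then global average pooling feeding a
#' two-node softmax. Channel counts are not part of the published schedule
#' and default to 16/32/64/64/64.
#'
#' @param conv_specs List of `c(filter_size, stride_xy, stride_z, channels)`.
#' @param n_maxpool Number of leading conv layers followed by a max pool.
#' @param gap Use global average pooling before the classifier head
#'   (`FALSE` flattens instead).
#' @param n_output Number of output classes (2 = control/case).
#' @param hidden_fc Integer widths of optional fully connected ReLU layers
#'   between GAP/flatten and the softmax (the "three fully connected layers"
#'   variant); empty for the pure GAP head.
#' @param padding `"same"` (zero padding, VGG convention; default) or
#'   `"valid"` (no padding; small inputs can exhaust the schedule).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(conv_specs = list(c(11, 4, 4, 16),
                                                  c(5, 1, 1, 32),
                                                  c(3, 1, 1, 64),
                                                  c(3, 1, 1, 64),
                                                  c(3, 1, 1, 64)),
                                n_maxpool = 5L, gap = TRUE, n_output = 2L,
                                hidden_fc = integer(0),
                                padding = c("same", "valid")) {
  padding <- match.arg(padding)
  for (cs in conv_specs)
    if (length(cs) != 4 || any(cs < 1))
      stop_field("conv_specs", "each entry must be c(filter_size, stride_xy, stride_z, channels)")
  n_maxpool <- check_count(n_maxpool, "n_maxpool", min = 0L)
  if (n_maxpool > length(conv_specs))
    stop_field("n_maxpool", "cannot exceed the number of conv layers")
  structure(list(conv_specs = lapply(conv_specs, as.integer),
                 n_maxpool = n_maxpool, gap = isTRUE(gap),
                 n_output = check_count(n_output, "n_output", min = 2L),
                 hidden_fc = as.integer(hidden_fc), padding = padding),
            class = "architecture_config")
}

conv_out_dim <- function(n, k, s, same) {
  if (same) ceiling(n / s) else floor((n - k) / s) + 1
}

#' Build an untrained 3D CNN classifier
#'
#' Lays out the layer stack for a given input grid, validating that every
#' layer keeps spatial dimensions >= 1 (with `padding = "valid"` an input can
#' be too small for the schedule; the error names the offending layer).
#'
#' @param cfg An [architecture_config()].
#' @param input_shape Integer vector of 3 voxel counts.
#' @param seed Seed for weight initialisation.
#' @param init `"he"` (scaled Gaussian) or `"zero"`.
#' @return An object of class `cnn_classifier`.
#' @export
build_classifier <- function(cfg = architecture_config(), input_shape,
                             seed = 1L, init = c("he", "zero")) {
  stopifnot(inherits(cfg, "architecture_config"))
  init <- match.arg(init)
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop_field("input_shape", "must be 3 positive voxel counts")
  same <- cfg$padding == "same"
  dims <- as.integer(input_shape); cin <- 1L
  layers <- list(); shapes <- list(c(dims, cin))
  withr::with_seed(seed, {
    for (i in seq_along(cfg$conv_specs)) {
      cs <- cfg$conv_specs[[i]]
      k <- cs[1]; sx <- cs[2]; sz <- cs[3]; cout <- cs[4]
      out <- c(conv_out_dim(dims[1], k, sx, same),
               conv_out_dim(dims[2], k, sx, same),
               conv_out_dim(dims[3], k, sz, same))
      if (any(out < 1))
        stop(sprintf("conv layer %d: input %s too small for filter %d / stride %d,%d (padding = %s)",
                     i, paste(dims, collapse = "x"), k, sx, sz, cfg$padding),
             call. = FALSE)
      w <- if (init == "zero") array(0, c(k, k, k, cin, cout))
           else array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
                      c(k, k, k, cin, cout))
      layers[[length(layers) + 1L]] <-
        list(type = "conv", w = w, b = numeric(cout),
             sx = sx, sz = sz, same = same)
      dims <- out; cin <- cout
      shapes[[length(shapes) + 1L]] <- c(dims, cin)
      if (i <= cfg$n_maxpool) {
        out <- pmax(ceiling(dims / 2), 1L)   # ceil-mode 2^3 pool
        layers[[length(layers) + 1L]] <- list(type = "pool")
        dims <- as.integer(out)
        shapes[[length(shapes) + 1L]] <- c(dims, cin)
      }
    }
    nfeat <- if (cfg$gap) cin else prod(dims) * cin
    layers[[length(layers) + 1L]] <- list(type = if (cfg$gap) "gap" else "flatten")
    widths <- c(nfeat, cfg$hidden_fc, cfg$n_output)
    for (j in seq_len(length(widths) - 1L)) {
      fan_in <- widths[j]
      w <- if (init == "zero") matrix(0, widths[j + 1L], fan_in)
           else matrix(rnorm(widths[j + 1L] * fan_in, 0, sqrt(2 / fan_in)),
                       widths[j + 1L], fan_in)
      layers[[length(layers) + 1L]] <-
        list(type = "dense", w = w, b = numeric(widths[j + 1L]),
             relu = j < length(widths) - 1L)
    }
  })
  structure(list(cfg = cfg, input_shape = as.integer(input_shape),
                 layers = layers, shapes = shapes, log = NULL),
            class = "cnn_classifier")
}

#' Number of trainable parameters in a classifier
#' @param model A `cnn_classifier`.
#' @return Integer parameter count (weights + biases).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (is.null(l$w)) 0L else length(l$w) + length(l$b)
  }, integer(1)))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## Forward pass for one volume. Returns class probabilities and, if
## keep_cache, the per-layer inputs/pre-activations needed for backprop.
forward_cnn <- function(model, vol, keep_cache = FALSE) {
  x <- array(as.numeric(vol), c(dim(vol), 1L))
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      pre <- .conv3d_fwd(x, dim(x), l$w, dim(l$w), l$b, l$sx, l$sx, l$sz, l$same)
      if (keep_cache) cache[[i]] <- list(x = x, pre = pre)
      x <- pre * (pre > 0)
      dim(x) <- dim(pre)
    } else if (l$type == "pool") {
      mp <- .maxpool3d_fwd(x, dim(x), TRUE)
      if (keep_cache) cache[[i]] <- list(argmax = mp$argmax, xdim = dim(x))
      x <- mp$out
    } else if (l$type == "gap") {
      d <- dim(x)
      if (keep_cache) cache[[i]] <- list(xdim = d)
      x <- colMeans(matrix(x, prod(d[1:3]), d[4]))
    } else if (l$type == "flatten") {
      if (keep_cache) cache[[i]] <- list(xdim = dim(x))
      x <- as.numeric(x)
    } else if (l$type == "dense") {
      pre <- as.numeric(l$w %*% x + l$b)
      if (keep_cache) cache[[i]] <- list(x = x, pre = pre)
      x <- if (l$relu) pre * (pre > 0) else pre
    }
  }
  list(probs = softmax(x), logits = x, cache = cache)
}

## Backward pass; dlogits is the gradient at the output logits.
## Returns list of per-layer list(gw, gb) (NULL for parameterless layers).
backward_cnn <- function(model, cache, dlogits) {
  g <- dlogits
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]; cc <- cache[[i]]
    if (l$type == "dense") {
      if (l$relu) g <- g * (cc$pre > 0)
      grads[[i]] <- list(gw = outer(g, as.numeric(cc$x)), gb = g)
      g <- as.numeric(crossprod(l$w, g))
    } else if (l$type == "gap") {
      d <- cc$xdim; nsp <- prod(d[1:3])
      g <- array(rep(g / nsp, each = nsp), d)
    } else if (l$type == "flatten") {
      g <- array(g, cc$xdim)
    } else if (l$type == "pool") {
      g <- .maxpool3d_bwd(cc$argmax, g, cc$xdim)
    } else if (l$type == "conv") {
      g <- g * (cc$pre > 0)
      bw <- .conv3d_bwd(cc$x, dim(cc$x), l$w, dim(l$w), g,
                        l$sx, l$sx, l$sz, l$same)
      grads[[i]] <- list(gw = bw$gw, gb = bw$gb)
      g <- bw$gx
    }
  }
  grads
}

#' Class probabilities for a set of volumes
#'
#' @param model A `cnn_classifier`.
#' @param volumes List of 3D arrays (or a single array).
#' @return Matrix (n x n_output) of probabilities; with two classes the
#'   columns are named `control` (label 0) and `case` (label 1).
#' @export
predict_proba <- function(model, volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  p <- t(vapply(volumes, function(v) forward_cnn(model, v)$probs,
                numeric(model$cfg$n_output)))
  if (model$cfg$n_output == 2L) colnames(p) <- c("control", "case")
  p
}

#' Train a 3D CNN classifier
#'
#' Mini-batch Adam on the softmax cross-entropy. The published study does not
#' print its optimiser settings; the defaults here (Adam, learning rate 1e-4,
#' 30 epochs, batch 8) are recorded in the returned log so every run states
#' what it used. Fixed seeds give bit-reproducible trajectories on this
#' backend.
#'
#' @param model An untrained (or previously trained) `cnn_classifier`.
#' @param volumes List of 3D arrays.
#' @param labels Integer labels 0/1 (1 = case), one per volume.
#' @param hyperparams List overriding `lr`, `epochs`, `batch_size`.
#' @param seed Integer seed for shuffling (and any weight re-init).
#' @return The trained `cnn_classifier`, with `$log` holding per-epoch mean
#'   loss and training accuracy plus the hyperparameters used.
#' @export
train_classifier <- function(model, volumes, labels,
                             hyperparams = list(), seed = 1L) {
  stopifnot(inherits(model, "cnn_classifier"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training requires at least two classes", call. = FALSE)
  if (length(volumes) != length(labels))
    stop("volumes and labels lengths differ", call. = FALSE)
  hp <- modifyList(list(lr = 1e-4, epochs = 30L, batch_size = 8L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8), hyperparams)
  n <- length(volumes)
  ## Adam moment state mirrors the parameter structure.
  m1 <- m2 <- lapply(model$layers, function(l)
    if (is.null(l$w)) NULL else list(w = l$w * 0, b = l$b * 0))
  step <- 0L
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  if (hp$epochs >= 1) withr::with_seed(seed, {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = hp$batch_size)) {
        batch <- ord[start:min(start + hp$batch_size - 1L, n)]
        acc_grads <- NULL
        for (j in batch) {
          fw <- forward_cnn(model, volumes[[j]], keep_cache = TRUE)
          target <- numeric(model$cfg$n_output)
          target[labels[j] + 1L] <- 1
          ep_loss <- ep_loss - log(max(fw$probs[labels[j] + 1L], 1e-12))
          ep_correct <- ep_correct + (which.max(fw$probs) == labels[j] + 1L)
          gr <- backward_cnn(model, fw$cache, fw$probs - target)
          if (is.null(acc_grads)) acc_grads <- gr
          else for (i in seq_along(gr)) if (!is.null(gr[[i]])) {
            acc_grads[[i]]$gw <- acc_grads[[i]]$gw + gr[[i]]$gw
            acc_grads[[i]]$gb <- acc_grads[[i]]$gb + gr[[i]]$gb
          }
        }
        step <- step + 1L
        bc1 <- 1 - hp$beta1^step; bc2 <- 1 - hp$beta2^step
        for (i in seq_along(model$layers)) {
          if (is.null(acc_grads[[i]])) next
          gw <- acc_grads[[i]]$gw / length(batch)
          gb <- acc_grads[[i]]$gb / length(batch)
          m1[[i]]$w <- hp$beta1 * m1[[i]]$w + (1 - hp$beta1) * gw
          m2[[i]]$w <- hp$beta2 * m2[[i]]$w + (1 - hp$beta2) * gw^2
          m1[[i]]$b <- hp$beta1 * m1[[i]]$b + (1 - hp$beta1) * gb
          m2[[i]]$b <- hp$beta2 * m2[[i]]$b + (1 - hp$beta2) * gb^2
          model$layers[[i]]$w <- model$layers[[i]]$w -
            hp$lr * (m1[[i]]$w / bc1) / (sqrt(m2[[i]]$w / bc2) + hp$eps)
          model$layers[[i]]$b <- model$layers[[i]]$b -
            hp$lr * (m1[[i]]$b / bc1) / (sqrt(m2[[i]]$b / bc2) + hp$eps)
        }
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                   accuracy = ep_correct / n))
    }
  })
  model$log <- list(history = log, hyperparams = hp, seed = seed)
  model
}
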