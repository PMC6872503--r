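## Minimal dense multilayer perceptrons with Adam, used by the conditional
## GAN. Rows are samples. Hidden activation is ReLU (generator) or leaky
## ReLU (discriminator); output is linear or sigmoid.

mlp_new <- function(sizes, hidden = c("relu", "lrelu"),
                    out = c("linear", "sigmoid")) {
  hidden <- match.arg(hidden); out <- match.arg(out)
  L <- length(sizes) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l + 1] * sizes[l], 0, sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, hidden = hidden, out = out, sizes = sizes)
}

mlp_act <- function(z, kind) {
  switch(kind,
         relu = z * (z > 0),
         lrelu = ifelse(z > 0, z, 0.2 * z),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

mlp_act_grad <- function(z, kind) {
  switch(kind,
         relu = (z > 0) * 1,
         lrelu = ifelse(z > 0, 1, 0.2),
         sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         linear = 1)
}

mlp_fwd <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  A <- X; Zs <- As <- if (cache) vector("list", L) else NULL
  if (cache) As0 <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], `+`)
    kind <- if (l < L) net$hidden else net$out
    Anew <- mlp_act(Z, kind)
    if (cache) { Zs[[l]] <- Z; As[[l]] <- A }
    A <- Anew
  }
  if (cache) list(out = A, Z = Zs, A = As) else A
}

## Backprop given gradient w.r.t. the output activation. Returns parameter
## grads and the gradient w.r.t. the input matrix.
mlp_bwd <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- gb <- vector("list", L)
  G <- dOut
  for (l in rev(seq_len(L))) {
    kind <- if (l < L) net$hidden else net$out
    G <- G * mlp_act_grad(fw$Z[[l]], kind)
    gW[[l]] <- crossprod(fw$A[[l]], G)
    gb[[l]] <- colSums(G)
    G <- tcrossprod(G, net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = G)
}

adam_new <- function(net) {
  lapply(net$W, function(w)
    list(mW = w * 0, vW = w * 0,
         mb = numeric(ncol(w)), vb = numeric(ncol(w))))
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in seq_along(net$W)) {
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads$gW[[l]]
    s$vW <- beta2 * s$vW + (1 - beta2) * grads$gW[[l]]^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads$gb[[l]]
    s$vb <- beta2 * s$vb + (1 - beta2) * grads$gb[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}
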