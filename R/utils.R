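## Shared validation and small array helpers.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_field(field, "must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_field(field, sprintf("must lie in %s%g, %g]",
                              if (strict_lower) "(" else "[", lower, upper))
  as.numeric(x)
}

#' Derive a child seed from a parent seed and a label
#'
#' Stage- and operation-level seeds are derived deterministically from one
#' global seed so that independent stages use independent, reproducible
#' streams. The result always fits in a 32-bit integer.
#'
#' @param seed Parent integer seed.
#' @param label Character label naming the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 10007) %% 2147483647)
}

## Gaussian kernel of odd size `size` with spread `sigma`, normalised.
gaussian_kernel_1d <- function(size, sigma) {
  stopifnot(size %% 2 == 1, sigma > 0)
  h <- (size - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a 3D volume
#'
#' Separable Gaussian smoothing with a cubic kernel of the given size and
#' spread. Border windows are renormalised so constant volumes are unchanged.
#'
#' @param vol 3D numeric array.
#' @param size Odd kernel size in voxels.
#' @param sigma Spread parameter (voxels).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur3d <- function(vol, size, sigma) {
  stopifnot(is.array(vol), length(dim(vol)) == 3)
  if (size %% 2 != 1) stop_field("size", "kernel size must be odd")
  k <- gaussian_kernel_1d(size, sigma)
  d <- dim(vol)
  out <- vol
  for (axis in 0:2) out <- .conv1d_axis(out, d, k, axis)
  out
}

#' Translate a 3D volume by whole voxels
#'
#' Shifts along each axis with zero fill in the vacated planes.
#'
#' @param vol 3D numeric array.
#' @param shift Integer vector of length 3 (voxels).
#' @return Shifted array of the same shape.
#' @export
translate3d <- function(vol, shift) {
  stopifnot(is.array(vol), length(dim(vol)) == 3, length(shift) == 3)
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- as.integer(shift[a])
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- seq_len(d[a] - s); dst[[a]] <- src[[a]] + s }
    else        { src[[a]] <- seq_len(d[a] + s) - s; dst[[a]] <- seq_len(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Flip a 3D volume along one axis
#'
#' @param vol 3D numeric array.
#' @param axis Axis to flip (1, 2 or 3); axis 1 is the left-right
#'   (anatomical horizontal) axis by convention.
#' @return Flipped array.
#' @export
flip3d <- function(vol, axis = 1L) {
  stopifnot(is.array(vol), length(dim(vol)) == 3)
  if (!axis %in% 1:3) stop_field("axis", "flip axis must be 1, 2 or 3")
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(vol)[axis]))
  do.call(`[`, c(list(vol), idx))
}

## Dice overlap of two logical masks (used by tests and reported by the
## pipeline when ground truth is available).
#' Dice coefficient of two voxel masks
#' @param a,b Logical arrays of identical shape.
#' @return Dice overlap in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a & b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * inter / denom
}
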