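## Functional principal component summaries: 3D FPC scores for an ROI's
## voxel intensities and 1D FPC scores for a gene's positional genotype
## profile. Both reduce to centering, an optional smoothing step, and an SVD
## of the subjects x features matrix; eigenvector signs are fixed so scores
## are deterministic.

fix_signs <- function(v) {
  ## Make the largest-magnitude loading of each eigenvector positive.
  flip <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  sweep(v, 2, ifelse(flip == 0, 1, flip), `*`)
}

fpc_from_matrix <- function(Xc, n_components, variance_target, max_components,
                            basis) {
  n <- nrow(Xc)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  keep_all <- sum(sv$d > max(sv$d) * 1e-12)
  prop <- if (sum(eig) > 0) eig / sum(eig) else eig
  if (is.null(n_components)) {
    k <- which(cumsum(prop) >= variance_target)[1]
    if (is.na(k)) k <- keep_all
    k <- min(k, max_components, keep_all)
  } else {
    k <- n_components
  }
  k <- max(k, 1L)
  v <- fix_signs(sv$v[, seq_len(k), drop = FALSE])
  scores <- Xc %*% v
  colnames(scores) <- paste0("FPC", seq_len(k))
  structure(list(scores = scores, eigenvalues = eig,
                 var_explained = prop, loadings = v,
                 n_components = k, basis = basis),
            class = "fpc_scores")
}

#' FPC scores of an ROI's imaging signal
#'
#' Summarises the voxel intensities of one region of interest across
#' subjects by functional principal components: columns are centred, each
#' subject's region image is optionally Gaussian-smoothed (in 3D, via the
#' ROI's bounding box), and the leading eigenvectors of the sample covariance
#' are obtained by SVD. Scores are the projections of the centred rows.
#'
#' @param mat Subjects x voxels matrix (see [region_signal_matrix()]);
#'   columns in lexicographic voxel order. The attribute `"voxels"` (0-based
#'   coordinates) is required only when `smooth_sigma > 0`.
#' @param n_components Fixed component count, or `NULL` to choose the
#'   smallest count explaining `variance_target` of variance (capped at
#'   `max_components`).
#' @param variance_target Proportion of variance to cover (default 0.8).
#' @param max_components Cap on the automatic component count (default 5).
#' @param smooth_sigma Pre-smoothing spread in voxels (0 = none).
#' @return An `fpc_scores` object: `scores` (subjects x k), `eigenvalues`
#'   (all, non-increasing), `var_explained`, `loadings`, `n_components`.
#' @export
fpca_region <- function(mat, n_components = NULL, variance_target = 0.8,
                        max_components = 5L, smooth_sigma = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop_field("mat", "need at least 2 subjects")
  if (ncol(mat) < 1) stop_field("mat", "need at least 1 voxel")
  if (any(!is.finite(mat))) stop_field("mat", "values must be finite")
  if (!is.null(n_components) &&
      n_components > min(nrow(mat) - 1L, ncol(mat)))
    stop_field("n_components", "cannot exceed min(subjects - 1, voxels)")
  if (smooth_sigma > 0) {
    vx <- attr(mat, "voxels")
    if (is.null(vx))
      stop_field("mat", "smoothing needs the \"voxels\" coordinate attribute")
    lo <- apply(vx, 2, min); hi <- apply(vx, 2, max)
    box <- hi - lo + 1L
    size <- 2L * as.integer(ceiling(2 * smooth_sigma)) + 1L
    idx <- sweep(vx, 2, lo) + 1L
    mat <- t(apply(mat, 1, function(row) {
      a <- array(0, box)
      a[idx] <- row
      gaussian_blur3d(a, size, smooth_sigma)[idx]
    }))
  }
  Xc <- scale(mat, center = TRUE, scale = FALSE)
  fpc_from_matrix(Xc, n_components, variance_target, max_components,
                  basis = sprintf("voxel grid (%d voxels%s)", ncol(mat),
                                  if (smooth_sigma > 0)
                                    sprintf(", smoothed sigma=%g", smooth_sigma)
                                  else ""))
}

#' FPC scores of a gene's genotype profile
#'
#' Treats each subject's genotypes as a function of genomic position: SNP
#' positions are rescaled to `[0, 1]`, genotype profiles are smoothed by
#' projection onto a B-spline basis over position, and the principal
#' components of the smoothed, centred profiles give the classical 1D FPC
#' scores. Single-SNP genes bypass the decomposition and return the centred
#' genotype as the sole score.
#'
#' @param genotypes Subjects x SNPs matrix (0/1/2 counts or dosages).
#' @param positions Strictly increasing base-pair positions, one per SNP.
#' @param n_components,variance_target,max_components As [fpca_region()].
#' @param n_basis B-spline basis dimension (default `min(#SNPs, 8)`,
#'   minimum 4).
#' @return An `fpc_scores` object.
#' @export
fpca_gene <- function(genotypes, positions, n_components = NULL,
                      variance_target = 0.8, max_components = 5L,
                      n_basis = NULL) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2) stop_field("genotypes", "need at least 2 subjects")
  if (length(positions) != ncol(G))
    stop_field("positions", "must have one position per SNP")
  if (ncol(G) > 1 && any(diff(positions) <= 0))
    stop_field("positions", "must be strictly increasing")
  if (all(apply(G, 2, function(col) length(unique(col)) == 1)))
    stop("monomorphic gene: no genotype variation to summarise", call. = FALSE)
  if (ncol(G) == 1) {
    scores <- matrix(G[, 1] - mean(G[, 1]), ncol = 1,
                     dimnames = list(rownames(G), "FPC1"))
    return(structure(list(scores = scores,
                          eigenvalues = var(G[, 1]),
                          var_explained = 1, loadings = matrix(1, 1, 1),
                          n_components = 1L, basis = "single SNP (centred genotype)"),
                     class = "fpc_scores"))
  }
  if (!is.null(n_components) && n_components > min(nrow(G) - 1L, ncol(G)))
    stop_field("n_components", "cannot exceed min(subjects - 1, SNPs)")
  pos01 <- (positions - positions[1]) / (positions[length(positions)] - positions[1])
  if (is.null(n_basis)) n_basis <- max(4L, min(ncol(G), 8L))
  n_basis <- min(n_basis, ncol(G))
  B <- if (n_basis >= 4L)
    splines::bs(pos01, df = n_basis, intercept = TRUE)
  else
    stats::poly(pos01, degree = n_basis - 1L, raw = TRUE)
  B <- cbind(B)
  ## Ridge-stabilised projection of each profile onto the basis.
  P <- B %*% solve(crossprod(B) + 1e-10 * diag(ncol(B))) %*% t(B)
  Xc <- scale(G, center = TRUE, scale = FALSE) %*% t(P)
  fpc_from_matrix(Xc, n_components, variance_target, max_components,
                  basis = sprintf("B-spline (df=%d) over rescaled position",
                                  ncol(B)))
}

#' Write FPC scores as TSV
#' @param scores An `fpc_scores` object.
#' @param path Output path.
#' @param subject_ids Optional ids for the first column.
#' @return Invisibly, the path.
#' @export
write_fpc_scores <- function(scores, path, subject_ids = NULL) {
  df <- as.data.frame(scores$scores)
  df <- cbind(subject_id = if (is.null(subject_ids))
    sprintf("S%03d", seq_len(nrow(df))) else subject_ids, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
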