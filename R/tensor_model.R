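# Voxelwise diffusion-tensor fit by log-linear least squares, plus the derived
# eigen-system, FA and ADC maps. Tensor components are ordered
# (xx, yy, zz, xy, xz, yz) everywhere.

#' Build the log-linear design matrix for the tensor fit
#'
#' One row per acquired volume maps the six unique tensor components plus
#' log(S0) to the log signal: for direction g at b-value b the row is
#' `-b * c(gx^2, gy^2, gz^2, 2*gx*gy, 2*gx*gz, 2*gy*gz)` augmented with 1 for
#' the log(S0) column; a b = 0 row is `c(0,0,0,0,0,0,1)`.
#'
#' @param gradients a [gradient_table()] with at least six distinct nonzero-b
#'   directions and at least one b = 0 entry.
#' @return An n x 7 matrix of full column rank.
#' @export
build_design_matrix <- function(gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  b <- gradients$bvals
  g <- gradients$bvecs
  if (sum(b > 0) < 6) stop("need at least 6 nonzero-b directions")
  X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3], 1)
  colnames(X) <- c("xx", "yy", "zz", "xy", "xz", "yz", "logS0")
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > 1e8 || sv[length(sv)] < 1e-12)
    stop("rank-deficient design: gradient directions do not span tensor space",
         " (condition number ", format(cond, digits = 3), ")")
  X
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, with negative
#' eigenvalues clamped to zero first and FA of the all-zero triple defined
#' as 0.
#'
#' @param eigenvalues numeric length-3 vector, or a 3 x n matrix (one column
#'   per voxel).
#' @return FA in `[0, 1]` (scalar or length-n vector).
#' @export
compute_fa <- function(eigenvalues) {
  l <- if (is.null(dim(eigenvalues))) matrix(eigenvalues, 3, 1)
       else eigenvalues
  l <- pmax(l, 0)
  m <- colMeans(l)
  num <- colSums((l - rep(m, each = 3))^2)
  den <- colSums(l^2)
  fa <- sqrt(1.5 * num / den)
  fa[den <= 0] <- 0
  pmin(fa, 1)
}

#' Mean diffusivity (ADC) from eigenvalues
#' @inheritParams compute_fa
#' @return `(l1 + l2 + l3) / 3`, negatives clamped to zero first.
#' @export
compute_adc <- function(eigenvalues) {
  l <- if (is.null(dim(eigenvalues))) matrix(eigenvalues, 3, 1)
       else eigenvalues
  colMeans(pmax(l, 0))
}

#' Eigen-system of a batch of symmetric tensors
#'
#' @param tensors6 6 x n matrix of tensor components (xx, yy, zz, xy, xz, yz).
#' @return list with `values` (3 x n, descending) and `e1` (3 x n unit
#'   principal eigenvectors; sign unconstrained).
#' @export
tensor_eigen <- function(tensors6) {
  .dti_eigen_batch(as.matrix(tensors6))
}

#' Principal diffusion direction of a single tensor
#'
#' Returns the unit eigenvector of the largest eigenvalue; the sign is
#' unconstrained (resolved downstream by alignment with the incoming tracking
#' direction). When the two largest eigenvalues coincide within `1e-12` the
#' direction is degenerate; it is still returned, with attribute
#' `degenerate = TRUE`.
#'
#' @param tensor 3x3 symmetric matrix or length-6 component vector.
#' @export
principal_direction <- function(tensor) {
  t6 <- if (is.matrix(tensor))
    c(tensor[1, 1], tensor[2, 2], tensor[3, 3], tensor[1, 2], tensor[1, 3],
      tensor[2, 3])
  else as.numeric(tensor)
  es <- .dti_eigen_batch(matrix(t6, 6, 1))
  v <- as.numeric(es$e1)
  attr(v, "degenerate") <- (es$values[1, 1] - es$values[2, 1]) <= 1e-12
  v
}

#' Fit the diffusion tensor per voxel by log-linear least squares
#'
#' Signals are clipped below at `floor_frac * S0` (per volume's fitted S0 is
#' not known in advance, so the per-voxel b0 mean is used) before taking logs.
#' Voxels whose signals are all zero are dropped from the fitted mask.
#' Negative eigenvalues from noisy fits are clamped to zero for the FA/ADC
#' maps but the raw eigenvalues are kept for diagnostics.
#'
#' @param dwi a [dwi_volume()].
#' @param mask optional 3-D logical array of voxels to fit (default: voxels
#'   with positive mean b0 signal).
#' @param floor_frac signal floor as a fraction of the voxel's b0 signal.
#' @return An object of class `tensor_field`: list with `tensor` (4-D array
#'   x,y,z,6), `eigenvalues` (x,y,z,3 descending, unclamped), `e1` (x,y,z,3),
#'   `fa`, `adc`, `s0`, `mask`, `voxel_size_mm`, `affine`.
#' @export
fit_tensor_loglinear <- function(dwi, mask = NULL, floor_frac = 1e-6) {
  stopifnot(inherits(dwi, "dwi_volume"))
  X <- build_design_matrix(dwi$gradients)
  d <- dim(dwi$data)
  nvox <- prod(d[1:3])
  S <- matrix(dwi$data, nrow = nvox, ncol = d[4])
  b0 <- rowMeans(S[, dwi$gradients$bvals == 0, drop = FALSE])
  if (is.null(mask)) mask <- array(b0 > 0, d[1:3])
  idx <- which(as.logical(mask) & b0 > 0 & rowSums(S) > 0)
  Sm <- S[idx, , drop = FALSE]
  Sm <- pmax(Sm, floor_frac * b0[idx])          # floor before log
  B <- t(qr.coef(qr(X), t(log(Sm))))            # n_idx x 7
  es <- .dti_eigen_batch(t(B[, 1:6, drop = FALSE]))
  blank <- function(k) array(NA_real_, c(d[1:3], k))
  out <- list(tensor = blank(6), eigenvalues = blank(3), e1 = blank(3),
              fa = array(NA_real_, d[1:3]), adc = array(NA_real_, d[1:3]),
              s0 = array(NA_real_, d[1:3]),
              mask = array(FALSE, d[1:3]),
              voxel_size_mm = dwi$voxel_size_mm, affine = dwi$affine)
  out$mask[idx] <- TRUE
  for (k in 1:6) out$tensor[idx + (k - 1) * nvox] <- B[, k]
  for (k in 1:3) {
    out$eigenvalues[idx + (k - 1) * nvox] <- es$values[k, ]
    out$e1[idx + (k - 1) * nvox] <- es$e1[k, ]
  }
  out$fa[idx] <- compute_fa(es$values)
  out$adc[idx] <- compute_adc(es$values)
  out$s0[idx] <- exp(B[, 7])
  class(out) <- "tensor_field"
  out
}
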