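# Voxel-wise Cohen's kappa between two operators' tracts and the inclusion
# gate (exclude below 0.7).

#' Voxelize a tractogram to a binary mask
#'
#' A voxel is TRUE iff at least one streamline point falls inside it.
#'
#' @param tractogram a `tractogram` (may be empty).
#' @param grid list with `dim`, `voxel_size_mm`, `affine`.
#' @param label mask label.
#' @return A `volume_mask`.
#' @export
binarize_tract <- function(tractogram, grid, label = "tract") {
  m <- array(FALSE, grid$dim[1:3])
  if (length(tractogram$streamlines) > 0) {
    pts <- do.call(rbind, tractogram$streamlines)
    vox <- round(world_to_voxel(pts, grid$affine))
    ok <- vox[, 1] >= 0 & vox[, 1] < grid$dim[1] &
          vox[, 2] >= 0 & vox[, 2] < grid$dim[2] &
          vox[, 3] >= 0 & vox[, 3] < grid$dim[3]
    m[vox[ok, , drop = FALSE] + 1] <- TRUE
  }
  volume_mask(m, label, grid$voxel_size_mm, grid$affine)
}

#' Restricted universe for tract agreement
#'
#' The agreement universe is the brain (or phantom) mask restricted to the
#' axial slabs spanned by either tract; a whole-volume universe would inflate
#' kappa through empty background.
#'
#' @param maskA,maskB tract `volume_mask`s.
#' @param brain_mask optional `volume_mask`; default is the full grid.
#' @return A `volume_mask` labelled `"universe"`.
#' @export
tract_universe <- function(maskA, maskB, brain_mask = NULL) {
  d <- dim(maskA$data)
  any_slice <- apply(maskA$data | maskB$data, 3, any)
  u <- array(FALSE, d)
  if (any(any_slice)) {
    k <- range(which(any_slice))
    u[, , k[1]:k[2]] <- TRUE
  }
  if (!is.null(brain_mask)) u <- u & brain_mask$data
  volume_mask(u, "universe", maskA$voxel_size_mm, maskA$affine)
}

#' Cohen's kappa between two binary masks
#'
#' Computes the 2x2 contingency over the universe voxels:
#' `Po = (both + neither) / N`, `Pe = pA*pB + (1-pA)*(1-pB)`,
#' `kappa = (Po - Pe) / (1 - Pe)`. When both masks are constant over the
#' universe (`Pe = 1`), kappa is defined as 1 if they are identical and is an
#' error otherwise.
#'
#' @param maskA,maskB `volume_mask`s on the same grid, contained in the
#'   universe.
#' @param universe a `volume_mask` defining the voxels over which agreement is
#'   evaluated (see [tract_universe()]).
#' @param threshold exclusion threshold applied by [exclusion_gate()].
#' @return An object of class `agreement_result`: list with `kappa`, `po`,
#'   `pe`, `universe_size`, and `decision` (`"include"` or `"exclude"`).
#' @export
cohen_kappa <- function(maskA, maskB, universe, threshold = 0.7) {
  stopifnot(identical(dim(maskA$data), dim(maskB$data)),
            identical(dim(maskA$data), dim(universe$data)))
  u <- universe$data
  n <- sum(u)
  if (n == 0) stop("empty universe")
  a <- maskA$data[u]
  b <- maskB$data[u]
  if (any(maskA$data & !u) || any(maskB$data & !u))
    stop("masks must be contained in the universe")
  both <- sum(a & b)
  neither <- sum(!a & !b)
  po <- (both + neither) / n
  pa <- sum(a) / n
  pb <- sum(b) / n
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (identical(a, b)) 1
    else stop("chance agreement is 1 but masks differ; kappa undefined")
  } else (po - pe) / (1 - pe)
  res <- structure(list(kappa = kappa, po = po, pe = pe, universe_size = n,
                        decision = NULL, threshold = threshold),
                   class = "agreement_result")
  res$decision <- exclusion_gate(res)
  res
}

#' Operator-agreement exclusion gate
#'
#' Exclude when kappa is below the threshold; the boundary value itself is
#' included.
#'
#' @param result an `agreement_result`, or a bare kappa value.
#' @param threshold exclusion threshold (default 0.7).
#' @return `"include"` or `"exclude"`.
#' @export
exclusion_gate <- function(result, threshold = 0.7) {
  kappa <- if (inherits(result, "agreement_result")) {
    if (!is.null(result$threshold)) threshold <- result$threshold
    result$kappa
  } else as.numeric(result)
  if (kappa < threshold) "exclude" else "include"
}
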