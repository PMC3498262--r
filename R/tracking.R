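# Tensor-deflection streamline tracking with the clinical parameter set and
# the three-VOI pyramidal-tract selection protocol.

#' Tracking parameter set
#'
#' Defaults are the clinical protocol: FA threshold 0.2, minimum fiber length
#' 50 mm, turning-angle threshold 30 degrees, step size 1/3 of the (smallest)
#' voxel dimension, and deflection weights 20% previous direction / 80% new
#' major eigenvector.
#'
#' @param fa_threshold minimum local FA for propagation.
#' @param min_length_mm minimum retained streamline length.
#' @param angle_threshold_deg maximum angle between successive step directions.
#' @param step_fraction_of_voxel step length as a fraction of the smallest
#'   voxel dimension.
#' @param weight_prev,weight_new deflection weights; must sum to 1.
#' @param max_steps optional hard safety bound per march; default (NULL) is
#'   10 x (volume diagonal / step), computed at run time.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(fa_threshold = 0.2, min_length_mm = 50,
                            angle_threshold_deg = 30,
                            step_fraction_of_voxel = 1 / 3,
                            weight_prev = 0.2, weight_new = 0.8,
                            max_steps = NULL) {
  stopifnot(fa_threshold > 0, min_length_mm > 0, angle_threshold_deg > 0,
            step_fraction_of_voxel > 0)
  if (abs(weight_prev + weight_new - 1) > 1e-12)
    stop("weight_prev + weight_new must equal 1")
  structure(list(fa_threshold = fa_threshold, min_length_mm = min_length_mm,
                 angle_threshold_deg = angle_threshold_deg,
                 step_fraction_of_voxel = step_fraction_of_voxel,
                 weight_prev = weight_prev, weight_new = weight_new,
                 max_steps = max_steps),
            class = "tracking_params")
}

step_mm_of <- function(params, voxel_size_mm) {
  params$step_fraction_of_voxel * min(voxel_size_mm)
}

max_steps_of <- function(params, dim, voxel_size_mm) {
  if (!is.null(params$max_steps)) return(as.integer(params$max_steps))
  diag_mm <- sqrt(sum((dim * voxel_size_mm)^2))
  as.integer(ceiling(10 * diag_mm / step_mm_of(params, voxel_size_mm)))
}

#' Tensor-deflection direction update
#'
#' The new major eigenvector is sign-flipped to lie within 90 degrees of the
#' incoming direction, then blended as
#' `normalize(weight_prev * v_prev + weight_new * e1)`.
#'
#' @param v_prev,e1 unit 3-vectors: previous step direction and local major
#'   eigenvector.
#' @param params a [tracking_params()].
#' @export
deflect_direction <- function(v_prev, e1, params = tracking_params()) {
  stopifnot(abs(sum(v_prev^2) - 1) < 1e-6, abs(sum(e1^2) - 1) < 1e-6)
  if (sum(v_prev * e1) < 0) e1 <- -e1
  v <- params$weight_prev * v_prev + params$weight_new * e1
  n <- sqrt(sum(v^2))
  if (n <= 0)
    stop("zero resultant deflection direction (exactly orthogonal boundary ",
         "case); tie broken by terminating the streamline")
  v / n
}

# Flatten the tensor component array for the C++ propagator; unfitted voxels
# become zero tensors (FA 0), which terminate any march entering them.
tensor_flat_of <- function(field) {
  tf <- field$tensor
  tf[is.na(tf)] <- 0
  as.numeric(tf)
}

#' Propagate one streamline by tensor deflection
#'
#' Bidirectional march from the seed along both signs of the local major
#' eigenvector; halves are concatenated through the seed. A march terminates
#' when the next position leaves the volume, local FA falls below the
#' threshold, or the turning angle between successive step directions exceeds
#' the angular threshold. The tensor is interpolated component-wise
#' (trilinear) at off-grid points.
#'
#' @param field a `tensor_field` from [fit_tensor_loglinear()].
#' @param seed_point world-mm coordinates of the seed.
#' @param params a [tracking_params()].
#' @return An object of class `streamline`: n x 3 matrix of world-mm points
#'   with attributes `length_mm` and `seed_index` (0-based voxel of the seed);
#'   a 0 x 3 matrix with attribute `reason = "seed_below_fa"` when the seed
#'   FA is below threshold.
#' @export
propagate_streamline <- function(field, seed_point, params = tracking_params()) {
  stopifnot_axis_aligned(field$affine)
  d <- dim(field$fa)
  seed_vox <- world_to_voxel(seed_point, field$affine)
  res <- .track_streamlines_cpp(
    tensor_flat_of(field), as.integer(d), field$voxel_size_mm,
    matrix(seed_vox, 1, 3), params$fa_threshold, params$angle_threshold_deg,
    step_mm_of(params, field$voxel_size_mm), params$weight_prev,
    max_steps_of(params, d, field$voxel_size_mm))[[1]]
  pts <- voxel_to_world(res, field$affine)
  sl <- structure(pts, class = "streamline",
                  seed_index = as.integer(round(seed_vox)),
                  length_mm = polyline_length(pts))
  if (nrow(pts) == 0) attr(sl, "reason") <- "seed_below_fa"
  sl
}

polyline_length <- function(pts) {
  if (is.null(nrow(pts)) || nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# TRUE per point: does the (rounded) containing voxel belong to the mask?
points_in_mask <- function(pts_world, mask) {
  if (nrow(pts_world) == 0) return(logical(0))
  vox <- round(world_to_voxel(pts_world, mask$affine))
  d <- dim(mask$data)
  ok <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 & vox[, 2] < d[2] &
        vox[, 3] >= 0 & vox[, 3] < d[3]
  inside <- logical(nrow(pts_world))
  if (any(ok))
    inside[ok] <- mask$data[vox[ok, , drop = FALSE] + 1]
  inside
}

# Unit tangents along a polyline (central differences; one-sided at the ends).
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(matrix(numeric(0), 0, 3))
  tg <- rbind(pts[2, ] - pts[1, ],
              if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
              pts[n, ] - pts[n - 1, ])
  tg / sqrt(rowSums(tg^2))
}

#' VOI set for the three-VOI pyramidal-tract protocol
#'
#' @param seed seed VOI mask covering the presumed course of the tract.
#' @param include_precentral VOI covering the precentral gyrus.
#' @param include_peduncle VOI at the cerebral peduncle.
#' @param excludes list of exclusion masks (may be empty).
#' @export
voi_set <- function(seed, include_precentral, include_peduncle,
                    excludes = list()) {
  masks <- c(list(seed, include_precentral, include_peduncle), excludes)
  dims <- vapply(masks, function(m) paste(dim(m$data), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("VOI masks must share one grid")
  structure(list(seed = seed, include_precentral = include_precentral,
                 include_peduncle = include_peduncle, excludes = excludes),
            class = "voi_set")
}

#' Run the three-VOI pyramidal-tract selection protocol
#'
#' Seeds every voxel of the seed VOI (one seed per voxel center) and retains
#' streamlines that (a) intersect the precentral VOI, (b) intersect the
#' peduncle VOI with craniocaudal orientation there (majority of in-VOI local
#' tangents with |z| exceeding the in-plane norm), (c) avoid all exclusion
#' masks, and (d) reach the minimum length. Provenance records the first
#' failed test per discarded seed.
#'
#' @param field a `tensor_field`.
#' @param vois a [voi_set()].
#' @param params a [tracking_params()].
#' @return An object of class `tractogram`: list with `streamlines` (world-mm
#'   point matrices), `params`, and `provenance` (one row per seed with its
#'   voxel index and status).
#' @export
run_pt_protocol <- function(field, vois, params = tracking_params()) {
  stopifnot(inherits(vois, "voi_set"))
  stopifnot_axis_aligned(field$affine)
  d <- dim(field$fa)
  seed_idx <- which(vois$seed$data, arr.ind = TRUE) - 1L
  if (nrow(seed_idx) == 0) stop("empty seed VOI")
  res <- .track_streamlines_cpp(
    tensor_flat_of(field), as.integer(d), field$voxel_size_mm,
    seed_idx * 1.0, params$fa_threshold, params$angle_threshold_deg,
    step_mm_of(params, field$voxel_size_mm), params$weight_prev,
    max_steps_of(params, d, field$voxel_size_mm))
  status <- character(length(res))
  keep <- vector("list", length(res))
  for (i in seq_along(res)) {
    pts <- voxel_to_world(res[[i]], field$affine)
    if (nrow(pts) < 2) { status[i] <- "empty"; next }
    if (!any(points_in_mask(pts, vois$include_precentral))) {
      status[i] <- "failed_precentral"; next
    }
    in_ped <- points_in_mask(pts, vois$include_peduncle)
    if (!any(in_ped)) { status[i] <- "failed_peduncle"; next }
    tg <- polyline_tangents(pts)[in_ped, , drop = FALSE]
    cc <- abs(tg[, 3]) > sqrt(tg[, 1]^2 + tg[, 2]^2)
    if (mean(cc) <= 0.5) { status[i] <- "failed_peduncle_orientation"; next }
    hit_excl <- any(vapply(vois$excludes,
                           function(m) any(points_in_mask(pts, m)), TRUE))
    if (isTRUE(hit_excl)) { status[i] <- "failed_exclude"; next }
    if (polyline_length(pts) < params$min_length_mm) {
      status[i] <- "failed_length"; next
    }
    status[i] <- "retained"
    keep[[i]] <- pts
  }
  prov <- data.frame(seed_i = seed_idx[, 1], seed_j = seed_idx[, 2],
                     seed_k = seed_idx[, 3], status = status)
  structure(list(streamlines = keep[status == "retained"], params = params,
                 provenance = prov),
            class = "tractogram")
}

#' Axial cross-section of a tractogram
#'
#' Collects streamline points whose world z lies within half a slice thickness
#' of the slice plane, rasterizes them to slice voxels, and returns the mean
#' of the contributing points.
#'
#' @param tractogram a `tractogram`.
#' @param axial_slice_index 0-based axial slice index.
#' @param grid list with `dim`, `voxel_size_mm`, `affine`.
#' @return list with `mask` (2-D logical, slice grid), `centroid` (world mm,
#'   or NULL when no point falls in the slab) and `n_points`.
#' @export
cross_section <- function(tractogram, axial_slice_index, grid) {
  if (length(tractogram$streamlines) == 0)
    return(list(mask = array(FALSE, grid$dim[1:2]), centroid = NULL,
                n_points = 0L))
  pts <- do.call(rbind, tractogram$streamlines)
  zc <- voxel_to_world(c(0, 0, axial_slice_index), grid$affine)[3]
  half <- grid$voxel_size_mm[3] / 2
  sel <- abs(pts[, 3] - zc) <= half
  mask <- array(FALSE, grid$dim[1:2])
  if (!any(sel))
    return(list(mask = mask, centroid = NULL, n_points = 0L))
  p <- pts[sel, , drop = FALSE]
  vox <- round(world_to_voxel(p, grid$affine))
  ok <- vox[, 1] >= 0 & vox[, 1] < grid$dim[1] &
        vox[, 2] >= 0 & vox[, 2] < grid$dim[2]
  mask[vox[ok, 1:2, drop = FALSE] + 1] <- TRUE
  list(mask = mask, centroid = unname(colMeans(p)), n_points = sum(sel))
}
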