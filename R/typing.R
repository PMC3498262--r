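# Eight-type tumor classification from the three-line geometry, the frozen
# type -> clock-sector prediction rule, and the observed sector measured from
# the tracked pyramidal tract.

TUMOR_TYPES <- c("T1", "T2", "T3A", "T3B", "T4A", "T4B", "T5", "T6")

#' The eight tumor types
#' @return Character vector `T1, T2, T3A, T3B, T4A, T4B, T5, T6`.
#' @export
tumor_types <- function() TUMOR_TYPES

# World x,y of the true voxels of a 3-D mask restricted to one axial slice.
slice_xy <- function(mask, monro_slice) {
  d <- dim(mask$data)
  sl <- mask$data[, , monro_slice + 1]
  idx <- which(sl, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2))
  voxel_to_world(cbind(idx, monro_slice), mask$affine)[, 1:2, drop = FALSE]
}

#' Centroid of a mask on one axial slice (world mm)
#' @param mask a `volume_mask`.
#' @param monro_slice 0-based axial slice index.
#' @export
mask_slice_centroid <- function(mask, monro_slice) {
  xy <- slice_xy(mask, monro_slice)
  if (nrow(xy) == 0) stop("mask is empty on the requested slice")
  colMeans(xy)
}

#' Quadrant areas of a tumor mask on the Monro slice
#'
#' Lines 1 and 2 divide the slice into four regions; areas are voxel counts.
#' A voxel whose center falls exactly on a line is assigned by the
#' inclusive-lower rule (to the lower-x side for line 1, i.e. lateral in the
#' left hemisphere, and to the lower-y = posterior side for lines 2 and 3).
#' The posterior mass is additionally split at line 3 into `beyond_line3`
#' (posterior to line 3) versus `between_lines_2_3`.
#'
#' @param tumor_mask a `volume_mask`.
#' @param lines a [build_reference_lines()] result.
#' @param monro_slice 0-based axial slice index.
#' @return list of counts: `anterior_medial`, `anterior_lateral`,
#'   `posterior_medial`, `posterior_lateral`, `beyond_line3`,
#'   `between_lines_2_3`, `total`.
#' @export
quadrant_areas <- function(tumor_mask, lines, monro_slice) {
  xy <- slice_xy(tumor_mask, monro_slice)
  if (nrow(xy) == 0)
    stop("tumor mask is empty on the Monro slice; nearest-slice fallback is ",
         "not supported")
  lateral <- xy[, 1] <= lines$line1_x          # left hemisphere: lateral = -x
  posterior <- xy[, 2] <= lines$line2_y
  beyond3 <- posterior & xy[, 2] <= lines$line3_y
  list(anterior_medial = sum(!posterior & !lateral),
       anterior_lateral = sum(!posterior & lateral),
       posterior_medial = sum(posterior & !lateral),
       posterior_lateral = sum(posterior & lateral),
       beyond_line3 = sum(beyond3),
       between_lines_2_3 = sum(posterior & !beyond3),
       total = nrow(xy))
}

#' Classify a tumor into one of the eight types
#'
#' When an abnormal-signal extent mask is supplied and the (enhanced) tumor
#' mask covers less than half of it, the extent is used for classification
#' (the shape of the abnormally signalling tissue, not the small enhancing
#' core, determines the type). Centered types come first: if the mask
#' centroid lies within `centered_tolerance` times the mask's bounding-box
#' width of line 1, the type is T1 (majority of area posterior to line 2) or
#' T2 (majority anterior). Otherwise the majority quadrant decides:
#' posterior-lateral T3, posterior-medial T4, anterior-lateral T5,
#' anterior-medial T6; T3/T4 take subtype A when the majority of the
#' posterior mass lies beyond (posterior to) line 3 and B when it lies
#' between lines 2 and 3. Exact 50/50 ties are an error demanding manual
#' adjudication.
#'
#' @param tumor_mask a `volume_mask` (enhanced tumor).
#' @param lines a [build_reference_lines()] result.
#' @param monro_slice 0-based axial slice index.
#' @param extent_mask optional abnormal-signal `volume_mask` containing the
#'   tumor mask.
#' @param centered_tolerance centroid-to-line-1 tolerance as a fraction of the
#'   mask bounding-box width.
#' @return One of [tumor_types()], with attribute `areas` (the
#'   [quadrant_areas()] used) and `used_extent` (logical).
#' @export
classify_tumor <- function(tumor_mask, lines, monro_slice, extent_mask = NULL,
                           centered_tolerance = 0.15) {
  mask <- tumor_mask
  used_extent <- FALSE
  if (!is.null(extent_mask)) {
    cover <- sum(tumor_mask$data) / sum(extent_mask$data)
    if (cover < 0.5) { mask <- extent_mask; used_extent <- TRUE }
  }
  ar <- quadrant_areas(mask, lines, monro_slice)
  xy <- slice_xy(mask, monro_slice)
  width <- diff(range(xy[, 1])) + mask$voxel_size_mm[1]
  centroid_x <- mean(xy[, 1])
  post <- ar$posterior_medial + ar$posterior_lateral
  ant <- ar$anterior_medial + ar$anterior_lateral
  tie <- function(a, b, what)
    if (a == b) stop("exact 50/50 area tie (", what,
                     "); manual adjudication required")
  type <-
    if (abs(centroid_x - lines$line1_x) <= centered_tolerance * width) {
      tie(post, ant, "anterior vs posterior")
      if (post > ant) "T1" else "T2"
    } else {
      quad <- c(posterior_lateral = ar$posterior_lateral,
                posterior_medial = ar$posterior_medial,
                anterior_lateral = ar$anterior_lateral,
                anterior_medial = ar$anterior_medial)
      top <- which(quad == max(quad))
      if (length(top) > 1)
        stop("exact tie between quadrants (",
             paste(names(quad)[top], collapse = ", "),
             "); manual adjudication required")
      switch(names(quad)[top],
             posterior_lateral = {
               tie(ar$beyond_line3, ar$between_lines_2_3, "line 3 split")
               if (ar$beyond_line3 > ar$between_lines_2_3) "T3A" else "T3B"
             },
             posterior_medial = {
               tie(ar$beyond_line3, ar$between_lines_2_3, "line 3 split")
               if (ar$beyond_line3 > ar$between_lines_2_3) "T4A" else "T4B"
             },
             anterior_lateral = "T5",
             anterior_medial = "T6")
    }
  structure(type, areas = ar, used_extent = used_extent)
}

PREDICTED_SECTOR <- c(T1 = "12", T2 = "6", T3A = "9-12", T3B = "6-9",
                      T4A = "12-3", T4B = "3", T5 = "6-9", T6 = "3-6")

#' Predicted clock sector of the pyramidal tract for a tumor type
#'
#' Frozen total lookup: T1 -> 12, T2 -> 6, T3A -> 9-12, T3B -> 6-9,
#' T4A -> 12-3, T4B -> 3, T5 -> 6-9, T6 -> 3-6.
#'
#' @param tumor_type one of [tumor_types()] (vectorized).
#' @return Clock sector label(s).
#' @export
predict_sector <- function(tumor_type) {
  bad <- !(tumor_type %in% TUMOR_TYPES)
  if (any(bad)) stop("unknown tumor type: ", paste(tumor_type[bad],
                                                   collapse = ", "))
  unname(PREDICTED_SECTOR[as.character(tumor_type)])
}

#' Observed clock sector of the tract relative to the tumor
#'
#' @param pt_centroid world-mm centroid of the tract cross-section on the
#'   Monro slice (e.g. from [cross_section()]); NULL propagates to NULL.
#' @param tumor_mask a `volume_mask`, non-empty on the slice.
#' @param monro_slice 0-based axial slice index.
#' @param frame an [anatomy_frame()].
#' @export
observed_sector <- function(pt_centroid, tumor_mask, monro_slice,
                            frame = anatomy_frame("left")) {
  if (is.null(pt_centroid)) return(NULL)
  clock_sector_of(pt_centroid, mask_slice_centroid(tumor_mask, monro_slice),
                  frame)
}
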