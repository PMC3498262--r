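# The foramen-of-Monro-slice reference frame: hemisphere mirroring, the three
# classification lines, and the eight-sector clock-face statistic.
#
# Anatomical conventions (RAS-like world frame): +y is anterior, +x is toward
# the subject's right. Analysis happens after mirroring every case to the LEFT
# hemisphere, where the medial direction is +x (toward the midline) and
# lateral is -x. "Posterior to" a horizontal line therefore means smaller y.

CLOCK_SECTORS <- c("12", "12-3", "3", "3-6", "6", "6-9", "9", "9-12")

#' The eight clock-face sectors
#'
#' Sector labels in clockwise order starting anteriorly: 12 o'clock is
#' anterior, 3 lateral, 6 posterior, 9 medial (left-hemisphere frame after
#' mirroring).
#' @return Character vector of the 8 sector labels.
#' @export
clock_sectors <- function() CLOCK_SECTORS

#' Anatomical frame for clock-face angles
#'
#' @param hemisphere hemisphere of analysis; the standard pipeline mirrors
#'   every case to `"left"`, where lateral is the -x world direction.
#' @return list with unit in-plane `anterior` and `lateral` axes (world x, y).
#' @export
anatomy_frame <- function(hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  list(anterior = c(0, 1),
       lateral = if (hemisphere == "left") c(-1, 0) else c(1, 0),
       hemisphere = hemisphere)
}

#' Axial landmarks on the foramen-of-Monro slice
#'
#' All points are world mm and must lie on one axial slice. The posterior-limb
#' endpoints are taken in the normal (non-tumor) hemisphere, as the limb on
#' the lesion side may be unrecognizable.
#'
#' @param foramen_of_monro,anterior_limb_vertex world points (length 3).
#' @param posterior_limb_genu_end,posterior_limb_posterior_end world points of
#'   the posterior limb of the internal capsule in the normal hemisphere.
#' @param midline_x world x of the midsagittal plane.
#' @return An object of class `axial_landmarks`.
#' @export
axial_landmarks <- function(foramen_of_monro, anterior_limb_vertex,
                            posterior_limb_genu_end,
                            posterior_limb_posterior_end, midline_x) {
  pts <- list(foramen_of_monro = as.numeric(foramen_of_monro),
              anterior_limb_vertex = as.numeric(anterior_limb_vertex),
              posterior_limb_genu_end = as.numeric(posterior_limb_genu_end),
              posterior_limb_posterior_end =
                as.numeric(posterior_limb_posterior_end))
  stopifnot(all(vapply(pts, length, 0L) == 3))
  zs <- vapply(pts, `[`, 0, 3)
  if (diff(range(zs)) > 1e-6)
    stop("all landmarks must lie on one axial slice")
  if (sqrt(sum((pts$posterior_limb_genu_end -
                pts$posterior_limb_posterior_end)^2)) < 1e-9)
    stop("degenerate posterior limb (zero length)")
  structure(c(pts, list(midline_x = as.numeric(midline_x))),
            class = "axial_landmarks")
}

#' Build the three classification lines from the landmarks
#'
#' Line 1 is vertical through the anterior-limb vertex (`line1_x`); line 2 is
#' horizontal through the foramen of Monro (`line2_y`); line 3 is horizontal
#' through the joint of the middle and lateral thirds of the posterior limb,
#' i.e. the point 2/3 of the way from the genu end toward the posterior end
#' (`line3_y`). Line 3 must fall posterior to line 2.
#'
#' @param landmarks an [axial_landmarks()].
#' @return An object of class `reference_lines` with `line1_x`, `line2_y`,
#'   `line3_y`.
#' @export
build_reference_lines <- function(landmarks) {
  stopifnot(inherits(landmarks, "axial_landmarks"))
  g <- landmarks$posterior_limb_genu_end
  p <- landmarks$posterior_limb_posterior_end
  junction <- g + 2 / 3 * (p - g)
  lines <- structure(list(line1_x = landmarks$anterior_limb_vertex[1],
                          line2_y = landmarks$foramen_of_monro[2],
                          line3_y = junction[2]),
                     class = "reference_lines")
  if (lines$line3_y >= lines$line2_y)
    stop("line 3 must be posterior to line 2; check landmark orientation")
  lines
}

#' Clock-face sector of a point relative to a reference centroid
#'
#' The angle is measured from the anterior axis, increasing toward lateral;
#' sectors are 45-degree bins centered at 0 (12 o'clock), 45 (12-3), 90 (3),
#' 135 (3-6), 180 (6), 225 (6-9), 270 (9) and 315 (9-12) degrees, with
#' boundaries at center +/- 22.5 degrees and the lower boundary inclusive.
#'
#' @param point,reference_centroid world coordinates (x, y in-plane; a third
#'   component is ignored).
#' @param frame an [anatomy_frame()].
#' @return One of the labels in [clock_sectors()].
#' @export
clock_sector_of <- function(point, reference_centroid,
                            frame = anatomy_frame("left")) {
  d <- as.numeric(point)[1:2] - as.numeric(reference_centroid)[1:2]
  if (sqrt(sum(d^2)) < 1e-12) stop("point coincides with reference centroid")
  a <- sum(d * frame$anterior)
  l <- sum(d * frame$lateral)
  theta <- (atan2(l, a) * 180 / pi) %% 360
  CLOCK_SECTORS[floor(((theta + 22.5) %% 360) / 45) + 1]
}

#' Axial slice index containing a world z coordinate
#'
#' Slice k spans the slab `(z_k - dz/2, z_k + dz/2]` around its center, so a
#' point exactly on a slab boundary belongs to the lower slice.
#'
#' @param landmarks an [axial_landmarks()] (its foramen-of-Monro z is used),
#'   or a numeric world z.
#' @param grid list with `dim`, `voxel_size_mm`, `affine`.
#' @return 0-based axial slice index.
#' @export
monro_axial_slice <- function(landmarks, grid) {
  z <- if (inherits(landmarks, "axial_landmarks"))
    landmarks$foramen_of_monro[3] else as.numeric(landmarks)
  kc <- world_to_voxel(c(0, 0, z), grid$affine)[3]
  k <- as.integer(ceiling(kc - 0.5))
  if (k < 0 || k >= grid$dim[3])
    stop("world z = ", z, " falls outside the volume")
  k
}

# ---- mirroring --------------------------------------------------------------

mirror_point <- function(p, midline_x) {
  p <- as.numeric(p)
  p[1] <- 2 * midline_x - p[1]
  p
}

mirror_points <- function(pts, midline_x) {
  pts[, 1] <- 2 * midline_x - pts[, 1]
  pts
}

mirror_mask <- function(mask, midline_x) {
  stopifnot_axis_aligned(mask$affine)
  d <- dim(mask$data)
  m_idx <- world_to_voxel(c(midline_x, 0, 0), mask$affine)[1]
  src <- round(2 * m_idx - (seq_len(d[1]) - 1)) + 1   # 1-based source column
  if (max(abs(2 * m_idx - (seq_len(d[1]) - 1) - (src - 1))) > 1e-6)
    warning("midline does not align with the voxel grid; mask mirroring is ",
            "rounded to the nearest voxel")
  out <- array(FALSE, d)
  ok <- src >= 1 & src <= d[1]
  out[ok, , ] <- mask$data[src[ok], , ]
  volume_mask(out, mask$label, mask$voxel_size_mm, mask$affine)
}

mirror_landmarks <- function(landmarks, midline_x) {
  axial_landmarks(mirror_point(landmarks$foramen_of_monro, midline_x),
                  mirror_point(landmarks$anterior_limb_vertex, midline_x),
                  mirror_point(landmarks$posterior_limb_genu_end, midline_x),
                  mirror_point(landmarks$posterior_limb_posterior_end,
                               midline_x),
                  midline_x)
}

#' Mirror a right-hemisphere case to the left
#'
#' Right-sided cases (tumor centroid right of the midline) are reflected about
#' the midsagittal plane; left-sided cases are returned unchanged. The
#' reflection preserves the relative tract-tumor geometry, and hence the clock
#' sector, because the anatomical frame flips its lateral axis with the
#' hemisphere. A tumor centroid exactly on the midline is not mirrored and is
#' flagged.
#'
#' @param geom list with `tumor_mask` (a `volume_mask`), optional
#'   `extent_mask`, optional `landmarks` (an [axial_landmarks()]), and optional
#'   `pt_points` (n x 3 world-mm matrix, e.g. pooled streamline points).
#' @param midline_x world x of the midsagittal plane.
#' @return The geometry list, with attributes `mirrored` (logical) and
#'   `on_midline` (logical).
#' @export
mirror_to_left <- function(geom, midline_x) {
  stopifnot(inherits(geom$tumor_mask, "volume_mask"))
  idx <- which(geom$tumor_mask$data, arr.ind = TRUE) - 1
  cx <- mean(voxel_to_world(idx, geom$tumor_mask$affine)[, 1])
  if (abs(cx - midline_x) < 1e-9) {
    attr(geom, "mirrored") <- FALSE
    attr(geom, "on_midline") <- TRUE
    return(geom)
  }
  if (cx < midline_x) {                       # already left
    attr(geom, "mirrored") <- FALSE
    attr(geom, "on_midline") <- FALSE
    return(geom)
  }
  out <- geom
  out$tumor_mask <- mirror_mask(geom$tumor_mask, midline_x)
  if (!is.null(geom$extent_mask))
    out$extent_mask <- mirror_mask(geom$extent_mask, midline_x)
  if (!is.null(geom$landmarks))
    out$landmarks <- mirror_landmarks(geom$landmarks, midline_x)
  if (!is.null(geom$pt_points))
    out$pt_points <- mirror_points(geom$pt_points, midline_x)
  attr(out, "mirrored") <- TRUE
  attr(out, "on_midline") <- FALSE
  out
}
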