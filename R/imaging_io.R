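#' @useDynLib ptclock, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- spatial conventions ----------------------------------------------------
#
# Voxel indices are 0-based throughout; `affine` is the 4x4 voxel->world (mm)
# transform in a RAS-like frame (+x toward the subject's right, +y anterior,
# +z superior). All downstream geometry is phrased anatomically
# (anterior/posterior, medial/lateral), never in display terms.

#' Map 0-based voxel indices to world millimetres
#'
#' @param idx numeric vector of length 3, or an n x 3 matrix of 0-based voxel
#'   indices (may be fractional).
#' @param affine 4x4 voxel-to-world transform.
#' @return World coordinates with the same shape as `idx`.
#' @export
voxel_to_world <- function(idx, affine) {
  if (is.null(dim(idx))) {
    as.numeric(affine %*% c(idx, 1))[1:3]
  } else if (nrow(idx) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  }
}

#' Map world millimetres to continuous 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param pts world coordinates (length-3 vector or n x 3 matrix).
#' @export
world_to_voxel <- function(pts, affine) {
  inv <- solve(affine)
  if (is.null(dim(pts))) {
    as.numeric(inv %*% c(pts, 1))[1:3]
  } else if (nrow(pts) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    t(inv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
  }
}

stopifnot_axis_aligned <- function(affine) {
  off <- affine[1:3, 1:3]
  diag(off) <- 0
  if (any(abs(off) > 1e-9) || any(diag(affine[1:3, 1:3]) <= 0))
    stop("this operation requires an axis-aligned affine with positive spacings")
  invisible(TRUE)
}

# ---- gradient table ---------------------------------------------------------

#' Diffusion gradient table
#'
#' Bundles b-values (s/mm^2) and unit gradient directions, one per acquired
#' volume. Directions of nonzero-b entries must be unit vectors; vectors off
#' unit norm by at most `tol` are re-normalized, larger deviations are an
#' error. At least one b = 0 entry is required.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions.
#' @param tol maximum tolerated deviation from unit norm before rejection.
#' @return An object of class `gradient_table` with elements `bvals` (numeric),
#'   `bvecs` (n x 3 matrix, unit rows for b > 0) and `n_b0`.
#' @export
gradient_table <- function(bvals, bvecs, tol = 1e-3) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3) stop("bvecs must be 3 x n or n x 3")
  if (length(bvals) != nrow(bvecs))
    stop("count mismatch: ", length(bvals), " b-values vs ", nrow(bvecs),
         " gradient directions")
  if (any(bvals < 0)) stop("negative b-value")
  nrm <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  bad <- nz & abs(nrm - 1) > tol
  if (any(bad))
    stop("gradient direction(s) off unit norm by more than ", tol, ": row(s) ",
         paste(which(bad), collapse = ", "))
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  dimnames(bvecs) <- NULL
  if (!any(!nz)) stop("gradient table needs at least one b=0 entry")
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = sum(!nz)),
            class = "gradient_table")
}

#' Read an FSL-style bval/bvec pair
#'
#' Accepts the usual three-row layout as well as one column per volume
#' (auto-detected by shape).
#'
#' @param bval_path,bvec_path whitespace-delimited text files.
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  raw <- as.matrix(utils::read.table(bvec_path))
  dimnames(raw) <- NULL
  if (nrow(raw) == 3 && ncol(raw) != 3) {
    bvecs <- t(raw)
  } else if (ncol(raw) == 3) {
    bvecs <- raw
  } else if (nrow(raw) == 3) {      # 3 x 3: assume FSL rows-are-axes dialect
    bvecs <- t(raw)
  } else stop("cannot interpret bvec file shape ", nrow(raw), " x ", ncol(raw))
  gradient_table(bvals, bvecs)
}

# ---- DWI volume -------------------------------------------------------------

#' Construct a diffusion-weighted volume
#'
#' @param data 4-D array of nonnegative signal intensities (x, y, z, volume).
#' @param voxel_size_mm length-3 voxel dimensions in mm.
#' @param affine 4x4 voxel-to-world transform; must be invertible.
#' @param gradients a [gradient_table()] whose length matches the 4th dimension.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size_mm, affine, gradients) {
  stopifnot(length(dim(data)) == 4, inherits(gradients, "gradient_table"))
  if (dim(data)[4] != length(gradients$bvals))
    stop("count mismatch: ", dim(data)[4], " volumes vs ",
         length(gradients$bvals), " gradient entries")
  if (any(data < 0)) stop("DWI signal must be nonnegative")
  d <- try(det(affine), silent = TRUE)
  if (inherits(d, "try-error") || !is.finite(d) || abs(d) < 1e-12)
    stop("affine is not invertible")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine, gradients = gradients),
            class = "dwi_volume")
}

#' Read a DWI series from NIfTI plus bval/bvec
#'
#' @param image_path 4-D NIfTI file.
#' @param bval_path,bvec_path FSL-style gradient files.
#' @return A validated [dwi_volume()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  gt <- read_gradient_table(bval_path, bvec_path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4) stop("expected a 4-D NIfTI image")
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  dwi_volume(arr, RNifti::pixdim(img)[1:3], aff, gt)
}

#' Write a 3-D or 4-D array as NIfTI with an explicit affine
#'
#' @param data array to write.
#' @param path output file (.nii or .nii.gz).
#' @param voxel_size_mm,affine grid geometry.
#' @export
write_nifti_volume <- function(data, path, voxel_size_mm, affine) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- masks ------------------------------------------------------------------

#' Construct a binary mask on a reference grid
#'
#' @param data 3-D logical (or coercible) array.
#' @param label free-text label (tumor, abnormal_signal, voi_seed, ...).
#' @param voxel_size_mm,affine grid geometry shared with the reference volume.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(data, label, voxel_size_mm, affine) {
  data <- array(as.logical(data), dim(data))
  structure(list(data = data, label = label,
                 voxel_size_mm = as.numeric(voxel_size_mm), affine = affine),
            class = "volume_mask")
}

#' Read a mask NIfTI against a reference volume
#'
#' Nonzero voxels become TRUE. An all-zero mask is accepted with a warning;
#' a grid-shape mismatch is an error.
#'
#' @param path NIfTI file.
#' @param reference a [dwi_volume()] (or any object with `$data` dims and
#'   `$affine`) defining the expected grid.
#' @param label mask label.
#' @export
read_mask <- function(path, reference, label = "other") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  ref_dim <- dim(reference$data)[1:3]
  if (!identical(as.integer(dim(arr)[1:3]), as.integer(ref_dim)))
    stop("mask grid ", paste(dim(arr), collapse = "x"),
         " does not match reference ", paste(ref_dim, collapse = "x"))
  m <- volume_mask(arr != 0, label, reference$voxel_size_mm, reference$affine)
  if (!any(m$data)) warning("mask '", label, "' is empty")
  m
}

# ---- TrackVis TRK streamline I/O -------------------------------------------
#
# Minimal version-2 TRK writer/reader. Points are stored in the TrackVis
# "voxmm" convention: (0-based voxel index + 0.5) * voxel size; the header
# carries the voxel->world affine so world coordinates round-trip.

#' Write streamlines to a TrackVis .trk file
#'
#' @param streamlines list of n x 3 matrices of world-mm points.
#' @param path output path.
#' @param dim,voxel_size_mm,affine reference grid geometry.
#' @export
write_trk <- function(streamlines, path, dim, voxel_size_mm, affine) {
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) c(charToRaw(s), raw(n - nchar(s)))
  writeBin(pad("TRACK", 6), con)                           # id_string
  writeBin(as.integer(dim), con, size = 2)
  writeBin(as.numeric(voxel_size_mm), con, size = 4)
  writeBin(rep(0, 3), con, size = 4)                       # origin
  writeBin(0L, con, size = 2)                              # n_scalars
  writeBin(raw(200), con)                                  # scalar names
  writeBin(0L, con, size = 2)                              # n_properties
  writeBin(raw(200), con)                                  # property names
  writeBin(as.numeric(t(affine)), con, size = 4)           # vox_to_ras, row-major
  writeBin(raw(444), con)                                  # reserved
  writeBin(pad("RAS", 4), con)                             # voxel_order
  writeBin(raw(4), con)                                    # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)             # image orientation
  writeBin(raw(2), con)                                    # pad1
  writeBin(raw(6), con)                                    # invert/swap flags
  writeBin(length(streamlines), con, size = 4)             # n_count
  writeBin(2L, con, size = 4)                              # version
  writeBin(1000L, con, size = 4)                           # hdr_size
  inv <- solve(affine)
  for (sl in streamlines) {
    sl <- matrix(sl, ncol = 3)
    writeBin(nrow(sl), con, size = 4)
    vox <- t(inv %*% rbind(t(sl), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2, voxel_size_mm, `*`)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file written by [write_trk()]
#'
#' @param path .trk file.
#' @return list with `streamlines` (world-mm point matrices), `voxel_size_mm`,
#'   `dim` and `affine`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK")) stop("not a TRK file")
  dims <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  seek(con, 440)
  aff <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) stop("unexpected TRK header size")
  out <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- matrix(readBin(con, "numeric", 3 * np, size = 4), ncol = 3,
                  byrow = TRUE)
    vox <- sweep(pts, 2, vs, `/`) - 0.5
    out[[i]] <- t(aff %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
  }
  list(streamlines = out, voxel_size_mm = vs, dim = dims, affine = aff)
}

# ---- case outputs -----------------------------------------------------------

#' Write the standard per-case file set
#'
#' Streamlines go out as TRK plus a diff-friendly JSON mirror, FA/ADC maps as
#' NIfTI, and the case report as JSON plus a one-row CSV.
#'
#' @param tractogram a `tractogram` (see [run_pt_protocol()]); may be empty.
#' @param maps named list of 3-D arrays (e.g. `fa`, `adc`) on the DWI grid.
#' @param report named list of scalars for the case report.
#' @param out_dir output directory (created if needed).
#' @param grid list with `dim`, `voxel_size_mm`, `affine`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_outputs <- function(tractogram, maps, report, out_dir, grid) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- c(trk = file.path(out_dir, "tract.trk"),
             trk_json = file.path(out_dir, "tract.json"),
             report_json = file.path(out_dir, "report.json"),
             report_csv = file.path(out_dir, "report.csv"))
  sls <- if (is.null(tractogram)) list() else tractogram$streamlines
  write_trk(sls, paths["trk"], grid$dim, grid$voxel_size_mm, grid$affine)
  jsonlite::write_json(lapply(sls, function(m) unname(as.matrix(m))),
                       paths["trk_json"], digits = NA)
  for (nm in names(maps)) {
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    write_nifti_volume(maps[[nm]], p, grid$voxel_size_mm, grid$affine)
    paths[nm] <- p
  }
  report$n_tracks <- length(sls)
  jsonlite::write_json(report, paths["report_json"], auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(report[!vapply(report, is.null, TRUE)]),
                   paths["report_csv"], row.names = FALSE)
  invisible(paths)
}
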