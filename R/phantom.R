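# Digital tensor phantoms with analytic ground truth.
#
# The phantom emulates the clinical acquisition (b = 1000 s/mm^2, 12
# directions + 1 b0, 1.9 x 1.9 x 3 mm voxels, 40+ axial slices) and the
# anatomical situation: a craniocaudal pyramidal-tract-like bundle with a
# gentle S-curve through the internal-capsule corridor of the left
# hemisphere, and an ellipsoidal tumor placed per type that displaces - but
# never encases - the bundle via a smooth radial displacement field. The
# tumor center is placed on the ray from the bundle's Monro-slice point at
# the clock angle the type predicts, so the analytic truth sector equals the
# predicted sector by construction; fitting, tracking and classification all
# intervene before the pipeline recovers it.

# Per-type tumor placement: clock angle (degrees from anterior, toward
# lateral) of the bundle relative to the tumor, center distance r (mm),
# in-plane semi-axis a (mm), craniocaudal semi-axis c (mm).
TUMOR_GEOMETRY <- data.frame(
  type = c("T1", "T2", "T3A", "T3B", "T4A", "T4B", "T5", "T6"),
  theta_deg = c(0, 180, 315, 225, 45, 100, 225, 150),
  r_mm = c(13, 26, 14, 14, 14, 13, 24, 20),
  a_mm = c(10, 10, 10, 10, 10, 9, 10, 10),
  c_mm = c(15, 15, 15, 15, 15, 15, 15, 15))

#' Phantom specification
#'
#' Defaults emulate the clinical acquisition: 96 x 96 x 60 grid at
#' 1.9 x 1.9 x 3 mm, b = 1000 s/mm^2 with 12 diffusion directions plus one
#' b0, Rician noise at SNR 25 (b0). Tumor size and position follow the
#' per-type geometry table; `tumor_radius_mm` overrides the in-plane
#' semi-axis.
#'
#' @param tumor_type one of [tumor_types()].
#' @param grid_dim,voxel_size_mm grid geometry.
#' @param tumor_radius_mm optional in-plane tumor semi-axis override (mm).
#' @param displacement_gain scales the radial displacement amplitude
#'   (1 = default 4 mm at the tumor surface).
#' @param snr per-acquisition Rician signal-to-noise ratio at b0
#'   (`Inf` = noiseless).
#' @param n_averages averaged acquisitions per volume (the clinical protocol
#'   applies five).
#' @param seed integer seed; the phantom and its noise are deterministic
#'   given the seed.
#' @param extent_margin_mm dilation margin of the abnormal-signal extent
#'   ellipsoid beyond the tumor.
#' @param jitter_mm amplitude of the seed-dependent jitter applied to the
#'   tumor center and radius (keeps replicates distinct without leaving the
#'   type's region).
#' @param fa_damping_shell optional list(outer, factor): damp bundle
#'   anisotropy by `factor` within the ellipsoidal shell `rho` in
#'   `[1, outer]` around the tumor (models infiltrative FA reduction; used to
#'   exercise the agreement-gate exclusion pathway).
#' @param bundle_fa,bundle_adc target FA and mean diffusivity (mm^2/s) of the
#'   bundle tensors.
#' @param bundle_radius_mm in-plane tube radius of the bundle.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor_type = "T4A", grid_dim = c(96, 96, 60),
                         voxel_size_mm = c(1.9, 1.9, 3),
                         tumor_radius_mm = NULL, displacement_gain = 1,
                         snr = 25, n_averages = 5, seed = 1,
                         extent_margin_mm = 2,
                         jitter_mm = 0.5, fa_damping_shell = NULL,
                         bundle_fa = 0.7, bundle_adc = 0.7e-3,
                         bundle_radius_mm = 4) {
  stopifnot(tumor_type %in% tumor_types(), snr > 0)
  structure(list(tumor_type = tumor_type, grid_dim = as.integer(grid_dim),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tumor_radius_mm = tumor_radius_mm,
                 displacement_gain = displacement_gain, snr = snr,
                 n_averages = n_averages,
                 seed = as.integer(seed), extent_margin_mm = extent_margin_mm,
                 jitter_mm = jitter_mm, fa_damping_shell = fa_damping_shell,
                 bundle_fa = bundle_fa, bundle_adc = bundle_adc,
                 bundle_radius_mm = bundle_radius_mm),
            class = "phantom_spec")
}

phantom_grid <- function(spec) {
  aff <- diag(4)
  diag(aff)[1:3] <- spec$voxel_size_mm
  list(dim = spec$grid_dim, voxel_size_mm = spec$voxel_size_mm, affine = aff)
}

#' Default acquisition gradient table
#'
#' One b0 plus `n_dirs` directions spread over the hemisphere by a Fibonacci
#' spiral, at the stated b-value.
#'
#' @param bvalue diffusion weighting in s/mm^2.
#' @param n_dirs number of diffusion directions.
#' @export
default_gradient_table <- function(bvalue = 1000, n_dirs = 12) {
  i <- seq_len(n_dirs) - 1
  z <- (i + 0.5) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  gradient_table(c(0, rep(bvalue, n_dirs)),
                 rbind(c(0, 0, 0), cbind(s * cos(phi), s * sin(phi), z)))
}

# Prolate tensor eigenvalues (l1, l2=l3) for a target FA and mean diffusivity.
prolate_eigenvalues <- function(fa, md) {
  # FA = 3 d / sqrt(3 + 6 d^2) with l1 = md (1 + 2d), l2 = l3 = md (1 - d),
  # so d^2 = 3 FA^2 / (9 - 6 FA^2)
  d <- sqrt(3 * fa^2 / (9 - 6 * fa^2))
  c(md * (1 + 2 * d), md * (1 - d), md * (1 - d))
}

# Undisplaced bundle centerline sampled on a fine z grid (world mm).
bundle_centerline <- function(spec, n = 400) {
  zmax <- (spec$grid_dim[3] - 1) * spec$voxel_size_mm[3]
  z <- seq(2 * spec$voxel_size_mm[3], zmax - spec$voxel_size_mm[3],
           length.out = n)
  x0 <- 67.333333; y0 <- 84; z0 <- 90
  cbind(x = x0 + 4 * sin(pi * (z - z0) / 81),
        y = y0 + 3 * sin(2 * pi * (z - z0) / 165),
        z = z)
}

#' Reference anatomy: tensor field, landmarks, undisplaced centerline
#'
#' Background voxels carry isotropic tensors (mean diffusivity
#' 0.7e-3 mm^2/s); the bundle is a craniocaudal tube of prolate tensors
#' (target FA 0.7) aligned to the local tangent. Landmarks (foramen of Monro,
#' anterior-limb vertex, posterior-limb endpoints in the normal hemisphere)
#' sit at fixed world coordinates on the Monro slice; the bundle crosses that
#' slice at the 2/3 point of the posterior limb.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tensor6` (x,y,z,6 array), `landmarks`, `centerline`
#'   (undisplaced, world mm), `grid`, `midline_x`.
#' @export
make_reference_anatomy <- function(spec) {
  grid <- phantom_grid(spec)
  midline_x <- (spec$grid_dim[1] - 1) / 2 * spec$voxel_size_mm[1]
  cl <- bundle_centerline(spec)
  if (any(cl[, 1] < 0 | cl[, 1] > (spec$grid_dim[1] - 1) * spec$voxel_size_mm[1] |
          cl[, 2] < 0 | cl[, 2] > (spec$grid_dim[2] - 1) * spec$voxel_size_mm[2]))
    stop("bundle centerline exits the grid")
  mirror_x <- function(x) 2 * midline_x - x
  landmarks <- axial_landmarks(
    foramen_of_monro = c(midline_x - 1.9, 98, 90),
    anterior_limb_vertex = c(67.5, 104, 90),
    posterior_limb_genu_end = c(mirror_x(70), 102, 90),
    posterior_limb_posterior_end = c(mirror_x(66), 75, 90),
    midline_x = midline_x)
  tensor6 <- background_tensor6(spec)
  tensor6 <- paint_bundle(tensor6, cl, spec, grid)
  list(tensor6 = tensor6, landmarks = landmarks, centerline = cl,
       grid = grid, midline_x = midline_x)
}

background_tensor6 <- function(spec, md = 0.7e-3) {
  t6 <- array(0, c(spec$grid_dim, 6))
  t6[, , , 1:3] <- md
  t6
}

# Paint prolate bundle tensors into the tube around a (possibly displaced)
# centerline. Works slice-wise: the centerline is near-vertical, so its
# in-plane center per axial slice is interpolated in z.
paint_bundle <- function(tensor6, centerline, spec, grid,
                         damp_fun = NULL) {
  ev <- prolate_eigenvalues(spec$bundle_fa, spec$bundle_adc)
  l1 <- ev[1]; l2 <- ev[2]
  d <- spec$grid_dim
  xw <- (seq_len(d[1]) - 1) * spec$voxel_size_mm[1]
  yw <- (seq_len(d[2]) - 1) * spec$voxel_size_mm[2]
  zs <- (seq_len(d[3]) - 1) * spec$voxel_size_mm[3]
  zr <- range(centerline[, 3])
  r2 <- spec$bundle_radius_mm^2
  for (k in seq_len(d[3])) {
    z <- zs[k]
    if (z < zr[1] || z > zr[2]) next
    cx <- stats::approx(centerline[, 3], centerline[, 1], z)$y
    cy <- stats::approx(centerline[, 3], centerline[, 2], z)$y
    # local tangent from the centerline polyline
    i <- which.min(abs(centerline[, 3] - z))
    i0 <- max(1, i - 2); i1 <- min(nrow(centerline), i + 2)
    tg <- centerline[i1, ] - centerline[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    dx2 <- outer((xw - cx)^2, (yw - cy)^2, `+`)
    sel <- which(dx2 <= r2, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    Dloc <- c(l2 + (l1 - l2) * tg[1]^2, l2 + (l1 - l2) * tg[2]^2,
              l2 + (l1 - l2) * tg[3]^2, (l1 - l2) * tg[1] * tg[2],
              (l1 - l2) * tg[1] * tg[3], (l1 - l2) * tg[2] * tg[3])
    if (!is.null(damp_fun)) {
      f <- damp_fun(xw[sel[, 1]], yw[sel[, 2]], z)    # in [0,1], 1 = intact
      md <- (Dloc[1] + Dloc[2] + Dloc[3]) / 3
      iso <- c(md, md, md, 0, 0, 0)
      for (c6 in 1:6)
        tensor6[cbind(sel, k, c6)] <- iso[c6] + f * (Dloc[c6] - iso[c6])
    } else {
      for (c6 in 1:6) tensor6[cbind(sel, k, c6)] <- Dloc[c6]
    }
  }
  tensor6
}

# Ellipsoidal normalized radius of world points relative to a tumor.
ellipsoid_rho <- function(x, y, z, center, a, c_) {
  sqrt(((x - center[1]) / a)^2 + ((y - center[2]) / a)^2 +
       ((z - center[3]) / c_)^2)
}

ellipsoid_mask <- function(center, a, c_, spec, label) {
  d <- spec$grid_dim
  xw <- (seq_len(d[1]) - 1) * spec$voxel_size_mm[1]
  yw <- (seq_len(d[2]) - 1) * spec$voxel_size_mm[2]
  zw <- (seq_len(d[3]) - 1) * spec$voxel_size_mm[3]
  rx <- ((xw - center[1]) / a)^2
  ry <- ((yw - center[2]) / a)^2
  rz <- ((zw - center[3]) / c_)^2
  m <- outer(outer(rx, ry, `+`), rz, `+`) <= 1
  volume_mask(m, label, spec$voxel_size_mm, phantom_grid(spec)$affine)
}

#' Place a tumor of the specified type and displace the bundle
#'
#' The ellipsoidal tumor center lies on the ray from the bundle's Monro-slice
#' point at the type's clock angle, inside the region the three lines dictate
#' for that type. The bundle centerline is pushed radially outward by a
#' smooth displacement field decaying with ellipsoidal distance; an error is
#' raised if the displaced centerline does not clear the tumor surface by at
#' least one voxel.
#'
#' @param spec a [phantom_spec()].
#' @param anatomy result of [make_reference_anatomy()].
#' @return list with `tumor_mask`, `extent_mask`, `center`, `theta_deg`,
#'   `a_mm`, `c_mm`, `displaced_centerline`, `displace` (the displacement
#'   function, world points -> world points).
#' @export
place_tumor <- function(spec, anatomy) {
  geo <- TUMOR_GEOMETRY[TUMOR_GEOMETRY$type == spec$tumor_type, ]
  a <- if (!is.null(spec$tumor_radius_mm)) spec$tumor_radius_mm else geo$a_mm
  c_ <- geo$c_mm
  # seed-dependent jitter, kept small enough to stay inside the type's region
  jit <- local_rng(spec$seed * 1009L + 17L, {
    stats::runif(3, -1, 1) * c(spec$jitter_mm, spec$jitter_mm, 0.6)
  })
  a <- a + jit[3]
  theta <- geo$theta_deg
  u <- c(-sin(theta * pi / 180), cos(theta * pi / 180))   # x,y of clock dir
  pt0 <- stats::approx(anatomy$centerline[, 3], anatomy$centerline[, 1], 90)$y
  pt0 <- c(pt0, stats::approx(anatomy$centerline[, 3],
                              anatomy$centerline[, 2], 90)$y)
  center <- c(pt0 - geo$r_mm * u + jit[1:2], 90)
  amp <- 4 * spec$displacement_gain
  tau <- 0.6
  displace <- function(pts) {
    rho <- ellipsoid_rho(pts[, 1], pts[, 2], pts[, 3], center, a, c_)
    g <- amp * exp(-pmax(0, rho - 1) / tau)
    dvec <- sweep(pts, 2, center, `-`)
    nrm <- sqrt(rowSums(dvec^2))
    pts + dvec / pmax(nrm, 1e-9) * g
  }
  dcl <- displace(anatomy$centerline)
  rho_d <- ellipsoid_rho(dcl[, 1], dcl[, 2], dcl[, 3], center, a, c_)
  clearance <- (min(rho_d) - 1) * min(a, c_)
  if (clearance < min(spec$voxel_size_mm))
    stop("tumor would not clear the displaced bundle by one voxel (type ",
         spec$tumor_type, ", clearance ", round(clearance, 2), " mm)")
  list(tumor_mask = ellipsoid_mask(center, a, c_, spec, "tumor"),
       extent_mask = ellipsoid_mask(center, a + spec$extent_margin_mm,
                                    c_ + spec$extent_margin_mm, spec,
                                    "abnormal_signal"),
       center = center, theta_deg = theta, a_mm = a, c_mm = c_,
       displaced_centerline = dcl, displace = displace)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Simulate the diffusion-weighted signal from a tensor field
#'
#' Noiseless signal `S = S0 * exp(-b g' D g)` per voxel and volume, with
#' Rician noise of scale `S0 / snr` applied deterministically under the seed.
#' The clinical protocol acquires five signal averages; `n_averages` draws
#' that many independent Rician realizations and stores their mean.
#'
#' @param tensor6 x,y,z,6 tensor component array (xx, yy, zz, xy, xz, yz).
#' @param grid list with `dim`, `voxel_size_mm`, `affine`.
#' @param gradients a [gradient_table()].
#' @param s0 b0 signal level.
#' @param snr per-acquisition Rician SNR at b0 (`Inf` = noiseless).
#' @param seed integer seed for the noise.
#' @param n_averages number of averaged acquisitions.
#' @return A [dwi_volume()].
#' @export
simulate_dwi <- function(tensor6, grid, gradients = default_gradient_table(),
                         s0 = 1000, snr = 25, seed = 1, n_averages = 1) {
  stopifnot(snr > 0)
  d <- dim(tensor6)[1:3]
  nvox <- prod(d)
  t6 <- matrix(tensor6, nvox, 6)
  nvol <- length(gradients$bvals)
  data <- array(0, c(d, nvol))
  for (j in seq_len(nvol)) {
    b <- gradients$bvals[j]
    g <- gradients$bvecs[j, ]
    q <- b * c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
               2 * g[2] * g[3])
    data[, , , j] <- s0 * exp(-as.numeric(t6 %*% q))
  }
  if (is.finite(snr)) {
    sigma <- s0 / snr
    data <- local_rng(seed, {
      acc <- array(0, dim(data))
      for (av in seq_len(n_averages)) {
        n1 <- stats::rnorm(length(data), 0, sigma)
        n2 <- stats::rnorm(length(data), 0, sigma)
        acc <- acc + sqrt((data + n1)^2 + n2^2)
      }
      acc / n_averages
    })
  }
  dwi_volume(data, grid$voxel_size_mm, grid$affine, gradients)
}

#' Analytic ground-truth clock sector of a phantom
#'
#' Sector of the displaced centerline's Monro-slice point relative to the
#' tumor centroid on that slice, via [clock_sector_of()].
#'
#' @param tumor_mask tumor `volume_mask`.
#' @param displaced_centerline n x 3 world-mm polyline.
#' @param landmarks an [axial_landmarks()].
#' @param grid grid list.
#' @export
truth_sector <- function(tumor_mask, displaced_centerline, landmarks, grid) {
  k <- monro_axial_slice(landmarks, grid)
  zc <- voxel_to_world(c(0, 0, k), grid$affine)[3]
  zr <- range(displaced_centerline[, 3])
  if (zc < zr[1] || zc > zr[2]) stop("centerline does not cross the Monro slice")
  px <- stats::approx(displaced_centerline[, 3], displaced_centerline[, 1], zc)$y
  py <- stats::approx(displaced_centerline[, 3], displaced_centerline[, 2], zc)$y
  clock_sector_of(c(px, py), mask_slice_centroid(tumor_mask, k),
                  anatomy_frame("left"))
}

# Box VOI around the displaced bundle over a range of axial slices.
box_voi <- function(dcl, slices, half_mm, spec, label) {
  d <- spec$grid_dim
  xw <- (seq_len(d[1]) - 1) * spec$voxel_size_mm[1]
  yw <- (seq_len(d[2]) - 1) * spec$voxel_size_mm[2]
  m <- array(FALSE, d)
  for (k in slices) {
    z <- k * spec$voxel_size_mm[3]
    cx <- stats::approx(dcl[, 3], dcl[, 1], z, rule = 2)$y
    cy <- stats::approx(dcl[, 3], dcl[, 2], z, rule = 2)$y
    m[, , k + 1] <- outer(abs(xw - cx) <= half_mm, abs(yw - cy) <= half_mm,
                          `&`)
  }
  volume_mask(m, label, spec$voxel_size_mm, phantom_grid(spec)$affine)
}

#' Generate a complete phantom case
#'
#' Assembles the reference anatomy, places the tumor, displaces and repaints
#' the bundle, simulates the noisy DWI, and derives the VOI set and analytic
#' truth.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `spec`, `dwi`,
#'   `grid`, `landmarks`, `midline_x`, `tumor_mask`, `extent_mask`, `vois`
#'   (a [voi_set()]), and `truth` (centerlines, true type/sector, tumor
#'   center).
#' @export
make_phantom_case <- function(spec) {
  anatomy <- make_reference_anatomy(spec)
  tum <- place_tumor(spec, anatomy)
  damp_fun <- NULL
  if (!is.null(spec$fa_damping_shell)) {
    sh <- spec$fa_damping_shell
    damp_fun <- function(x, y, z) {
      rho <- ellipsoid_rho(x, y, z, tum$center, tum$a_mm, tum$c_mm)
      ifelse(rho >= 1 & rho <= sh$outer, sh$factor, 1)
    }
  }
  tensor6 <- background_tensor6(spec)
  tensor6 <- paint_bundle(tensor6, tum$displaced_centerline, spec,
                          anatomy$grid, damp_fun = damp_fun)
  # tumor voxels: isotropic, slightly elevated diffusivity
  tmask <- tum$tumor_mask$data
  nvox <- prod(spec$grid_dim)
  for (c6 in 1:6)
    tensor6[which(tmask) + (c6 - 1) * nvox] <- if (c6 <= 3) 1.0e-3 else 0
  dwi <- simulate_dwi(tensor6, anatomy$grid, default_gradient_table(),
                      s0 = 1000, snr = spec$snr, seed = spec$seed,
                      n_averages = spec$n_averages)
  dcl <- tum$displaced_centerline
  vois <- voi_set(
    seed = box_voi(dcl, 28:32, 4, spec, "voi_seed"),
    include_precentral = box_voi(dcl, 53:56, 8, spec, "voi_precentral"),
    include_peduncle = box_voi(dcl, 3:6, 8, spec, "voi_peduncle"))
  truth <- list(
    bundle_centerline = dcl,
    undisplaced_centerline = anatomy$centerline,
    true_type = spec$tumor_type,
    true_sector = truth_sector(tum$tumor_mask, dcl, anatomy$landmarks,
                               anatomy$grid),
    tumor_center = tum$center, theta_deg = tum$theta_deg)
  structure(list(spec = spec, dwi = dwi, grid = anatomy$grid,
                 landmarks = anatomy$landmarks, midline_x = anatomy$midline_x,
                 tumor_mask = tum$tumor_mask, extent_mask = tum$extent_mask,
                 vois = vois, truth = truth),
            class = "phantom_case")
}

#' Write a phantom case to a directory of standard files
#'
#' DWI as NIfTI with FSL-style bval/bvec, masks and VOIs as NIfTI, landmarks
#' as JSON, truth as JSON.
#'
#' @param case a `phantom_case`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- case$grid
  write_nifti_volume(case$dwi$data, file.path(dir, "dwi.nii.gz"),
                     g$voxel_size_mm, g$affine)
  gt <- case$dwi$gradients
  writeLines(paste(gt$bvals, collapse = " "), file.path(dir, "dwi.bval"))
  # FSL layout: three rows (x, y, z), one column per volume
  write(gt$bvecs, file.path(dir, "dwi.bvec"), ncolumns = nrow(gt$bvecs))
  masks <- list(tumor = case$tumor_mask, abnormal_signal = case$extent_mask,
                voi_seed = case$vois$seed,
                voi_precentral = case$vois$include_precentral,
                voi_peduncle = case$vois$include_peduncle)
  for (nm in names(masks))
    write_nifti_volume(masks[[nm]]$data * 1L,
                       file.path(dir, paste0(nm, ".nii.gz")),
                       g$voxel_size_mm, g$affine)
  lm <- case$landmarks
  jsonlite::write_json(
    list(foramen_of_monro = lm$foramen_of_monro,
         anterior_limb_vertex = lm$anterior_limb_vertex,
         posterior_limb_genu_end = lm$posterior_limb_genu_end,
         posterior_limb_posterior_end = lm$posterior_limb_posterior_end,
         midline_x = lm$midline_x),
    file.path(dir, "landmarks.json"), digits = NA)
  jsonlite::write_json(
    list(true_type = case$truth$true_type,
         true_sector = case$truth$true_sector,
         tumor_center = case$truth$tumor_center,
         seed = case$spec$seed, snr = case$spec$snr),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a phantom case directory written by [write_phantom_case()]
#'
#' @param dir case directory.
#' @return A `phantom_case`-like list sufficient for [run_case()] (without
#'   the generator-only truth centerlines).
#' @export
read_phantom_case <- function(dir) {
  need <- c("dwi.nii.gz", "dwi.bval", "dwi.bvec")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("ingest: case directory is missing ", paste(missing, collapse = ", "))
  dwi <- read_dwi(file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"),
                  file.path(dir, "dwi.bvec"))
  grid <- list(dim = dim(dwi$data)[1:3], voxel_size_mm = dwi$voxel_size_mm,
               affine = dwi$affine)
  lm <- jsonlite::read_json(file.path(dir, "landmarks.json"),
                            simplifyVector = TRUE)
  landmarks <- axial_landmarks(lm$foramen_of_monro, lm$anterior_limb_vertex,
                               lm$posterior_limb_genu_end,
                               lm$posterior_limb_posterior_end, lm$midline_x)
  rd <- function(nm, lab) read_mask(file.path(dir, paste0(nm, ".nii.gz")),
                                    dwi, lab)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(dwi = dwi, grid = grid, landmarks = landmarks,
                 midline_x = lm$midline_x,
                 tumor_mask = rd("tumor", "tumor"),
                 extent_mask = rd("abnormal_signal", "abnormal_signal"),
                 vois = voi_set(rd("voi_seed", "voi_seed"),
                                rd("voi_precentral", "voi_precentral"),
                                rd("voi_peduncle", "voi_peduncle")),
                 truth = truth),
            class = "phantom_case")
}
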