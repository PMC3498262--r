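# Independent oracles and small fixture builders shared across tests.

# Build a tensor_field object directly from a function tensor_fun(x, y, z)
# returning the 6 components (xx, yy, zz, xy, xz, yz) at a world point.
# Voxel (i,j,k) [0-based] sits at world (i,j,k) * voxel_size.
make_field <- function(dim, voxel_size, tensor_fun) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  t6 <- array(0, c(dim, 6))
  xw <- (seq_len(dim[1]) - 1) * voxel_size[1]
  yw <- (seq_len(dim[2]) - 1) * voxel_size[2]
  zw <- (seq_len(dim[3]) - 1) * voxel_size[3]
  for (k in seq_len(dim[3])) for (j in seq_len(dim[2])) {
    comp <- tensor_fun(xw, yw[j], zw[k])     # 6 x nx or length 6
    if (is.null(dim(comp))) comp <- matrix(comp, 6, dim[1])
    for (c6 in 1:6) t6[, j, k, c6] <- comp[c6, ]
  }
  es <- ptclock::tensor_eigen(t(matrix(t6, ncol = 6)))
  field <- list(tensor = t6,
                eigenvalues = array(t(es$values), c(dim, 3)),
                e1 = array(t(es$e1), c(dim, 3)),
                fa = array(ptclock::compute_fa(es$values), dim),
                adc = array(ptclock::compute_adc(es$values), dim),
                mask = array(TRUE, dim), voxel_size_mm = voxel_size,
                affine = aff)
  class(field) <- "tensor_field"
  field
}

# 6-component prolate tensor along unit direction t.
prolate6 <- function(tg, l1 = 1.4e-3, l2 = 0.35e-3) {
  c(l2 + (l1 - l2) * tg[1]^2, l2 + (l1 - l2) * tg[2]^2,
    l2 + (l1 - l2) * tg[3]^2, (l1 - l2) * tg[1] * tg[2],
    (l1 - l2) * tg[1] * tg[3], (l1 - l2) * tg[2] * tg[3])
}

# --- independent reference integrator (pure R) -------------------------------
# Trilinear interpolation of tensor components, base eigen(), and the same
# deflection update, marched at a finer step. Written independently of the
# package's C++ propagator.
ref_interp6 <- function(t6, p) {
  d <- dim(t6)[1:3]
  f <- floor(p); r <- p - f
  i0 <- pmin(pmax(f, 0), d - 1); i1 <- pmin(i0 + 1, d - 1)
  out <- numeric(6)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, r, 1 - r))
    if (w == 0) next
    ii <- ifelse(c(dx, dy, dz) == 1, i1, i0) + 1
    out <- out + w * t6[ii[1], ii[2], ii[3], ]
  }
  out
}

ref_eig <- function(t6c) {
  D <- matrix(c(t6c[1], t6c[4], t6c[5],
                t6c[4], t6c[2], t6c[6],
                t6c[5], t6c[6], t6c[3]), 3, 3)
  es <- eigen(D, symmetric = TRUE)
  list(values = es$values, e1 = es$vectors[, 1])
}

ref_fa <- function(l) {
  l <- pmax(l, 0)
  if (sum(l^2) <= 0) return(0)
  sqrt(1.5 * sum((l - mean(l))^2) / sum(l^2))
}

# Reference streamline: bidirectional march at step_mm / refine.
ref_track <- function(field, seed_world, params = ptclock::tracking_params(),
                      refine = 10, max_steps = 50000) {
  vs <- field$voxel_size_mm
  d <- dim(field$fa)
  step <- params$step_fraction_of_voxel * min(vs) / refine
  seed_vox <- seed_world / vs
  e0 <- ref_eig(ref_interp6(field$tensor, seed_vox))
  if (ref_fa(e0$values) < params$fa_threshold)
    return(matrix(numeric(0), 0, 3))
  one_dir <- function(v0) {
    p <- seed_vox; v <- v0
    pts <- list()
    cos_thr <- cos(params$angle_threshold_deg * pi / 180)
    for (s in seq_len(max_steps)) {
      pn <- p + step * v / vs
      if (any(pn < 0) || any(pn > d - 1)) break
      e <- ref_eig(ref_interp6(field$tensor, pn))
      if (ref_fa(e$values) < params$fa_threshold) break
      e1 <- e$e1
      if (sum(v * e1) < 0) e1 <- -e1
      vn <- params$weight_prev * v + params$weight_new * e1
      vn <- vn / sqrt(sum(vn^2))
      if (sum(v * vn) < cos_thr) break
      pts[[length(pts) + 1]] <- pn
      p <- pn; v <- vn
    }
    if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)
  }
  fwd <- one_dir(e0$e1)
  bwd <- one_dir(-e0$e1)
  vox <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed_vox, 1, 3), fwd)
  sweep(vox, 2, vs, `*`)
}

# Symmetric Hausdorff distance between two point sets (n x 3, m x 3).
hausdorff <- function(A, B) {
  dmin <- function(P, Q) {
    max(apply(P, 1, function(p)
      sqrt(min(colSums((t(Q) - p)^2)))))
  }
  max(dmin(A, B), dmin(B, A))
}

# Per-step turning angles (degrees) along a polyline.
step_angles <- function(pts) {
  v <- diff(pts)
  v <- v / sqrt(rowSums(v^2))
  if (nrow(v) < 2) return(numeric(0))
  d <- rowSums(v[-nrow(v), , drop = FALSE] * v[-1, , drop = FALSE])
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

# Smooth curved test field: tangent rotating in the x-z plane as a function
# of z, parameters drawn from the supplied seed.
random_smooth_field <- function(seed, dim = c(40, 40, 40), voxel = c(1, 1, 1)) {
  set.seed(seed)
  th0 <- stats::runif(1, -20, 20)
  rate <- stats::runif(1, 2, 5)          # degrees of tangent rotation per mm
  make_field(dim, voxel, function(xv, y, z) {
    th <- (th0 + rate * z) * pi / 180
    tg <- c(sin(th), 0, cos(th))
    matrix(prolate6(tg), 6, length(xv))
  })
}
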