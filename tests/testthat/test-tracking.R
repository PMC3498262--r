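test_that("deflection blends 20/80 with sign alignment", {
  p <- tracking_params()
  expect_equal(deflect_direction(c(1, 0, 0), c(1, 0, 0), p), c(1, 0, 0))
  # eigenvector sign ambiguity: antiparallel e1 is flipped
  expect_equal(deflect_direction(c(1, 0, 0), c(-1, 0, 0), p), c(1, 0, 0))
  # orthogonal e1: direct arithmetic oracle
  v <- deflect_direction(c(1, 0, 0), c(0, 1, 0), p)
  expect_equal(v, c(0.2, 0.8, 0) / sqrt(0.2^2 + 0.8^2))
  ang <- acos(sum(v * c(1, 0, 0))) * 180 / pi
  expect_equal(ang, atan(0.8 / 0.2) * 180 / pi, tolerance = 1e-10)
  expect_gt(ang, 30)  # the 30-degree rule terminates this step
  expect_error(tracking_params(weight_prev = 0.3, weight_new = 0.8),
               "equal 1")
})

test_that("uniform field gives a straight, volume-spanning, equal-step line", {
  field <- make_field(c(12, 12, 30), c(2, 2, 2),
                      function(x, y, z) matrix(prolate6(c(0, 0, 1)), 6,
                                               length(x)))
  sl <- propagate_streamline(field, c(11, 11, 29))
  expect_s3_class(sl, "streamline")
  # straight in x, y
  expect_lt(max(abs(sl[, 1] - 11)), 1e-9)
  expect_lt(max(abs(sl[, 2] - 11)), 1e-9)
  # spans the volume in z
  expect_lt(min(sl[, 3]), 1)
  expect_gt(max(sl[, 3]), 57)
  # consecutive steps equal the configured step within 1e-6
  steps <- sqrt(rowSums(diff(sl)^2))
  expect_lt(max(abs(steps - 2 / 3)), 1e-6)
  expect_equal(max(step_angles(sl)), 0, tolerance = 1e-9)
  # bidirectional: seed is interior to the polyline, not an endpoint
  seed_row <- which.min(rowSums(sweep(sl, 2, c(11, 11, 29))^2))
  expect_gt(seed_row, 1)
  expect_lt(seed_row, nrow(sl))
})

test_that("a sub-threshold FA slab stops the march at its boundary", {
  field <- make_field(c(12, 12, 30), c(2, 2, 2), function(x, y, z) {
    t6 <- prolate6(c(0, 0, 1))
    if (z >= 40) t6 <- prolate6(c(0, 0, 1), l1 = 0.75e-3, l2 = 0.68e-3)
    matrix(t6, 6, length(x))  # slab FA ~ 0.05 < 0.2
  })
  expect_lt(max(compute_fa(field$eigenvalues[6, 6, 25, ]), 0), 0.2)
  sl <- propagate_streamline(field, c(11, 11, 20))
  expect_lt(max(sl[, 3]), 40.5)  # never crosses into the slab
  expect_gt(max(sl[, 3]), 37)    # but reaches its boundary
  # sub-threshold seed yields an empty result with a reason code
  empty <- propagate_streamline(field, c(11, 11, 50))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "reason"), "seed_below_fa")
})

test_that("curved fields match a 10x-finer reference integrator", {
  for (seed in c(11, 23)) {
    field <- random_smooth_field(seed)
    seed_pt <- c(19, 19, 19)
    sl <- propagate_streamline(field, seed_pt)
    ref <- ref_track(field, seed_pt, refine = 10)
    expect_gt(nrow(sl), 30)
    expect_lt(hausdorff(sl, ref), 1)  # within one (1 mm) voxel
    # post-hoc audit: every step within the angular threshold
    expect_lt(max(step_angles(sl)), 30)
  }
})

test_that("three-VOI protocol retains the bundle and rejects violators", {
  vs <- c(2, 2, 2)
  dimg <- c(16, 16, 40)
  field <- make_field(dimg, vs, function(x, y, z) {
    # craniocaudal bundle at x,y ~ 15 +/- 4 mm; transverse bundle at z ~ 50
    out <- matrix(c(7e-4, 7e-4, 7e-4, 0, 0, 0), 6, length(x))
    sel <- abs(x - 15) <= 4
    out[, sel] <- prolate6(c(0, 0, 1))
    if (abs(z - 50) <= 2) out[, !sel] <- prolate6(c(1, 0, 0))
    if (abs(y - 15) > 4) out[] <- c(7e-4, 7e-4, 7e-4, 0, 0, 0)
    out
  })
  grid <- list(dim = dimg, voxel_size_mm = vs, affine = field$affine)
  boxmask <- function(xr, yr, zr, label) {
    m <- array(FALSE, dimg)
    xw <- (seq_len(dimg[1]) - 1) * vs[1]
    yw <- (seq_len(dimg[2]) - 1) * vs[2]
    zw <- (seq_len(dimg[3]) - 1) * vs[3]
    m[xw >= xr[1] & xw <= xr[2],
      yw >= yr[1] & yw <= yr[2],
      zw >= zr[1] & zw <= zr[2]] <- TRUE
    volume_mask(m, label, vs, field$affine)
  }
  vois <- voi_set(seed = boxmask(c(13, 17), c(13, 17), c(38, 42), "voi_seed"),
                  include_precentral = boxmask(c(9, 21), c(9, 21), c(70, 76),
                                               "voi_precentral"),
                  include_peduncle = boxmask(c(9, 21), c(9, 21), c(2, 8),
                                             "voi_peduncle"))
  tr <- run_pt_protocol(field, vois)
  expect_gt(length(tr$streamlines), 0)
  expect_true(all(tr$provenance$status[tr$provenance$status != "empty"] %in%
                  c("retained", "failed_precentral", "failed_peduncle",
                    "failed_peduncle_orientation", "failed_exclude",
                    "failed_length")))
  # every retained streamline satisfies the length rule and the audit sweep
  for (sl in tr$streamlines) {
    expect_gte(sum(sqrt(rowSums(diff(sl)^2))), 50)
    expect_lt(max(step_angles(sl)), 30)
  }
  # an exclusion mask across the corridor discards everything
  vois_x <- voi_set(vois$seed, vois$include_precentral, vois$include_peduncle,
                    excludes = list(boxmask(c(9, 21), c(9, 21), c(20, 24),
                                            "exclude")))
  tr_x <- run_pt_protocol(field, vois_x)
  expect_length(tr_x$streamlines, 0)
  expect_true(any(tr_x$provenance$status == "failed_exclude"))
  # a transverse fiber in the peduncle VOI fails the craniocaudal test
  vois_t <- voi_set(boxmask(c(21, 27), c(13, 17), c(48, 52), "voi_seed"),
                    boxmask(c(0, 30), c(9, 21), c(48, 52), "voi_precentral"),
                    boxmask(c(0, 30), c(9, 21), c(48, 52), "voi_peduncle"))
  tr_t <- run_pt_protocol(field, vois_t)
  expect_length(tr_t$streamlines, 0)
  expect_true(any(tr_t$provenance$status %in%
                  c("failed_peduncle_orientation", "failed_length")))
})

test_that("cross-section collects in-slab points and their centroid", {
  grid <- list(dim = c(16L, 16L, 40L), voxel_size_mm = c(2, 2, 2),
               affine = diag(c(2, 2, 2, 1)))
  vert <- function(x, y) cbind(x, y, seq(0, 78, by = 0.5))
  cs <- cross_section(list(streamlines = list(vert(10, 14))), 20, grid)
  expect_equal(sum(cs$mask), 1)
  expect_equal(cs$centroid[1:2], c(10, 14))
  # two parallel streamlines 4 mm apart: centroid at the midpoint
  cs2 <- cross_section(list(streamlines = list(vert(8, 14), vert(12, 14))),
                       20, grid)
  expect_equal(cs2$centroid[1:2], c(10, 14))
  # oblique streamline: brute-force point-filter oracle
  obl <- cbind(seq(0, 30, by = 0.11), 14, seq(0, 78, length.out = 273))
  cs3 <- cross_section(list(streamlines = list(obl)), 20, grid)
  sel <- abs(obl[, 3] - 40) <= 1
  expect_equal(cs3$centroid, colMeans(obl[sel, , drop = FALSE]))
  expect_equal(cs3$n_points, sum(sel))
  # no points in slab: explicit null centroid
  cs4 <- cross_section(list(streamlines = list(obl[1:10, ])), 39, grid)
  expect_null(cs4$centroid)
})
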