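# Small-grid helpers: 40 x 40 x 5 at 1 mm, Monro slice k = 2, left frame with
# the midline far to the right so all geometry is "left hemisphere".
tiny_grid <- function() {
  list(dim = c(40L, 40L, 5L), voxel_size_mm = c(1, 1, 1), affine = diag(4))
}

blob_mask <- function(xr, yr, grid = tiny_grid(), k = 2) {
  m <- array(FALSE, grid$dim)
  m[xr[1]:xr[2] + 1, yr[1]:yr[2] + 1, k + 1] <- TRUE
  volume_mask(m, "tumor", grid$voxel_size_mm, grid$affine)
}

tiny_lines <- function() {
  lm <- axial_landmarks(foramen_of_monro = c(30, 20, 2),
                        anterior_limb_vertex = c(15, 24, 2),
                        posterior_limb_genu_end = c(46, 22, 2),
                        posterior_limb_posterior_end = c(52, 4, 2),
                        midline_x = 35)
  build_reference_lines(lm)   # line1_x = 15, line2_y = 20, line3_y = 10
}

test_that("quadrant areas match a brute-force per-voxel classification", {
  lines <- tiny_lines()
  # square wholly posterior-lateral
  ar <- quadrant_areas(blob_mask(c(2, 9), c(2, 9)), lines, 2)
  expect_equal(ar$posterior_lateral, 64)
  expect_equal(ar$anterior_medial + ar$anterior_lateral + ar$posterior_medial,
               0)
  expect_equal(ar$total, 64)
  # symmetric about line 1: medial and lateral halves equal
  ar2 <- quadrant_areas(blob_mask(c(12, 19), c(2, 9)), lines, 2)
  expect_equal(ar2$posterior_lateral, ar2$posterior_medial)
  # random blobs against a per-voxel oracle
  set.seed(99)
  for (rep in 1:20) {
    g <- tiny_grid()
    m <- array(FALSE, g$dim)
    m[, , 3] <- matrix(runif(1600) < 0.3, 40, 40)
    mask <- volume_mask(m, "tumor", g$voxel_size_mm, g$affine)
    ar3 <- quadrant_areas(mask, lines, 2)
    cnt <- c(am = 0, al = 0, pm = 0, pl = 0, b3 = 0, b23 = 0)
    for (i in 0:39) for (j in 0:39) if (m[i + 1, j + 1, 3]) {
      lat <- i <= lines$line1_x; post <- j <= lines$line2_y
      if (!post && !lat) cnt["am"] <- cnt["am"] + 1
      if (!post && lat) cnt["al"] <- cnt["al"] + 1
      if (post && !lat) cnt["pm"] <- cnt["pm"] + 1
      if (post && lat) cnt["pl"] <- cnt["pl"] + 1
      if (post && j <= lines$line3_y) cnt["b3"] <- cnt["b3"] + 1
      if (post && j > lines$line3_y) cnt["b23"] <- cnt["b23"] + 1
    }
    expect_equal(with(ar3, c(anterior_medial, anterior_lateral,
                             posterior_medial, posterior_lateral,
                             beyond_line3, between_lines_2_3)),
                 unname(cnt))
    expect_equal(ar3$total, sum(cnt[1:4]))
  }
  # empty on the slice
  expect_error(quadrant_areas(blob_mask(c(2, 9), c(2, 9), k = 2), lines, 4),
               "empty")
})

test_that("classification follows the centered and majority rules", {
  lines <- tiny_lines()
  # centered on line 1, mass posterior to line 2 -> T1
  expect_equal(as.character(classify_tumor(blob_mask(c(11, 19), c(4, 16)),
                                           lines, 2)), "T1")
  # centered, mass anterior -> T2
  expect_equal(as.character(classify_tumor(blob_mask(c(11, 19), c(22, 34)),
                                           lines, 2)), "T2")
  # posterior-lateral, majority beyond line 3 -> T3A
  expect_equal(as.character(classify_tumor(blob_mask(c(2, 9), c(2, 12)),
                                           lines, 2)), "T3A")
  # posterior-lateral, majority between lines 2 and 3 -> T3B
  expect_equal(as.character(classify_tumor(blob_mask(c(2, 9), c(9, 19)),
                                           lines, 2)), "T3B")
  # 30/70 split across the posterior quadrants -> majority (medial) wins
  m70 <- blob_mask(c(13, 22), c(2, 8))    # 3 lateral cols, 7 medial cols
  expect_equal(as.character(classify_tumor(m70, lines, 2)), "T4A")
  # anterior-lateral -> T5; anterior-medial -> T6
  expect_equal(as.character(classify_tumor(blob_mask(c(2, 9), c(24, 34)),
                                           lines, 2)), "T5")
  expect_equal(as.character(classify_tumor(blob_mask(c(22, 30), c(24, 34)),
                                           lines, 2)), "T6")
  # exact 50/50 -> error demanding adjudication
  expect_error(classify_tumor(blob_mask(c(2, 9), c(13, 28)), lines, 2),
               "tie")
})

test_that("small enhancing cores defer to the abnormal-signal extent", {
  lines <- tiny_lines()
  extent <- blob_mask(c(2, 13), c(2, 16))       # posterior-lateral extent
  core <- blob_mask(c(12, 13), c(14, 16))       # tiny medial core, < 50%
  with_ext <- classify_tumor(core, lines, 2, extent_mask = extent)
  expect_true(attr(with_ext, "used_extent"))
  expect_equal(as.character(with_ext), "T3A")
  # a core covering most of the extent keeps its own shape
  big_core <- blob_mask(c(2, 13), c(2, 14))
  no_ext <- classify_tumor(big_core, lines, 2, extent_mask = extent)
  expect_false(attr(no_ext, "used_extent"))
})

test_that("classification agrees with a brute-force reimplementation", {
  lines <- tiny_lines()
  set.seed(7)
  brute <- function(mask, k = 2) {
    idx <- which(mask$data[, , k + 1], arr.ind = TRUE) - 1
    x <- idx[, 1]; y <- idx[, 2]
    width <- diff(range(x)) + 1
    post <- y <= lines$line2_y
    lat <- x <= lines$line1_x
    if (abs(mean(x) - lines$line1_x) <= 0.15 * width)
      return(if (sum(post) > sum(!post)) "T1" else "T2")
    counts <- c(pl = sum(post & lat), pm = sum(post & !lat),
                al = sum(!post & lat), am = sum(!post & !lat))
    best <- names(which.max(counts))
    a_side <- sum(post & y <= lines$line3_y) > sum(post & y > lines$line3_y)
    switch(best, pl = if (a_side) "T3A" else "T3B",
           pm = if (a_side) "T4A" else "T4B", al = "T5", am = "T6")
  }
  n_match <- 0
  for (rep in 1:1000) {
    cx <- sample(3:32, 1); cy <- sample(3:32, 1)
    w <- sample(2:6, 1); h <- sample(2:6, 1)
    mask <- blob_mask(c(max(0, cx - w), min(39, cx + w)),
                      c(max(0, cy - h), min(39, cy + h)))
    got <- try(classify_tumor(mask, lines, 2), silent = TRUE)
    want <- try(brute(mask), silent = TRUE)
    if (inherits(got, "try-error")) {
      expect_true(inherits(want, "try-error") ||
                  grepl("tie", attr(got, "condition")$message))
    } else {
      expect_equal(as.character(got), want)
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 800)
})

test_that("the prediction lookup is total and rejects unknown types", {
  expect_length(predict_sector(tumor_types()), 8)
  expect_true(all(predict_sector(tumor_types()) %in% clock_sectors()))
  expect_error(predict_sector("T7"), "unknown")
})

test_that("observed sector reduces to the clock angle of the centroids", {
  grid <- tiny_grid()
  tumor <- blob_mask(c(10, 20), c(10, 20))
  cen <- mask_slice_centroid(tumor, 2)
  expect_equal(observed_sector(cen + c(0, 5), tumor, 2), "12")
  th <- 225 * pi / 180                     # postero-medial, 6-9 o'clock
  off <- 6 * c(-sin(th), cos(th))          # anterior = +y, lateral = -x
  expect_equal(observed_sector(cen + off, tumor, 2), "6-9")
  expect_null(observed_sector(NULL, tumor, 2))
})

test_that("classification is invariant under hemisphere mirroring", {
  # a left-hemisphere phantom tumor and its right-sided twin
  spec <- phantom_spec("T3B", seed = 3)
  anatomy <- make_reference_anatomy(spec)
  tum <- place_tumor(spec, anatomy)
  lines <- build_reference_lines(anatomy$landmarks)
  k <- monro_axial_slice(anatomy$landmarks, anatomy$grid)
  left_type <- classify_tumor(tum$tumor_mask, lines, k)
  # mirror the whole case to the right, then let mirror_to_left undo it
  right_geom <- list(
    tumor_mask = ptclock:::mirror_mask(tum$tumor_mask, anatomy$midline_x),
    landmarks = ptclock:::mirror_landmarks(anatomy$landmarks,
                                           anatomy$midline_x))
  back <- mirror_to_left(right_geom, anatomy$midline_x)
  expect_true(attr(back, "mirrored"))
  back_type <- classify_tumor(back$tumor_mask,
                              build_reference_lines(back$landmarks), k)
  expect_equal(as.character(back_type), as.character(left_type))
  expect_equal(as.character(left_type), "T3B")
})
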