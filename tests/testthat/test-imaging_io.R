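test_that("gradient table validates counts, norms and b0 presence", {
  g12 <- default_gradient_table()
  expect_s3_class(g12, "gradient_table")
  expect_equal(g12$n_b0, 1)
  expect_length(g12$bvals, 13)
  expect_equal(sqrt(rowSums(g12$bvecs[g12$bvals > 0, ]^2)), rep(1, 12))

  # slightly off-unit vector is renormalized
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(0.9995, 0, 0)))
  expect_equal(gt$bvecs[2, ], c(1, 0, 0))

  # clearly off-unit is rejected; count mismatch is an error
  expect_error(gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(0.9, 0, 0))),
               "unit norm")
  expect_error(gradient_table(rep(1000, 12), matrix(rnorm(39), 13, 3)),
               "count mismatch")
  expect_error(gradient_table(c(-5, 1000), rbind(c(0, 0, 0), c(1, 0, 0))),
               "negative b-value")
  expect_error(gradient_table(c(1000, 1000), rbind(c(1, 0, 0), c(0, 1, 0))),
               "b=0")
})

test_that("bvec dialects (3-row and one-column-per-volume) read identically", {
  gt <- default_gradient_table()
  d <- withr::local_tempdir()
  writeLines(paste(gt$bvals, collapse = " "), file.path(d, "a.bval"))
  # FSL 3-row layout (rows are axes, columns are volumes)
  write(gt$bvecs, file.path(d, "rows.bvec"), ncolumns = nrow(gt$bvecs))
  # one row per volume
  write(t(gt$bvecs), file.path(d, "cols.bvec"), ncolumns = 3)
  g1 <- read_gradient_table(file.path(d, "a.bval"), file.path(d, "rows.bvec"))
  g2 <- read_gradient_table(file.path(d, "a.bval"), file.path(d, "cols.bvec"))
  expect_equal(g1$bvecs, g2$bvecs, tolerance = 1e-12)
  expect_equal(g1$bvals, gt$bvals)
})

test_that("DWI NIfTI + gradients round-trip through read_dwi", {
  d <- withr::local_tempdir()
  gt <- default_gradient_table()
  arr <- array(abs(rnorm(8 * 8 * 6 * 13, 500, 100)), c(8, 8, 6, 13))
  aff <- diag(c(1.9, 1.9, 3, 1))
  write_nifti_volume(arr, file.path(d, "dwi.nii.gz"), c(1.9, 1.9, 3), aff)
  writeLines(paste(gt$bvals, collapse = " "), file.path(d, "dwi.bval"))
  write(gt$bvecs, file.path(d, "dwi.bvec"), ncolumns = 13)
  dwi <- read_dwi(file.path(d, "dwi.nii.gz"), file.path(d, "dwi.bval"),
                  file.path(d, "dwi.bvec"))
  expect_s3_class(dwi, "dwi_volume")
  expect_equal(dwi$gradients$n_b0, 1)
  expect_equal(dwi$data, arr, tolerance = 1e-4)
  expect_equal(dwi$affine, aff, tolerance = 1e-6)

  # 13 volumes with 12 bvals must fail
  writeLines(paste(gt$bvals[-2], collapse = " "), file.path(d, "bad.bval"))
  write(gt$bvecs[-2, ], file.path(d, "bad.bvec"), ncolumns = 12)
  expect_error(read_dwi(file.path(d, "dwi.nii.gz"), file.path(d, "bad.bval"),
                        file.path(d, "bad.bvec")), "count mismatch")
})

test_that("mask reading enforces the grid and flags empty masks", {
  d <- withr::local_tempdir()
  aff <- diag(c(1.9, 1.9, 3, 1))
  ref <- list(data = array(1, c(8, 8, 6, 13)), voxel_size_mm = c(1.9, 1.9, 3),
              affine = aff)
  m <- array(0L, c(8, 8, 6)); m[3:5, 3:5, 2:4] <- 1L
  write_nifti_volume(m, file.path(d, "tumor.nii.gz"), c(1.9, 1.9, 3), aff)
  mk <- read_mask(file.path(d, "tumor.nii.gz"), ref, "tumor")
  expect_s3_class(mk, "volume_mask")
  expect_equal(sum(mk$data), 27)
  expect_equal(mk$label, "tumor")

  write_nifti_volume(array(0L, c(8, 8, 6)), file.path(d, "empty.nii.gz"),
                     c(1.9, 1.9, 3), aff)
  expect_warning(read_mask(file.path(d, "empty.nii.gz"), ref, "tumor"),
                 "empty")
  write_nifti_volume(array(1L, c(9, 8, 6)), file.path(d, "bad.nii.gz"),
                     c(1.9, 1.9, 3), aff)
  expect_error(read_mask(file.path(d, "bad.nii.gz"), ref), "does not match")
})

test_that("TRK round-trip preserves streamline coordinates", {
  d <- withr::local_tempdir()
  aff <- diag(c(1.9, 1.9, 3, 1))
  sl1 <- cbind(c(10, 10.5, 11), c(20, 20.2, 20.4), c(30, 33, 36))
  sl2 <- cbind(seq(5, 50, by = 0.7), 40, 60)
  f <- file.path(d, "t.trk")
  write_trk(list(sl1, sl2), f, c(96, 96, 60), c(1.9, 1.9, 3), aff)
  back <- read_trk(f)
  expect_length(back$streamlines, 2)
  expect_equal(nrow(back$streamlines[[1]]), 3)
  expect_lt(max(abs(back$streamlines[[1]] - sl1)), 1e-4)
  expect_lt(max(abs(back$streamlines[[2]] - sl2)), 1e-4)
  expect_equal(back$voxel_size_mm, c(1.9, 1.9, 3), tolerance = 1e-6)

  # empty tractogram: valid file with zero tracks
  write_trk(list(), f, c(96, 96, 60), c(1.9, 1.9, 3), aff)
  expect_length(read_trk(f)$streamlines, 0)
})

test_that("write_outputs emits the full per-case file set", {
  d <- withr::local_tempdir()
  grid <- list(dim = c(8L, 8L, 6L), voxel_size_mm = c(1.9, 1.9, 3),
               affine = diag(c(1.9, 1.9, 3, 1)))
  tract <- list(streamlines = list(cbind(5, 5, c(1, 2, 3)),
                                   cbind(7, 7, c(1, 4, 7, 10))))
  maps <- list(fa = array(0.5, c(8, 8, 6)))
  paths <- write_outputs(tract, maps, list(case_id = "x", kappa = 0.9),
                         file.path(d, "out"), grid)
  expect_true(all(file.exists(paths)))
  mirror <- jsonlite::read_json(paths[["trk_json"]], simplifyVector = TRUE)
  expect_equal(mirror[[1]], unname(tract$streamlines[[1]]))
  expect_equal(mirror[[2]], unname(tract$streamlines[[2]]))
  rep <- jsonlite::read_json(paths[["report_json"]])
  expect_equal(rep$n_tracks, 2)
  # empty tractogram still writes a valid report
  paths2 <- write_outputs(list(streamlines = list()), list(),
                          list(case_id = "y"), file.path(d, "out2"), grid)
  expect_equal(jsonlite::read_json(paths2[["report_json"]])$n_tracks, 0)
})
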