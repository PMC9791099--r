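test_that("crop selects closed intervals and is idempotent", {
  g <- tiny_grid()
  w_full <- crop_window(0, 10, 0, 100)
  expect_equal(crop(g, w_full)$intensity, g$intensity)

  # middle rt value, middle two dt values
  w <- crop_window(1.5, 2.5, 20, 30)
  sub <- crop(g, w)
  expect_identical(dim(sub$intensity), c(1L, 2L))
  expect_equal(sub$intensity[1, ], c(8, 1))
  expect_equal(sub$rt_axis, 2)
  expect_equal(sub$dt_axis, c(20, 30))

  # idempotence
  expect_identical(crop(crop(g, w), w), crop(g, w))

  expect_error(crop(g, crop_window(50, 60, 20, 30)), class = "vocims_empty_crop")
  expect_error(crop_window(5, 1, 0, 1), class = "vocims_invalid_window")
})

test_that("apply_threshold zeroes strictly-below values only", {
  g <- chromatogram_grid(c(1, 2), c(1, 2), matrix(c(1, 5, 3, 0), 2, byrow = TRUE))
  expect_equal(apply_threshold(g, 0)$intensity, g$intensity)
  expect_equal(
    apply_threshold(g, 3)$intensity,
    matrix(c(0, 5, 3, 0), 2, byrow = TRUE)
  )
  expect_true(all(apply_threshold(g, 100)$intensity == 0))
  expect_error(apply_threshold(g, -1), class = "vocims_invalid_threshold")
})

test_that("vectorize flattens row-major with a recoverable index", {
  g <- chromatogram_grid(c(1, 2), c(10, 20), matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  v <- vectorize(g)
  expect_equal(v$values, c(1, 2, 3, 4))
  expect_equal(v$feature_index$rt[1], 1)
  expect_equal(v$feature_index$dt[1], 10)
  # round trip
  expect_equal(matrix(v$values, 2, byrow = TRUE), g$intensity)
  # index covers every cell
  expect_identical(nrow(v$feature_index), length(g$intensity))
})

test_that("crop and threshold commute", {
  d <- small_design(n_per_class = c(term = 1, preterm = 0))
  g <- generate_cohort(d)$grids[[1]]
  w <- small_crop()
  a <- apply_threshold(crop(g, w), 2)
  b <- crop(apply_threshold(g, 2), w)
  expect_identical(a$intensity, b$intensity)
})

test_that("build_matrix applies one crop/threshold uniformly", {
  d <- small_design(n_per_class = c(term = 3, preterm = 2))
  co <- generate_cohort(d)
  fm <- build_matrix(co$grids, small_crop(), tau = 2)
  expect_identical(nrow(fm$matrix), 5L)
  expect_identical(fm$sample_ids, names(co$grids))
  expect_equal(fm$threshold_used, 2)
  expect_true(all(fm$matrix >= 0))

  # each row re-derivable from its raw grid via crop -> threshold -> flatten
  for (i in c(1, 4)) {
    ref <- vectorize(apply_threshold(crop(co$grids[[i]], small_crop()), 2))
    expect_identical(unname(fm$matrix[i, ]), ref$values)
    expect_equal(fm$feature_index, ref$feature_index)
  }

  # identical grids give identical rows
  fm2 <- build_matrix(list(a = co$grids[[1]], b = co$grids[[1]]), small_crop(), tau = 2)
  expect_identical(unname(fm2$matrix[1, ]), unname(fm2$matrix[2, ]))

  # one sample
  fm1 <- build_matrix(co$grids[1], small_crop(), tau = 2)
  expect_identical(dim(fm1$matrix), c(1L, ncol(fm$matrix)))

  # axis mismatch
  other <- make_grid(c(1, 2), c(3, 4))
  expect_error(
    build_matrix(c(co$grids[1], list(x = other)), small_crop(), tau = 2),
    class = "vocims_incompatible_grids"
  )
})

test_that("non-zero count is non-increasing in the threshold", {
  d <- small_design(n_per_class = c(term = 2, preterm = 2))
  co <- generate_cohort(d)
  taus <- seq(0, 6, by = 0.5)
  for (g in co$grids) {
    nnz <- vapply(taus, function(t) sum(apply_threshold(g, t)$intensity > 0), numeric(1))
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("calibrate_threshold picks the smallest admissible candidate", {
  d <- small_design(n_per_class = c(term = 4, preterm = 4))
  co <- generate_cohort(d)
  cropped <- lapply(co$grids, crop, window = small_crop())
  cands <- seq(0, 6, by = 0.25)
  target <- 800
  tau <- calibrate_threshold(cropped, target, candidates = cands)
  med_at <- function(t) {
    median(vapply(cropped, function(g) sum(apply_threshold(g, t)$intensity > 0), numeric(1)))
  }
  expect_true(med_at(tau) <= target)
  prev <- cands[which(cands == tau) - 1]
  if (length(prev)) {
    expect_true(med_at(prev) > target)
  }

  # target >= total cells -> tau = 0 admissible
  total <- length(cropped[[1]]$intensity)
  expect_equal(calibrate_threshold(cropped, total + 1, candidates = cands), 0)

  # all-zero samples: nnz is 0 everywhere, smallest candidate returned
  z <- list(make_grid(c(1, 2), c(1, 2, 3)))
  expect_equal(calibrate_threshold(z, 5, candidates = c(0.5, 1)), 0.5)

  # unattainable target
  expect_error(
    calibrate_threshold(cropped, 1, candidates = c(0, 0.1)),
    class = "vocims_calibration_error"
  )
})

test_that("chromatogram text round-trip preserves the grid", {
  d <- small_design(n_per_class = c(term = 1, preterm = 0))
  g <- generate_cohort(d)$grids[[1]]
  path <- withr::local_tempfile(fileext = ".txt")
  write_chromatogram(g, path)
  g2 <- read_chromatogram(path)
  expect_equal(g2$rt_axis, g$rt_axis, tolerance = 1e-7)
  expect_equal(g2$dt_axis, g$dt_axis, tolerance = 1e-7)
  expect_equal(g2$intensity, g$intensity, tolerance = 1e-6)
})

test_that("write_cohort lays out manifest, chromatograms and ground truth", {
  d <- small_design(n_per_class = c(term = 2, preterm = 2)) |> plant_effect(n_peaks = 2)
  co <- generate_cohort(d)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(m), 4L)
  expect_true(all(file.exists(file.path(dir, m$chromatogram_path))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(length(gt$planted), 2L)
  grids <- vocims:::read_cohort_grids(m, dir)
  expect_identical(names(grids), m$sample_id)
})
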