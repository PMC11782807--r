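test_that("percentile normalisation clips at 3rd/97th and maps to [0,1]", {
  x <- array(0:99, c(10, 10, 1))
  out <- normalize_intensity(x)
  # oracle: direct percentile + affine map on the flat vector
  q <- quantile(0:99, c(0.03, 0.97), names = FALSE)
  expected <- pmin(pmax(0:99, q[1]), q[2])
  expected <- (expected - min(expected)) / (max(expected) - min(expected))
  expect_equal(as.numeric(out), expected)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # values at or beyond the percentiles collapse to the endpoints
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[10, 10, 1], 1)
})

test_that("normalisation endpoints hold for arbitrary non-degenerate input", {
  withr::with_seed(5, {
    for (i in 1:5) {
      x <- array(rexp(500, 1 / 50), c(10, 10, 5))
      out <- normalize_intensity(x)
      expect_equal(range(out), c(0, 1))
    }
  })
})

test_that("a constant series normalises to zeros with a warning", {
  x <- array(7, c(4, 4, 3))
  expect_warning(out <- normalize_intensity(x), "degenerate")
  expect_true(all(out == 0))
})

test_that("resampling hits the target spacing and size", {
  s <- cine_series(array(runif(128 * 128 * 2), c(128, 128, 2)), 1.88, "SAX")
  out <- resample_to_spacing(s, 0.94)
  expect_equal(dim(out$frames), c(256, 256, 2))
  expect_equal(out$pixel_spacing, 0.94)

  s <- cine_series(array(runif(256 * 256), c(256, 256, 1)), 0.94, "SAX")
  expect_identical(resample_to_spacing(s, 0.94)$frames, s$frames)

  s <- cine_series(array(runif(200 * 200), c(200, 200, 1)), 1.5, "2CH")
  out <- resample_to_spacing(s, 0.94)
  expect_equal(dim(out$frames)[1:2], c(319, 319))  # round(200*1.5/0.94)

  expect_error(resample_to_spacing(s, -1), "positive")
})

test_that("crop_or_pad centres crops and pads symmetrically", {
  s <- cine_series(array(runif(300 * 300 * 2), c(300, 300, 2)), 0.94, "SAX")
  out <- crop_or_pad(s, 256)
  expect_equal(dim(out$frames), c(256, 256, 2))
  expect_equal(out$frames[, , 1], s$frames[23:278, 23:278, 1])

  s <- cine_series(array(1, c(200, 256, 1)), 0.94, "SAX")
  out <- crop_or_pad(s, 256)
  expect_true(all(out$frames[1:28, , 1] == 0))
  expect_true(all(out$frames[229:256, , 1] == 0))
  expect_true(all(out$frames[29:228, , 1] == 1))

  # round trip on an already-256 input
  s <- cine_series(array(runif(256 * 256), c(256, 256, 1)), 0.94, "SAX")
  expect_equal(crop_or_pad(crop_or_pad(s, 300), 256)$frames[, , 1],
               s$frames[, , 1])
})

test_that("preprocessing yields 20x256x256 in [0,1] for varied raw inputs", {
  shapes <- list(c(100, 120, 1.9), c(300, 280, 0.7), c(256, 256, 0.94))
  for (k in seq_along(shapes)) {
    sp <- shapes[[k]]
    s <- raw_series(sp[1], sp[2], 20, sp[3], seed = k)
    out <- preprocess_series(s)
    expect_s3_class(out, "preprocessed_cine_series")
    expect_equal(dim(out$frames), c(256, 256, 20))
    expect_true(all(out$frames >= 0 & out$frames <= 1))
    expect_equal(out$pixel_spacing, 0.94)
    # physical field of view ~ 240 mm, to within one pixel extent
    expect_lt(abs(256 * 0.94 - 240), 2 * 0.94)
  }
  expect_error(preprocess_series(raw_series(n = 10)), "phases")
})

test_that("augmentation is deterministic, identity at zero magnitude, and flips involute", {
  ex <- phantom_exam(seed = 9, masks = FALSE)
  pex <- preprocess_exam(ex)

  p0 <- augmentation_params(flip_prob = 0, max_shift_px = 0,
                            scale_range = c(1, 1), max_rotation_deg = 0,
                            seed = 1)
  expect_identical(augment_exam(pex, p0)$series$SAX$frames,
                   pex$series$SAX$frames)

  p <- augmentation_params(seed = 42)
  a1 <- augment_exam(pex, p)
  a2 <- augment_exam(pex, p)
  expect_identical(a1$series$`4CH`$frames, a2$series$`4CH`$frames)

  pf <- augmentation_params(flip_prob = 1, max_shift_px = 0,
                            scale_range = c(1, 1), max_rotation_deg = 0,
                            seed = 1)
  once <- augment_exam(pex, pf)
  expect_equal(once$series$SAX$frames[, , 1],
               pex$series$SAX$frames[, 256:1, 1], tolerance = 1e-12)
  twice <- augment_exam(once, pf)
  expect_equal(twice$series$SAX$frames, pex$series$SAX$frames,
               tolerance = 1e-12)
})

test_that("one sampled transform applies to all frames of a series", {
  # a series whose frames are all identical must stay frame-wise identical
  fr <- phantom_exam(seed = 2, masks = FALSE)$series$SAX$frames
  same <- array(fr[, , 1], c(256, 256, 20))
  ex <- cine_exam(list(SAX = cine_series(same, 0.94, "SAX")))
  ex$series$SAX$frames <- pmin(pmax(ex$series$SAX$frames / max(same), 0), 1)
  aug <- augment_exam(ex, augmentation_params(seed = 7))
  for (p in 2:20) {
    expect_identical(aug$series$SAX$frames[, , p], aug$series$SAX$frames[, , 1])
  }
})
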