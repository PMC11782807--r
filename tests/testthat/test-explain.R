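test_that("Gaussian dilation extends support and matches the brute-force footprint", {
  empty <- matrix(0, 40, 40)
  expect_true(all(dilate_mask(empty) == FALSE))

  # single centre pixel: truncated separable kernel -> 33x33 square support
  m <- matrix(0, 64, 64); m[32, 32] <- 1
  d <- dilate_mask(m, sigma = 4, radius = 16)
  expect_equal(sum(d), 33 * 33)
  # brute-force support oracle: the separable truncated kernel is strictly
  # positive on, and only on, the 33x33 Chebyshev box around the pixel
  oracle <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    di <- abs(i - 32); dj <- abs(j - 32)
    oracle[i, j] <- di <= 16 && dj <= 16  # product kernel support
  }
  expect_equal(unname(d), oracle)

  # monotonicity: dilate(dilate(m)) >= dilate(m) >= m
  withr::with_seed(3, m2 <- matrix(rbinom(64 * 64, 1, 0.02), 64, 64))
  d1 <- dilate_mask(m2); d2 <- dilate_mask(d1)
  expect_true(all(d1[m2 == 1]))
  expect_true(all(d2[d1]))
  expect_gte(sum(d1), sum(m2))

  # symmetric masks keep their centroid
  disc <- matrix(0, 65, 65)
  for (i in 1:65) for (j in 1:65) disc[i, j] <- (i - 33)^2 + (j - 33)^2 <= 100
  dd <- dilate_mask(disc)
  cen <- c(mean(row(dd)[dd]), mean(col(dd)[dd]))
  expect_lt(max(abs(cen - 33)), 1)

  expect_error(dilate_mask(matrix(0.5, 4, 4)), "binary")
})

test_that("mask and paste are exact pixelwise complements", {
  ex <- preprocess_exam(phantom_exam(seed = 17))
  mk <- list(SAX = dilate_mask(ex$masks$SAX$RV[, , 1]))
  masked <- apply_mask(ex, mk)
  pasted <- apply_paste(ex, mk)
  for (v in names(ex$series)) {
    expect_identical(masked$series[[v]]$frames + pasted$series[[v]]$frames,
                     ex$series[[v]]$frames)
  }
  # empty mask: mask is identity on pixels; paste is an all-black input
  none <- list(SAX = matrix(0, 256, 256))
  expect_identical(apply_mask(ex, none)$series$SAX$frames, ex$series$SAX$frames)
  p0 <- apply_paste(ex, none)
  expect_true(all(vapply(p0$series, function(s) all(s$frames == 0), logical(1))))
  # full mask: masked view goes black; paste keeps that view, blacks the rest
  full <- list(SAX = matrix(1, 256, 256))
  expect_true(all(apply_mask(ex, full)$series$SAX$frames == 0))
  pf <- apply_paste(ex, full)
  expect_identical(pf$series$SAX$frames, ex$series$SAX$frames)
  expect_true(all(pf$series$`4CH`$frames == 0))
  # misaligned masks rejected
  expect_error(apply_mask(ex, list(SAX = matrix(1, 10, 10))), "spatial size")
})

test_that("untrained scorer with zero weights yields uniform attention means", {
  m <- full_model()
  m$params$scorers$shared$w_a <- rep(0, 64)
  ds <- generate_dataset(phantom_config(), n_train = 2, n_val = 0, n_test = 2,
                         seed = 5)
  feats <- encode_dataset(ds, m$config)
  aw <- mean_attention_weights(m, feats, split = "test")
  expect_equal(unname(aw$mean$view_wise), matrix(1 / 4, 20, 4), tolerance = 1e-9)
  expect_equal(unname(aw$mean$phase_wise), matrix(1 / 20, 4, 20), tolerance = 1e-9)
  expect_equal(unname(aw$mean$final), rep(1 / 24, 24), tolerance = 1e-9)
})

test_that("averaged attention weights still sum to one per fusion group", {
  m <- full_model(seed = 3)
  ds <- generate_dataset(phantom_config(), n_train = 2, n_val = 0, n_test = 3,
                         seed = 6)
  feats <- encode_dataset(ds, m$config)
  aw <- mean_attention_weights(m, feats, split = "test")
  expect_equal(unname(rowSums(aw$mean$view_wise)), rep(1, 20), tolerance = 1e-6)
  expect_equal(unname(rowSums(aw$mean$phase_wise)), rep(1, 4), tolerance = 1e-6)
  expect_equal(sum(aw$mean$final), 1, tolerance = 1e-6)
  sums <- dplyr::summarise(dplyr::group_by(aw$table, fusion, group),
                           s = sum(mean_weight), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-6))
})

test_that("the per-feature table has one row per feature with group-wise weights", {
  m <- full_model(seed = 2)
  ds <- generate_dataset(phantom_config(), n_train = 2, n_val = 0, n_test = 4,
                         seed = 7)
  feats <- encode_dataset(ds, m$config)
  expect_warning(fi <- per_feature_performance(m, feats), "untrained")
  expect_equal(nrow(fi), 105)
  expect_equal(sum(fi$level == "frame"), 80)
  expect_equal(sum(fi$level == "spatial_summary"), 20)
  expect_equal(sum(fi$level == "temporal_summary"), 4)
  expect_equal(sum(fi$level == "final"), 1)
  # frame weights within one phase's view-wise group sum to 1
  g <- fi[fi$level == "frame" & fi$phase == 5, ]
  expect_equal(sum(g$weight_view_fusion), 1, tolerance = 1e-6)
  # stage-2 weights across the 24 summaries sum to 1
  expect_equal(sum(fi$weight_final, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("a constant regression head degrades gracefully to NA metrics", {
  m <- full_model()
  m$params$w_r <- rep(0, 64)
  ds <- generate_dataset(phantom_config(), n_train = 2, n_val = 0, n_test = 3,
                         seed = 8)
  feats <- encode_dataset(ds, m$config)
  expect_warning(fi <- per_feature_performance(m, feats), "untrained")
  expect_true(all(is.na(fi$pcc)))
  # a constant head gives identical rows: one shared MAE/R2 across features
  expect_length(unique(fi$mae), 1)
  expect_length(unique(fi$r2), 1)
  expect_false(anyNA(fi$mae))
})
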