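test_that("img_negative maps max to zero and is an involution when 0 is present", {
  m <- matrix(c(0, 10, 200, 255), 2, 2)
  expect_identical(img_negative(m), matrix(c(255, 245, 55, 0), 2, 2))
  expect_identical(img_negative(img_negative(m)), m)
  expect_identical(img_negative(matrix(7, 3, 3)), matrix(0, 3, 3))
})

test_that("to_grayscale matches the per-pixel luma oracle", {
  set.seed(1)
  img <- array(sample(0:255, 10 * 12 * 3, replace = TRUE), dim = c(10, 12, 3))
  g <- to_grayscale(img)
  oracle <- matrix(0, 10, 12)
  for (i in 1:10) for (j in 1:12) {
    oracle[i, j] <- round(0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] +
                            0.114 * img[i, j, 3])
  }
  expect_equal(g, oracle)
  expect_true(all(g >= 0 & g <= 255))
})

test_that("median filter equals the sliding-window oracle and removes salt noise", {
  set.seed(2)
  m <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  expect_equal(median_filter(m, 3), oracle_median(m, 3))
  expect_equal(median_filter(m, 5), oracle_median(m, 5))
  # constant image unchanged
  expect_equal(median_filter(matrix(80, 8, 8), 3), matrix(80, 8, 8))
  # isolated impulse removed
  imp <- matrix(100, 9, 9); imp[5, 5] <- 255
  expect_equal(median_filter(imp, 3), matrix(100, 9, 9))
  expect_error(median_filter(m, 4), "odd")
})

test_that("gaussian filter preserves constants, spreads impulses, reduces variance", {
  expect_equal(gaussian_filter(matrix(50, 10, 10), 1), matrix(50, 10, 10))
  # impulse response is the (separable) kernel: symmetric, mass-preserving
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1000
  g <- gaussian_filter(imp, 2, round = FALSE)
  expect_equal(sum(g), 1000, tolerance = 1e-9)
  expect_equal(g, t(g), tolerance = 1e-12)
  expect_equal(g[11, 11], max(g))
  expect_equal(g, g[21:1, ], tolerance = 1e-12)
  set.seed(3)
  noisy <- matrix(128 + rnorm(40 * 40, sd = 20), 40, 40)
  expect_lt(var(as.vector(gaussian_filter(noisy, 2, round = FALSE))),
            var(as.vector(noisy)) / 4)
})

test_that("lee filter smooths homogeneous noise but keeps a strong edge in place", {
  expect_equal(lee_filter(matrix(99, 12, 12), 5), matrix(99, 12, 12))
  set.seed(4)
  noisy <- matrix(100 + rnorm(40 * 40, sd = 15), 40, 40)
  expect_lt(var(as.vector(lee_filter(noisy, 5))), var(as.vector(noisy)))
  # step edge: the 50% crossing stays between the original edge columns
  step <- matrix(40, 30, 30); step[, 16:30] <- 220
  f <- lee_filter(step, 5)
  profile <- colMeans(f)
  crossing <- min(which(profile > (40 + 220) / 2))
  expect_true(crossing %in% 14:18)
  expect_lt(mean(abs(f[, c(1:12, 19:30)] - step[, c(1:12, 19:30)])), 3)
})

test_that("contrast enhancement stretches narrow ranges and fixes edge cases", {
  narrow <- matrix(seq(100, 140, length.out = 100), 10, 10)
  e <- enhance_contrast(narrow, clip = 0.02)
  expect_gt(diff(range(e)), 200)
  expect_equal(min(e), 0)
  expect_equal(max(e), 255)
  # monotone in the input ordering
  o <- order(narrow)
  expect_true(all(diff(e[o]) >= 0))
  expect_equal(enhance_contrast(matrix(77, 5, 5)), matrix(77, 5, 5))
  full <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_true(all(enhance_contrast(full, 1e-6) >= 0 & enhance_contrast(full, 1e-6) <= 255))
})

test_that("hair removal reduces hair error and barely touches clean images", {
  spec <- lesion_spec(center = c(96, 96), axes = c(40, 34),
                      boundary_wobble = 0.05, texture_noise_sd = 7)
  s <- generate_lesion_image(spec, 192, 192, seed = 5)
  clean_gray <- to_grayscale(s$image)
  # clean image: pass-through within a small modified fraction
  out_clean <- remove_hair(s$image)
  frac_mod <- mean(out_clean != s$image)
  expect_lt(frac_mod, 0.01)

  hairy <- add_hair_artifacts(s, 6, seed = 6)
  out <- remove_hair(hairy$image)
  err_before <- mean(abs(to_grayscale(hairy$image) - clean_gray))
  err_after <- mean(abs(to_grayscale(out) - clean_gray))
  expect_lt(err_after, err_before / 2)
  # detected hair overlaps real hair substantially
  hm <- attr(out, "hair_mask")
  expect_gt(sum(hm & hairy$hair_mask) / sum(hairy$hair_mask), 0.6)
})

test_that("preprocess_pipeline output shape, determinism and stage log", {
  spec <- lesion_spec(center = c(64, 64), axes = c(25, 20), texture_noise_sd = 10)
  s <- generate_lesion_image(spec, 128, 128, seed = 8)
  g1 <- preprocess_pipeline(s$image)
  g2 <- preprocess_pipeline(s$image)
  expect_identical(dim(g1), c(128L, 128L))
  expect_true(all(g1 >= 0 & g1 <= 255))
  expect_identical(as.vector(g1), as.vector(g2))  # stage timings aside
  st <- attr(g1, "stages")
  expect_identical(st$stage, c("remove_hair", "to_grayscale", "enhance_contrast",
                               "median_filter", "gaussian_filter", "lee_filter"))
  gn <- preprocess_pipeline(s$image, preprocess_config(apply_negative = TRUE))
  expect_identical(nrow(attr(gn, "stages")), 7L)
})

test_that("hair removal before segmentation improves the mask on hairy input", {
  spec <- lesion_spec(center = c(96, 96), axes = c(40, 34),
                      boundary_wobble = 0.05, texture_noise_sd = 7)
  s <- add_hair_artifacts(generate_lesion_image(spec, 192, 192, seed = 10),
                          7, seed = 11)
  cfg <- preprocess_config()
  with_removal <- preprocess_pipeline(s$image, cfg)
  # identical chain minus the hair-removal stage
  without <- lee_filter(gaussian_filter(median_filter(enhance_contrast(
    to_grayscale(s$image), cfg$contrast_clip), cfg$median_window),
    cfg$gaussian_sigma), cfg$lee_window)
  d_with <- segmentation_accuracy(region_growing(with_removal,
    region_grow_params(seed = c(96, 96))), s$truth_mask)$dice
  d_without <- segmentation_accuracy(region_growing(without,
    region_grow_params(seed = c(96, 96))), s$truth_mask)$dice
  expect_gte(d_with, d_without)
  expect_gt(d_with, 0.9)
})
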