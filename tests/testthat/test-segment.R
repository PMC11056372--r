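# A smooth two-level scene used by several segmentation tests: dark disc
# (intensity 60) on bright skin (200) with mild blur, no noise.
disc_scene <- function(r = 40, n = 160, lo = 60, hi = 200) {
  m <- make_disc(r, n)
  img <- ifelse(m == 1L, lo, hi)
  list(image = gaussian_filter(img, 1), truth = m)
}

test_that("make_init_mask places the expected rectangle", {
  m <- make_init_mask(20, 12, margin = 0.25)
  expect_identical(dim(m), c(20L, 12L))
  expect_identical(sum(m), (20L - 10L) * (12L - 6L))
  expect_identical(m[6, 4], 1L)
  expect_identical(m[5, 4], 0L)
  expect_error(make_init_mask(20, 12, margin = 0.6), "margin")
})

test_that("snake with zero iterations returns the initialization unchanged", {
  sc <- disc_scene()
  p <- snake_params(max_iterations = 0L)
  m <- adaptive_snake(sc$image, p)
  expect_identical(as.vector(m), as.vector(make_init_mask(160, 160, 0.25)))
  expect_identical(attr(m, "snake")$iterations, 0L)
})

test_that("snake recovers a disc from the rectangular initialization", {
  sc <- disc_scene()
  m <- adaptive_snake(sc$image)
  sa <- segmentation_accuracy(m, sc$truth)
  expect_gt(sa$dice, 0.95)
  info <- attr(m, "snake")
  expect_true(info$converged)
  # area trace approaches the true area (the first trace point is already
  # 10 iterations in, so compare against the absolute scale, not a ratio)
  at <- info$area_trace
  true_area <- sum(sc$truth)
  expect_lt(abs(at[length(at)] - true_area), 0.05 * true_area)
  expect_lte(abs(at[length(at)] - true_area), abs(at[1] - true_area))
})

test_that("a snake initialized on the true boundary stays there (fixed point)", {
  sc <- disc_scene()
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  init <- cbind(80.5 + 40 * cos(th), 80.5 + 40 * sin(th))
  m <- adaptive_snake(sc$image, init_contour = init)
  expect_gt(segmentation_accuracy(m, sc$truth)$dice, 0.99)
})

test_that("snake area trace moves monotonically toward the true disc area", {
  sc <- disc_scene()
  m <- adaptive_snake(sc$image)
  at <- attr(m, "snake")$area_trace
  err <- abs(at - sum(sc$truth))
  # tolerance-based monotonicity: each step shrinks the error up to 5% slack
  expect_true(all(diff(err) <= 0.05 * err[-length(err)] + 1))
})

test_that("region growing equals the flood-fill oracle on two-level images", {
  set.seed(5)
  img <- matrix(200, 60, 60)
  blob <- make_disc(15, 60)
  img[blob == 1L] <- 60
  # an unconnected second dark blob must NOT be reached
  img[5:8, 5:8] <- 60
  for (conn in c(4L, 8L)) {
    m <- region_growing(img, region_grow_params(seed = c(30, 30),
                                                intensity_tolerance = 30,
                                                connectivity = conn),
                        cleanup = FALSE)
    expect_identical(m, oracle_flood_fill(img, c(30, 30), 30, conn))
    expect_true(all(m[5:8, 5:8] == 0L))
  }
})

test_that("region growing edge cases: tolerance 0 and constant image", {
  img <- matrix(100, 10, 10); img[3, 3] <- 101
  m <- region_growing(img, region_grow_params(seed = c(5, 5),
                                              intensity_tolerance = 0),
                      cleanup = FALSE)
  expect_identical(sum(m), 99L)          # everything except the off pixel
  expect_identical(m[3, 3], 0L)
  const <- matrix(42, 12, 12)
  mc <- region_growing(const, region_grow_params(seed = c(1, 1),
                                                 intensity_tolerance = 0),
                       cleanup = FALSE)
  expect_identical(sum(mc), 144L)
  expect_error(region_growing(const, region_grow_params(seed = c(0, 5))), "outside")
})

test_that("default seed lands inside a dark lesion", {
  sc <- disc_scene()
  sd_ <- default_seed(sc$image)
  expect_identical(sc$truth[sd_[1], sd_[2]], 1L)
})

test_that("morphological cleanup removes speckle, keeps the largest blob, fills holes", {
  m <- make_disc(15, 60)
  m[2, 2] <- 1L                          # speckle
  m[40:43, 50:53] <- 1L                  # small separate blob
  holed <- m; holed[30, 30] <- 0L        # interior hole
  out <- morphological_cleanup(holed, open_radius = 2L, close_radius = 2L)
  expect_identical(out[2, 2], 0L)
  expect_true(all(out[40:43, 50:53] == 0L))
  expect_identical(out[30, 30], 1L)
  # radius-0 cleanup on a clean single blob is the identity
  clean <- make_disc(10, 40)
  expect_identical(morphological_cleanup(clean, 0L, 0L), clean)
  empty <- matrix(0L, 8, 8)
  expect_identical(morphological_cleanup(empty), empty)
})

test_that("segmentation_accuracy agrees with hand-computed overlaps", {
  a <- matrix(0L, 10, 10); a[3:6, 3:6] <- 1L
  expect_equal(segmentation_accuracy(a, a)$accuracy, 1)
  expect_equal(segmentation_accuracy(a, a)$dice, 1)
  b <- matrix(0L, 10, 10); b[4:7, 3:6] <- 1L   # shifted by one row
  sa <- segmentation_accuracy(b, a)
  expect_identical(sa$tp, 12L)
  expect_identical(sa$fp, 4L)
  expect_identical(sa$fn, 4L)
  expect_equal(sa$accuracy, (12 + 80) / 100)
  expect_equal(sa$dice, 2 * 12 / (2 * 12 + 4 + 4))
  expect_equal(sa$jaccard, 12 / 20)
  inv <- (1L - a); storage.mode(inv) <- "integer"
  expect_equal(segmentation_accuracy(inv, a)$accuracy, 0)
  expect_error(segmentation_accuracy(a, matrix(0L, 5, 5)), "differ")
})
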