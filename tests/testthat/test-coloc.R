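full_mask <- function(img) matrix(TRUE, nrow(img), ncol(img))

test_that("background subtraction clips at zero and preserves shape", {
  img <- matrix(c(0, 10, 20, 5), 2L)
  expect_equal(subtract_background(img, 0), img)
  expect_equal(subtract_background(img, 10),
               matrix(c(0, 0, 10, 0), 2L))
  expect_equal(subtract_background(matrix(5, 3L, 3L), 7),
               matrix(0, 3L, 3L))
  expect_error(subtract_background(img, -1), "constant")
})

test_that("masked Pearson matches the textbook formula and its invariances", {
  ch1 <- matrix(1:9, 3L)
  expect_equal(pearson_roi(ch1, ch1, full_mask(ch1)), 1.0)
  expect_equal(pearson_roi(ch1, 3 * ch1 + 2, full_mask(ch1)), 1.0)
  rev9 <- matrix(9:1, 3L)
  expect_equal(pearson_roi(ch1, rev9, full_mask(ch1)), -1.0)

  set.seed(77)
  for (i in 1:20) {
    a <- matrix(runif(9, 0, 100), 3L)
    b <- matrix(runif(9, 0, 100), 3L)
    expect_equal(pearson_roi(a, b, full_mask(a)),
                 oracle_pearson(as.vector(a), as.vector(b)),
                 tolerance = 1e-12)
    # reflecting one channel about its midrange (negating deviations,
    # values staying non-negative) flips the sign
    b_neg <- matrix(max(b) + min(b) - b, 3L)
    expect_equal(pearson_roi(a, b_neg, full_mask(a)),
                 -pearson_roi(a, b, full_mask(a)), tolerance = 1e-12)
  }

  expect_error(pearson_roi(ch1, matrix(5, 3L, 3L), full_mask(ch1)),
               "constant")
  m1px <- matrix(FALSE, 3L, 3L); m1px[1L] <- TRUE
  expect_error(pearson_roi(ch1, ch1, m1px), "2 pixels")
})

test_that("Manders coefficients match hand computation and bounds", {
  pos <- matrix(c(4, 0, 0, 6), 2L)
  mm <- manders(pos, pos, t1 = 0, t2 = 0)
  expect_equal(as.numeric(mm), c(1, 1))

  disjoint1 <- matrix(c(5, 0, 0, 0), 2L)
  disjoint2 <- matrix(c(0, 0, 0, 7), 2L)
  expect_equal(as.numeric(manders(disjoint1, disjoint2)), c(0, 0))

  # hand-worked 2x2 case: M1 = 4 / (4 + 6) = 0.4
  ch1 <- matrix(c(4, 0, 0, 6), 2L)
  ch2 <- matrix(c(1, 0, 0, 0), 2L)
  mm2 <- manders(ch1, ch2)
  expect_equal(unname(mm2["M1"]), 0.4)
  expect_equal(unname(mm2["M2"]), 1.0)  # all of ch2 sits where ch1 > 0

  expect_error(manders(matrix(0, 2L, 2L), ch2), "zero total")
})

test_that("M1 is non-increasing in the partner threshold", {
  set.seed(5)
  si <- synth_coloc_image(shape = c(96L, 96L), n_objects = 5L,
                          overlap_fraction = 0.6, noise_sd = 0.001,
                          seed = 9L)
  t2s <- quantile(si$ch2, c(0, 0.25, 0.5, 0.75, 0.9))
  m1s <- vapply(t2s, function(t2) {
    unname(manders(si$ch1, si$ch2, t2 = t2)["M1"])
  }, numeric(1))
  expect_true(all(diff(m1s) <= 1e-12))
  expect_true(all(m1s >= 0 & m1s <= 1))
})

test_that("metrics depend only on pixels inside the mask", {
  set.seed(8)
  a <- matrix(runif(100), 10L)
  b <- matrix(runif(100), 10L)
  mask <- matrix(FALSE, 10L, 10L)
  mask[3:7, 3:7] <- TRUE
  r0 <- pearson_roi(a, b, mask)
  m0 <- manders(a, b, mask)
  i0 <- masked_mean_intensity(a, mask)
  # perturb everything outside the mask
  a2 <- a; b2 <- b
  a2[!mask] <- a2[!mask] + 100
  b2[!mask] <- 0
  expect_identical(pearson_roi(a2, b2, mask), r0)
  expect_identical(manders(a2, b2, mask), m0)
  expect_identical(masked_mean_intensity(a2, mask), i0)
})

test_that("Otsu binarization separates a two-mode image and maximizes between-class variance", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10L)
  mask <- binarize_marker(img, method = "otsu")
  expect_identical(which(mask), which(img > 100))  # high mode only
  thr <- attr(mask, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  # the threshold attains the exhaustive-sweep variance maximum (the
  # maximizer itself is a plateau between well-separated modes)
  expect_equal(between_class_variance(img, thr),
               max_between_class_variance(img), tolerance = 1e-9)

  set.seed(12)
  noisy <- matrix(c(rnorm(200, 20, 3), rnorm(200, 120, 10)), 20L)
  noisy <- pmax(noisy, 0)
  thr2 <- attr(binarize_marker(noisy), "threshold")
  expect_equal(between_class_variance(noisy, thr2),
               max_between_class_variance(noisy), tolerance = 1e-3)

  # fixed threshold and degenerate inputs
  fm <- binarize_marker(matrix(c(5, 15, 5, 15), 2L), method = "fixed",
                        fixed_threshold = 10)
  expect_equal(sum(fm), 2L)
  expect_warning(z <- binarize_marker(matrix(0, 4L, 4L)), "empty mask")
  expect_equal(sum(z), 0L)
  expect_error(binarize_marker(matrix(1:4, 2L), method = "fixed"),
               "fixed_threshold")
})

test_that("masked mean intensity averages over the mask area", {
  img <- matrix(0, 4L, 4L)
  mask <- matrix(FALSE, 4L, 4L)
  mask[c(1L, 6L, 11L)] <- TRUE
  img[c(1L, 6L, 11L)] <- c(2, 4, 9)
  expect_equal(masked_mean_intensity(img, mask), 5.0)
  expect_equal(masked_mean_intensity(matrix(0, 4L, 4L), mask), 0)
  # uniform signal v inside the mask -> v in pixel units
  expect_equal(masked_mean_intensity(matrix(7, 4L, 4L), mask), 7)
  # physical pixel size rescales the area
  expect_equal(masked_mean_intensity(img, mask, pixel_size = 0.5),
               15 / (3 * 0.25))
  expect_error(masked_mean_intensity(img, matrix(FALSE, 4L, 4L)), "empty")
})

test_that("line profiles are max-normalized and geometrically consistent", {
  # constant positive image -> flat profile at 1
  flat <- line_profile(list(ch = matrix(3, 20L, 20L)),
                       from = c(5, 2), to = c(5, 18))
  expect_true(all(flat$intensity == 1))

  # profile along the diagonal of an n x n image spans (n-1) * sqrt(2)
  n <- 33L
  diagp <- line_profile(list(ch = matrix(1, n, n) + 0),
                        from = c(1, 1), to = c(n, n))
  expect_equal(max(diagp$distance) <= (n - 1) * sqrt(2), TRUE)
  expect_gt(max(diagp$distance), (n - 1) * sqrt(2) - 1)

  # a single bright pixel at the segment midpoint peaks at 1 there
  img <- matrix(0.01, 21L, 21L)
  img[11L, 11L] <- 10
  prof <- line_profile(list(ch = img), from = c(11, 1), to = c(11, 21))
  expect_equal(prof$intensity[which.max(prof$intensity)], 1)
  expect_equal(prof$distance[which.max(prof$intensity)], 10)

  # physical pixel size scales the distance axis
  prof_um <- line_profile(list(ch = img), from = c(11, 1), to = c(11, 21),
                          pixel_size = 0.02)
  expect_equal(max(prof_um$distance), max(prof$distance) * 0.02)

  # degenerate inputs
  expect_error(line_profile(list(ch = img), from = c(5, 5), to = c(5, 5)),
               "zero-length")
  expect_error(line_profile(list(ch = img), from = c(0, 1), to = c(5, 5)),
               "inside the image")
  expect_error(line_profile(list(ch = matrix(0, 9L, 9L)),
                            from = c(1, 1), to = c(9, 9)),
               "all-zero")
})

test_that("designed-overlap images recover their Manders ground truth", {
  # f = 1, no noise: perfect colocalization
  s1 <- synth_coloc_image(shape = c(128L, 128L), n_objects = 6L,
                          overlap_fraction = 1, seed = 1L)
  mm1 <- manders(s1$ch1, s1$ch2)
  expect_equal(as.numeric(mm1), c(1, 1), tolerance = 1e-6)

  # f = 0, no noise, non-overlapping placements: zero colocalization
  s0 <- synth_coloc_image(shape = c(160L, 160L), n_objects = 6L,
                          overlap_fraction = 0, seed = 2L)
  mm0 <- manders(s0$ch1, s0$ch2)
  expect_equal(as.numeric(mm0), c(0, 0), tolerance = 1e-6)

  # f = 0.5 recovered within +/- 0.05 averaged over 20 seeds
  m1s <- vapply(1:20, function(s) {
    si <- synth_coloc_image(shape = c(256L, 256L), n_objects = 20L,
                            overlap_fraction = 0.5, seed = s)
    unname(manders(si$ch1, si$ch2)["M1"])
  }, numeric(1))
  expect_lt(abs(mean(m1s) - 0.5), 0.05)
})

test_that("TIFF image planes round-trip and feed coloc_stats", {
  set.seed(3)
  img <- matrix(runif(64), 8L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_plane(img, path)
  back <- read_image_plane(path)
  expect_equal(back, img, tolerance = 1e-6)

  si <- synth_coloc_image(shape = c(96L, 96L), n_objects = 4L,
                          overlap_fraction = 1, seed = 4L)
  st <- coloc_stats(si$ch1, si$ch1 + 1e-9)
  expect_equal(st$pearson_r, 1, tolerance = 1e-9)
  expect_equal(st$m1, 1, tolerance = 1e-6)
  expect_equal(st$n_pixels, 96L * 96L)
  expect_gt(st$masked_intensity, 0)
})
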