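make_rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  structure(m, class = "binary_mask")
}

test_that("pixel pigmentation is 1 at the target and NA off-patch", {
  img <- flat_image("803D33", 8, 8)
  mask <- make_rect_mask(8, 8, 1:8, 1:4)
  p <- pixel_pigmentation(img, mask)
  expect_equal(p[1, 1], 1, tolerance = 1e-8)
  expect_true(all(is.na(p[, 5:8])))
  expect_error(pixel_pigmentation(img, make_rect_mask(4, 4, 1:2, 1:2)),
               "dimensions differ")
})

test_that("pigmentation increases monotonically toward the pigment color", {
  # gradient strip from agar color to pigment color
  n <- 64
  agar <- as.numeric(hex_to_srgb("33393E"))
  pig <- as.numeric(hex_to_srgb("803D33"))
  w <- seq(0, 1, length.out = n)
  img <- array(0, dim = c(4, n, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix((1 - w) * agar[ch] + w * pig[ch], 4, n,
                          byrow = TRUE)
  }
  p <- pixel_pigmentation(img, make_rect_mask(4, n, 1:4, 1:n))
  expect_true(all(diff(p[1, ]) > 0))
})

test_that("ROI is the central band, 20% of patch height, rounded", {
  m <- make_rect_mask(200, 300, 51:150, 21:280)   # height 100
  roi <- select_roi(m)
  expect_equal(roi$y1 - roi$y0, 20)
  expect_equal(c(roi$x0, roi$x1), c(20, 280))
  # height 101 -> round(20.2) = 20
  roi2 <- select_roi(make_rect_mask(200, 300, 50:150, 21:280))
  expect_equal(roi2$y1 - roi2$y0, 20)
  expect_error(select_roi(make_rect_mask(20, 300, 10:13, 1:300)),
               "degenerate")
  # ROI stays inside the patch bounding box on synthetic patches
  for (s in 1:5) {
    pl <- generate_plate(small_plate_params(seed = 400 + s))
    mm <- make_patch_mask(pl$image)
    r <- select_roi(mm)
    idx <- which(unclass(mm)[, ] != 0, arr.ind = TRUE)
    expect_gte(r$y0, min(idx[, 1]) - 1L)
    expect_lte(r$y1, max(idx[, 1]))
    expect_equal(c(r$x0 + 1L, r$x1), unname(range(idx[, 2])))
  }
})

test_that("breakpoint binning partitions columns and averages pixels", {
  mask <- make_rect_mask(40, 400, 1:40, 1:400)
  roi <- select_roi(mask)
  # constant raster
  vals <- matrix(0.37, 40, 400)
  prof <- bin_breakpoints(vals, mask, roi)
  expect_equal(nrow(prof), 200)
  expect_true(all(abs(prof$mean - 0.37) < 1e-12))
  expect_true(all(prof$sd == 0))
  expect_true(all(prof$n_pixels == 2 * 8))       # 2 columns x ROI height 8
  # step raster: left half 0, right half 1
  step <- cbind(matrix(0, 40, 200), matrix(1, 40, 200))
  ps <- bin_breakpoints(step, mask, roi)
  expect_equal(ps$mean, c(rep(0, 100), rep(1, 100)))
  # brute-force per-column averaging oracle on a random raster
  set.seed(5)
  rnd <- matrix(runif(40 * 400), 40, 400)
  pr <- bin_breakpoints(rnd, mask, roi)
  rows <- (roi$y0 + 1):roi$y1
  for (b in sample(200, 12)) {
    cols <- roi$x0 + which(floor((seq_len(400) - 1) * 200 / 400) + 1 == b)
    expect_equal(pr$mean[b], mean(rnd[rows, cols]))
    expect_equal(pr$sd[b], sd(as.vector(rnd[rows, cols])))
  }
  expect_error(bin_breakpoints(vals, mask,
                               structure(list(x0 = 0, x1 = 150, y0 = 10,
                                              y1 = 20), class = "roi")),
               "higher-resolution")
})

test_that("empty breakpoints are interpolated and flagged", {
  mask <- make_rect_mask(20, 200, 1:20, 1:200)
  vals <- matrix(rep(seq(0, 1, length.out = 200), each = 20), 20, 200)
  # knock out all pixels feeding bins 100 and 101 (columns 100:101)
  mask[, 100:101] <- FALSE
  prof <- bin_breakpoints(vals, mask, select_roi(
    structure(matrix(TRUE, 20, 200), class = "binary_mask")))
  expect_equal(prof$n_pixels[100:101], c(0L, 0L))
  expect_gt(prof$mean[100], prof$mean[99])
  expect_lt(prof$mean[101], prof$mean[102])
})

test_that("baseline averaging and its minimum follow the definitions", {
  p1 <- profile_from_means(rep(0.3, 200))
  p2 <- profile_from_means(rep(0.4, 200))
  b1 <- compute_baseline(list(p1))
  expect_equal(b1$pb, p1$mean)
  b <- compute_baseline(list(p1, p2))
  expect_true(all(b$pb == 0.35))
  expect_equal(b$pb_min, 0.35)
  expect_equal(b$n_images, 2L)
  expect_error(compute_baseline(list(p1, profile_from_means(rep(0.1, 150)))),
               "same number of breakpoints")
})

test_that("effective pigmentation rescales between Pb_min and 1", {
  expect_equal(effective_pigmentation(1, 0.342), 1)
  expect_equal(effective_pigmentation(0.342, 0.342), 0)
  expect_equal(effective_pigmentation(0.2, 0.342), 0)
  expect_equal(effective_pigmentation(0.671, 0.342),
               (0.671 - 0.342) / (1 - 0.342))
  expect_equal(effective_pigmentation(0.671, 0.342), 0.5)
  expect_error(effective_pigmentation(0.5, 1), "below 1")
})

test_that("a flat baseline leaves effective pigmentation unchanged", {
  mask <- make_rect_mask(40, 400, 1:40, 1:400)
  roi <- select_roi(mask)
  set.seed(8)
  pe <- matrix(runif(40 * 400, 0, 0.8), 40, 400)
  flat <- default_baseline(pb_min = 0.3)
  prof <- corrected_profile(pe, mask, roi, flat)
  expect_equal(prof$mean, bin_breakpoints(pe, mask, roi)$mean)
})

test_that("edge vignette artifacts are suppressed by the correction", {
  wt <- lapply(1:4, function(s) generate_plate(
    small_plate_params(profile_fn = profile_flat(0), seed = 500 + s)))
  base <- compute_baseline(lapply(wt, function(p) raw_profile(p$image)))
  img <- wt[[1]]$image
  m <- make_patch_mask(img)
  roi <- select_roi(m)
  pe <- effective_pigmentation(pixel_pigmentation(img, m), base$pb_min)
  uncorrected <- bin_breakpoints(pe, m, roi)
  corrected <- corrected_profile(pe, m, roi, base)
  expect_lt(max(corrected$mean), 0.05)
  expect_lt(max(corrected$mean), max(uncorrected$mean))
})

test_that("profile extraction is deterministic and mirror-symmetric", {
  pl <- generate_plate(small_plate_params(seed = 77))
  a <- extract_profile(pl$image)
  b <- extract_profile(pl$image)
  expect_identical(a, b)
  mirrored <- pl$image[, dim(pl$image)[2]:1, , drop = FALSE]
  flipped <- extract_profile(mirrored, flip = TRUE)
  expect_equal(flipped$mean, a$mean)
  expect_true(all(a$mean >= 0 & a$mean <= 1))
})

test_that("interaction plates peak in the first quarter; isolated stay low", {
  wt <- lapply(1:4, function(s) generate_plate(
    small_plate_params(profile_fn = profile_flat(0), seed = 600 + s)))
  base <- compute_baseline(lapply(wt, function(p) raw_profile(p$image)))
  inter <- generate_plate(small_plate_params(seed = 55))
  prof <- extract_profile(inter$image, baseline = base)
  expect_lte(which.max(prof$mean), 50)
  expect_gt(max(prof$mean), 0.5)    # easily visible pigmentation
  iso <- extract_profile(wt[[1]]$image, baseline = base)
  expect_true(all(iso$mean < 0.5))  # no visible pigmentation in isolation
})

test_that("profiles are stable under 2x upscaling", {
  pl <- generate_plate(small_plate_params(seed = 9))
  wt <- generate_plate(small_plate_params(profile_fn = profile_flat(0),
                                          seed = 10))
  base <- compute_baseline(list(raw_profile(wt$image)))
  a <- extract_profile(pl$image, baseline = base)
  up <- pl$image[rep(seq_len(dim(pl$image)[1]), each = 2),
                 rep(seq_len(dim(pl$image)[2]), each = 2), , drop = FALSE]
  b <- extract_profile(up, baseline = base)
  expect_lt(max(abs(a$mean - b$mean)), 0.02)
})
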