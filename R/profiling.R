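#' Per-pixel pigmentation
#'
#' Pigmentation of a pixel is `p = 1 - d_s`, one minus the normalized
#' CIELAB distance to the red pigment target color, so a pixel exactly
#' matching the target scores 1 and a maximally different pixel scores 0.
#' Only foreground (patch) pixels are scored; background pixels are `NA`.
#'
#' @param img H x W x 3 sRGB array with channels in `[0, 1]`.
#' @param mask A `binary_mask` of the same height and width.
#' @param pigment_color Pigment target color (default `803D33`, red
#'   pigmentation).
#' @return H x W numeric matrix of `p` values, `NA` outside the patch.
#' @export
pixel_pigmentation <- function(img, mask, pigment_color = "803D33") {
  if (!identical(dim(img)[1:2], dim(mask))) {
    stop("image and mask dimensions differ")
  }
  p <- 1 - raster_distance(img, pigment_color)
  p[!mask] <- NA_real_
  p
}

#' Select the profiling region of interest
#'
#' The ROI is a rectangle spanning the patch's horizontal bounding box,
#' vertically centered on the bounding box midpoint, with a height of 20%
#' (rounded) of the maximum patch height. The profile is computed only in
#' this central band so the strongly curved top and bottom of the patch do
#' not enter the horizontal profile.
#'
#' @param mask A finalized `binary_mask` with one foreground component.
#' @param height_fraction Fraction of the maximum patch height (default
#'   0.20).
#' @return A list of class `roi` with 0-based half-open bounds
#'   `x0, x1` (columns) and `y0, y1` (rows).
#' @export
select_roi <- function(mask, height_fraction = 0.20) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask has no foreground pixels")
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  patch_height <- rows[2] - rows[1] + 1L
  if (patch_height < 5L) stop("degenerate patch: height below 5 pixels")
  h <- max(1L, as.integer(round(height_fraction * patch_height)))
  mid <- (rows[1] + rows[2]) / 2
  y0 <- as.integer(round(mid - h / 2))
  structure(list(x0 = cols[1] - 1L, x1 = cols[2],
                 y0 = y0, y1 = y0 + h),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI cols [%d, %d), rows [%d, %d) (%d x %d)\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

# Breakpoint index (1..n_bins) for each of the w columns of an ROI.
breakpoint_of_column <- function(w, n_bins = 200L) {
  as.integer(floor((seq_len(w) - 1L) * n_bins / w)) + 1L
}

new_profile <- function(df, orientation = "interaction_left") {
  structure(df, orientation = orientation,
            class = c("pigmentation_profile", "data.frame"))
}

#' Average a raster over profile breakpoints
#'
#' The ROI columns are partitioned into `n_bins` contiguous, near-equal
#' groups (breakpoints) across the horizontal axis; within each group the
#' mean and standard deviation of the raster values over foreground pixels
#' are computed. Breakpoints with no foreground pixels in the ROI are
#' linearly interpolated from their nearest non-empty neighbours and
#' flagged with `n_pixels = 0`.
#'
#' @param values H x W numeric raster (e.g. pigmentation), `NA` outside
#'   the patch.
#' @param mask A `binary_mask`.
#' @param roi An [select_roi()] rectangle.
#' @param n_bins Number of breakpoints (default 200).
#' @return A `pigmentation_profile` data frame with columns `bin`, `mean`,
#'   `sd`, `n_pixels`.
#' @export
bin_breakpoints <- function(values, mask, roi, n_bins = 200L) {
  w <- roi$x1 - roi$x0
  if (w < n_bins) {
    stop(sprintf(paste("ROI width (%d columns) is below the %d requested",
                       "breakpoints; use a higher-resolution image"),
                 w, n_bins))
  }
  rows <- (roi$y0 + 1L):roi$y1
  cols <- (roi$x0 + 1L):roi$x1
  sub <- values[rows, cols, drop = FALSE]
  sub[!mask[rows, cols]] <- NA_real_
  bin <- breakpoint_of_column(w, n_bins)
  g <- matrix(bin, nrow = length(rows), ncol = w, byrow = TRUE)
  keep <- !is.na(sub)
  n <- tabulate(g[keep], nbins = n_bins)
  m <- s <- rep(NA_real_, n_bins)
  if (any(keep)) {
    sums <- vapply(split(sub[keep], g[keep]), sum, 0)
    ids <- as.integer(names(sums))
    m[ids] <- sums / n[ids]
    sq <- vapply(split(sub[keep]^2, g[keep]), sum, 0)
    v <- pmax(0, sq / n[ids] - m[ids]^2)
    s[ids] <- sqrt(v * ifelse(n[ids] > 1, n[ids] / (n[ids] - 1), 0))
    s[ids][n[ids] == 1L] <- 0
  }
  if (anyNA(m)) {
    if (all(is.na(m))) stop("no foreground pixels in the ROI")
    filled <- which(!is.na(m))
    m <- stats::approx(filled, m[filled], xout = seq_len(n_bins),
                       rule = 2)$y
    s[is.na(s)] <- 0
  }
  new_profile(data.frame(bin = seq_len(n_bins), mean = m, sd = s,
                         n_pixels = n))
}

#' Raw pigmentation profile of a single image
#'
#' Convenience composition used when building baselines: mask the image,
#' score per-pixel pigmentation `p`, and average it over breakpoints with
#' no baseline normalization applied.
#'
#' @inheritParams pixel_pigmentation
#' @param config A [masking_config()].
#' @param n_bins Number of breakpoints.
#' @return A `pigmentation_profile` of raw `P` values.
#' @export
raw_profile <- function(img, config = masking_config(),
                        pigment_color = "803D33", n_bins = 200L) {
  mask <- make_patch_mask(img, config)
  p <- pixel_pigmentation(img, mask, pigment_color)
  bin_breakpoints(p, mask, select_roi(mask), n_bins)
}

#' Baseline pigmentation distribution from unpigmented patches
#'
#' Averages the per-breakpoint raw pigmentation of a set of unpigmented
#' (wild-type, isolated) patches into the baseline distribution `Pb`,
#' whose minimum `Pb_min` anchors the effective-pigmentation rescaling.
#' The reference study used 12 wild-type isolated patches.
#'
#' @param profiles List of raw-`P` profiles (from [raw_profile()] or
#'   [bin_breakpoints()]), all with the same number of breakpoints.
#' @return A list of class `baseline_distribution` with elements `pb`
#'   (per-breakpoint baseline), `pb_min`, and `n_images`.
#' @export
compute_baseline <- function(profiles) {
  if (!length(profiles)) stop("at least one profile is required")
  means <- lapply(profiles, function(p) p$mean)
  n_bins <- length(means[[1]])
  if (!all(vapply(means, length, 0L) == n_bins)) {
    stop("all baseline profiles must have the same number of breakpoints")
  }
  pb <- rowMeans(do.call(cbind, means))
  structure(list(pb = pb, pb_min = min(pb), n_images = length(profiles)),
            class = "baseline_distribution")
}

#' Packaged default baseline
#'
#' A flat baseline at the reference study's published minimum baseline
#' pigmentation (`Pb_min = 0.342`). With a flat `Pb` the spatial edge
#' correction vanishes, but the effective-pigmentation threshold still
#' matches the published calibration, so users without their own
#' wild-type baseline images get sensible absolute values. Recomputing the
#' baseline from matched unpigmented patches via [compute_baseline()] is
#' recommended whenever possible.
#'
#' @param pb_min Baseline minimum (default 0.342).
#' @param n_bins Number of breakpoints.
#' @return A `baseline_distribution`.
#' @export
default_baseline <- function(pb_min = 0.342, n_bins = 200L) {
  structure(list(pb = rep(pb_min, n_bins), pb_min = pb_min, n_images = 0L),
            class = "baseline_distribution")
}

#' @export
print.baseline_distribution <- function(x, ...) {
  cat(sprintf(
    "baseline distribution: %d breakpoints, Pb_min = %.3f (from %d images)\n",
    length(x$pb), x$pb_min, x$n_images))
  invisible(x)
}

#' Effective pigmentation
#'
#' Rescales raw pigmentation so the baseline minimum maps to 0 and full
#' pigmentation stays at 1: `P_e = 0` when `P < Pb_min`, otherwise
#' `P_e = (P - Pb_min) / (1 - Pb_min)`. This spreads the values of
#' visibly pigmented patches evenly over `[0, 1]`.
#'
#' @param p Raw pigmentation values in `[0, 1]` (vector or raster).
#' @param pb_min Baseline minimum pigmentation.
#' @return `P_e` with the same shape as `p`.
#' @export
effective_pigmentation <- function(p, pb_min) {
  if (pb_min >= 1) stop("pb_min must be below 1")
  out <- (p - pb_min) / (1 - pb_min)
  out[!is.na(out) & out < 0] <- 0
  out
}

#' Baseline-corrected pigmentation profile
#'
#' Applies the spatially specific edge correction per pixel:
#' `P_f = P_e - (Pb_i - Pb_min)`, where `i` is the breakpoint the pixel's
#' column falls in, clamped at 0. Patch edges are shadowed by the
#' three-dimensional shape of the colony, which inflates apparent
#' pigmentation near the profile ends; subtracting each breakpoint's
#' baseline excess removes that artifact. The corrected raster is then
#' averaged over breakpoints.
#'
#' @param pe_raster H x W raster of effective pigmentation (`NA` outside
#'   the patch).
#' @param mask A `binary_mask`.
#' @param roi An [select_roi()] rectangle.
#' @param baseline A `baseline_distribution`.
#' @return A `pigmentation_profile` of `P_f` values.
#' @export
corrected_profile <- function(pe_raster, mask, roi, baseline) {
  n_bins <- length(baseline$pb)
  w <- roi$x1 - roi$x0
  correction <- baseline$pb - baseline$pb_min
  col_corr <- rep(0, ncol(pe_raster))
  col_corr[(roi$x0 + 1L):roi$x1] <- correction[breakpoint_of_column(w, n_bins)]
  pf <- sweep(pe_raster, 2L, col_corr, `-`)
  pf[!is.na(pf) & pf < 0] <- 0
  bin_breakpoints(pf, mask, roi, n_bins)
}

#' Extract a pigmentation profile from a plate image
#'
#' Full composition of the pipeline for one image: build the patch mask,
#' score per-pixel pigmentation against the pigment target, select the
#' central ROI, rescale to effective pigmentation, apply the spatial
#' baseline correction, and average over breakpoints. By convention
#' breakpoint 1 is the patch edge facing the interacting strain (the left
#' edge of the image); set `flip = TRUE` when the partner was on the
#' right.
#'
#' @param img H x W x 3 sRGB array in `[0, 1]`, or a file path readable by
#'   [load_image()].
#' @param baseline A `baseline_distribution` (default: the packaged flat
#'   baseline at `Pb_min = 0.342`).
#' @param config A [masking_config()].
#' @param pigment_color Pigment target color.
#' @param flip Mirror the image horizontally before profiling.
#' @param n_bins Number of breakpoints.
#' @return A `pigmentation_profile` with columns `bin`, `mean`, `sd`,
#'   `n_pixels` and an `orientation` attribute.
#' @export
extract_profile <- function(img, baseline = default_baseline(),
                            config = masking_config(),
                            pigment_color = "803D33",
                            flip = FALSE, n_bins = 200L) {
  if (is.character(img)) img <- load_image(img)
  if (flip) img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (length(baseline$pb) != n_bins) {
    stop("baseline and profile breakpoint counts differ")
  }
  mask <- make_patch_mask(img, config)
  p <- pixel_pigmentation(img, mask, pigment_color)
  roi <- select_roi(mask)
  pe <- effective_pigmentation(p, baseline$pb_min)
  prof <- corrected_profile(pe, mask, roi, baseline)
  attr(prof, "orientation") <- "interaction_left"
  prof
}
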