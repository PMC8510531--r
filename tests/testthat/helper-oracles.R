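# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Textbook sRGB -> XYZ (D65) -> CIELAB conversion, normalized into the
# package's unit-sphere frame (L*/100, a*/255, b*/255).
reference_lab <- function(rgb01) {
  if (is.null(dim(rgb01))) rgb01 <- matrix(rgb01, nrow = 1)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92,
                ((rgb01 + 0.055) / 1.055)^2.4)
  xyz <- t(M %*% t(lin))
  wn <- c(0.95047, 1.00000, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(sweep(xyz, 2, wn, "/"))
  cbind((116 * fx[, 2] - 16) / 100,
        500 * (fx[, 1] - fx[, 2]) / 255,
        200 * (fx[, 2] - fx[, 3]) / 255)
}

# Brute-force connected-component labeling by iterated minimum-label
# propagation: every foreground pixel starts with its own linear index as
# label and repeatedly adopts the minimum label among itself and its
# neighbours until a fixed point. Independent of the BFS implementation.
brute_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- which(mask)
  shifts4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  shifts8 <- c(shifts4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  shifts <- if (connectivity == 8) shifts8 else shifts4
  repeat {
    new <- lab
    for (s in shifts) {
      shifted <- matrix(0L, h, w)
      rs <- max(1, 1 + s[1]):min(h, h + s[1])
      cs <- max(1, 1 + s[2]):min(w, w + s[2])
      shifted[rs, cs] <- lab[rs - s[1], cs - s[2]]
      upd <- mask & shifted > 0 & (new == 0 | shifted < new)
      new[upd] <- shifted[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Relabel components in column-major order of first appearance so two
# labelings of the same partition compare equal.
normalize_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# A uniform-color H x W x 3 image.
flat_image <- function(hex, h, w) {
  rgb <- as.numeric(hex_to_srgb(hex))
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Small, fast synthetic-plate parameters for tests that only need a
# working image, not the default study-scale geometry.
small_plate_params <- function(...) {
  defaults <- list(width = 300, height = 200, axes = c(120, 60),
                   speck_radius = 3, hole_radius = 5)
  do.call(plate_sim_params, utils::modifyList(defaults, list(...)))
}

# A pigmentation_profile from a plain vector of bin means.
profile_from_means <- function(means, sd = 0) {
  structure(data.frame(bin = seq_along(means), mean = means,
                       sd = sd, n_pixels = 1L),
            orientation = "interaction_left",
            class = c("pigmentation_profile", "data.frame"))
}
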