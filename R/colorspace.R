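#' Parse hexadecimal sRGB colors
#'
#' Accepts 6-hex-digit color strings, case-insensitive, with or without a
#' leading `#`, and returns sRGB channel values scaled to `[0, 1]`.
#'
#' @param hex Character vector of colors such as `"803D33"` or `"#33393e"`.
#' @return A numeric matrix with one row per color and columns `r`, `g`, `b`
#'   in `[0, 1]`.
#' @examples
#' hex_to_srgb("803D33")
#' @export
hex_to_srgb <- function(hex) {
  if (!is.character(hex)) stop("colors must be given as hex strings")
  clean <- sub("^#", "", trimws(hex))
  bad <- !grepl("^[0-9a-fA-F]{6}$", clean)
  if (any(bad)) {
    stop(sprintf("malformed hex color: '%s'", hex[which(bad)[1]]))
  }
  out <- t(grDevices::col2rgb(paste0("#", clean))) / 255
  colnames(out) <- c("r", "g", "b")
  rownames(out) <- NULL
  out
}

#' Format an sRGB triple as a hex string
#'
#' @param rgb Numeric vector or 1-row matrix of channel values in `[0, 1]`.
#' @return A 6-hex-digit string (no leading `#`).
#' @export
srgb_to_hex <- function(rgb) {
  rgb <- as_srgb_matrix(rgb)
  toupper(substring(grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3]), 2))
}

# Coerce hex strings / vectors / matrices to an N x 3 sRGB matrix in [0, 1].
as_srgb_matrix <- function(col) {
  if (is.character(col)) return(hex_to_srgb(col))
  if (is.null(dim(col))) {
    if (length(col) != 3L) stop("an sRGB color needs 3 channels")
    col <- matrix(col, nrow = 1L)
  }
  col <- as.matrix(col)
  if (ncol(col) != 3L) stop("sRGB matrix must have 3 columns")
  if (any(col < 0 | col > 1, na.rm = TRUE))
    stop("sRGB channel values must lie in [0, 1]")
  col
}

#' Convert sRGB colors to the normalized CIELAB frame
#'
#' Colors are converted to CIELAB (D65 white point, 2 degree observer,
#' standard sRGB transfer function) and then rescaled so the whole space
#' fits a sphere of diameter 1 centered at mid-gray: lightness
#' `lam = L*/100` and the opponent axes `alp = a*/ab_scale`,
#' `bet = b*/ab_scale`. Mid-gray (`L* = 50, a* = b* = 0`) maps to
#' `(0.5, 0, 0)`, the center of the sphere; all pixel color distance
#' calculations happen in this frame.
#'
#' @param col Hex string(s), a length-3 vector, or an N x 3 matrix of sRGB
#'   values in `[0, 1]`.
#' @param ab_scale Divisor applied to `a*` and `b*` (default 255, i.e. the
#'   nominal 8-bit opponent-axis span). Exposed because the normalization
#'   convention, not the conversion itself, is a modelling choice.
#' @return An N x 3 matrix with columns `lam`, `alp`, `bet`.
#' @examples
#' srgb_to_lab("FFFFFF") # lightness 1, opponent axes ~ 0
#' @export
srgb_to_lab <- function(col, ab_scale = 255) {
  rgb <- as_srgb_matrix(col)
  lab <- farver::convert_colour(rgb * 255, from = "rgb", to = "lab",
                                white_from = "D65", white_to = "D65")
  out <- cbind(lam = lab[, 1] / 100,
               alp = lab[, 2] / ab_scale,
               bet = lab[, 3] / ab_scale)
  rownames(out) <- NULL
  out
}

# Coerce to an N x 3 normalized-Lab matrix; hex/sRGB input is converted.
as_lab_matrix <- function(col) {
  if (is.character(col)) return(srgb_to_lab(col))
  if (is.null(dim(col))) {
    if (length(col) != 3L) stop("a Lab color needs 3 coordinates")
    col <- matrix(col, nrow = 1L)
  }
  col <- as.matrix(col)
  if (ncol(col) != 3L) stop("Lab matrix must have 3 columns")
  col
}

#' Euclidean color distance in the normalized CIELAB frame
#'
#' @param x,y Normalized Lab coordinates (N x 3 matrices, length-3 vectors,
#'   or hex strings); rows are recycled if one argument has a single color.
#' @return Numeric vector of distances.
#' @export
color_distance <- function(x, y) {
  x <- as_lab_matrix(x); y <- as_lab_matrix(y)
  if (nrow(x) == 1L && nrow(y) > 1L) x <- x[rep(1L, nrow(y)), , drop = FALSE]
  if (nrow(y) == 1L && nrow(x) > 1L) y <- y[rep(1L, nrow(x)), , drop = FALSE]
  sqrt(rowSums((x - y)^2))
}

#' Maximum attainable distance from a target color
#'
#' Within the unit-diameter color sphere the farthest point from a target
#' `c` is diametrically opposite through the center, so
#' `d_max = distance(c, center) + 0.5` with center `(0.5, 0, 0)`. A target
#' at the center has `d_max = 0.5`; a target on the sphere surface has
#' `d_max = 1`.
#'
#' @param target Normalized Lab coordinates or hex string(s).
#' @return Numeric vector of maximum distances.
#' @export
max_distance <- function(target) {
  target <- as_lab_matrix(target)
  color_distance(target, c(0.5, 0, 0)) + 0.5
}

#' Normalized pixel color distance (PCDC)
#'
#' The pixel color distance calculation: the Euclidean distance from each
#' pixel to the target color, divided by the target's maximum attainable
#' distance and clamped into `[0, 1]`. 0 means the pixel matches the target
#' exactly; 1 means it is maximally different. Saturated colors can fall
#' marginally outside the unit sphere, hence the clamp.
#'
#' @param pixel Pixel color(s): hex, length-3 Lab vector, or N x 3 Lab
#'   matrix.
#' @param target A single target color (hex or Lab).
#' @return Numeric vector of normalized distances in `[0, 1]`.
#' @export
normalized_distance <- function(pixel, target) {
  target <- as_lab_matrix(target)
  if (nrow(target) != 1L) stop("normalized_distance expects a single target")
  d <- color_distance(pixel, target)
  pmin(1, pmax(0, d / max_distance(target)[1]))
}

# Flatten an H x W x 3 raster into an (H*W) x 3 normalized-Lab matrix.
raster_to_lab <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  srgb_to_lab(cbind(as.vector(img[, , 1]),
                    as.vector(img[, , 2]),
                    as.vector(img[, , 3])))
}

# Per-pixel normalized distance of a raster to a target color, as an
# H x W matrix.
raster_distance <- function(img, target) {
  d <- normalized_distance(raster_to_lab(img), as_lab_matrix(target))
  matrix(d, nrow = dim(img)[1], ncol = dim(img)[2])
}
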