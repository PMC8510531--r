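# Readers and writers for the pipeline's file formats. All tabular
# outputs are TSV with headers; masks are written as 1-bit-style PNGs
# with a JSON corrections log alongside.

#' Load a plate image
#'
#' Reads PNG or TIFF into an H x W x 3 sRGB array in `[0, 1]`. Grayscale
#' images are expanded to 3 channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path))
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image as PNG
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path Output path.
#' @export
save_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as PNG plus a JSON corrections log
#'
#' @param mask A `binary_mask`.
#' @param path Output PNG path; the log goes to `<path>.json`.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  jsonlite::write_json(corrections_log(mask), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a pigmentation profile as TSV
#'
#' Columns `bin_index`, `mean_Pf`, `sd_Pf`, `n_pixels`.
#'
#' @param profile A `pigmentation_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(bin_index = profile$bin, mean_Pf = profile$mean,
                    sd_Pf = profile$sd, n_pixels = profile$n_pixels)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path)
  new_profile(data.frame(bin = df$bin_index, mean = df$mean_Pf,
                         sd = df$sd_Pf, n_pixels = df$n_pixels))
}

#' Write / read a baseline distribution as TSV
#'
#' Columns `bin_index`, `Pb`; `Pb_min` is recomputed on read.
#'
#' @param baseline A `baseline_distribution`.
#' @param path File path.
#' @export
write_baseline <- function(baseline, path) {
  utils::write.table(
    data.frame(bin_index = seq_along(baseline$pb), Pb = baseline$pb),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  df <- utils::read.delim(path)
  structure(list(pb = df$Pb, pb_min = min(df$Pb), n_images = NA_integer_),
            class = "baseline_distribution")
}
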