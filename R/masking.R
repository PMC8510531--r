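#' Masking configuration
#'
#' Parameters controlling how a plate image is turned into a binary patch
#' mask. Defaults are the pipeline's standard settings: agar target color
#' `33393E`, background cutoff 0.15 (normalized color distance), noise
#' components below 2% of the image area removed, interior holes below 20%
#' of the image area filled, 8-connectivity for foreground components.
#' Background hole components use the dual connectivity (4 when the
#' foreground uses 8, and vice versa), which avoids the topological
#' paradoxes of using one connectivity for both phases.
#'
#' @param background_color Agar target color (hex or sRGB triple).
#' @param background_cutoff Pixels at normalized distance `<= cutoff` from
#'   the background color are classified as background.
#' @param noise_fraction Foreground components smaller than this fraction
#'   of total image pixels are erased as noise.
#' @param hole_fraction Interior background components smaller than this
#'   fraction of total image pixels are filled as part of the patch.
#' @param connectivity Pixel connectivity for foreground components, 4 or 8.
#' @return A list of class `masking_config`.
#' @export
masking_config <- function(background_color = "33393E",
                           background_cutoff = 0.15,
                           noise_fraction = 0.02,
                           hole_fraction = 0.20,
                           connectivity = 8) {
  stopifnot(background_cutoff > 0, background_cutoff < 1,
            noise_fraction > 0, hole_fraction < 1,
            noise_fraction < hole_fraction)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(background_color = background_color,
                 background_cutoff = background_cutoff,
                 noise_fraction = noise_fraction,
                 hole_fraction = hole_fraction,
                 connectivity = as.integer(connectivity)),
            class = "masking_config")
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer matrix of component labels (background = 0), numbered
#'   in column-major order of first appearance.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "logical"
  .label_components_cpp(mask, as.integer(connectivity))
}

new_binary_mask <- function(values, corrections = list()) {
  structure(values, corrections = corrections, class = "binary_mask")
}

add_correction <- function(mask, op, components_changed, pixels_changed) {
  log <- attr(mask, "corrections")
  log[[length(log) + 1L]] <- list(operation = op,
                                  components_changed = components_changed,
                                  pixels_changed = pixels_changed)
  attr(mask, "corrections") <- log
  mask
}

#' Corrections applied while building a mask
#'
#' @param mask A `binary_mask`.
#' @return A data frame with one row per correction step (operation,
#'   components changed, pixels changed).
#' @export
corrections_log <- function(mask) {
  log <- attr(mask, "corrections")
  if (is.null(log) || !length(log)) {
    return(data.frame(operation = character(), components_changed = integer(),
                      pixels_changed = integer()))
  }
  do.call(rbind, lapply(log, as.data.frame))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary mask %d x %d: %d foreground pixels (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  log <- corrections_log(x)
  if (nrow(log)) {
    cat("corrections:\n")
    print(log, row.names = FALSE)
  }
  invisible(x)
}

#' Classify background pixels by color distance
#'
#' A pixel belongs to the background (agar) when its normalized CIELAB
#' distance to the background target color is at or below the cutoff;
#' everything else is foreground.
#'
#' @param img H x W x 3 sRGB array with channels in `[0, 1]`.
#' @param config A [masking_config()].
#' @return A `binary_mask` (`TRUE` = foreground).
#' @export
classify_background <- function(img, config = masking_config()) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- raster_distance(img, config$background_color)
  new_binary_mask(d > config$background_cutoff)
}

#' Remove small foreground components
#'
#' Foreground connected components covering less than `noise_fraction` of
#' the total image pixels are treated as specks (bubbles, agar
#' imperfections) and erased. A component of exactly the threshold size is
#' kept: the rule is strictly "less than".
#'
#' @param mask A `binary_mask`.
#' @param config A [masking_config()].
#' @return The corrected `binary_mask`; errors if nothing survives.
#' @export
remove_foreground_noise <- function(mask, config = masking_config()) {
  lab <- label_components(mask, config$connectivity)
  sizes <- tabulate(lab)
  cut <- config$noise_fraction * length(mask)
  drop <- which(sizes < cut & sizes > 0)
  out <- mask
  if (length(drop)) out[lab %in% drop] <- FALSE
  if (!any(out)) stop("no patch found: every foreground component was below the noise threshold")
  new_binary_mask(unclass(out),
                  attr(mask, "corrections")) |>
    add_correction("remove_foreground_noise", length(drop),
                   as.integer(sum(sizes[drop])))
}

#' Fill interior holes in the patch
#'
#' Background connected components that do not touch the image border
#' (interior holes) and cover less than `hole_fraction` of the total image
#' pixels are reassigned to the patch. Border-connected background (the
#' agar) is never filled, and a hole of exactly the threshold size is
#' retained.
#'
#' @param mask A `binary_mask` with at least one foreground component.
#' @param config A [masking_config()].
#' @return The corrected `binary_mask`.
#' @export
fill_holes <- function(mask, config = masking_config()) {
  bg_conn <- if (config$connectivity == 8L) 4L else 8L
  lab <- label_components(!mask, bg_conn)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0]
  sizes <- tabulate(lab)
  cut <- config$hole_fraction * length(mask)
  fill <- setdiff(which(sizes < cut & sizes > 0), border)
  out <- mask
  if (length(fill)) out[lab %in% fill] <- TRUE
  new_binary_mask(unclass(out),
                  attr(mask, "corrections")) |>
    add_correction("fill_holes", length(fill),
                   as.integer(sum(sizes[fill])))
}

#' Build the patch mask for a plate image
#'
#' Composition of [classify_background()], [remove_foreground_noise()] and
#' [fill_holes()], in that order. The finished mask must contain exactly
#' one foreground component (the patch); anything else is an error.
#'
#' @param img H x W x 3 sRGB array with channels in `[0, 1]`.
#' @param config A [masking_config()].
#' @return A `binary_mask` with a corrections log.
#' @export
make_patch_mask <- function(img, config = masking_config()) {
  mask <- classify_background(img, config)
  if (!any(mask)) stop("no patch found: image is entirely background")
  mask <- remove_foreground_noise(mask, config)
  mask <- fill_holes(mask, config)
  ncomp <- max(label_components(mask, config$connectivity))
  if (ncomp != 1L) {
    stop(sprintf("expected exactly one patch component, found %d", ncomp))
  }
  mask
}
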