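# Synthetic plate images and differential-expression tables with known
# ground truth, so every pipeline stage can be exercised without the
# study's raw photographs or sequencing data.

#' One-dimensional pigment weight functions
#'
#' Ground-truth spatial pigmentation patterns along the patch's
#' normalized horizontal axis (`x = 0` is the edge facing the interacting
#' strain). `profile_first_quarter_peak` emulates the wild-type
#' interaction phenotype: intense pigmentation in the first quarter of
#' the patch followed by lighter pigmentation across the rest.
#'
#' @param x Normalized position in `[0, 1]`.
#' @return Pigment weight in `[0, 1]`.
#' @name profile_functions
NULL

#' @rdname profile_functions
#' @param level Constant weight.
#' @export
profile_flat <- function(level = 0) function(x) rep(level, length(x))

#' @rdname profile_functions
#' @param at Step position; `high` applies for `x <= at`.
#' @param high,low Weights on either side of the step.
#' @export
profile_step <- function(at = 0.25, high = 0.9, low = 0.1) {
  function(x) ifelse(x <= at, high, low)
}

#' @rdname profile_functions
#' @export
profile_ramp <- function(high = 0.9, low = 0.05) {
  function(x) high - (high - low) * x
}

#' @rdname profile_functions
#' @export
profile_first_quarter_peak <- function(high = 0.85, low = 0.15) {
  function(x) low + (high - low) * exp(-((x - 0.125) / 0.1)^2)
}

#' Parameters for the synthetic plate generator
#'
#' The defaults mirror the imaging conditions of the reference study: an
#' elliptical bacterial patch on dark agar (`33393E`), an unpigmented
#' colony base color (`CCC3B2`, whose pigmentation score sits at the
#' published unpigmented baseline of about 0.34), the red pigment target
#' `803D33`, a mild multiplicative edge vignette emulating the shadowing
#' of the three-dimensional patch rim, Gaussian channel noise, off-patch
#' specks, and interior holes. Specks and holes are sized well below the
#' masking module's correction thresholds so the ground-truth footprint
#' is exactly recoverable.
#'
#' @param width,height Image size in pixels.
#' @param agar_color,colony_base_color,pigment_color Hex colors.
#' @param center Patch center `(row, col)`; defaults to the image
#'   center.
#' @param axes Patch semi-axes `(rx, ry)` in pixels (columns, rows).
#' @param shape_exponent Superellipse exponent: 2 gives an ellipse, the
#'   default 4 a rounded rectangle like a streaked patch.
#' @param profile_fn Pigment weight function over normalized x.
#' @param speck_count,speck_radius Off-patch specks (colony-colored).
#' @param hole_count,hole_radius Interior agar-colored holes.
#' @param vignette_strength Maximum fractional linear-light luminance drop
#'   at the patch rim (quadratic radial falloff).
#' @param pixel_noise_sd Gaussian channel noise SD in 8-bit units.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `plate_sim_params`.
#' @export
plate_sim_params <- function(width = 600, height = 360,
                             agar_color = "33393E",
                             colony_base_color = "CCC3B2",
                             pigment_color = "803D33",
                             center = NULL,
                             axes = c(280, 130),
                             shape_exponent = 4,
                             profile_fn = profile_first_quarter_peak(),
                             speck_count = 6, speck_radius = 4,
                             hole_count = 3, hole_radius = 8,
                             vignette_strength = 0.06,
                             pixel_noise_sd = 2,
                             seed = 1L) {
  if (is.null(center)) center <- c(height / 2, width / 2)
  npix <- width * height
  if (pi * speck_radius^2 >= 0.02 * npix) {
    stop("specks must stay below the 2% noise-removal threshold")
  }
  if (pi * hole_radius^2 >= 0.20 * npix) {
    stop("holes must stay below the 20% hole-fill threshold")
  }
  if (center[2] - axes[1] < 1 || center[2] + axes[1] > width ||
      center[1] - axes[2] < 1 || center[1] + axes[2] > height) {
    stop("patch ellipse exceeds the image bounds")
  }
  structure(list(width = width, height = height, agar_color = agar_color,
                 colony_base_color = colony_base_color,
                 pigment_color = pigment_color, center = center,
                 axes = axes, shape_exponent = shape_exponent,
                 profile_fn = profile_fn,
                 speck_count = speck_count, speck_radius = speck_radius,
                 hole_count = hole_count, hole_radius = hole_radius,
                 vignette_strength = vignette_strength,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
            class = "plate_sim_params")
}

srgb_decode <- function(u) {
  out <- u
  lo <- !is.na(u) & u <= 0.04045
  out[lo] <- u[lo] / 12.92
  out[!lo] <- ((u[!lo] + 0.055) / 1.055)^2.4
  out
}
srgb_encode <- function(u) {
  out <- u
  lo <- !is.na(u) & u <= 0.0031308
  out[lo] <- 12.92 * u[lo]
  out[!lo] <- 1.055 * u[!lo]^(1 / 2.4) - 0.055
  out
}

disc_indices <- function(h, w, center, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  which((rows - center[1])^2 + (cols - center[2])^2 <= radius^2)
}

#' Generate a synthetic plate image with known ground truth
#'
#' Renders an elliptical patch whose pixel colors are a linear-light
#' convex blend of the colony base color and the pigment color, weighted
#' by `profile_fn` of the normalized horizontal position within the
#' patch's bounding box. A quadratic radial vignette darkens the patch
#' rim, Gaussian channel noise is added everywhere, interior holes are
#' painted agar-colored, and small colony-colored specks are scattered on
#' the agar. The generator is a pure function of its parameters: the same
#' seed yields a bit-identical image.
#'
#' @param params A [plate_sim_params()] list.
#' @return A list with `image` (H x W x 3 array in `[0, 1]`), `footprint`
#'   (the true patch mask, holes included as patch), `truth_profile` (the
#'   pigment weight at 200 breakpoint centers), and `params`.
#' @export
generate_plate <- function(params = plate_sim_params()) {
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    rx <- params$axes[1]; ry <- params$axes[2]
    e <- params$shape_exponent
    rho <- (abs((cols - params$center[2]) / rx)^e +
            abs((rows - params$center[1]) / ry)^e)^(1 / e)
    footprint <- rho <= 1

    agar <- srgb_decode(hex_to_srgb(params$agar_color))
    base <- srgb_decode(hex_to_srgb(params$colony_base_color))
    pig <- srgb_decode(hex_to_srgb(params$pigment_color))

    xmin <- min(cols[footprint]); xmax <- max(cols[footprint])
    xnorm <- (cols - xmin) / (xmax - xmin)
    weight <- matrix(params$profile_fn(pmin(1, pmax(0, as.vector(xnorm)))),
                     h, w)
    shade <- 1 - params$vignette_strength * pmin(rho, 1)^2

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      lin <- matrix(agar[ch], h, w)
      patch_lin <- (1 - weight) * base[ch] + weight * pig[ch]
      lin[footprint] <- (patch_lin * shade)[footprint]
      img[, , ch] <- lin
    }

    # Interior agar-colored holes on the patch's upper/lower shoulders,
    # where specular glare on the domed colony surface occurs; kept off
    # the central profiling band and away from the rim.
    for (k in seq_len(params$hole_count)) {
      ang <- runif(1, pi / 6, 5 * pi / 6) * sample(c(-1, 1), 1)
      rad <- runif(1, 0.6, 0.85)
      ctr <- c(params$center[1] + rad * ry * sin(ang),
               params$center[2] + rad * rx * cos(ang))
      idx <- disc_indices(h, w, ctr, params$hole_radius)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[idx] <- agar[ch]; img[, , ch] <- plane
      }
    }
    # off-patch specks in colony color
    placed <- 0L; tries <- 0L
    while (placed < params$speck_count && tries < 200L) {
      tries <- tries + 1L
      ctr <- c(runif(1, 1, h), runif(1, 1, w))
      rho_s <- (abs((ctr[2] - params$center[2]) / rx)^e +
                abs((ctr[1] - params$center[1]) / ry)^e)^(1 / e)
      if (rho_s < 1.2) next # keep specks clear of the patch
      idx <- disc_indices(h, w, ctr, params$speck_radius)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[idx] <- base[ch]; img[, , ch] <- plane
      }
      placed <- placed + 1L
    }

    img <- srgb_encode(pmin(pmax(img, 0), 1))
    if (params$pixel_noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, params$pixel_noise_sd / 255),
                         dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    # quantize to 8 bits, as a camera would
    img <- round(img * 255) / 255

    centers <- (seq_len(200) - 0.5) / 200
    list(image = img, footprint = footprint,
         truth_profile = params$profile_fn(centers), params = params)
  })
}

#' Parameters for the synthetic expression-table generator
#'
#' @param n_genes Number of genes per table (default 8000, about the size
#'   of the *S. coelicolor* genome).
#' @param null_mean,null_sd Normal distribution of null log2 fold
#'   changes.
#' @param planted List of planted regulation groups, each a list with
#'   `genes` (character ids), `effect` (log2 fold change added), and
#'   `conditions` (integer vector of condition indices the effect applies
#'   in).
#' @param n_conditions Number of comparison tables to generate.
#' @param planted_p_max Planted genes draw p-values uniformly from
#'   `[0, planted_p_max]`; null genes from `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `de_sim_params`.
#' @export
de_sim_params <- function(n_genes = 8000,
                          null_mean = 0, null_sd = 1,
                          planted = list(
                            list(genes = sprintf("PLANT_ALL%02d", 1:5),
                                 effect = 8, conditions = 1:4),
                            list(genes = sprintf("PLANT_TRI%02d", 1:8),
                                 effect = 5, conditions = 1:3)),
                          n_conditions = 4,
                          planted_p_max = 1e-4,
                          seed = 1L) {
  ids <- unlist(lapply(planted, `[[`, "genes"))
  if (anyDuplicated(ids)) stop("planted gene sets must be disjoint")
  structure(list(n_genes = n_genes, null_mean = null_mean,
                 null_sd = null_sd, planted = planted,
                 n_conditions = n_conditions,
                 planted_p_max = planted_p_max, seed = as.integer(seed)),
            class = "de_sim_params")
}

#' Generate synthetic differential-expression tables
#'
#' Per condition, null genes draw log2 fold changes from the null normal
#' distribution with uniform p-values; planted genes are shifted by their
#' group's effect size with near-zero p-values in the conditions the
#' group applies to. The truth record lists the planted gene ids per
#' condition.
#'
#' @param params A [de_sim_params()] list.
#' @return A list with `tables` (named list of `de_table`) and `truth`
#'   (`planted_by_condition`, a list of character vectors).
#' @export
generate_de_tables <- function(params = de_sim_params()) {
  with_seed(params$seed, {
    planted_ids <- unlist(lapply(params$planted, `[[`, "genes"))
    n_null <- params$n_genes - length(planted_ids)
    if (n_null < 0) stop("more planted genes than genes in the table")
    ids <- c(planted_ids, sprintf("GENE%05d", seq_len(n_null)))
    tables <- list()
    truth <- vector("list", params$n_conditions)
    for (cond in seq_len(params$n_conditions)) {
      lfc <- rnorm(params$n_genes, params$null_mean, params$null_sd)
      pv <- runif(params$n_genes)
      here <- character()
      for (grp in params$planted) {
        if (!cond %in% grp$conditions) next
        at <- match(grp$genes, ids)
        lfc[at] <- lfc[at] + grp$effect
        pv[at] <- runif(length(at), 0, params$planted_p_max)
        here <- c(here, grp$genes)
      }
      lab <- sprintf("condition%d_vs_control", cond)
      tables[[lab]] <- de_table(ids, lfc, pv, comparison = lab)
      truth[[cond]] <- here
    }
    list(tables = tables, truth = list(planted_by_condition = truth))
  })
}
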