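#' Aggregate replicate pigmentation profiles
#'
#' Per-breakpoint mean and sample (n - 1) standard deviation across a set
#' of replicate profiles of the same condition. All profiles must share
#' the breakpoint count and orientation.
#'
#' @param profiles List of `pigmentation_profile` objects (the reference
#'   study used 20 replicates per interaction condition).
#' @param condition Optional condition label carried into the result.
#' @return A list of class `aggregate_profile` with elements `mean`, `sd`
#'   (vectors over breakpoints), `n`, and `condition`.
#' @export
aggregate_profiles <- function(profiles, condition = NULL) {
  if (!length(profiles)) stop("at least one profile is required")
  ori <- unique(vapply(profiles, function(p) {
    o <- attr(p, "orientation"); if (is.null(o)) "interaction_left" else o
  }, ""))
  if (length(ori) > 1L) stop("profiles have mixed orientations")
  m <- do.call(cbind, lapply(profiles, function(p) p$mean))
  if (length(unique(vapply(profiles, nrow, 0L))) != 1L) {
    stop("profiles have differing breakpoint counts")
  }
  structure(list(mean = rowMeans(m),
                 sd = if (ncol(m) > 1L) apply(m, 1L, stats::sd)
                      else rep(0, nrow(m)),
                 n = length(profiles),
                 condition = condition),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf(
    "aggregate profile over %d replicates%s: mean pigmentation %.3f (max %.3f)\n",
    x$n, if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    mean(x$mean), max(x$mean)))
  invisible(x)
}

#' Select the representative replicate
#'
#' Picks the replicate most similar to the across-replicate average
#' profile, measured by Euclidean distance between the 200-breakpoint mean
#' vectors; ties go to the lowest index. This is the replicate shown as
#' "representative" in figures.
#'
#' @param profiles List of `pigmentation_profile` objects.
#' @return The 1-based index of the representative replicate, with the
#'   distances of all replicates attached as attribute `distances`.
#' @export
select_representative <- function(profiles) {
  agg <- aggregate_profiles(profiles)
  d <- vapply(profiles, function(p) sqrt(sum((p$mean - agg$mean)^2)), 0)
  structure(which.min(d), distances = d)
}
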