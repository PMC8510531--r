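#' Pipeline configuration
#'
#' Bundles every tunable of the image pipeline. A run writes the resolved
#' configuration alongside its outputs so results are traceable to the
#' exact settings that produced them.
#'
#' @param masking A [masking_config()].
#' @param pigment_color Pigment target color.
#' @param baseline A `baseline_distribution`, a baseline TSV path, or
#'   `NULL` for the packaged default.
#' @param flip Mirror images horizontally (interacting partner on the
#'   right).
#' @param n_bins Number of profile breakpoints.
#' @param seed Seed used by simulation entry points.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(masking = masking_config(),
                            pigment_color = "803D33",
                            baseline = NULL,
                            flip = FALSE,
                            n_bins = 200L,
                            seed = 1L) {
  structure(list(masking = masking, pigment_color = pigment_color,
                 baseline = baseline, flip = flip,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_baseline <- function(baseline, n_bins) {
  if (is.null(baseline)) return(default_baseline(n_bins = n_bins))
  if (is.character(baseline)) return(read_baseline(baseline))
  baseline
}

config_as_list <- function(config) {
  list(masking = unclass(config$masking),
       pigment_color = config$pigment_color,
       baseline = if (is.character(config$baseline)) config$baseline
                  else if (is.null(config$baseline)) "packaged-default"
                  else "in-memory",
       flip = config$flip, n_bins = config$n_bins, seed = config$seed)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    masking = do.call(masking_config, y$masking),
    pigment_color = y$pigment_color,
    baseline = if (identical(y$baseline, "packaged-default")) NULL
               else y$baseline,
    flip = isTRUE(y$flip), n_bins = y$n_bins, seed = y$seed)
}

provenance_record <- function(config, inputs) {
  hashes <- vapply(inputs, function(f) {
    if (is.character(f) && file.exists(f)) unname(tools::md5sum(f))
    else NA_character_
  }, "")
  list(tool = "pigmentr",
       version = as.character(utils::packageVersion("pigmentr")),
       config = config_as_list(config),
       inputs = data.frame(input = vapply(inputs, function(f) {
         if (is.character(f)) f else "<in-memory image>"
       }, ""), md5 = hashes))
}

#' Run the image pipeline over a replicate set
#'
#' For each input image: build the patch mask, extract the
#' baseline-normalized pigmentation profile, and write it as TSV. Then
#' aggregate the successful profiles, select the representative
#' replicate, write the aggregate TSV, a JSON record naming the
#' representative, a profile plot, and a provenance record. Unreadable or
#' failing inputs are reported and skipped; the run fails only if every
#' input fails.
#'
#' @param images Character paths or a list of H x W x 3 arrays.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param condition Condition label used in output names.
#' @param plot Also write a `profiles.pdf` overview plot.
#' @return Invisibly, a list with `profiles`, `aggregate`,
#'   `representative`, and `failures`.
#' @export
run_image_pipeline <- function(images, config = pipeline_config(),
                               out_dir = ".", condition = "condition",
                               plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  baseline <- resolve_baseline(config$baseline, config$n_bins)
  names_in <- if (is.character(images)) {
    tools::file_path_sans_ext(basename(images))
  } else {
    sprintf("%s_rep%02d", condition, seq_along(images))
  }
  profiles <- list(); failures <- character()
  for (i in seq_along(images)) {
    img <- if (is.character(images)) images[[i]] else images[[i]]
    res <- tryCatch(
      extract_profile(img, baseline = baseline, config = config$masking,
                      pigment_color = config$pigment_color,
                      flip = config$flip, n_bins = config$n_bins),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s: %s", names_in[i], conditionMessage(res)))
      next
    }
    profiles[[names_in[i]]] <- res
    write_profile(res, file.path(out_dir,
                                 paste0(names_in[i], "_profile.tsv")))
  }
  if (!length(profiles)) {
    stop(sprintf("all %d inputs failed:\n%s", length(images),
                 paste(failures, collapse = "\n")))
  }
  agg <- aggregate_profiles(profiles, condition = condition)
  rep_idx <- select_representative(profiles)
  utils::write.table(
    data.frame(bin_index = seq_along(agg$mean), mean_Pf = agg$mean,
               sd_Pf = agg$sd, n_replicates = agg$n),
    file.path(out_dir, paste0(condition, "_aggregate.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(condition = condition,
         representative = names(profiles)[rep_idx],
         representative_index = unclass(rep_idx)[1],
         distances = as.numeric(attr(rep_idx, "distances")),
         failures = failures),
    file.path(out_dir, paste0(condition, "_representative.json")),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    provenance_record(config, as.list(images)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  if (plot) {
    plot_profiles(profiles, agg,
                  file.path(out_dir, paste0(condition, "_profiles.pdf")))
  }
  if (length(failures)) {
    warning(sprintf("%d input(s) failed: %s", length(failures),
                    paste(failures, collapse = "; ")))
  }
  invisible(list(profiles = profiles, aggregate = agg,
                 representative = rep_idx, failures = failures))
}

# Overview plot: per-replicate profiles in gray, aggregate mean +/- SD.
plot_profiles <- function(profiles, agg, path) {
  per_rep <- do.call(rbind, lapply(names(profiles), function(n) {
    data.frame(replicate = n, bin = profiles[[n]]$bin,
               mean = profiles[[n]]$mean)
  }))
  agg_df <- data.frame(bin = seq_along(agg$mean), mean = agg$mean,
                       lo = pmax(0, agg$mean - agg$sd),
                       hi = pmin(1, agg$mean + agg$sd))
  gg <- ggplot2::ggplot(agg_df, ggplot2::aes(x = bin, y = mean)) +
    ggplot2::geom_line(data = per_rep,
                       ggplot2::aes(group = replicate),
                       color = "gray70", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "black", linewidth = 0.8) +
    ggplot2::labs(x = "breakpoint (1 = interaction edge)",
                  y = "pigmentation (P_f)") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 6, height = 4)
  invisible(path)
}

#' Run the expression pipeline over a set of comparison tables
#'
#' Applies the 2-SD rule and a fixed fold-change rule to each table,
#' writes per-table flag TSVs, the shared-gene (Venn) counts as JSON,
#' and, when cluster definitions are supplied, a cluster-summary TSV
#' with mean/SD log2 fold change per cluster and table.
#'
#' @param tables Named list of `de_table` objects or file paths.
#' @param clusters Named list of `gene_cluster_def`, a cluster TSV path,
#'   or `NULL`.
#' @param out_dir Output directory.
#' @param min_abs_log2fc Threshold for the fixed fold-change rule.
#' @param alpha Significance cutoff.
#' @param use_padj Use adjusted instead of raw p-values.
#' @return Invisibly, a list with `flags_2sd`, `flags_threshold`, `venn`,
#'   and `cluster_summary`.
#' @export
run_expression_pipeline <- function(tables, clusters = NULL,
                                    out_dir = ".",
                                    min_abs_log2fc = 2, alpha = 0.05,
                                    use_padj = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(tables)) {
    paths <- tables
    tables <- lapply(paths, read_de_table)
    names(tables) <- tools::file_path_sans_ext(basename(paths))
  }
  if (is.null(names(tables))) {
    names(tables) <- sprintf("table%d", seq_along(tables))
  }
  if (is.character(clusters)) clusters <- read_cluster_defs(clusters)

  # header-only tables yield empty flag sets rather than an error
  empty_or <- function(tab, fn, ...) {
    if (nrow(tab) == 0L) {
      structure(data.frame(gene_id = character(), flagged = logical()),
                class = c("de_flagset", "data.frame"))
    } else {
      fn(tab, ...)
    }
  }
  flags_2sd <- lapply(tables, empty_or, flag_de_2sd, alpha = alpha,
                      use_padj = use_padj)
  flags_thr <- lapply(tables, empty_or, flag_de_threshold,
                      min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                      use_padj = use_padj)
  for (n in names(tables)) {
    out <- data.frame(gene_id = flags_2sd[[n]]$gene_id,
                      flagged_2sd = flags_2sd[[n]]$flagged,
                      flagged_threshold = flags_thr[[n]]$flagged)
    utils::write.table(out, file.path(out_dir, paste0(n, "_flags.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  venn <- if (length(tables) >= 2L) venn_shared_counts(flags_2sd)
  if (!is.null(venn)) {
    jsonlite::write_json(venn, file.path(out_dir, "venn_counts.json"),
                         digits = NA)
  }
  summary_df <- NULL
  if (!is.null(clusters) && length(clusters)) {
    rows <- list()
    for (n in names(tables)) {
      for (cl in clusters) {
        cs <- tryCatch(cluster_average_lfc(tables[[n]], cl),
                       error = function(e) NULL,
                       warning = function(w) suppressWarnings(
                         cluster_average_lfc(tables[[n]], cl)))
        if (is.null(cs)) next
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = n, cluster = cs$name, mean_log2fc = cs$mean,
          sd_log2fc = cs$sd, n_genes_found = cs$n_found,
          n_genes_missing = length(cs$missing))
      }
    }
    if (length(rows)) {
      summary_df <- do.call(rbind, rows)
      utils::write.table(summary_df,
                         file.path(out_dir, "cluster_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else if (!is.null(clusters)) {
    warning("empty cluster definitions; cluster summaries skipped")
  }
  invisible(list(flags_2sd = flags_2sd, flags_threshold = flags_thr,
                 venn = venn, cluster_summary = summary_df))
}
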