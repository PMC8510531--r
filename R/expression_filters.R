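#' Construct a differential-expression table
#'
#' One strain/condition-versus-control comparison: per-gene log2 fold
#' change and p-value, as produced by a standard differential-expression
#' tool. The selection rules in this package consume these tables; they
#' never recompute the differential test itself.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param log2fc Numeric log2 fold changes.
#' @param pvalue Numeric p-values in `[0, 1]`.
#' @param padj Optional adjusted p-values.
#' @param comparison Optional label for the comparison.
#' @return A data frame of class `de_table`.
#' @export
de_table <- function(gene_id, log2fc, pvalue, padj = NULL,
                     comparison = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique within a table")
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  df <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                   pvalue = as.numeric(pvalue))
  if (!is.null(padj)) df$padj <- as.numeric(padj)
  structure(df, comparison = comparison,
            class = c("de_table", "data.frame"))
}

#' Read a differential-expression table from TSV/CSV
#'
#' Expects a header with columns `gene_id`, `log2fc`, `pvalue` and
#' optionally `padj`; the separator is inferred from the file extension
#' (`.csv` means comma, anything else tab).
#'
#' @param path File path.
#' @param comparison Optional comparison label (defaults to the file
#'   name).
#' @return A `de_table`.
#' @export
read_de_table <- function(path, comparison = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    stop(sprintf("table %s lacks required columns (%s)", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  de_table(df$gene_id, df$log2fc, df$pvalue,
           padj = if ("padj" %in% names(df)) df$padj,
           comparison = comparison %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pvals_for <- function(tab, use_padj) {
  if (use_padj) {
    if (is.null(tab$padj)) stop("table has no padj column")
    tab$padj
  } else {
    tab$pvalue
  }
}

new_flagset <- function(tab, flagged, rule, thresholds) {
  structure(data.frame(gene_id = tab$gene_id, flagged = flagged),
            rule = rule, thresholds = thresholds,
            comparison = attr(tab, "comparison"),
            class = c("de_flagset", "data.frame"))
}

#' Flag differentially expressed genes by the 2-SD rule
#'
#' A gene is flagged when its log2 fold change lies more than two standard
#' deviations from the mean log2 fold change of the entire table and its
#' p-value is below `alpha`. Mean and SD are computed per comparison
#' table, so the criterion is invariant to a location shift of the whole
#' table; on a zero-variance table no gene passes.
#'
#' @param tab A `de_table` with at least 3 genes.
#' @param alpha Significance cutoff on the (raw) p-value, default 0.05.
#' @param use_padj Use the `padj` column instead of raw p-values.
#' @return A `de_flagset` data frame (`gene_id`, `flagged`).
#' @export
flag_de_2sd <- function(tab, alpha = 0.05, use_padj = FALSE) {
  if (nrow(tab) < 3L) stop("need at least 3 genes to estimate mean and SD")
  mu <- mean(tab$log2fc)
  s <- stats::sd(tab$log2fc)
  p <- pvals_for(tab, use_padj)
  flagged <- abs(tab$log2fc - mu) > 2 * s & !is.na(p) & p < alpha
  if (s == 0) flagged[] <- FALSE
  new_flagset(tab, flagged, "2sd",
              list(mean = mu, sd = s, alpha = alpha))
}

#' Flag genes by a fixed fold-change threshold
#'
#' A gene is flagged when `|log2fc| >= min_abs_log2fc` (boundary
#' inclusive) and its p-value is below `alpha`. The reference analyses use
#' 2 (4-fold) for heatmap inclusion and 1.58 (3-fold) for calling
#' significant regulation of specialized-metabolite genes.
#'
#' @inheritParams flag_de_2sd
#' @param min_abs_log2fc Minimum absolute log2 fold change (> 0).
#' @return A `de_flagset` data frame.
#' @export
flag_de_threshold <- function(tab, min_abs_log2fc, alpha = 0.05,
                              use_padj = FALSE) {
  stopifnot(min_abs_log2fc > 0)
  p <- pvals_for(tab, use_padj)
  flagged <- abs(tab$log2fc) >= min_abs_log2fc & !is.na(p) & p < alpha
  new_flagset(tab, flagged, "threshold",
              list(min_abs_log2fc = min_abs_log2fc, alpha = alpha))
}

#' Shared-gene counts across conditions
#'
#' Tallies, over the union of gene identifiers, how many genes are flagged
#' in exactly k and in at least k of the supplied flag sets (the counts
#' behind a multi-condition Venn diagram). A gene absent from a table
#' counts as unflagged there.
#'
#' @param flagsets List of `de_flagset` objects (>= 2).
#' @return A data frame with columns `k`, `exactly`, `at_least`.
#' @export
venn_shared_counts <- function(flagsets) {
  if (length(flagsets) < 2L) stop("need at least 2 flag sets")
  flagged <- lapply(flagsets, function(f) f$gene_id[f$flagged])
  universe <- unique(unlist(flagged))
  k <- length(flagsets)
  if (!length(universe)) {
    return(data.frame(k = seq_len(k), exactly = 0L, at_least = 0L))
  }
  tally <- rowSums(vapply(flagged, function(g) universe %in% g,
                          logical(length(universe))))
  exactly <- vapply(seq_len(k), function(i) sum(tally == i), 0L)
  data.frame(k = seq_len(k), exactly = exactly,
             at_least = rev(cumsum(rev(exactly))))
}

#' Define a gene cluster
#'
#' @param name Cluster name (e.g. `act`, `red`, `cpk`, `lan`).
#' @param gene_ids Ordered, non-empty character vector of gene ids.
#' @return A list of class `gene_cluster_def`.
#' @export
gene_cluster_def <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("a gene cluster needs at least one gene")
  structure(list(name = name, gene_ids = gene_ids),
            class = "gene_cluster_def")
}

#' The lan lanthipeptide cluster definition
#'
#' The cryptic lanthipeptide biosynthetic gene cluster of
#' *Streptomyces coelicolor*, genes SCO6927 through SCO6938.
#'
#' @return A `gene_cluster_def`.
#' @export
lan_cluster <- function() {
  gene_cluster_def("lan", sprintf("SCO%d", 6927:6938))
}

#' Read cluster definitions from a two-column TSV
#'
#' @param path TSV with header columns `cluster_name`, `gene_id`.
#' @return Named list of `gene_cluster_def` objects.
#' @export
read_cluster_defs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_name", "gene_id") %in% names(df))) {
    stop("cluster file needs columns cluster_name and gene_id")
  }
  sets <- split(df$gene_id, df$cluster_name)
  out <- lapply(names(sets), function(n) gene_cluster_def(n, sets[[n]]))
  names(out) <- names(sets)
  out
}

#' Average log2 fold change of a gene cluster
#'
#' Mean and sample SD of the log2 fold changes of the cluster's genes that
#' are present in the table; missing genes are reported, never imputed.
#'
#' @param tab A `de_table`.
#' @param cluster A `gene_cluster_def`.
#' @return A list with `name`, `mean`, `sd`, `n_found`, `missing`, and the
#'   per-gene `values`.
#' @export
cluster_average_lfc <- function(tab, cluster) {
  hit <- match(cluster$gene_ids, tab$gene_id)
  found <- !is.na(hit)
  if (!any(found)) {
    stop(sprintf("no genes of cluster '%s' found in the table",
                 cluster$name))
  }
  vals <- tab$log2fc[hit[found]]
  names(vals) <- cluster$gene_ids[found]
  if (length(vals) == 1L) {
    warning(sprintf("cluster '%s' has a single gene in the table; SD set to 0",
                    cluster$name))
  }
  list(name = cluster$name,
       mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n_found = length(vals),
       missing = cluster$gene_ids[!found],
       values = vals)
}

#' Significance stars for a p-value
#'
#' Maps p-values to the star annotations used in the cluster-summary
#' figures: `****` for p <= 0.0001, `***` for p <= 0.001, `**` for
#' p <= 0.01, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  cut_stars <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x <= 1e-4) "****" else if (x <= 1e-3) "***" else
      if (x <= 1e-2) "**" else if (x <= 0.05) "*" else "ns"
  }
  vapply(p, cut_stars, "")
}

#' Compare cluster expression between two growth conditions
#'
#' Two-sample t-test between the per-gene cluster log2 fold changes of an
#' isolated-growth comparison and an interaction comparison. Welch's
#' unequal-variance test is the default; set `var_equal = TRUE` for the
#' pooled-variance variant.
#'
#' @param iso_values,int_values Numeric vectors (length >= 2) of per-gene
#'   log2 fold changes.
#' @param var_equal Assume equal variances.
#' @return A list with `t`, `p`, `stars`, and the underlying `htest`.
#' @export
compare_conditions <- function(iso_values, int_values, var_equal = FALSE) {
  if (length(iso_values) < 2L || length(int_values) < 2L) {
    stop("each condition needs at least 2 values")
  }
  if (isTRUE(all.equal(iso_values, int_values))) {
    # identical samples: the test statistic is exactly 0
    return(list(t = 0, p = 1, stars = "ns", test = NULL))
  }
  ht <- stats::t.test(iso_values, int_values, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       stars = significance_stars(ht$p.value), test = ht)
}

#' PCA and hierarchical clustering of comparisons
#'
#' Treats each comparison table's log2-fold-change vector over the shared
#' gene universe as one observation, computes principal components, and
#' hierarchically clusters the comparisons by Euclidean distance
#' (average linkage).
#'
#' @param tables Named list of `de_table` objects (>= 2) sharing at least
#'   2 genes.
#' @return A list with `scores` (comparisons x PCs), `var_explained`
#'   (percent per component), `hc` (an `hclust`), and `order` (dendrogram
#'   order of the comparison labels).
#' @export
pca_and_cluster <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 tables")
  shared <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  if (length(shared) < 2L) stop("fewer than 2 genes shared across tables")
  m <- vapply(tables, function(t) t$log2fc[match(shared, t$gene_id)],
              numeric(length(shared)))
  labs <- names(tables) %||% paste0("table", seq_along(tables))
  colnames(m) <- labs
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) 100 * pc$sdev^2 / tot else rep(0, length(pc$sdev))
  hc <- stats::hclust(stats::dist(t(m)), method = "average")
  list(scores = pc$x, var_explained = ve, hc = hc,
       order = labs[hc$order], n_shared_genes = length(shared))
}
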