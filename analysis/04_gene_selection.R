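#!/usr/bin/env Rscript
# Gene selection over the simulated expression tables: the 2-SD rule per
# table, shared-gene (Venn) counts across the four conditions, fixed
# fold-change flags (|log2FC| >= 2 for heatmap inclusion, >= 1.58 for
# significant regulation), a planted-cluster summary with an
# isolated-vs-interaction t-test, and PCA / hierarchical clustering of
# the four comparisons. Run after analysis/03_simulate_expression.R.

suppressPackageStartupMessages(library(pigmentr))

src <- "results/expression"
out <- "results/gene_selection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

paths <- list.files(src, pattern = "_vs_control\\.tsv$", full.names = TRUE)
tables <- lapply(paths, read_de_table)
names(tables) <- sub("\\.tsv$", "", basename(paths))
truth <- jsonlite::read_json(file.path(src, "truth.json"),
                             simplifyVector = TRUE)

message("2-SD rule and shared-gene counts across the four conditions")
res <- run_expression_pipeline(tables, out_dir = out, min_abs_log2fc = 2)
print(res$venn)
planted_all4 <- Reduce(intersect, truth$planted_by_condition)
flagged_all4 <- Reduce(intersect, lapply(res$flags_2sd, function(f) {
  f$gene_id[f$flagged]
}))
message(sprintf("  genes flagged in all 4 conditions: %d (planted: %d, recovered: %d)",
                length(flagged_all4), length(planted_all4),
                sum(planted_all4 %in% flagged_all4)))

message("fixed-threshold flags (3-fold rule, |log2FC| >= 1.58, p < 0.05)")
f158 <- lapply(tables, flag_de_threshold, min_abs_log2fc = 1.58)
message(sprintf("  flagged per table: %s",
                paste(vapply(f158, function(f) sum(f$flagged), 0L),
                      collapse = ", ")))

message("planted-cluster summary and isolated-vs-interaction comparison")
cluster <- gene_cluster_def("planted_all4", planted_all4)
cs <- cluster_average_lfc(tables[[1]], cluster)
message(sprintf("  cluster '%s' mean log2FC %.2f (SD %.2f, n = %d)",
                cs$name, cs$mean, cs$sd, cs$n_found))
# contrast the cluster's per-gene values against a null 'isolated' draw
set.seed(7)
iso_values <- rnorm(length(cs$values), 0, 1)
cmp <- compare_conditions(iso_values, cs$values)
message(sprintf("  isolated vs interaction t = %.2f, p = %.2g (%s)",
                cmp$t, cmp$p, cmp$stars))
write.table(data.frame(gene_id = names(cs$values), log2fc = cs$values),
            file.path(out, "planted_cluster_values.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("PCA and hierarchical clustering of the four comparisons")
pc <- pca_and_cluster(tables)
message(sprintf("  variance explained: %s",
                paste(sprintf("%.1f%%", pc$var_explained), collapse = ", ")))
message(sprintf("  dendrogram order: %s", paste(pc$order, collapse = " | ")))
write.table(data.frame(comparison = rownames(pc$scores),
                       round(pc$scores, 4)),
            file.path(out, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
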