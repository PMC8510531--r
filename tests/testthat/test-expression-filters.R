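test_that("de_table validates its inputs", {
  expect_error(de_table(c("a", "a"), c(1, 2), c(0.1, 0.2)), "unique")
  expect_error(de_table(c("a", "b"), c(1, 2), c(0.1, 1.2)), "\\[0, 1\\]")
  t <- de_table(c("a", "b"), c(1, -2), c(0.1, 0.2), comparison = "x")
  expect_s3_class(t, "de_table")
  expect_equal(attr(t, "comparison"), "x")
})

test_that("the 2-SD rule flags outliers of the table's own distribution", {
  # zero-variance table: nothing can be 2 SD away
  flat <- de_table(letters[1:5], rep(1.3, 5), rep(0.01, 5))
  expect_false(any(flag_de_2sd(flat)$flagged))
  # planted outliers among a null bulk
  set.seed(23)
  n <- 9996
  tab <- de_table(c(sprintf("g%05d", 1:n), paste0("hit", 1:4)),
                  c(rnorm(n), rep(10, 4)),
                  rep(0.001, n + 4))
  fl <- flag_de_2sd(tab)
  # brute-force recomputation of the rule
  mu <- mean(tab$log2fc); s <- sd(tab$log2fc)
  manual <- abs(tab$log2fc - mu) > 2 * s & tab$pvalue < 0.05
  expect_equal(fl$flagged, manual)
  expect_true(all(fl$flagged[tab$gene_id %in% paste0("hit", 1:4)]))
  # the p-value gate applies
  tab2 <- de_table(tab$gene_id, tab$log2fc, rep(0.5, n + 4))
  expect_false(any(flag_de_2sd(tab2)$flagged))
})

test_that("the 2-SD rule is invariant to a location shift", {
  set.seed(24)
  tab <- de_table(sprintf("g%04d", 1:2000), rnorm(2000), runif(2000))
  shifted <- de_table(tab$gene_id, tab$log2fc + 3.7, tab$pvalue)
  expect_equal(flag_de_2sd(tab)$flagged, flag_de_2sd(shifted)$flagged)
})

test_that("fixed-threshold flags are boundary-inclusive with a p gate", {
  tab <- de_table(c("a", "b", "c", "d"),
                  c(2.0, -1.58, 5, 1.99),
                  c(0.04, 0.01, 0.2, 0.001))
  f2 <- flag_de_threshold(tab, 2)
  expect_equal(f2$flagged, c(TRUE, FALSE, FALSE, FALSE))
  f158 <- flag_de_threshold(tab, 1.58)
  expect_equal(f158$flagged, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("shared-gene counts match a brute-force tally", {
  mk <- function(ids, flagged_ids) {
    structure(data.frame(gene_id = ids, flagged = ids %in% flagged_ids),
              class = c("de_flagset", "data.frame"))
  }
  ids <- sprintf("g%03d", 1:20)
  same <- mk(ids, ids[1:7])
  v <- venn_shared_counts(list(same, same))
  expect_equal(v$exactly, c(0L, 7L))
  expect_equal(v$at_least, c(7L, 7L))
  dis <- venn_shared_counts(list(mk(ids, ids[1:3]), mk(ids, ids[10:13])))
  expect_equal(dis$exactly, c(7L, 0L))
  # random flag sets vs per-gene tally over 1000 genes
  set.seed(25)
  ids <- sprintf("g%04d", 1:1000)
  sets <- lapply(1:4, function(i) mk(ids, sample(ids, rpois(1, 50))))
  v4 <- venn_shared_counts(sets)
  counts <- rowSums(sapply(sets, function(s) s$flagged))
  for (k in 1:4) {
    expect_equal(v4$exactly[k], sum(counts == k))
    expect_equal(v4$at_least[k], sum(counts >= k))
  }
  expect_equal(sum(v4$exactly), length(unique(unlist(
    lapply(sets, function(s) s$gene_id[s$flagged])))))
  expect_true(all(diff(v4$at_least) <= 0))
})

test_that("cluster averages summarize found genes and report missing ones", {
  tab <- de_table(c("a", "b", "c"), c(2, -2, 1), c(0.1, 0.1, 0.1))
  cl <- gene_cluster_def("toy", c("a", "b", "z"))
  cs <- cluster_average_lfc(tab, cl)
  expect_equal(cs$mean, 0)
  expect_equal(cs$n_found, 2L)
  expect_equal(cs$missing, "z")
  expect_warning(
    single <- cluster_average_lfc(tab, gene_cluster_def("one", "c")),
    "single gene")
  expect_equal(single$sd, 0)
  expect_error(cluster_average_lfc(tab, gene_cluster_def("none", "q")),
               "none")
  # planted +3 cluster shift is recovered
  set.seed(26)
  genes <- sprintf("g%04d", 1:2000)
  lfc <- rnorm(2000, 0, 0.2)
  planted <- sample(genes, 20)
  lfc[genes %in% planted] <- lfc[genes %in% planted] + 3
  big <- de_table(genes, lfc, runif(2000))
  rec <- cluster_average_lfc(big, gene_cluster_def("plant", planted))
  expect_equal(rec$mean, 3, tolerance = 0.1 / 3)
})

test_that("the lan cluster spans SCO6927 through SCO6938", {
  lan <- lan_cluster()
  expect_equal(lan$gene_ids[1], "SCO6927")
  expect_equal(lan$gene_ids[12], "SCO6938")
  expect_length(lan$gene_ids, 12)
})

test_that("condition comparison uses a two-sample t-test with stars", {
  same <- c(0.1, 0.2, 0.3)
  res <- compare_conditions(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  set.seed(27)
  iso <- rnorm(20, 0, 0.1); int <- rnorm(20, 3, 0.1)
  strong <- compare_conditions(iso, int)
  expect_lte(strong$p, 1e-4)
  expect_equal(strong$stars, "****")
  # textbook Welch statistic recomputed by hand
  x <- c(1.1, 0.9, 1.4, 1.0); y <- c(2.0, 2.2, 1.8, 2.4)
  manual_t <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(compare_conditions(x, y)$t, manual_t)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
  expect_equal(significance_stars(c(0.03, 0.2, 0.0005, 2e-5)),
               c("*", "ns", "***", "****"))
})

test_that("PCA and clustering place identical tables together", {
  set.seed(28)
  genes <- sprintf("g%03d", 1:200)
  base_lfc <- rnorm(200)
  t1 <- de_table(genes, base_lfc, runif(200))
  t2 <- de_table(genes, base_lfc, runif(200))
  t3 <- de_table(genes, base_lfc + rnorm(200, 0, 3), runif(200))
  res <- pca_and_cluster(list(a = t1, b = t2, c = t3))
  expect_equal(unname(dist(res$scores[c("a", "b"), ])[1]), 0,
               tolerance = 1e-8)
  # the identical pair merges first
  expect_equal(sort(res$hc$merge[1, ]), c(-2, -1))
  expect_true(all(diff(res$var_explained) <= 1e-8))
  expect_lte(sum(res$var_explained), 100 + 1e-8)
  expect_error(pca_and_cluster(list(t1)), "at least 2")
})

test_that("tables and cluster files round-trip through disk", {
  dir <- withr::local_tempdir()
  tab <- de_table(c("a", "b", "c"), c(1.5, -2, 0), c(0.01, 0.2, 0.9),
                  padj = c(0.05, 0.4, 0.95))
  path <- file.path(dir, "t.tsv")
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_de_table(path)
  expect_equal(back$log2fc, tab$log2fc)
  expect_equal(back$padj, tab$padj)
  expect_error(flag_de_2sd(back, use_padj = TRUE), NA)
  cpath <- file.path(dir, "clusters.tsv")
  write.table(data.frame(cluster_name = c("x", "x", "y"),
                         gene_id = c("a", "b", "c")),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  defs <- read_cluster_defs(cpath)
  expect_named(defs, c("x", "y"))
  expect_equal(defs$x$gene_ids, c("a", "b"))
})
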