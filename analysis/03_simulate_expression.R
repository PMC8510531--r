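#!/usr/bin/env Rscript
# Simulate the transcriptome side: four interaction conditions' worth of
# differential-expression tables (log2 fold change + p-value per gene)
# with a null background and two planted regulated gene groups — one
# shared by all four conditions, one by three — mimicking the structure
# of a multi-interaction comparison.

suppressPackageStartupMessages(library(pigmentr))

out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_de_tables(de_sim_params(seed = 7))
for (n in names(sim$tables)) {
  write.table(as.data.frame(sim$tables[[n]]),
              file.path(out, paste0(n, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("wrote %d tables of %d genes each to %s",
                length(sim$tables), nrow(sim$tables[[1]]), out))
message(sprintf("planted: %d genes in all 4 conditions, %d in 3",
                sum(table(unlist(sim$truth$planted_by_condition)) == 4),
                sum(table(unlist(sim$truth$planted_by_condition)) == 3)))
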