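#!/usr/bin/env Rscript
# Step 2: call and classify DEGs, then quantify co-regulation.
#
# Reads the three DE tables written by step 1, calls DEGs per contrast
# (|log2FC| >= 0.5, FDR < 0.05), classifies each gene by its detection
# pattern (L_DEG / S_DEG / LS_DEG / OTHER) and summarizes how the shared
# LS class behaves across the two single-mutant contrasts: the Pearson
# correlation of effect pairs and the inversely regulated share.

suppressPackageStartupMessages(library(epideg))

data_dir <- "results/data"
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tables <- lapply(c(L = "L", S = "S", LS = "LS"), function(ct) {
  read_de_table(file.path(data_dir, sprintf("de_%s.tsv", ct)), ct)
})

cls <- classify_contrasts(tables, thresholds(lfc_min = 0.5, fdr_max = 0.05))
coreg <- coregulation_stats(cls, tables$L, tables$S)

write.table(as.data.frame(cls), file.path(out, "classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coreg$scatter, file.path(out, "coregulation_scatter.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  c(as.list(attr(cls, "counts")),
    coreg[c("pearson_r", "n_ls", "n_inverse", "frac_inverse")]),
  file.path(out, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

counts <- attr(cls, "counts")
cat("class counts:\n"); print(counts)
cat(sprintf("LS share of universe: %.1f%%\n",
            100 * counts[["LS_DEG"]] / sum(counts)))
cat(sprintf("pearson r (L vs S log2FC over LS-DEGs): %.3f\n",
            coreg$pearson_r))
cat(sprintf("inversely regulated: %d / %d (%.1f%%)\n", coreg$n_inverse,
            coreg$n_ls, 100 * coreg$frac_inverse))
cat("wrote", out, "\n")
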