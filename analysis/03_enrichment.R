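#!/usr/bin/env Rscript
# Step 3: over-representation analysis per DEG class with term clustering.
#
# Simulates a GO-BP-style gene-set collection over the detected universe
# (random background sets plus sets planted inside the LS class so real
# signal exists), runs the hypergeometric ORA on up/down/complete lists,
# merges directions, filters (>3 hits, FDR < 0.05), builds the Jaccard
# term-similarity matrix and clusters terms with silhouette-selected k.

suppressPackageStartupMessages(library(epideg))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cls <- read.table("results/classification/classification.tsv",
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
ls_tab <- read_de_table("results/data/de_LS.tsv", "LS")
lfc <- setNames(ls_tab$log2fc, ls_tab$gene)

# three planted functional modules inside the LS class, plus background
set.seed(20260103)
ls_genes <- cls$gene[cls$label == "LS_DEG"]
planted <- list(
  "MOD:lipid_a" = sample(ls_genes[1:400], 30),
  "MOD:lipid_b" = sample(ls_genes[1:400], 25),
  "MOD:cycle_a" = sample(ls_genes[1000:1400], 30),
  "MOD:cycle_b" = sample(ls_genes[1000:1400], 25),
  "MOD:chromatin" = sample(ls_genes[2000:2400], 35))
sets <- simulate_gene_sets(cls$gene, n_sets = 120, size_range = c(15, 60),
                           planted = planted, seed = 20260104)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

universe <- intersect(cls$gene, unique(unlist(sets)))
for (lab in c("L_DEG", "S_DEG", "LS_DEG")) {
  genes <- intersect(cls$gene[cls$label == lab], universe)
  tab <- enrich_class(genes, lfc, universe, sets)
  flat <- as.data.frame(tab)
  flat$intersection <- vapply(tab$intersection, paste, "", collapse = ";")
  write.table(flat, file.path(out, sprintf("enrichment_%s.tsv", lab)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes -> %d enriched terms\n", lab, length(genes),
              nrow(tab)))
  if (lab == "LS_DEG" && nrow(tab) >= 3) {
    clu <- cluster_terms(term_similarity(tab), seed = 20260105)
    write.table(data.frame(term_id = names(clu$labels),
                           cluster = clu$labels),
                file.path(out, "term_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(clu$silhouette_curve,
                file.path(out, "silhouette_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cat(sprintf("LS-term clustering: k = %d (mean silhouette %.2f)\n",
                clu$k, max(clu$silhouette_curve$mean_silhouette)))
    for (k in names(clu$unique_genes)) {
      cat(sprintf("  cluster %s: %d unique gene ids\n", k,
                  length(clu$unique_genes[[k]])))
    }
  }
}
cat("wrote", out, "\n")
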