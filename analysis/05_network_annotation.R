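#!/usr/bin/env Rscript
# Step 5: annotate a protein-interaction network with DEG classes.
#
# Builds a STRING-style edge list over the genes of one enriched module
# (plus random background edges with varied confidence scores), filters at
# medium confidence (600) and annotates every remaining node with its DEG
# class and regulation direction, the table a network-rendering tool
# would consume.

suppressPackageStartupMessages(library(epideg))

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cls_df <- read.table("results/classification/classification.tsv",
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
cls <- classify_degs(cls_df$gene[cls_df$detected_L],
                     cls_df$gene[cls_df$detected_S],
                     cls_df$gene[cls_df$detected_LS],
                     cls_df$gene)
stopifnot(identical(cls$label, cls_df$label[match(cls$gene, cls_df$gene)]))
tabs <- lapply(c(L = "L", S = "S", LS = "LS"), function(ct) {
  read_de_table(sprintf("results/data/de_%s.tsv", ct), ct)
})

set.seed(20260107)
module <- unlist(read_gmt("results/enrichment/gene_sets.gmt")["MOD:lipid_a"])
others <- sample(setdiff(cls$gene, module), 40)
nodes <- c(module, others)
n_edges <- 400
a <- sample(nodes, n_edges, replace = TRUE)
b <- sample(nodes, n_edges, replace = TRUE)
scores <- sample(300:999, n_edges, replace = TRUE)
el <- edge_list(a, b, scores)
write.table(as.data.frame(el), file.path(out, "edges_raw.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ann <- annotate_network_nodes(el, cls, tabs, min_score = 600)
write.table(ann$nodes, file.path(out, "nodes_annotated.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(ann$edges), file.path(out, "edges_filtered.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("edges: %d raw -> %d at confidence >= 600\n", nrow(el),
            nrow(ann$edges)))
cat("node class x direction:\n")
print(table(ann$nodes$deg_class, ann$nodes$direction))
cat("wrote", out, "\n")
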