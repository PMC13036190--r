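# DEG calling, epistasis-style set classification and co-regulation
# statistics for the three mutant-vs-WT contrasts L, S and LS.
#
# A gene is a DEG in a contrast when |log2FC| >= lfc_min (closed bound,
# matching the "log2FC = 0.5 threshold" convention) and adj_p < fdr_max
# (open bound, "p < 0.05"). Classification follows the set rules:
#   L_DEG:  detected in L and LS, not in S
#   S_DEG:  detected in S and LS, not in L
#   LS_DEG: detected in L, S and LS
#   OTHER:  every remaining detection pattern

#' Detection thresholds
#'
#' @param lfc_min minimum absolute log2 fold change (inclusive), default 0.5.
#' @param fdr_max FDR-adjusted p-value cutoff (exclusive), default 0.05.
#' @return A `thresholds` list.
#' @export
thresholds <- function(lfc_min = 0.5, fdr_max = 0.05) {
  stopifnot(is.numeric(lfc_min), lfc_min > 0,
            is.numeric(fdr_max), fdr_max > 0, fdr_max < 1)
  structure(list(lfc_min = lfc_min, fdr_max = fdr_max),
            class = "thresholds")
}

#' Call differentially expressed genes in one contrast
#'
#' @param table a [de_table()].
#' @param thresholds a [thresholds()] object.
#' @return Character vector of gene ids with `|log2fc| >= lfc_min` and
#'   `adj_p < fdr_max`, sorted.
#' @export
call_degs <- function(table, thresholds = epideg::thresholds()) {
  validate_de_table(table)
  sort(table$gene[abs(table$log2fc) >= thresholds$lfc_min &
                    table$adj_p < thresholds$fdr_max])
}

#' Classify genes by their cross-contrast detection pattern
#'
#' @param deg_L,deg_S,deg_LS character vectors of DEGs called in the
#'   LKB1-mutant, SMARCA4-mutant and double-mutant contrasts.
#' @param universe character vector of all genes considered (every DEG set
#'   must be a subset).
#' @return A `deg_classification` object: a data frame with columns `gene`,
#'   `detected_L`, `detected_S`, `detected_LS`, `label`, plus attributes
#'   `counts` (named counts of the four labels) and `pattern_counts`
#'   (counts of all eight detection patterns).
#' @export
classify_degs <- function(deg_L, deg_S, deg_LS, universe) {
  universe <- sort(unique(as.character(universe)))
  for (nm in c("deg_L", "deg_S", "deg_LS")) {
    extra <- setdiff(get(nm), universe)
    if (length(extra)) {
      stop("gene(s) in ", nm, " but not in universe: ",
           paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
    }
  }
  dL <- universe %in% deg_L
  dS <- universe %in% deg_S
  dLS <- universe %in% deg_LS
  label <- rep("OTHER", length(universe))
  label[dL & dLS & !dS] <- "L_DEG"
  label[dS & dLS & !dL] <- "S_DEG"
  label[dL & dS & dLS] <- "LS_DEG"
  out <- data.frame(gene = universe, detected_L = dL, detected_S = dS,
                    detected_LS = dLS, label = label,
                    stringsAsFactors = FALSE)
  lv <- c("L_DEG", "S_DEG", "LS_DEG", "OTHER")
  counts <- stats::setNames(tabulate(factor(label, lv), length(lv)), lv)
  pattern <- ifelse(!dL & !dS & !dLS, "none",
                    gsub("^\\+|\\+$", "",
                         paste0(ifelse(dL, "L+", ""), ifelse(dS, "S+", ""),
                                ifelse(dLS, "LS", ""))))
  pattern_counts <- table(pattern)
  attr(out, "counts") <- counts
  attr(out, "pattern_counts") <- pattern_counts
  class(out) <- c("deg_classification", "data.frame")
  out
}

#' Call and classify DEGs from three aligned DE tables
#'
#' Convenience wrapper: the universe is the set of genes present in all
#' three tables (genes missing from any table are excluded with a message),
#' DEGs are called per contrast under one shared [thresholds()] object, and
#' the detection patterns are classified with [classify_degs()].
#'
#' @param tables named list of [de_table()] objects with names `L`, `S`,
#'   `LS`.
#' @param thresholds a [thresholds()] object.
#' @return A `deg_classification` (see [classify_degs()]).
#' @export
classify_contrasts <- function(tables, thresholds = epideg::thresholds()) {
  stopifnot(all(c("L", "S", "LS") %in% names(tables)))
  universe <- Reduce(intersect, lapply(tables[c("L", "S", "LS")],
                                       function(t) t$gene))
  n_drop <- length(unique(unlist(lapply(tables, function(t) t$gene)))) -
    length(universe)
  if (n_drop > 0) {
    message(n_drop, " gene(s) absent from at least one contrast excluded ",
            "from the universe")
  }
  degs <- lapply(tables[c("L", "S", "LS")], function(t) {
    intersect(call_degs(t, thresholds), universe)
  })
  classify_degs(degs$L, degs$S, degs$LS, universe)
}

#' Co-regulation statistics over shared (LS) DEGs
#'
#' Compares the log2 fold changes of LS-classified genes between the two
#' single-mutant contrasts. A gene is *inverse* when its two log2FCs have
#' opposite signs and both magnitudes reach `lfc_min`; *sub-threshold* when
#' either magnitude falls below `lfc_min`; *concordant* otherwise.
#'
#' @param classification a `deg_classification` from [classify_degs()].
#' @param table_L,table_S the single-mutant [de_table()]s.
#' @param thresholds a [thresholds()] object (only `lfc_min` is used here).
#' @return A `coregulation_summary` list: `pearson_r`, `n_ls`, `n_inverse`,
#'   `frac_inverse`, and `scatter`, a data frame (`gene`, `lfc_L`, `lfc_S`,
#'   `concordance`) ready for scatter plotting.
#' @export
coregulation_stats <- function(classification, table_L, table_S,
                               thresholds = epideg::thresholds()) {
  stopifnot(inherits(classification, "deg_classification"))
  ls_genes <- classification$gene[classification$label == "LS_DEG"]
  if (length(ls_genes) < 2L) {
    stop("correlation undefined: fewer than 2 LS-classified genes",
         call. = FALSE)
  }
  missing <- setdiff(ls_genes, intersect(table_L$gene, table_S$gene))
  if (length(missing)) {
    stop("LS gene(s) absent from a contrast table: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lfc_L <- table_L$log2fc[match(ls_genes, table_L$gene)]
  lfc_S <- table_S$log2fc[match(ls_genes, table_S$gene)]
  both_over <- abs(lfc_L) >= thresholds$lfc_min &
    abs(lfc_S) >= thresholds$lfc_min
  concordance <- ifelse(!both_over, "sub-threshold",
                        ifelse(sign(lfc_L) != sign(lfc_S), "inverse",
                               "concordant"))
  n_inverse <- sum(concordance == "inverse")
  structure(list(pearson_r = stats::cor(lfc_L, lfc_S),
                 n_ls = length(ls_genes),
                 n_inverse = n_inverse,
                 frac_inverse = n_inverse / length(ls_genes),
                 scatter = data.frame(gene = ls_genes, lfc_L = lfc_L,
                                      lfc_S = lfc_S,
                                      concordance = concordance,
                                      stringsAsFactors = FALSE)),
            class = "coregulation_summary")
}
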