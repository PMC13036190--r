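# Over-representation analysis with direction merging, redundancy collapse,
# term filtering, gene-overlap similarity and silhouette-selected term
# clustering. The hypergeometric test is computed in-package so the whole
# enrichment path runs offline and reproducibly.

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under sampling without replacement from the universe:
#' the one-sided upper-tail probability of observing at least the realized
#' number of hits, given the set's annotated size within the universe, the
#' query size and the universe size. Benjamini-Hochberg adjustment is
#' applied across all tested terms of the run. Terms with no gene in the
#' universe are not testable and are dropped; terms with zero hits are
#' retained with p = 1 so that downstream merging sees every testable term.
#'
#' @param query character vector of genes of interest (must lie within
#'   `universe`).
#' @param universe character vector, the detected-gene background.
#' @param sets a `gene_sets` collection (see [read_gmt()]).
#' @param direction run label propagated to the result: `"up"`, `"down"` or
#'   `"all"`.
#' @return An `enrichment_table`: data frame with columns `term_id`,
#'   `term_name`, `p_value`, `adj_p`, `hits`, `term_size` (genes of the set
#'   within the universe), `gene_ratio` (`hits / term_size`), `direction`,
#'   and a list column `intersection` of hit genes.
#' @export
ora_test <- function(query, universe, sets, direction = "all") {
  stopifnot(inherits(sets, "gene_sets"), length(universe) > 0)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) not in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    ann <- intersect(sets[[id]], universe)
    K <- length(ann)
    if (K == 0L) return(NULL)
    inter <- intersect(ann, query)
    k <- length(inter)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    list(term_id = id, p_value = p, hits = k, term_size = K,
         intersection = list(sort(inter)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(.empty_enrichment_table(direction))
  }
  out <- data.frame(term_id = vapply(rows, `[[`, "", "term_id"),
                    stringsAsFactors = FALSE)
  nm <- attr(sets, "term_names")
  out$term_name <- unname(nm[out$term_id])
  out$p_value <- vapply(rows, `[[`, 0, "p_value")
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$hits <- vapply(rows, function(r) as.integer(r$hits), 0L)
  out$term_size <- vapply(rows, function(r) as.integer(r$term_size), 0L)
  out$gene_ratio <- out$hits / out$term_size
  out$direction <- direction
  out$intersection <- I(lapply(rows, function(r) r$intersection[[1L]]))
  out <- out[order(out$adj_p, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

.empty_enrichment_table <- function(direction = "all") {
  out <- data.frame(term_id = character(0), term_name = character(0),
                    p_value = numeric(0), adj_p = numeric(0),
                    hits = integer(0), term_size = integer(0),
                    gene_ratio = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  out$intersection <- I(list())
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Merge up-, down- and complete-list enrichment runs
#'
#' Combines the three per-direction runs into one table with a single row
#' per term: the row with the largest intersection size wins; ties are
#' broken by smaller adjusted p, then by direction precedence
#' `all > up > down`.
#'
#' @param up,down,all `enrichment_table`s from [ora_test()] over the same
#'   gene-set collection.
#' @return A merged `enrichment_table` with unique `term_id`s.
#' @export
merge_direction_runs <- function(up, down, all) {
  combined <- rbind(as.data.frame(up), as.data.frame(down),
                    as.data.frame(all))
  if (!nrow(combined)) return(.empty_enrichment_table())
  prec <- match(combined$direction, c("all", "up", "down"))
  ord <- order(combined$term_id, -combined$hits, combined$adj_p, prec)
  combined <- combined[ord, , drop = FALSE]
  combined <- combined[!duplicated(combined$term_id), , drop = FALSE]
  combined <- combined[order(combined$adj_p, combined$p_value,
                             combined$term_id), , drop = FALSE]
  rownames(combined) <- NULL
  class(combined) <- c("enrichment_table", "data.frame")
  combined
}

#' Filter enrichment terms on hit count and significance
#'
#' Retains terms with more than three hit genes (`hits >= min_hits`) and
#' FDR-adjusted p below `fdr_max`.
#'
#' @param table an `enrichment_table`.
#' @param min_hits minimum intersection size retained (default 4, i.e.
#'   "more than 3 genes").
#' @param fdr_max adjusted-p cutoff (exclusive).
#' @return The filtered `enrichment_table`.
#' @export
filter_terms <- function(table, min_hits = 4L, fdr_max = 0.05) {
  keep <- table$hits >= min_hits & table$adj_p < fdr_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Term-term similarity from overlapping gene ids
#'
#' @param table an `enrichment_table` with at least two rows.
#' @param metric `"jaccard"` (intersection over union, default) or
#'   `"overlap"` (intersection over smaller set).
#' @return A `term_similarity` object: `matrix` (symmetric, unit diagonal),
#'   `terms`, and the per-term hit-gene sets used.
#' @export
term_similarity <- function(table, metric = c("jaccard", "overlap")) {
  metric <- match.arg(metric)
  if (nrow(table) < 2L) {
    stop("term similarity needs at least 2 retained terms", call. = FALSE)
  }
  sets <- table$intersection
  names(sets) <- table$term_id
  n <- length(sets)
  S <- diag(1, n)
  dimnames(S) <- list(table$term_id, table$term_id)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- sets[[i]]; b <- sets[[j]]
      inter <- length(intersect(a, b))
      denom <- switch(metric,
                      jaccard = length(union(a, b)),
                      overlap = min(length(a), length(b)))
      S[i, j] <- S[j, i] <- if (denom == 0L) 0 else inter / denom
    }
  }
  structure(list(matrix = S, terms = table$term_id, gene_sets = sets,
                 metric = metric),
            class = "term_similarity")
}

#' Cluster enrichment terms with silhouette-selected k
#'
#' Embeds each term as its row of the similarity matrix and runs k-means for
#' every candidate k, selecting the k with the highest mean silhouette width
#' under the distance `1 - similarity` (smallest k wins ties). An
#' average-linkage hierarchical ordering over the same distance is emitted
#' for display, and each cluster is summarized by its unique gene ids (genes
#' hit by the cluster's terms and by no other cluster).
#'
#' @param sim a `term_similarity` from [term_similarity()].
#' @param k_min,k_max candidate cluster-count range; `k_max` defaults to
#'   `min(10, n_terms - 1)` and must not exceed `n_terms - 1`.
#' @param seed integer seed; clustering is deterministic given the seed.
#' @param restarts k-means restarts per candidate k.
#' @return The `term_similarity` object augmented with `labels` (named
#'   integer cluster ids), `k`, `silhouette_curve` (data frame `k`,
#'   `mean_silhouette`), `hclust_order` and `unique_genes` (list per
#'   cluster).
#' @export
cluster_terms <- function(sim, k_min = 2L, k_max = NULL, seed = 1L,
                          restarts = 50L) {
  stopifnot(inherits(sim, "term_similarity"))
  S <- sim$matrix
  n <- nrow(S)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  if (k_max > n - 1L) stop("k_max must be <= n_terms - 1", call. = FALSE)
  D <- 1 - S
  n_distinct <- nrow(unique(S))
  if (n_distinct < 2L) {
    warning("degenerate similarity matrix (all terms identical): ",
            "returning a single cluster")
    sim$labels <- stats::setNames(rep(1L, n), rownames(S))
    sim$k <- 1L
    sim$silhouette_curve <- data.frame(k = integer(0),
                                       mean_silhouette = numeric(0))
    sim$hclust_order <- seq_len(n)
    sim$unique_genes <- list(`1` = sort(unique(unlist(sim$gene_sets))))
    return(sim)
  }
  ks <- seq.int(k_min, min(k_max, n_distinct))
  fits <- list(); sil <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed + ks[i])
    km <- stats::kmeans(S, centers = ks[i], nstart = restarts,
                        iter.max = 100L)
    sw <- cluster::silhouette(km$cluster, dmatrix = D)
    sil[i] <- mean(sw[, "sil_width"])
    fits[[i]] <- km$cluster
  }
  best <- which.max(sil)  # ties: first (smallest k) wins
  labels <- stats::setNames(fits[[best]], rownames(S))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  uniq <- lapply(sort(unique(labels)), function(cl) {
    inside <- sort(unique(unlist(sim$gene_sets[labels == cl])))
    outside <- unique(unlist(sim$gene_sets[labels != cl]))
    setdiff(inside, outside)
  })
  names(uniq) <- as.character(sort(unique(labels)))
  sim$labels <- labels
  sim$k <- ks[best]
  sim$silhouette_curve <- data.frame(k = ks, mean_silhouette = sil)
  sim$hclust_order <- hc$order
  sim$unique_genes <- uniq
  sim
}

#' One-call enrichment workflow for a DEG class
#'
#' Runs [ora_test()] on the up-regulated, down-regulated and complete gene
#' lists of one DEG class, merges the runs ([merge_direction_runs()]) and
#' applies the hit-count/FDR filter ([filter_terms()]).
#'
#' @param genes character vector, the DEG class gene list.
#' @param log2fc named numeric vector of log2 fold changes used to split
#'   `genes` into up and down lists (names are gene ids).
#' @param universe background gene universe.
#' @param sets a `gene_sets` collection.
#' @param min_hits,fdr_max filter settings, see [filter_terms()].
#' @return A filtered, merged `enrichment_table`.
#' @export
enrich_class <- function(genes, log2fc, universe, sets, min_hits = 4L,
                         fdr_max = 0.05) {
  lfc <- log2fc[genes]
  up <- ora_test(genes[!is.na(lfc) & lfc > 0], universe, sets, "up")
  down <- ora_test(genes[!is.na(lfc) & lfc < 0], universe, sets, "down")
  full <- ora_test(genes, universe, sets, "all")
  filter_terms(merge_direction_runs(up, down, full), min_hits, fdr_max)
}
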