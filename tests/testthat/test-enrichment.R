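test_that("ORA handles forced and empty overlaps", {
  universe <- sprintf("u%02d", 1:20)
  sets <- gene_sets(list(T1 = universe[1:5], T2 = universe[16:20]))
  # zero hits -> p = 1
  et <- ora_test(universe[6:11], universe, sets)
  expect_equal(et$p_value[et$term_id == "T1"], 1)
  # query == universe forces full overlap and p = 1 everywhere
  et2 <- ora_test(universe, universe, sets)
  expect_equal(et2$hits, et2$term_size)
  expect_equal(et2$p_value, rep(1, 2))
  expect_equal(et2$gene_ratio, rep(1, 2))
  # query outside universe is an error naming the offender
  expect_error(ora_test(c("u01", "zz"), universe, sets), "zz")
})

test_that("ORA matches exhaustive enumeration over small universes", {
  # every attainable overlap for a dense grid of small configurations,
  # compared against brute-force enumeration of all C(N, n) query draws
  for (N in c(5, 8, 12)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in seq_len(N - 1L)) {
      sets <- gene_sets(list(TT = universe[seq_len(K)]))
      for (n in seq_len(N - 1L)) {
        ks <- max(0L, n - (N - K)):min(K, n)
        for (k in ks) {
          query <- c(universe[seq_len(k)],
                     if (n - k > 0) universe[K + seq_len(n - k)])
          et <- ora_test(query, universe, sets)
          expect_equal(et$p_value, enum_overlap_tail(N, K, n, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("ORA matches enumeration at the largest supported universe", {
  N <- 20
  universe <- sprintf("u%02d", 1:N)
  for (K in c(4, 9, 15)) {
    sets <- gene_sets(list(TT = universe[1:K]))
    for (n in c(3, 6, 10)) {
      for (k in unique(c(max(0, n - (N - K)), min(K, n) %/% 2,
                         min(K, n)))) {
        if (k < max(0, n - (N - K))) next
        query <- c(universe[seq_len(k)],
                   if (n - k > 0) universe[K + seq_len(n - k)])
        et <- ora_test(query, universe, sets)
        expect_equal(et$p_value, enum_overlap_tail(N, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(3)
  universe <- sprintf("u%03d", 1:200)
  sets <- simulate_gene_sets(universe, n_sets = 30, seed = 4)
  et <- ora_test(sample(universe, 60), universe, sets)
  expect_equal(order(et$p_value), order(et$adj_p))  # pre-sorted by adj_p
  expect_equal(et$adj_p, bh_bruteforce(et$p_value), tolerance = 1e-12)
})

test_that("direction merging keeps the max-hit row with stated tie-breaks", {
  row <- function(id, hits, adj, dir) {
    out <- data.frame(term_id = id, term_name = id, p_value = adj / 2,
                      adj_p = adj, hits = hits, term_size = 50L,
                      gene_ratio = hits / 50, direction = dir,
                      stringsAsFactors = FALSE)
    out$intersection <- I(list(sprintf("%s_g%d", id, seq_len(hits))))
    class(out) <- c("enrichment_table", "data.frame")
    out
  }
  up <- rbind(row("A", 5L, 0.01, "up"), row("B", 4L, 0.01, "up"),
              row("D", 2L, 0.2, "up"))
  down <- rbind(row("B", 4L, 0.03, "down"), row("C", 7L, 0.001, "down"))
  all <- rbind(row("A", 9L, 0.02, "all"), row("B", 4L, 0.01, "all"))
  class(up) <- class(down) <- class(all) <- c("enrichment_table",
                                              "data.frame")
  m <- merge_direction_runs(up, down, all)
  expect_equal(anyDuplicated(m$term_id), 0L)
  g <- function(id, col) m[[col]][m$term_id == id]
  expect_equal(g("A", "hits"), 9L)          # largest hits wins
  expect_equal(g("A", "direction"), "all")
  expect_equal(g("B", "adj_p"), 0.01)       # tie on hits -> smaller adj_p
  expect_equal(g("B", "direction"), "all")  # then precedence all > up
  expect_equal(g("C", "direction"), "down") # single-run term unchanged
  expect_equal(g("D", "hits"), 2L)
  # per-term hits equal the max across inputs
  expect_equal(g("B", "hits"), 4L)
})

test_that("term filtering applies the >3-hits and FDR rules idempotently", {
  tab <- data.frame(term_id = c("A", "B", "C", "D"),
                    term_name = c("A", "B", "C", "D"),
                    p_value = c(1e-4, 1e-4, 0.02, 0.9),
                    adj_p = c(0.001, 0.049, 0.051, 0.9),
                    hits = c(3L, 4L, 10L, 5L), term_size = 20L,
                    gene_ratio = c(3, 4, 10, 5) / 20,
                    direction = "all", stringsAsFactors = FALSE)
  tab$intersection <- I(lapply(tab$hits, function(h) sprintf("g%d", 1:h)))
  class(tab) <- c("enrichment_table", "data.frame")
  f <- filter_terms(tab)
  expect_identical(f$term_id, "B")  # A: only 3 hits; C: adj >= 0.05
  expect_identical(filter_terms(f), f)
  expect_equal(nrow(filter_terms(.empty <- f[0, ])), 0L)
})

test_that("term similarity matches hand-computed jaccard and overlap", {
  tab <- data.frame(term_id = c("A", "B", "C"), term_name = c("A", "B", "C"),
                    p_value = 0.01, adj_p = 0.01, hits = 3L, term_size = 10L,
                    gene_ratio = 0.3, direction = "all",
                    stringsAsFactors = FALSE)
  tab$intersection <- I(list(c("A", "B", "C"), c("B", "C", "D"),
                             c("X", "Y", "Z")))
  class(tab) <- c("enrichment_table", "data.frame")
  S <- term_similarity(tab)$matrix
  expect_equal(S["A", "B"], 0.5)   # {A,B,C} vs {B,C,D}: 2/4
  expect_equal(S["A", "C"], 0)     # disjoint
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  So <- term_similarity(tab, metric = "overlap")$matrix
  expect_equal(So["A", "B"], 2 / 3)
  expect_error(term_similarity(tab[1, ]), "at least 2")
})

test_that("silhouette selection recovers clean block structure", {
  sim <- make_block_similarity(2, 5, within = 1, between = 0)
  cl <- cluster_terms(sim, k_max = 5, seed = 3)
  expect_equal(cl$k, 2L)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  expect_false(cl$labels[1] == cl$labels[6])
  # selected k has the maximal mean silhouette on the curve
  expect_equal(cl$silhouette_curve$k[which.max(
    cl$silhouette_curve$mean_silhouette)], cl$k)
  # determinism
  cl2 <- cluster_terms(sim, k_max = 5, seed = 3)
  expect_identical(cl$labels, cl2$labels)
})

test_that("noisy three-block structure is recovered in >= 95% of replicates", {
  hits <- 0L
  for (rep in 1:100) {
    sim <- make_block_similarity(3, 6, within = 0.9, between = 0.1,
                                 noise_sd = 0.05, seed = rep)
    cl <- cluster_terms(sim, k_max = 6, seed = 101)
    if (cl$k == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("degenerate all-equal similarity collapses to one labeled cluster", {
  sim <- make_block_similarity(1, 4, within = 1, between = 1)
  expect_warning(cl <- cluster_terms(sim, k_max = 3, seed = 1),
                 "degenerate")
  expect_equal(cl$k, 1L)
  expect_equal(unname(unique(cl$labels)), 1L)
})

test_that("cluster-unique gene sets exclude genes shared across clusters", {
  sim <- make_block_similarity(2, 3, within = 1, between = 0)
  # inject one gene shared between the two blocks
  sim$gene_sets[[1]] <- c(sim$gene_sets[[1]], "shared")
  sim$gene_sets[[4]] <- c(sim$gene_sets[[4]], "shared")
  cl <- cluster_terms(sim, k_max = 4, seed = 2)
  expect_false(any(vapply(cl$unique_genes, function(g) "shared" %in% g,
                          logical(1))))
})
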