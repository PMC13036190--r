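# Programmatic fixtures shared across test files.

make_de <- function(genes, lfc, p = rep(0.001, length(genes)),
                    adj = p, contrast = "L") {
  de_table(genes, lfc, p, adj, contrast_id = contrast)
}

# truth label -> classifier label
truth_label_map <- c(L = "L_DEG", S = "S_DEG", LS = "LS_DEG",
                     null = "OTHER")

# block-structured term-similarity object with n_per terms per block
make_block_similarity <- function(n_blocks, n_per, within, between,
                                  noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- n_blocks * n_per
  block <- rep(seq_len(n_blocks), each = n_per)
  S <- matrix(between, n, n)
  S[outer(block, block, "==")] <- within
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n * n, 0, noise_sd), n)
    eps <- (eps + t(eps)) / 2
    S <- pmin(pmax(S + eps, 0), 1)
  }
  diag(S) <- 1
  ids <- sprintf("T%02d", seq_len(n))
  dimnames(S) <- list(ids, ids)
  structure(list(matrix = S, terms = ids,
                 gene_sets = stats::setNames(
                   lapply(block, function(b) sprintf("g%d_%d", b, 1:4)),
                   ids),
                 metric = "jaccard"),
            class = c("term_similarity"))
}

# small four-group cohort config
small_cohort_config <- function(n_genes = 300, n = 8, shifts = list(),
                                seed = 1) {
  cohort_sim_config(
    n_genes = n_genes,
    group_sizes = data.frame(
      genotype = rep(c("WT", "LKB1", "SMARCA4", "TP53"), each = 2),
      stage = rep(c("early", "late"), 4),
      n = n),
    shifts = shifts, seed = seed)
}
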