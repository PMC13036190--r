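test_that("DEG calling applies closed lfc and open fdr bounds", {
  tab <- make_de(c("a", "b", "c", "d", "e"),
                 lfc = c(0.6, 0.5, 0.49, -0.8, 1.5),
                 p = c(0.01, 0.01, 0.001, 0.01, 0.05),
                 adj = c(0.01, 0.01, 0.001, 0.01, 0.05))
  called <- call_degs(tab, thresholds(0.5, 0.05))
  expect_true(all(c("a", "b", "d") %in% called))   # 0.5 is inclusive
  expect_false("c" %in% called)                    # below lfc
  expect_false("e" %in% called)                    # adj_p == fdr_max excluded
})

test_that("classification matches the independent eight-pattern truth table", {
  # truth table written directly from the set-membership rules
  patterns <- expand.grid(dL = c(TRUE, FALSE), dS = c(TRUE, FALSE),
                          dLS = c(TRUE, FALSE))
  expected <- apply(patterns, 1L, function(p) {
    if (p[["dL"]] && p[["dS"]] && p[["dLS"]]) "LS_DEG"
    else if (p[["dL"]] && !p[["dS"]] && p[["dLS"]]) "L_DEG"
    else if (!p[["dL"]] && p[["dS"]] && p[["dLS"]]) "S_DEG"
    else "OTHER"
  })
  genes <- sprintf("g%d", seq_len(nrow(patterns)))
  cl <- classify_degs(genes[patterns$dL], genes[patterns$dS],
                      genes[patterns$dLS], genes)
  expect_identical(cl$label[match(genes, cl$gene)], unname(expected))
  # partition invariant
  expect_equal(sum(attr(cl, "counts")), length(genes))
})

test_that("genes outside the universe are rejected", {
  expect_error(classify_degs("x", character(0), character(0), c("a", "b")),
               "not in universe")
})

test_that("noise-free simulation is classified exactly; order never matters", {
  s <- simulate_contrasts(contrast_sim_config(
    1000, c(0.15, 0.15, 0.4, 0.3), effect_magnitude_sd = 0, seed = 13))
  cl <- classify_contrasts(s$tables)
  expect_identical(cl$label, unname(truth_label_map[s$truth$class]))

  # permuting table rows changes nothing
  perm <- lapply(s$tables, function(t) {
    set.seed(99)
    t2 <- t[sample(nrow(t)), ]
    de_table(t2$gene, t2$log2fc, t2$p_value, t2$adj_p,
             attr(t, "contrast_id"))
  })
  expect_identical(classify_contrasts(perm), cl)
})

test_that("raising lfc_min or lowering fdr_max never adds a called gene", {
  set.seed(31)
  for (i in 1:5) {
    tab <- make_de(sprintf("g%03d", 1:200), rnorm(200, 0, 1),
                   p = runif(200), adj = runif(200))
    loose <- call_degs(tab, thresholds(0.3, 0.1))
    for (th in list(thresholds(0.6, 0.1), thresholds(0.3, 0.01),
                    thresholds(0.8, 0.005))) {
      expect_true(all(call_degs(tab, th) %in% loose))
    }
  }
})

test_that("co-regulation statistics follow the stated rules", {
  genes <- c("g1", "g2", "g3", "g4", "g5")
  cl <- classify_degs(genes, genes, genes, genes)  # all LS
  tl <- make_de(genes, c(1, 2, 3, 0.6, 0.6))
  ts <- make_de(genes, c(1, 2, 3, -0.6, -0.3), contrast = "S")
  cs <- coregulation_stats(cl, tl, ts)
  sc <- cs$scatter
  expect_equal(sc$concordance[sc$gene == "g4"], "inverse")
  expect_equal(sc$concordance[sc$gene == "g5"], "sub-threshold")
  expect_equal(cs$n_inverse, 1L)
  expect_equal(cs$frac_inverse, 1 / 5)
  expect_equal(cs$pearson_r,
               pearson_bruteforce(tl$log2fc, ts$log2fc), tolerance = 1e-12)

  # perfectly collinear pairs
  cl3 <- classify_degs(genes[1:3], genes[1:3], genes[1:3], genes[1:3])
  cs3 <- coregulation_stats(cl3, make_de(genes[1:3], c(1, 2, 3)),
                            make_de(genes[1:3], c(1, 2, 3), contrast = "S"))
  expect_equal(cs3$pearson_r, 1)
  expect_equal(cs3$n_inverse, 0L)
})

test_that("pearson_r is invariant under positive affine rescaling", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:50)
  cl <- classify_degs(genes, genes, genes, genes)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.5)
  base <- coregulation_stats(cl, make_de(genes, x),
                             make_de(genes, y, contrast = "S"))
  scaled <- coregulation_stats(cl, make_de(genes, 3 * x + 2),
                               make_de(genes, 0.5 * y - 1, contrast = "S"))
  expect_equal(scaled$pearson_r, base$pearson_r, tolerance = 1e-12)
})

test_that("correlation over fewer than two LS genes is an error", {
  genes <- c("g1", "g2")
  cl <- classify_degs("g1", character(0), "g1", genes)  # one L_DEG, no LS
  expect_error(coregulation_stats(cl, make_de(genes, c(1, 1)),
                                  make_de(genes, c(1, 1), contrast = "S")),
               "correlation undefined")
})

test_that("recovery at the published operating point: r and inverse share", {
  s <- simulate_contrasts(contrast_sim_config(
    5000, c(0, 0, 1, 0), rho_ls = 0.69, inverse_fraction = 0.082,
    seed = 17))
  cl <- classify_contrasts(s$tables)
  cs <- coregulation_stats(cl, s$tables$L, s$tables$S)
  expect_equal(cs$n_ls, 5000L)
  expect_lt(abs(cs$pearson_r - 0.69), 0.05)
  ci_half <- 1.96 * sqrt(0.082 * 0.918 / 5000)
  expect_lt(abs(cs$frac_inverse - 0.082), ci_half + 1e-12)
})
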