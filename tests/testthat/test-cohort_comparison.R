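test_that("subgroup selection follows three-valued flags and stage filters", {
  s <- simulate_cohort(small_cohort_config(n_genes = 50, n = 4, seed = 2))
  subs <- suppressWarnings(select_subgroups(s$cohort, default_subgroup_defs()))
  # planted group sizes recovered exactly
  expect_equal(lengths(subs)[c("WT", "LKB1", "SMARCA4", "TP53")],
               c(WT = 8L, LKB1 = 8L, SMARCA4 = 8L, TP53 = 8L))
  grp <- s$truth$group_of
  expect_setequal(subs$LKB1, names(grp)[startsWith(grp, "LKB1.")])

  staged <- select_subgroups(
    s$cohort, list(subgroup_def("LKB1_late", LKB1_mut = TRUE,
                                stage = "late")))
  expect_equal(length(staged$LKB1_late), 4L)

  # overlapping definitions are rejected by default, allowed on request
  overlapping <- list(subgroup_def("any_LKB1", LKB1_mut = TRUE),
                      subgroup_def("not_TP53", TP53_mut = FALSE))
  expect_error(select_subgroups(s$cohort, overlapping),
               "more than one subgroup")
  both <- select_subgroups(s$cohort, overlapping, allow_overlap = TRUE)
  expect_gt(length(intersect(both$any_LKB1, both$not_TP53)), 0L)
})

test_that("PCA reduction respects rank and the variance target", {
  # rank-1 matrix: one component explains everything
  u <- abs(rnorm(10)); v <- abs(rnorm(40))
  m <- (2^outer(u, v)) - 1
  dimnames(m) <- list(paste0("s", 1:10), paste0("g", 1:40))
  red <- pca_reduce(m, variance_target = 0.8)
  ev <- attr(red, "explained_variance")
  expect_equal(ncol(red), 1L)
  expect_gt(ev[1], 0.999)
  # explained variances are non-increasing and sum to <= 1
  expect_true(all(diff(ev) <= 1e-8))
  expect_lte(sum(ev), 1 + 1e-8)
  expect_error(pca_reduce(m[1:2, ]), "at least 3")
})

test_that("a planted two-factor cohort is captured by two components", {
  set.seed(6)
  n <- 30; g <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  load1 <- rnorm(g); load2 <- rnorm(g)
  logx <- 5 + outer(f1, load1) + outer(f2, load2) +
    matrix(rnorm(n * g, 0, 0.05), n)
  m <- 2^logx
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("g%03d", 1:g))
  red <- pca_reduce(m, variance_target = 0.95, max_components = 10)
  ev <- attr(red, "explained_variance")
  expect_gte(sum(ev[1:2]), 0.95)
  expect_lte(ncol(red), 3L)
})

test_that("correlation analysis equals the textbook computation", {
  set.seed(11)
  for (i in 1:5) {
    profiles <- lapply(stats::setNames(nm = letters[1:10]),
                       function(x) rnorm(10))
    R <- correlation_analysis(profiles)
    for (a in 1:9) for (b in (a + 1):10) {
      expect_equal(R[a, b], pearson_bruteforce(profiles[[a]],
                                               profiles[[b]]),
                   tolerance = 1e-12)
    }
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, 10))
  }
  p <- list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(-1, -2, -3))
  R <- correlation_analysis(p)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  expect_warning(correlation_analysis(list(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant profile")
})

test_that("subgroups sharing a planted program correlate highest", {
  cfg <- cohort_sim_config(
    500,
    group_sizes = data.frame(genotype = c("WT", "LKB1", "SMARCA4", "TP53"),
                             stage = "early", n = 12),
    shifts = list(
      list(genotype = "LKB1", stage = "early", genes = sprintf("g%03d", 1:60),
           log2_shift = 1.5),
      list(genotype = "SMARCA4", stage = "early",
           genes = sprintf("g%03d", 1:60), log2_shift = 1.5)),
    seed = 14)
  s <- simulate_cohort(cfg)
  logm <- log2(s$cohort$matrix + 1)
  grp <- s$truth$group_of[rownames(logm)]
  wt <- colMeans(logm[grp == "WT.early", ])
  prof <- lapply(c(LKB1 = "LKB1.early", SMARCA4 = "SMARCA4.early",
                   TP53 = "TP53.early"),
                 function(k) colMeans(logm[grp == k, ]) - wt)
  R <- correlation_analysis(prof)
  expect_gt(R["LKB1", "SMARCA4"], R["LKB1", "TP53"])
  expect_gt(R["LKB1", "SMARCA4"], R["SMARCA4", "TP53"])
})

test_that("cross-dataset correlation links matching programs and guards n", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:500)
  eff <- stats::setNames(rnorm(500, 0, 1), genes)
  cellines <- list(L_line = eff + rnorm(500, 0, 0.3),
                   S_line = rnorm(500))
  subgroups <- list(LKB1 = eff + rnorm(500, 0, 0.3),
                    TP53 = rnorm(500))
  for (l in names(cellines)) names(cellines[[l]]) <- genes
  for (l in names(subgroups)) names(subgroups[[l]]) <- genes
  R <- cross_dataset_correlation(cellines, subgroups)
  expect_equal(attr(R, "shared_genes"), 500L)
  expect_equal(colnames(R)[which.max(R["L_line", ])], "LKB1")
  expect_gt(R["L_line", "LKB1"], 0.5)
  expect_error(cross_dataset_correlation(
    lapply(cellines, function(v) v[1:10]), subgroups), "need >= 30")
})

test_that("independent random profiles stay near zero correlation", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    genes <- sprintf("g%04d", 1:1000)
    a <- list(x = stats::setNames(rnorm(1000), genes))
    b <- list(y = stats::setNames(rnorm(1000), genes))
    if (abs(cross_dataset_correlation(a, b)[1, 1]) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("stage-stratified DEA finds no markers when groups are identical", {
  s <- simulate_cohort(small_cohort_config(n_genes = 300, n = 10, seed = 4))
  subs <- suppressWarnings(select_subgroups(s$cohort, default_subgroup_defs()))
  subs <- subs[lengths(subs) > 0]
  mk <- stage_stratified_dea(s$cohort, subs)
  expect_s3_class(mk, "stage_marker_table")
  expect_equal(sum(mk$marker), 0L)
})

test_that("planted stage-specific shifts are recovered with FDR control", {
  cfg <- cohort_sim_config(
    2000,
    group_sizes = data.frame(genotype = c("WT", "WT", "LKB1", "LKB1"),
                             stage = c("early", "late", "early", "late"),
                             n = 30),
    shifts = list(list(genotype = "LKB1", stage = "late", n_genes = 50,
                       log2_shift = 2)),
    seed = 33)
  s <- simulate_cohort(cfg)
  subs <- suppressWarnings(select_subgroups(s$cohort, default_subgroup_defs()))
  subs <- subs[lengths(subs) > 0]
  mk <- stage_stratified_dea(s$cohort, subs)
  planted <- s$truth$shifted_genes[["LKB1.late"]]$gene
  late <- mk[mk$stage == "late" & mk$genotype == "LKB1", ]
  found <- late$gene[late$marker]
  expect_gte(length(intersect(found, planted)), 45L)
  fdr <- length(setdiff(found, planted)) / max(1L, length(found))
  expect_lte(fdr, 0.05 + 1.96 * sqrt(0.05 * 0.95 / max(1L, length(found))))
  # the unshifted early stratum stays clean
  early <- mk[mk$stage == "early" & mk$genotype == "LKB1", ]
  expect_equal(sum(early$marker), 0L)
})

test_that("tiny groups run without crashing and undersized ones are skipped", {
  cfg <- cohort_sim_config(
    50,
    group_sizes = data.frame(genotype = c("WT", "LKB1", "SMARCA4"),
                             stage = "early", n = c(2, 2, 1)),
    seed = 5)
  s <- simulate_cohort(cfg)
  subs <- suppressWarnings(select_subgroups(s$cohort, default_subgroup_defs()))
  subs <- subs[lengths(subs) > 0]
  expect_warning(mk <- stage_stratified_dea(s$cohort, subs,
                                            stages = "early"),
                 "below min_group_size")
  expect_true(all(mk$genotype == "LKB1"))
  expect_equal(sum(mk$marker), 0L)
})

test_that("row scaling maps rows to the stated ranges and conventions", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-2, 0, 2))
  mm <- rowscale_for_heatmap(m, "minmax")
  expect_equal(unname(mm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(mm["b", ]), c(0, 0, 0))  # constant-row convention
  z <- rowscale_for_heatmap(m, "zscore")
  expect_equal(unname(rowMeans(z)), c(0, 0, 0))
  expect_equal(unname(apply(z[c("a", "c"), ], 1, sd)), c(1, 1))
})

test_that("type-I error stays at the nominal level on pure-null cohorts", {
  false_pos <- 0L; tests <- 0L
  for (seed in 1:6) {
    cfg <- cohort_sim_config(
      800,
      group_sizes = data.frame(genotype = c("WT", "LKB1"),
                               stage = "early", n = 30),
      seed = 100 + seed)
    s <- simulate_cohort(cfg)
    subs <- suppressWarnings(select_subgroups(s$cohort, default_subgroup_defs()))
    subs <- subs[lengths(subs) > 0]
    mk <- stage_stratified_dea(s$cohort, subs, stages = "early")
    false_pos <- false_pos + sum(mk$marker)
    tests <- tests + nrow(mk)
  }
  # under the null, marker calls should be (essentially) absent
  expect_lte(false_pos / tests, 0.05)
})
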