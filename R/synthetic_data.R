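# Synthetic multi-contrast DE tables and TPM cohorts with planted structure.
#
# The contrast generator plants four gene classes (L-only, S-only, shared LS,
# null) in exact, largest-remainder proportions. True effect sizes are
# |log2FC| = floor + s with s log-normal, so every true effect clears the
# fold-change threshold by construction; effect directions are random 50/50.
# For shared (LS-class) genes the two single-mutant effects share a sign
# (concordant) or oppose (inverse, Bernoulli(inverse_fraction)); magnitudes
# are coupled through a Gaussian copula whose correlation is solved in closed
# form so that the Pearson correlation of the signed (L, S) effect pairs over
# all LS-class genes -- inverse genes included -- equals rho_ls.

#' Configuration for the multi-contrast DE simulator
#'
#' @param n_genes number of genes in the shared universe.
#' @param class_proportions numeric length-4 vector `(L, S, LS, null)`
#'   summing to 1; converted to exact counts by largest-remainder rounding.
#' @param effect_magnitude_mean mean |log2FC| of true effects (must exceed
#'   `effect_floor`).
#' @param effect_magnitude_sd standard deviation of true |log2FC|; 0 gives
#'   the noise-free regime with all magnitudes equal to the mean (and
#'   `rho_ls` ignored, since a degenerate magnitude distribution admits no
#'   correlation target).
#' @param effect_floor minimum |log2FC| of a true effect; defaults to the
#'   conventional detection threshold 0.5 so every planted effect is
#'   callable.
#' @param rho_ls target Pearson correlation of the signed (L-contrast,
#'   S-contrast) log2FC pairs across all LS-class genes. Feasibility
#'   requires `rho_ls <= 1 - 2 * inverse_fraction`.
#' @param inverse_fraction probability that an LS-class gene is inversely
#'   regulated (opposite signs, both magnitudes above the floor).
#' @param null_noise_sd standard deviation of the log2FC noise carried by
#'   unaffected genes.
#' @param target_fdr significance level the planted p-values are calibrated
#'   against: detected true effects receive `adj_p < target_fdr`, nulls
#'   `adj_p >= target_fdr` (subject to the error rates below). Raw p-values
#'   follow `p ~ U(0, target_fdr / 10)` for detected effects and
#'   `p ~ U(0, 1)` for nulls.
#' @param false_negative_rate fraction of true effects planted to miss the
#'   significance threshold.
#' @param false_positive_rate fraction of null genes planted to pass both
#'   thresholds.
#' @param seed integer random seed.
#' @return A validated `contrast_sim_config` list.
#' @export
contrast_sim_config <- function(n_genes,
                                class_proportions = c(0.083, 0.074, 0.502,
                                                      0.341),
                                effect_magnitude_mean = 1.25,
                                effect_magnitude_sd = 0.5,
                                effect_floor = 0.5,
                                rho_ls = 0.69,
                                inverse_fraction = 0.082,
                                null_noise_sd = 0.1,
                                target_fdr = 0.05,
                                false_negative_rate = 0,
                                false_positive_rate = 0,
                                seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_proportions = as.numeric(class_proportions),
              effect_magnitude_mean = effect_magnitude_mean,
              effect_magnitude_sd = effect_magnitude_sd,
              effect_floor = effect_floor,
              rho_ls = rho_ls,
              inverse_fraction = inverse_fraction,
              null_noise_sd = null_noise_sd,
              target_fdr = target_fdr,
              false_negative_rate = false_negative_rate,
              false_positive_rate = false_positive_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, length(cfg$class_proportions) == 4L,
            all(cfg$class_proportions >= 0),
            cfg$effect_magnitude_sd >= 0, cfg$effect_floor > 0,
            cfg$rho_ls >= -1, cfg$rho_ls <= 1,
            cfg$inverse_fraction >= 0, cfg$inverse_fraction <= 1,
            cfg$null_noise_sd >= 0,
            cfg$target_fdr > 0, cfg$target_fdr < 1,
            cfg$false_negative_rate >= 0, cfg$false_negative_rate <= 1,
            cfg$false_positive_rate >= 0, cfg$false_positive_rate <= 1)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ",
         sum(cfg$class_proportions), ")", call. = FALSE)
  }
  if (cfg$effect_magnitude_mean <= cfg$effect_floor) {
    stop("effect_magnitude_mean must exceed effect_floor", call. = FALSE)
  }
  if (cfg$effect_magnitude_sd > 0) .ls_copula_rho(cfg)  # fail early if infeasible
  class(cfg) <- "contrast_sim_config"
  cfg
}

# Closed-form Gaussian-copula correlation for the LS magnitude pairs.
# Magnitudes are m = floor + s, s ~ logNormal(mu_n, sigma_n) with
# E[s] = effect_magnitude_mean - floor and Var[s] = effect_magnitude_sd^2.
# Signed pairs have corr (Em^2 + C) / (Em^2 + V) per concordant gene and the
# negated value per inverse gene, so the required magnitude covariance is
# C = rho_ls * (Em^2 + V) / (1 - 2 f) - Em^2.
.ls_copula_rho <- function(cfg) {
  Es <- cfg$effect_magnitude_mean - cfg$effect_floor
  V <- cfg$effect_magnitude_sd^2
  Em <- cfg$effect_magnitude_mean
  f <- cfg$inverse_fraction
  if (abs(1 - 2 * f) < 1e-12) {
    stop("rho_ls is undefined at inverse_fraction = 0.5", call. = FALSE)
  }
  C <- cfg$rho_ls * (Em^2 + V) / (1 - 2 * f) - Em^2
  sigma_n2 <- log(1 + V / Es^2)
  arg <- 1 + C / Es^2
  if (arg <= 0) {
    stop("rho_ls = ", cfg$rho_ls, " is infeasible for these effect ",
         "magnitudes and inverse_fraction", call. = FALSE)
  }
  rho_g <- log(arg) / sigma_n2
  if (rho_g < -1 || rho_g > 1) {
    stop("rho_ls = ", cfg$rho_ls, " is infeasible: requires |copula ",
         "correlation| > 1 (note rho_ls <= 1 - 2*inverse_fraction)",
         call. = FALSE)
  }
  rho_g
}

# exact integer class counts by largest-remainder rounding, order L,S,LS,null
.allocate_classes <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# log-normal magnitude draws above the floor; z is standard normal
.magnitude <- function(cfg, z) {
  Es <- cfg$effect_magnitude_mean - cfg$effect_floor
  if (cfg$effect_magnitude_sd == 0) {
    return(rep(cfg$effect_magnitude_mean, length(z)))
  }
  sigma_n2 <- log(1 + cfg$effect_magnitude_sd^2 / Es^2)
  mu_n <- log(Es) - sigma_n2 / 2
  cfg$effect_floor + exp(mu_n + sqrt(sigma_n2) * z)
}

.runif_open <- function(n, min, max) {
  pmin(pmax(stats::runif(n, min, max), .Machine$double.xmin), 1)
}

#' Simulate three mutant-vs-WT differential-expression tables
#'
#' Generates aligned DE tables for the single-mutant contrasts `L` and `S`
#' and the double-mutant contrast `LS` over a shared gene universe, plus the
#' planted truth used as the oracle in recovery tests. L-class genes carry a
#' true effect in the `L` and `LS` tables only, S-class genes in `S` and
#' `LS`, LS-class genes in all three; null genes carry noise everywhere.
#' The double-mutant effect of an LS-class gene is the mean of its two
#' single-mutant effects (for inverse genes, the larger-magnitude effect),
#' perturbed by `N(0, effect_magnitude_sd / 2)` noise and kept above the
#' effect floor so planted effects remain callable.
#'
#' @param config a [contrast_sim_config()].
#' @return A list with elements `tables` (named list of [de_table()] for
#'   `L`, `S`, `LS`) and `truth` (data frame: `gene`, `class`, `beta_L`,
#'   `beta_S`, `inverse`).
#' @export
simulate_contrasts <- function(config) {
  stopifnot(inherits(config, "contrast_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("g%0*d", nchar(n), seq_len(n))
  counts <- .allocate_classes(n, cfg$class_proportions)
  cls <- rep(c("L", "S", "LS", "null"), counts)

  beta_L <- beta_S <- rep(NA_real_, n)
  inverse <- rep(NA, n)

  iL <- which(cls == "L"); iS <- which(cls == "S"); iLS <- which(cls == "LS")
  beta_L[iL] <- sample(c(-1, 1), length(iL), TRUE) *
    .magnitude(cfg, stats::rnorm(length(iL)))
  beta_S[iS] <- sample(c(-1, 1), length(iS), TRUE) *
    .magnitude(cfg, stats::rnorm(length(iS)))

  if (length(iLS)) {
    nls <- length(iLS)
    inverse[iLS] <- stats::runif(nls) < cfg$inverse_fraction
    rho_g <- if (cfg$effect_magnitude_sd > 0) .ls_copula_rho(cfg) else 1
    z1 <- stats::rnorm(nls)
    z2 <- rho_g * z1 + sqrt(max(0, 1 - rho_g^2)) * stats::rnorm(nls)
    m1 <- .magnitude(cfg, z1)
    m2 <- .magnitude(cfg, z2)
    s <- sample(c(-1, 1), nls, TRUE)
    beta_L[iLS] <- s * m1
    beta_S[iLS] <- ifelse(inverse[iLS], -s, s) * m2
  }

  # double-mutant effect per gene, floor-clamped on the magnitude scale
  eff_noise <- function(b) {
    sign(b) * pmax(abs(b) + stats::rnorm(length(b), 0,
                                         cfg$effect_magnitude_sd / 2),
                   cfg$effect_floor)
  }
  beta_LS <- rep(NA_real_, n)
  beta_LS[iL] <- eff_noise(beta_L[iL])
  beta_LS[iS] <- eff_noise(beta_S[iS])
  if (length(iLS)) {
    conc <- iLS[!inverse[iLS]]
    inv <- iLS[inverse[iLS]]
    beta_LS[conc] <- eff_noise((beta_L[conc] + beta_S[conc]) / 2)
    dom <- ifelse(abs(beta_L[inv]) >= abs(beta_S[inv]),
                  beta_L[inv], beta_S[inv])
    beta_LS[inv] <- eff_noise(dom)
  }

  affected <- list(L = cls %in% c("L", "LS"),
                   S = cls %in% c("S", "LS"),
                   LS = cls != "null")
  betas <- list(L = beta_L, S = beta_S, LS = beta_LS)

  tables <- lapply(c(L = "L", S = "S", LS = "LS"), function(ct) {
    hit <- affected[[ct]]
    lfc <- stats::rnorm(n, 0, cfg$null_noise_sd)
    lfc[hit] <- betas[[ct]][hit]
    miss <- hit & (stats::runif(n) < cfg$false_negative_rate)
    fp <- !hit & (stats::runif(n) < cfg$false_positive_rate)
    p <- .runif_open(n, 0, 1)
    adj <- .runif_open(n, cfg$target_fdr, 1)
    det <- (hit & !miss) | fp
    p[det] <- .runif_open(sum(det), 0, cfg$target_fdr / 10)
    adj[det] <- .runif_open(sum(det), 1e-8, cfg$target_fdr / 2)
    # injected false positives must clear the fold-change threshold too
    lfc[fp] <- sample(c(-1, 1), sum(fp), TRUE) *
      (cfg$effect_floor + abs(stats::rnorm(sum(fp), 0, 0.2)))
    de_table(genes, lfc, p, adj, contrast_id = ct)
  })

  truth <- data.frame(gene = genes, class = cls, beta_L = beta_L,
                      beta_S = beta_S, inverse = inverse,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene), , drop = FALSE]
  rownames(truth) <- NULL
  list(tables = tables, truth = truth)
}

# ---- cohort simulation ------------------------------------------------------

.GENOTYPE_LEVELS <- c("WT", "LKB1", "SMARCA4", "TP53", "KRAS",
                      "LKB1_SMARCA4")

#' Configuration for the TPM-cohort simulator
#'
#' @param n_genes number of genes.
#' @param group_sizes data frame with columns `genotype` (one of `WT`,
#'   `LKB1`, `SMARCA4`, `TP53`, `KRAS`, `LKB1_SMARCA4`), `stage` (`early`,
#'   `late`, `unknown`) and `n` (samples per group, each >= 1).
#' @param baseline_log_mean,baseline_log_sd mean and sd of the per-gene
#'   baseline expression on the log2 scale.
#' @param dispersion per-sample log2-scale noise sd.
#' @param shifts list of planted group effects; each element is a list with
#'   `genotype`, `stage`, `log2_shift` and either `n_genes` (genes drawn at
#'   random) or `genes` (explicit ids).
#' @param seed integer random seed.
#' @return A validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_genes,
                              group_sizes,
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              dispersion = 0.5,
                              shifts = list(),
                              seed = 1L) {
  stopifnot(is.data.frame(group_sizes),
            all(c("genotype", "stage", "n") %in% names(group_sizes)))
  if (any(group_sizes$n < 1)) stop("every group needs >= 1 sample",
                                   call. = FALSE)
  bad <- setdiff(group_sizes$genotype, .GENOTYPE_LEVELS)
  if (length(bad)) stop("unknown genotype label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad_stage <- setdiff(group_sizes$stage, .STAGE_TOKENS)
  if (length(bad_stage)) stop("unknown stage token(s): ",
                              paste(bad_stage, collapse = ", "),
                              call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion, shifts = shifts,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$dispersion >= 0, cfg$baseline_log_sd >= 0)
  class(cfg) <- "cohort_sim_config"
  cfg
}

.genotype_flags <- function(genotype) {
  stats::setNames(vapply(c("LKB1", "SMARCA4", "TP53", "KRAS"),
                         function(g) grepl(g, genotype, fixed = TRUE),
                         logical(1L)),
                  c("LKB1_mut", "SMARCA4_mut", "TP53_mut", "KRAS_mut"))
}

#' Simulate a TPM-normalized expression cohort with planted group shifts
#'
#' Per-gene baselines are drawn on the log2 scale, per-sample noise and any
#' planted group-specific log2 shifts are added, values are exponentiated
#' and each sample is renormalized to a constant library size of 1e6
#' (TPM convention).
#'
#' @param config a [cohort_sim_config()].
#' @return A list with elements `cohort` (an [expression_cohort()]) and
#'   `truth` (list: `shifted_genes`, a named list of planted gene/shift
#'   tables keyed by `genotype.stage`, and `group_of`, the planted group of
#'   every sample).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("g%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log_mean,
                           cfg$baseline_log_sd)

  shift_map <- list()
  for (sh in cfg$shifts) {
    key <- paste(sh$genotype, sh$stage, sep = ".")
    picked <- if (!is.null(sh$genes)) as.character(sh$genes) else
      sample(genes, sh$n_genes)
    if (!all(picked %in% genes)) stop("shift names unknown genes",
                                      call. = FALSE)
    delta <- stats::setNames(rep(0, cfg$n_genes), genes)
    if (!is.null(shift_map[[key]])) delta <- shift_map[[key]]
    delta[picked] <- delta[picked] + sh$log2_shift
    shift_map[[key]] <- delta
  }

  rows <- list(); meta <- list(); group_of <- character(0)
  for (i in seq_len(nrow(cfg$group_sizes))) {
    g <- cfg$group_sizes$genotype[i]; st <- cfg$group_sizes$stage[i]
    ni <- cfg$group_sizes$n[i]
    key <- paste(g, st, sep = ".")
    delta <- if (!is.null(shift_map[[key]])) shift_map[[key]] else 0
    ids <- sprintf("%s_%s_s%02d", g, st, seq_len(ni))
    logx <- matrix(baseline, nrow = ni, ncol = cfg$n_genes, byrow = TRUE) +
      matrix(delta, nrow = ni, ncol = cfg$n_genes, byrow = TRUE) +
      matrix(stats::rnorm(ni * cfg$n_genes, 0, cfg$dispersion), nrow = ni)
    x <- 2^logx
    x <- x / rowSums(x) * 1e6
    rownames(x) <- ids; colnames(x) <- genes
    rows[[key]] <- x
    fl <- .genotype_flags(g)
    meta[[key]] <- data.frame(sample_id = ids,
                              LKB1_mut = fl[["LKB1_mut"]],
                              SMARCA4_mut = fl[["SMARCA4_mut"]],
                              TP53_mut = fl[["TP53_mut"]],
                              KRAS_mut = fl[["KRAS_mut"]],
                              stage = st, stringsAsFactors = FALSE)
    group_of <- c(group_of, stats::setNames(rep(key, ni), ids))
  }
  mat <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  shifted <- lapply(shift_map, function(d) {
    d <- d[d != 0]
    data.frame(gene = names(d), log2_shift = unname(d),
               stringsAsFactors = FALSE)
  })
  list(cohort = expression_cohort(mat, metadata),
       truth = list(shifted_genes = shifted, group_of = group_of))
}

#' Simulate a GMT-style gene-set collection
#'
#' Plumbing for demos and tests: draws random gene sets from a universe,
#' optionally planting sets that are enriched in a target gene list.
#'
#' @param genes character vector, the gene universe.
#' @param n_sets number of random sets.
#' @param size_range integer length-2 range of set sizes.
#' @param planted optional named list of explicit gene vectors added as
#'   additional sets.
#' @param seed integer random seed.
#' @return A `gene_sets` collection (see [read_gmt()]).
#' @export
simulate_gene_sets <- function(genes, n_sets = 50, size_range = c(10, 40),
                               planted = list(), seed = 1L) {
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  members <- lapply(sizes, function(k) sample(genes, k))
  names(members) <- sprintf("SET:%04d", seq_len(n_sets))
  members <- c(members, planted)
  gene_sets(members)
}
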