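# Mutation-stratified analysis of TPM expression cohorts: subgroup
# selection from genotype flags, PCA reduction, Pearson correlation within
# and across datasets, stage-stratified marker detection against
# stage-matched wild-type samples, and heatmap-ready row scaling.
# Expression enters every comparison on the log2(TPM + 1) scale.

#' Define a mutation subgroup
#'
#' Flags are three-valued: `TRUE` (mutation required), `FALSE` (wild type
#' required) or `NA` (don't care). Unlisted flags default to don't-care.
#'
#' @param name subgroup label.
#' @param LKB1_mut,SMARCA4_mut,TP53_mut,KRAS_mut required genotype flags.
#' @param stage optional stage filter (`"early"`, `"late"`).
#' @return A `subgroup_def` list.
#' @export
subgroup_def <- function(name, LKB1_mut = NA, SMARCA4_mut = NA,
                         TP53_mut = NA, KRAS_mut = NA, stage = NULL) {
  structure(list(name = name,
                 flags = c(LKB1_mut = LKB1_mut, SMARCA4_mut = SMARCA4_mut,
                           TP53_mut = TP53_mut, KRAS_mut = KRAS_mut),
                 stage = stage),
            class = "subgroup_def")
}

#' Assign cohort samples to mutation subgroups
#'
#' @param cohort an [expression_cohort()].
#' @param defs list of [subgroup_def()]s.
#' @param allow_overlap may one sample match several definitions? If
#'   `FALSE` (default) an overlapping sample raises an error naming it.
#' @return Named list mapping subgroup name to a character vector of sample
#'   ids; empty subgroups are kept (with a warning).
#' @export
select_subgroups <- function(cohort, defs, allow_overlap = FALSE) {
  stopifnot(inherits(cohort, "expression_cohort"))
  md <- cohort$metadata
  assign <- lapply(defs, function(d) {
    keep <- rep(TRUE, nrow(md))
    for (fl in names(d$flags)) {
      if (!is.na(d$flags[[fl]])) keep <- keep & (md[[fl]] == d$flags[[fl]])
    }
    if (!is.null(d$stage)) keep <- keep & md$stage %in% d$stage
    md$sample_id[keep]
  })
  names(assign) <- vapply(defs, `[[`, "", "name")
  empty <- names(assign)[lengths(assign) == 0L]
  if (length(empty)) warning("empty subgroup(s): ",
                             paste(empty, collapse = ", "))
  if (!allow_overlap) {
    all_ids <- unlist(assign)
    dup <- unique(all_ids[duplicated(all_ids)])
    if (length(dup)) {
      stop("sample '", dup[1L], "' matches more than one subgroup ",
           "definition (set allow_overlap = TRUE to permit this)",
           call. = FALSE)
    }
  }
  assign
}

#' PCA dimension reduction of a cohort matrix
#'
#' Log2(TPM + 1)-transforms and gene-centers the matrix, then retains the
#' smallest number of principal components explaining at least
#' `variance_target` of the variance, capped at `max_components`.
#'
#' @param x an [expression_cohort()] or a samples-by-genes TPM matrix.
#' @param variance_target fraction of variance to capture (default 0.8).
#' @param max_components hard cap on retained components (default 10).
#' @return Samples-by-components score matrix with attribute
#'   `explained_variance` (per-component fractions, full curve).
#' @export
pca_reduce <- function(x, variance_target = 0.8, max_components = 10L) {
  m <- if (inherits(x, "expression_cohort")) x$matrix else x
  stopifnot(is.matrix(m))
  if (nrow(m) < 3L) stop("PCA reduction needs at least 3 samples",
                         call. = FALSE)
  lm2 <- log2(m + 1)
  lm2 <- sweep(lm2, 2L, colMeans(lm2))
  pc <- stats::prcomp(lm2, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_keep <- which(cumsum(ev) >= variance_target)[1L]
  if (is.na(n_keep)) n_keep <- length(ev)
  n_keep <- min(n_keep, max_components, ncol(pc$x))
  out <- pc$x[, seq_len(n_keep), drop = FALSE]
  attr(out, "explained_variance") <- ev
  out
}

#' Pairwise Pearson correlation of entity profiles
#'
#' @param profiles named list of numeric vectors over an identical index
#'   (samples, subgroup means, cell-line profiles, ...).
#' @param zscore also return a display transform with off-diagonal entries
#'   standardized to z-scores?
#' @return A symmetric correlation matrix (unit diagonal). Pairs involving
#'   a constant profile are `NA` (reported via a warning). With
#'   `zscore = TRUE` the z-scored copy is attached as attribute `"zscore"`.
#' @export
correlation_analysis <- function(profiles, zscore = FALSE) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  len <- unique(lengths(profiles))
  if (length(len) != 1L) stop("profiles must share an identical index",
                              call. = FALSE)
  m <- do.call(cbind, profiles)
  constant <- apply(m, 2L, function(v) stats::sd(v) == 0)
  R <- suppressWarnings(stats::cor(m))
  diag(R) <- 1
  if (any(constant)) {
    warning("constant profile(s), correlations undefined: ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  if (zscore) {
    off <- R[upper.tri(R)]
    z <- R
    z[upper.tri(R) | lower.tri(R)] <-
      (R[upper.tri(R) | lower.tri(R)] - mean(off, na.rm = TRUE)) /
      stats::sd(off, na.rm = TRUE)
    attr(R, "zscore") <- z
  }
  R
}

#' Correlate cell-line contrast profiles with tumor-subgroup profiles
#'
#' Restricts both profile sets to their shared gene index and reports the
#' rectangular Pearson block (cell lines by subgroups), making single-cell
#' contrast log2FCs and bulk subgroup-vs-WT log2FCs commensurable.
#'
#' @param contrast_profiles named list of named log2FC vectors (cell-line
#'   contrasts).
#' @param subgroup_profiles named list of named log2FC-vs-WT vectors
#'   (tumor subgroups).
#' @param min_shared minimum shared-gene count (default 30).
#' @return Matrix of Pearson r, rows = cell lines, columns = subgroups,
#'   with attribute `shared_genes`.
#' @export
cross_dataset_correlation <- function(contrast_profiles, subgroup_profiles,
                                      min_shared = 30L) {
  shared <- Reduce(intersect, c(lapply(contrast_profiles, names),
                                lapply(subgroup_profiles, names)))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared gene(s); need >= ", min_shared,
         call. = FALSE)
  }
  A <- vapply(contrast_profiles, function(v) v[shared],
              numeric(length(shared)))
  B <- vapply(subgroup_profiles, function(v) v[shared],
              numeric(length(shared)))
  R <- stats::cor(A, B)
  attr(R, "shared_genes") <- length(shared)
  R
}

#' Stage-stratified marker detection against stage-matched wild type
#'
#' For every mutant subgroup and stage, compares each gene's log2(TPM + 1)
#' values against the stage-matched wild-type samples: the effect is the
#' difference in group means, significance is a two-sided Wilcoxon rank-sum
#' test, and Benjamini-Hochberg adjustment is applied across genes within
#' each (genotype, stage) stratum. Markers are rows passing the shared
#' [thresholds()] used throughout the workflow, so the bulk analysis runs
#' under the same parameters as the contrast-level DEG calling.
#'
#' @param cohort an [expression_cohort()].
#' @param subgroups named list mapping subgroup name to sample ids (see
#'   [select_subgroups()]); must include the wild-type group.
#' @param thresholds a [thresholds()] object.
#' @param min_group_size groups smaller than this are skipped with a
#'   warning (default 2).
#' @param wt_name name of the wild-type subgroup (default `"WT"`).
#' @param stages stages analyzed (default early and late).
#' @return A `stage_marker_table` data frame: `genotype`, `stage`, `gene`,
#'   `log2fc`, `p_value`, `adj_p`, `direction`, `marker`.
#' @export
stage_stratified_dea <- function(cohort, subgroups,
                                 thresholds = epideg::thresholds(),
                                 min_group_size = 2L, wt_name = "WT",
                                 stages = c("early", "late")) {
  stopifnot(inherits(cohort, "expression_cohort"),
            wt_name %in% names(subgroups))
  md <- cohort$metadata
  logm <- log2(cohort$matrix + 1)
  stage_of <- stats::setNames(md$stage, md$sample_id)
  res <- list()
  for (st in stages) {
    wt <- subgroups[[wt_name]][stage_of[subgroups[[wt_name]]] == st]
    if (length(wt) < min_group_size) {
      warning("stage '", st, "': wild-type group below min_group_size, ",
              "stage skipped")
      next
    }
    for (grp in setdiff(names(subgroups), wt_name)) {
      mut <- subgroups[[grp]][stage_of[subgroups[[grp]]] == st]
      if (length(mut) < min_group_size) {
        warning("group '", grp, "' at stage '", st,
                "' below min_group_size, skipped")
        next
      }
      mm <- logm[mut, , drop = FALSE]
      wm <- logm[wt, , drop = FALSE]
      lfc <- colMeans(mm) - colMeans(wm)
      p <- vapply(seq_len(ncol(logm)), function(j) {
        stats::wilcox.test(mm[, j], wm[, j], exact = FALSE)$p.value
      }, 0)
      p[is.na(p)] <- 1  # all-tied genes carry no evidence
      adj <- stats::p.adjust(p, method = "BH")
      res[[paste(grp, st)]] <- data.frame(
        genotype = grp, stage = st, gene = colnames(logm),
        log2fc = unname(lfc), p_value = p, adj_p = adj,
        direction = ifelse(lfc >= 0, "up", "down"),
        marker = abs(lfc) >= thresholds$lfc_min & adj < thresholds$fdr_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(genotype = character(0), stage = character(0),
               gene = character(0), log2fc = numeric(0),
               p_value = numeric(0), adj_p = numeric(0),
               direction = character(0), marker = logical(0))
  rownames(out) <- NULL
  class(out) <- c("stage_marker_table", "data.frame")
  out
}

#' Row scaling for heatmap display
#'
#' @param matrix numeric matrix.
#' @param mode `"minmax"` maps each row onto \[0, 1\]; `"zscore"` centers
#'   and scales each row. Constant rows map to all-zero in both modes.
#' @return The scaled matrix.
#' @export
rowscale_for_heatmap <- function(matrix, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  t(apply(matrix, 1L, function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(rep(0, length(v)))
    if (mode == "minmax") (v - rng[1L]) / diff(rng)
    else (v - mean(v)) / stats::sd(v)
  }))
}
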