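# Network-node annotation and the end-to-end pipeline driver.

#' Annotate interaction-network nodes with DEG class and direction
#'
#' Drops edges below the confidence cutoff (STRING-style medium confidence
#' is 600; an edge scoring exactly 600 is kept) and labels every remaining
#' node with its DEG class and a regulation direction: `up` or `down` when
#' the gene's log2FC sign agrees across every contrast in which it was
#' detected, `inconsistent` otherwise. Genes absent from the classification
#' are labeled `OTHER`; for genes detected in no contrast the sign is read
#' across all three tables. The `display_code` (`"LS_DEG/up"`, ...) is a
#' semantic token mirroring the usual color scheme of such network figures.
#'
#' @param edges an `edge_list` (see [read_edge_list()]).
#' @param classification a `deg_classification` from [classify_degs()].
#' @param tables named list of the three [de_table()]s (`L`, `S`, `LS`).
#' @param min_score minimum confidence score retained (default 600).
#' @return List with `nodes` (data frame: `gene`, `deg_class`, `direction`,
#'   `display_code`) and `edges` (the filtered `edge_list`).
#' @export
annotate_network_nodes <- function(edges, classification, tables,
                                   min_score = 600L) {
  stopifnot(inherits(edges, "edge_list"),
            inherits(classification, "deg_classification"),
            all(c("L", "S", "LS") %in% names(tables)))
  kept <- edges[edges$score >= min_score, , drop = FALSE]
  class(kept) <- c("edge_list", "data.frame")
  if (!nrow(kept)) {
    warning("no edge reaches the confidence cutoff (", min_score,
            "); returning empty annotation")
    return(list(nodes = data.frame(gene = character(0),
                                   deg_class = character(0),
                                   direction = character(0),
                                   display_code = character(0)),
                edges = kept))
  }
  genes <- sort(unique(c(kept$node_a, kept$node_b)))
  idx <- match(genes, classification$gene)
  deg_class <- ifelse(is.na(idx), "OTHER", classification$label[idx])
  det <- cbind(L = ifelse(is.na(idx), FALSE, classification$detected_L[idx]),
               S = ifelse(is.na(idx), FALSE, classification$detected_S[idx]),
               LS = ifelse(is.na(idx), FALSE,
                           classification$detected_LS[idx]))
  lfc <- vapply(c("L", "S", "LS"), function(ct) {
    tables[[ct]]$log2fc[match(genes, tables[[ct]]$gene)]
  }, numeric(length(genes)))
  direction <- vapply(seq_along(genes), function(i) {
    use <- if (any(det[i, ])) det[i, ] else !is.na(lfc[i, ])
    sgn <- sign(lfc[i, use])
    sgn <- sgn[!is.na(sgn)]
    if (!length(sgn)) return(NA_character_)
    if (all(sgn > 0)) "up" else if (all(sgn < 0)) "down" else "inconsistent"
  }, "")
  nodes <- data.frame(gene = genes, deg_class = deg_class,
                      direction = direction,
                      display_code = paste(deg_class, direction, sep = "/"),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = kept)
}

#' Default mutation-subgroup definitions
#'
#' The four tumor genotypes matched to the cell-line panel: wild type for
#' all three tumor suppressors, LKB1-mutant only, SMARCA4-mutant only,
#' TP53-mutant only, plus the LKB1-SMARCA4 double mutant. Definitions are
#' mutually exclusive.
#'
#' @return List of [subgroup_def()]s.
#' @export
default_subgroup_defs <- function() {
  list(subgroup_def("WT", FALSE, FALSE, FALSE),
       subgroup_def("LKB1", TRUE, FALSE, FALSE),
       subgroup_def("SMARCA4", FALSE, TRUE, FALSE),
       subgroup_def("TP53", FALSE, FALSE, TRUE),
       subgroup_def("LKB1_SMARCA4", TRUE, TRUE, NA))
}

#' DEG class counts reported for the Calu-3/H460/H1299/A549 comparison
#'
#' Headline counts from the published single-cell comparison of the four
#' lung cancer cell lines that this workflow models: the detected-gene
#' universe, the three DEG classes, the inversely regulated shared genes,
#' and the immune-response annotation split. Shipped as a plain-text table
#' under `inst/extdata` so the dataset-level ratios can be recomputed.
#'
#' @return Named numeric vector of counts.
#' @export
reported_deg_counts <- function() {
  path <- system.file("extdata", "reported_deg_counts.tsv",
                      package = "epideg", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$value), tab$quantity)
}

#' Dataset-level shares from DEG class counts
#'
#' @param counts named numeric vector with entries `detected_degs`,
#'   `ls_degs`, `inverse_ls_degs`, `immune_response_degs`,
#'   `immune_response_ls_degs` (defaults to [reported_deg_counts()]).
#' @return Named numeric vector of percentages: `ls_share_pct` (shared DEGs
#'   among all detected genes), `inverse_pct` (inversely regulated among
#'   shared DEGs), `immune_ls_pct` (shared DEGs among immune-response DEGs).
#' @export
deg_count_shares <- function(counts = reported_deg_counts()) {
  c(ls_share_pct = 100 * counts[["ls_degs"]] / counts[["detected_degs"]],
    inverse_pct = 100 * counts[["inverse_ls_degs"]] / counts[["ls_degs"]],
    immune_ls_pct = 100 * counts[["immune_response_ls_degs"]] /
      counts[["immune_response_degs"]])
}

# ---- pipeline ---------------------------------------------------------------

.pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full workflow from a YAML configuration
#'
#' Orchestrates simulate (optional) -> classify -> co-regulation ->
#' enrichment per DEG class -> cohort analysis (optional) -> network
#' annotation (optional), writing TSV/JSON outputs plus a `manifest.json`
#' listing versions, seeds, thresholds, per-stage row counts and an MD5
#' checksum for every output file. Re-running an identical configuration
#' reproduces byte-identical outputs. Any stage failure aborts with the
#' stage name and cause.
#'
#' Configuration keys: `seed` (mandatory), `out_dir`, optional `thresholds`
#' (`lfc_min`, `fdr_max`), a `simulate` block (`contrasts`, optional
#' `cohort`, optional `gene_sets`) and/or an `inputs` block (`de_tables`
#' with paths for `L`/`S`/`LS`, `gmt`, `cohort` with `matrix`/`metadata`,
#' `edges`), an `enrich` block (`min_hits`, `fdr_max`, `metric`, `k_max`)
#' and a `network` block (`min_score`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return The output directory, invisibly; side effect: files and
#'   `manifest.json` under it.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set an integer 'seed'",
                              call. = FALSE)
  seed <- as.integer(cfg$seed)
  out <- out_dir %||% cfg$out_dir
  if (is.null(out)) stop("no output directory given", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th_cfg <- cfg$thresholds %||% list()
  th <- thresholds(lfc_min = th_cfg$lfc_min %||% 0.5,
                   fdr_max = th_cfg$fdr_max %||% 0.05)
  files <- character(0)
  stage_rows <- list()

  # -- inputs: simulated and/or read from disk
  tables <- NULL; sets <- NULL; cohort <- NULL; edges <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- .pipeline_stage("simulate", {
      sc <- cfg$simulate$contrasts
      if (is.null(sc)) stop("simulate block needs a 'contrasts' entry")
      ccfg <- contrast_sim_config(
        n_genes = sc$n_genes,
        class_proportions = unlist(sc$class_proportions %||%
                                     c(0.083, 0.074, 0.502, 0.341)),
        effect_magnitude_mean = sc$effect_magnitude_mean %||% 1.25,
        effect_magnitude_sd = sc$effect_magnitude_sd %||% 0.5,
        rho_ls = sc$rho_ls %||% 0.69,
        inverse_fraction = sc$inverse_fraction %||% 0.082,
        null_noise_sd = sc$null_noise_sd %||% 0.1,
        seed = seed)
      simulate_contrasts(ccfg)
    })
    tables <- sim$tables
    truth <- sim$truth
    files <- c(files, .write_tsv(truth, file.path(out, "sim_truth.tsv")))
    for (ct in names(tables)) {
      files <- c(files, write_de_table(
        tables[[ct]], file.path(out, sprintf("de_table_%s.tsv", ct))))
    }
    if (!is.null(cfg$simulate$gene_sets)) {
      gs <- cfg$simulate$gene_sets
      sets <- simulate_gene_sets(tables$L$gene,
                                 n_sets = gs$n_sets %||% 50L,
                                 size_range = unlist(gs$size_range %||%
                                                       c(10L, 40L)),
                                 seed = seed + 1L)
      files <- c(files, write_gmt(sets, file.path(out, "gene_sets.gmt")))
    }
    if (!is.null(cfg$simulate$cohort)) {
      sco <- cfg$simulate$cohort
      gcfg <- cohort_sim_config(
        n_genes = sco$n_genes,
        group_sizes = do.call(rbind, lapply(sco$group_sizes, function(g) {
          data.frame(genotype = g$genotype, stage = g$stage, n = g$n)
        })),
        dispersion = sco$dispersion %||% 0.5,
        shifts = sco$shifts %||% list(),
        seed = seed + 2L)
      csim <- .pipeline_stage("simulate", simulate_cohort(gcfg))
      cohort <- csim$cohort
      files <- c(files, write_expression_cohort(
        cohort, file.path(out, "cohort_tpm.tsv"),
        file.path(out, "cohort_metadata.tsv")))
    }
  }
  if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    if (!is.null(ip$de_tables)) {
      tables <- .pipeline_stage("read_inputs", {
        lapply(stats::setNames(nm = c("L", "S", "LS")), function(ct) {
          read_de_table(ip$de_tables[[ct]], contrast_id = ct)
        })
      })
    }
    if (!is.null(ip$gmt)) sets <- .pipeline_stage("read_inputs",
                                                  read_gmt(ip$gmt))
    if (!is.null(ip$cohort)) {
      cohort <- .pipeline_stage("read_inputs", read_expression_cohort(
        ip$cohort$matrix, ip$cohort$metadata))
    }
    if (!is.null(ip$edges)) edges <- .pipeline_stage("read_inputs",
                                                     read_edge_list(ip$edges))
  }
  if (is.null(tables)) stop("pipeline stage 'classify' failed: no DE ",
                            "tables (provide simulate or inputs$de_tables)",
                            call. = FALSE)

  # -- classify + co-regulation
  cls <- .pipeline_stage("classify", classify_contrasts(tables, th))
  files <- c(files, .write_tsv(as.data.frame(cls),
                               file.path(out, "classification.tsv")))
  counts <- attr(cls, "counts")
  jsonlite::write_json(as.list(counts), file.path(out, "class_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(out, "class_counts.json"))
  stage_rows$classify <- nrow(cls)

  coreg <- .pipeline_stage("coregulation", coregulation_stats(
    cls, tables$L, tables$S, th))
  files <- c(files, .write_tsv(coreg$scatter,
                               file.path(out, "coregulation_scatter.tsv")))
  jsonlite::write_json(coreg[c("pearson_r", "n_ls", "n_inverse",
                               "frac_inverse")],
                       file.path(out, "coregulation_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(out, "coregulation_summary.json"))
  stage_rows$coregulation <- coreg$n_ls

  # -- enrichment per class
  if (!is.null(cfg$enrich)) {
    en <- cfg$enrich
    if (is.null(sets)) {
      stop("pipeline stage 'enrich' failed: no gene sets (provide ",
           "inputs$gmt or simulate$gene_sets)", call. = FALSE)
    }
    lfc_ls <- stats::setNames(tables$LS$log2fc, tables$LS$gene)
    annotated <- unique(unlist(sets))
    universe <- intersect(cls$gene, annotated)
    enr_rows <- 0L
    ls_table <- NULL
    for (lab in c("L_DEG", "S_DEG", "LS_DEG")) {
      genes <- intersect(cls$gene[cls$label == lab], universe)
      tab <- .pipeline_stage("enrich", enrich_class(
        genes, lfc_ls, universe, sets,
        min_hits = en$min_hits %||% 4L, fdr_max = en$fdr_max %||% 0.05))
      flat <- as.data.frame(tab)
      flat$intersection <- vapply(tab$intersection, paste, "",
                                  collapse = ";")
      files <- c(files, .write_tsv(
        flat, file.path(out, sprintf("enrichment_%s.tsv", lab))))
      enr_rows <- enr_rows + nrow(tab)
      if (lab == "LS_DEG") ls_table <- tab
    }
    stage_rows$enrich <- enr_rows
    if (!is.null(ls_table) && nrow(ls_table) >= 3L) {
      clu <- .pipeline_stage("enrich", {
        sim_m <- term_similarity(ls_table,
                                 metric = en$metric %||% "jaccard")
        cluster_terms(sim_m, k_max = min(en$k_max %||% 8L,
                                         nrow(ls_table) - 1L),
                      seed = seed + 3L)
      })
      files <- c(files, .write_tsv(
        data.frame(term_id = names(clu$labels), cluster = clu$labels),
        file.path(out, "term_clusters.tsv")))
      files <- c(files, .write_tsv(clu$silhouette_curve,
                                   file.path(out, "silhouette_curve.tsv")))
    }
  }

  # -- cohort analysis
  if (!is.null(cohort)) {
    coh <- .pipeline_stage("cohort", {
      subs <- select_subgroups(cohort, default_subgroup_defs())
      subs <- subs[lengths(subs) > 0L]
      logm <- log2(cohort$matrix + 1)
      profiles <- lapply(subs, function(ids) {
        colMeans(logm[ids, , drop = FALSE])
      })
      R <- correlation_analysis(profiles)
      markers <- suppressWarnings(
        stage_stratified_dea(cohort, subs, th))
      group_means <- do.call(rbind, profiles)
      list(subs = subs, R = R, markers = markers,
           scaled = rowscale_for_heatmap(t(group_means), "minmax"))
    })
    jsonlite::write_json(lapply(coh$subs, length),
                         file.path(out, "subgroup_counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, file.path(out, "subgroup_counts.json"))
    files <- c(files, .write_tsv(
      data.frame(subgroup = rownames(coh$R), coh$R, check.names = FALSE),
      file.path(out, "subgroup_correlation.tsv")))
    files <- c(files, .write_tsv(coh$markers,
                                 file.path(out, "stage_markers.tsv")))
    files <- c(files, .write_tsv(
      data.frame(gene = rownames(coh$scaled), coh$scaled,
                 check.names = FALSE),
      file.path(out, "heatmap_minmax.tsv")))
    stage_rows$cohort <- nrow(coh$markers)
  }

  # -- network annotation
  if (!is.null(edges)) {
    net <- .pipeline_stage("network", annotate_network_nodes(
      edges, cls, tables,
      min_score = (cfg$network$min_score %||% 600L)))
    files <- c(files, .write_tsv(net$nodes,
                                 file.path(out, "network_nodes.tsv")))
    files <- c(files, .write_tsv(as.data.frame(net$edges),
                                 file.path(out, "network_edges.tsv")))
    stage_rows$network <- nrow(net$nodes)
  }

  manifest <- list(
    package = "epideg",
    version = as.character(utils::packageVersion("epideg")),
    seed = seed,
    thresholds = list(lfc_min = th$lfc_min, fdr_max = th$fdr_max),
    stage_rows = stage_rows,
    outputs = lapply(stats::setNames(nm = sort(basename(files))),
                     function(f) {
                       unname(tools::md5sum(file.path(out, f)))
                     }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
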