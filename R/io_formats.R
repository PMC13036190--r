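# Readers and writers for the external formats the workflow touches:
# per-contrast differential-expression tables (TSV/CSV), GMT gene-set
# collections, TPM expression cohorts (TSV or MatrixMarket triplet) with
# sample metadata, and STRING-export-style interaction edge lists.
# All readers validate on entry and normalize gene order lexicographically
# so that write/read round-trips are exact.

.DE_COLUMNS <- c(gene = "gene", log2fc = "log2fc",
                 p_value = "p_value", adj_p = "adj_p")
.STAGE_TOKENS <- c("early", "late", "unknown")
.GENOTYPE_FLAGS <- c("LKB1_mut", "SMARCA4_mut", "TP53_mut", "KRAS_mut")

#' Construct a differential-expression table
#'
#' A `de_table` is a data frame with one row per gene and columns `gene`,
#' `log2fc` (log2 fold change, mutant over wild-type), `p_value` and `adj_p`,
#' carrying the contrast label (`"L"`, `"S"`, `"LS"`, or any other label) as
#' an attribute. Rows are kept sorted by gene identifier; gene identifiers
#' are case-sensitive opaque strings.
#'
#' @param genes character vector of unique gene identifiers.
#' @param log2fc numeric vector of finite log2 fold changes.
#' @param p_value numeric vector of p-values in (0, 1].
#' @param adj_p numeric vector of adjusted p-values in (0, 1], or `NULL` to
#'   derive them from `p_value` by Benjamini-Hochberg.
#' @param contrast_id single character label naming the contrast.
#' @return A `de_table` object (a data frame).
#' @export
de_table <- function(genes, log2fc, p_value, adj_p = NULL, contrast_id) {
  stopifnot(is.character(contrast_id), length(contrast_id) == 1L)
  genes <- as.character(genes)
  adj_derived <- is.null(adj_p)
  if (adj_derived) adj_p <- stats::p.adjust(p_value, method = "BH")
  df <- data.frame(gene = genes, log2fc = as.numeric(log2fc),
                   p_value = as.numeric(p_value), adj_p = as.numeric(adj_p),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "contrast_id") <- contrast_id
  attr(df, "adj_p_derived") <- adj_derived
  class(df) <- c("de_table", "data.frame")
  validate_de_table(df)
}

#' @rdname de_table
#' @param x object to validate.
#' @export
validate_de_table <- function(x) {
  stopifnot(inherits(x, "data.frame"))
  for (col in .DE_COLUMNS) {
    if (!col %in% names(x)) {
      stop("differential-expression table is missing required column '",
           col, "'", call. = FALSE)
    }
  }
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup)) {
    stop("duplicate gene_id in differential-expression table: '",
         dup[1L], "'", call. = FALSE)
  }
  if (anyNA(x$log2fc) || any(!is.finite(x$log2fc))) {
    stop("log2fc must be finite for every gene", call. = FALSE)
  }
  for (col in c("p_value", "adj_p")) {
    v <- x[[col]]
    if (anyNA(v) || any(v <= 0 | v > 1)) {
      stop(col, " must lie in (0, 1]", call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a differential-expression table from TSV/CSV
#'
#' The file must have a header. Default column names are `gene`, `log2fc`,
#' `p_value`, `adj_p`; other schemas are mapped via `column_map`. When the
#' adjusted-p column is absent, Benjamini-Hochberg adjusted values are
#' computed from `p_value` and the table is flagged (`attr(x,
#' "adj_p_derived")`).
#'
#' @param path path to a tab- or comma-separated file with a header row.
#' @param contrast_id contrast label stored on the returned table.
#' @param column_map optional named character vector mapping canonical names
#'   (`gene`, `log2fc`, `p_value`, `adj_p`) to the file's column names,
#'   e.g. `c(gene = "SYMBOL", log2fc = "logFC")`.
#' @return A validated [de_table()].
#' @export
read_de_table <- function(path, contrast_id, column_map = NULL) {
  raw <- .read_delim_auto(path)
  cmap <- .DE_COLUMNS
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad)) stop("unknown column_map keys: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cmap[names(column_map)] <- column_map
  }
  for (canon in c("gene", "log2fc", "p_value")) {
    if (!cmap[[canon]] %in% names(raw)) {
      stop("file '", basename(path), "' is missing required column '",
           cmap[[canon]], "' (", canon, ")", call. = FALSE)
    }
  }
  lfc <- suppressWarnings(as.numeric(raw[[cmap[["log2fc"]]]]))
  bad_row <- which(is.na(lfc) & !is.na(raw[[cmap[["log2fc"]]]]))
  if (length(bad_row)) {
    stop("non-numeric log2FC at data row ", bad_row[1L], " of '",
         basename(path), "'", call. = FALSE)
  }
  has_adj <- cmap[["adj_p"]] %in% names(raw)
  de_table(genes = raw[[cmap[["gene"]]]],
           log2fc = lfc,
           p_value = as.numeric(raw[[cmap[["p_value"]]]]),
           adj_p = if (has_adj) as.numeric(raw[[cmap[["adj_p"]]]]) else NULL,
           contrast_id = contrast_id)
}

#' Write a differential-expression table to TSV
#'
#' @param x a [de_table()].
#' @param path output path.
#' @export
write_de_table <- function(x, path) {
  validate_de_table(x)
  utils::write.table(as.data.frame(x)[, .DE_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Standard GMT: `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate genes within a set are collapsed; empty sets are dropped with a
#' warning. Members are stored sorted; terms are ordered by `term_id`.
#'
#' @param path path to a GMT file.
#' @return A `gene_sets` object: a named list of character vectors with a
#'   `term_names` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    sort(unique(m[nzchar(m)]))
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped: ",
            paste(ids[empty], collapse = ", "))
    ids <- ids[!empty]; descs <- descs[!empty]; members <- members[!empty]
  }
  gene_sets(members = stats::setNames(members, ids),
            term_names = stats::setNames(descs, ids))
}

#' @rdname read_gmt
#' @param members named list of gene-id character vectors (names = term ids).
#' @param term_names optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @export
gene_sets <- function(members, term_names = NULL) {
  stopifnot(is.list(members), !is.null(names(members)))
  if (anyDuplicated(names(members))) {
    stop("duplicate term_id in gene-set collection", call. = FALSE)
  }
  if (any(lengths(members) == 0L)) stop("gene sets must be non-empty",
                                        call. = FALSE)
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  members <- members[order(names(members))]
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(members), names(members))
  }
  attr(members, "term_names") <- term_names[names(members)]
  class(members) <- "gene_sets"
  members
}

#' @rdname read_gmt
#' @param x a `gene_sets` object.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  nm <- attr(x, "term_names")
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], nm[[names(x)[i]]], x[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- expression cohorts -----------------------------------------------------

#' Construct an expression cohort
#'
#' A samples-by-genes TPM-normalized expression matrix paired with per-sample
#' metadata: four genotype flags (`LKB1_mut`, `SMARCA4_mut`, `TP53_mut`,
#' `KRAS_mut`, logical) and a tumor `stage` (`early`, `late` or `unknown`).
#'
#' @param matrix numeric samples-by-genes matrix, non-negative, with sample
#'   row names and gene column names.
#' @param metadata data frame with a `sample_id` column covering every row of
#'   `matrix`, the four genotype flags and `stage`.
#' @return An `expression_cohort` object.
#' @export
expression_cohort <- function(matrix, metadata) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.data.frame(metadata))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs sample row names and gene column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate sample ids",
                                            call. = FALSE)
  if (anyDuplicated(colnames(matrix))) stop("duplicate gene ids",
                                            call. = FALSE)
  if (anyNA(matrix) || any(matrix < 0)) {
    stop("expression values must be non-negative and non-missing",
         call. = FALSE)
  }
  need <- c("sample_id", .GENOTYPE_FLAGS, "stage")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  orphan <- setdiff(rownames(matrix), metadata$sample_id)
  if (length(orphan)) {
    stop("sample(s) missing from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  bad_stage <- setdiff(unique(metadata$stage), .STAGE_TOKENS)
  if (length(bad_stage)) {
    stop("unknown stage token(s): ", paste(bad_stage, collapse = ", "),
         " (expected early/late/unknown)", call. = FALSE)
  }
  ord_s <- order(rownames(matrix))
  ord_g <- order(colnames(matrix))
  matrix <- matrix[ord_s, ord_g, drop = FALSE]
  metadata <- metadata[match(rownames(matrix), metadata$sample_id), ,
                       drop = FALSE]
  for (fl in .GENOTYPE_FLAGS) metadata[[fl]] <- as.logical(metadata[[fl]])
  rownames(metadata) <- NULL
  structure(list(matrix = matrix, metadata = metadata),
            class = "expression_cohort")
}

#' Read an expression cohort from a TSV matrix or MatrixMarket triplet
#'
#' The matrix may have samples in rows or genes in rows; orientation is
#' auto-detected by overlap of row/column names with the metadata sample ids.
#' MatrixMarket input (`*.mtx`, 1-based indices) uses sidecar name files
#' `<path>.rownames` and `<path>.colnames`, one name per line. All-zero genes
#' are retained: filtering is a downstream decision.
#'
#' @param matrix_path path to the expression matrix (TSV with row names in
#'   the first column, or a `.mtx` file).
#' @param metadata_path path to a TSV with `sample_id`, genotype flags and
#'   `stage` columns.
#' @return An [expression_cohort()].
#' @export
read_expression_cohort <- function(matrix_path, metadata_path) {
  metadata <- .read_delim_auto(metadata_path)
  if (grepl("\\.mtx$", matrix_path)) {
    m <- as.matrix(Matrix::readMM(matrix_path))
    rn <- readLines(paste0(matrix_path, ".rownames"))
    cn <- readLines(paste0(matrix_path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match the sidecar name files", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
  } else {
    tab <- .read_delim_auto(matrix_path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- as.character(tab[[1L]])
  }
  ov_rows <- mean(rownames(m) %in% metadata$sample_id)
  ov_cols <- mean(colnames(m) %in% metadata$sample_id)
  if (ov_cols > ov_rows) m <- t(m)  # genes were in rows
  expression_cohort(m, metadata)
}

#' Write an expression cohort
#'
#' @param cohort an [expression_cohort()].
#' @param matrix_path output matrix path; a `.mtx` suffix selects
#'   MatrixMarket output with sidecar name files, anything else TSV
#'   (samples in rows).
#' @param metadata_path output metadata TSV path.
#' @export
write_expression_cohort <- function(cohort, matrix_path, metadata_path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (grepl("\\.mtx$", matrix_path)) {
    Matrix::writeMM(Matrix::Matrix(cohort$matrix, sparse = TRUE), matrix_path)
    writeLines(rownames(cohort$matrix), paste0(matrix_path, ".rownames"))
    writeLines(colnames(cohort$matrix), paste0(matrix_path, ".colnames"))
  } else {
    out <- data.frame(sample_id = rownames(cohort$matrix),
                      cohort$matrix, check.names = FALSE)
    utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(cohort$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

# ---- interaction edge lists -------------------------------------------------

#' Read a protein-interaction edge list
#'
#' Expects a STRING-export-style table with columns `node_a`, `node_b` and an
#' integer `score` in \[0, 1000\]. Edges are undirected; self-loops are
#' dropped on load and duplicate (unordered) pairs collapsed to their
#' maximum score.
#'
#' @param path path to a TSV/CSV edge list.
#' @return A data frame of class `edge_list` with columns `node_a`,
#'   `node_b`, `score` (node_a < node_b lexicographically).
#' @export
read_edge_list <- function(path) {
  raw <- .read_delim_auto(path)
  need <- c("node_a", "node_b", "score")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("edge list is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  edge_list(raw$node_a, raw$node_b, raw$score)
}

#' @rdname read_edge_list
#' @param node_a,node_b character vectors of gene identifiers.
#' @param score integer confidence scores in \[0, 1000\].
#' @export
edge_list <- function(node_a, node_b, score) {
  node_a <- as.character(node_a); node_b <- as.character(node_b)
  score <- as.numeric(score)
  if (any(is.na(score)) || any(score < 0 | score > 1000)) {
    stop("edge confidence scores must lie in [0, 1000]", call. = FALSE)
  }
  keep <- node_a != node_b
  a <- pmin(node_a[keep], node_b[keep])
  b <- pmax(node_a[keep], node_b[keep])
  df <- data.frame(node_a = a, node_b = b, score = score[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$node_a, df$node_b, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("edge_list", "data.frame")
  df
}
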