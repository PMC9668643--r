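#' Construct a two-group expression matrix
#'
#' Bundles a log2-scale gene-by-sample value matrix with a group assignment
#' for each sample. This is the raw input of the pipeline, mirroring a
#' normalized microarray series with "normal" and "disease" arms.
#'
#' @param values Numeric matrix, rows = genes (rownames are gene IDs),
#'   columns = samples (colnames are sample IDs). Values are expected on the
#'   log2 scale; use [auto_log_check()] if unsure.
#' @param groups Character vector naming the group of each sample, either
#'   named by sample ID or in column order. Accepted labels
#'   (case-insensitive): `"normal"`, `"disease"`, and `"psoriasis"` as a
#'   synonym of disease.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (named character vector, levels
#'   `normal`/`disease`).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("input error: 'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("input error: 'values' needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_input("input error: duplicate gene IDs: %s",
               paste(unique(rownames(values)[duplicated(rownames(values))]),
                     collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_input("input error: duplicate sample IDs")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_input("parse error: non-finite value at row %d, column %d",
               bad[[1L]], bad[[2L]])
  }
  groups <- normalize_groups(groups, colnames(values))
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

normalize_groups <- function(groups, sample_ids) {
  groups <- vapply(groups, as.character, character(1))
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing)) {
      stop_input("input error: samples missing a group assignment: %s",
                 paste(missing, collapse = ", "))
    }
    groups <- groups[sample_ids]
  } else if (length(groups) == length(sample_ids)) {
    names(groups) <- sample_ids
  } else {
    stop_input("input error: %d group labels for %d samples",
               length(groups), length(sample_ids))
  }
  lab <- tolower(trimws(groups))
  mapped <- ifelse(lab == "normal", "normal",
                   ifelse(lab %in% c("disease", "psoriasis"), "disease", NA))
  if (anyNA(mapped)) {
    stop_input("input error: unrecognized group label(s): %s",
               paste(unique(groups[is.na(mapped)]), collapse = ", "))
  }
  names(mapped) <- sample_ids
  if (!all(c("normal", "disease") %in% mapped)) {
    stop_input("input error: both 'normal' and 'disease' groups must be non-empty")
  }
  mapped
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d normal, %d disease)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "normal"), sum(x$groups == "disease")))
  invisible(x)
}

#' Detect and undo missing log transformation
#'
#' Heuristic mirroring the auto-detect step of standard two-group microarray
#' front ends: if the 99th percentile of the values exceeds 50 the matrix is
#' judged to be on the raw intensity scale and is replaced by `log2(x + 1)`
#' (with a warning); otherwise it is returned unchanged.
#'
#' @param matrix An [expression_matrix()].
#' @return The (possibly transformed) `expr_matrix`.
#' @export
auto_log_check <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  q99 <- stats::quantile(matrix$values, 0.99, names = FALSE)
  if (q99 > 50) {
    if (any(matrix$values < 0)) {
      stop_input("input error: matrix looks unlogged (99th percentile %.1f > 50) but contains negative values",
                 q99)
    }
    warning("values appear unlogged (99th percentile ", format(q99),
            " > 50); applying log2(x + 1)", call. = FALSE)
    matrix$values <- log2(matrix$values + 1)
  }
  matrix
}

#' Write / read an expression matrix and its sample metadata
#'
#' The matrix is written as TSV with the gene ID in the first column
#' (`gene_id`) and one column per sample; metadata as a two-column TSV
#' (`sample_id`, `group`). `read_expression()` validates the pair and maps
#' group labels case-insensitively, accepting `"Psoriasis"` for disease.
#'
#' @param matrix An [expression_matrix()].
#' @param matrix_path,metadata_path File paths.
#' @return `read_expression()` returns an `expr_matrix`;
#'   `write_expression()` returns the paths invisibly.
#' @export
write_expression <- function(matrix, matrix_path, metadata_path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(matrix$groups),
                     group = unname(matrix$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, metadata_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop_input("parse error: expression TSV needs gene_id plus sample columns")
  gene_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop_input("parse error: non-numeric cell at row %d, column '%s'",
                 bad, colnames(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            comment.char = "#")
  if (!all(c("sample_id", "group") %in% colnames(meta))) {
    stop_input("parse error: metadata must have columns sample_id, group")
  }
  missing <- setdiff(meta$sample_id, colnames(m))
  if (length(missing)) {
    stop_input("input error: sample(s) in metadata absent from matrix: %s",
               paste(missing, collapse = ", "))
  }
  unassigned <- setdiff(colnames(m), meta$sample_id)
  if (length(unassigned)) {
    stop_input("input error: sample(s) missing from metadata: %s",
               paste(unassigned, collapse = ", "))
  }
  groups <- stats::setNames(meta$group, meta$sample_id)
  expression_matrix(m[, meta$sample_id, drop = FALSE], groups)
}
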