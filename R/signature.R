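#' Signature extraction parameters
#'
#' Thresholds used to call differentially expressed genes and cap the query
#' signature: adjusted p-value below `adj_p_max`, absolute log2 fold change
#' of at least `lfc_min` (i.e. outside the `(-lfc_min, lfc_min)` window),
#' and at most `top_n` genes per direction.
#'
#' @param adj_p_max Adjusted p-value threshold, in (0, 1). Default 0.05.
#' @param lfc_min Minimum absolute log2 fold change. Default 1.
#' @param top_n Per-direction signature size. Default 100.
#' @return A list of class `signature_params`.
#' @export
signature_params <- function(adj_p_max = 0.05, lfc_min = 1, top_n = 100L) {
  structure(list(
    adj_p_max = check_number(adj_p_max, "adj_p_max", min = 0, max = 1,
                             strict_min = TRUE),
    lfc_min = check_number(lfc_min, "lfc_min", min = 0),
    top_n = check_count(top_n, "top_n", min = 1L)
  ), class = "signature_params")
}

#' Construct a disease signature
#'
#' An ordered pair of tag lists: `up_tags` sorted by descending log2 fold
#' change, `down_tags` ascending (most extreme first in both). This is the
#' query object scored against each perturbagen profile.
#'
#' @param up_tags,down_tags Character vectors of gene IDs; disjoint, no
#'   duplicates.
#' @return A list of class `disease_signature`.
#' @export
disease_signature <- function(up_tags, down_tags) {
  up_tags <- as.character(up_tags)
  down_tags <- as.character(down_tags)
  if (anyDuplicated(up_tags) || anyDuplicated(down_tags)) {
    stop_input("input error: duplicate genes within a tag list")
  }
  if (length(intersect(up_tags, down_tags))) {
    stop_input("input error: up and down tag lists overlap: %s",
               paste(utils::head(intersect(up_tags, down_tags), 5L),
                     collapse = ", "))
  }
  structure(list(up_tags = up_tags, down_tags = down_tags),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("disease_signature: %d up tags, %d down tags\n",
              length(x$up_tags), length(x$down_tags)))
  invisible(x)
}

#' Extract the query signature from a differential expression table
#'
#' Candidate up genes satisfy `adj_pvalue < adj_p_max` and
#' `log2fc >= lfc_min`; they are sorted by log2 fold change descending and
#' truncated to the top `top_n`. Down genes are the mirror image
#' (`log2fc <= -lfc_min`, sorted ascending). Ties in log2 fold change are
#' broken by smaller adjusted p-value, then lexicographic gene ID, so the
#' cut is deterministic. Fewer than `top_n` passing genes in a direction
#' yields all of them with a warning; zero passing genes in a direction is
#' an error.
#'
#' @param table Data.frame from [differential_expression()].
#' @param params A [signature_params()].
#' @return A [disease_signature()].
#' @export
extract_signature <- function(table, params = signature_params()) {
  stopifnot(is.data.frame(table), inherits(params, "signature_params"))
  if (!nrow(table)) stop_input("input error: empty DGE table")
  needed <- c("gene_id", "log2fc", "adj_pvalue")
  if (!all(needed %in% colnames(table))) {
    stop_input("input error: DGE table needs columns %s",
               paste(needed, collapse = ", "))
  }
  pass <- table$adj_pvalue < params$adj_p_max
  take <- function(direction) {
    cand <- if (direction == "up") {
      table[pass & table$log2fc >= params$lfc_min, , drop = FALSE]
    } else {
      table[pass & table$log2fc <= -params$lfc_min, , drop = FALSE]
    }
    if (!nrow(cand)) {
      stop_input("signature error: no gene passes in the '%s' direction",
                 direction)
    }
    ord <- order(if (direction == "up") -cand$log2fc else cand$log2fc,
                 cand$adj_pvalue, cand$gene_id)
    cand <- cand[ord, , drop = FALSE]
    if (nrow(cand) < params$top_n) {
      warning(sprintf("only %d of %d requested '%s' tags pass the thresholds",
                      nrow(cand), params$top_n, direction), call. = FALSE)
    }
    utils::head(cand$gene_id, params$top_n)
  }
  disease_signature(up_tags = take("up"), down_tags = take("down"))
}

#' Write / read a disease signature
#'
#' Two-column TSV (`gene_id`, `direction`), order-preserving; direction
#' tokens are read case-insensitively (`up`/`UP`, `down`/`DN`).
#' `write_signature_gmt()` additionally exports the paired two-line
#' GMT-style format (`<name>_UP`, `<name>_DN`) used when querying
#' connectivity portals.
#'
#' @param signature A [disease_signature()].
#' @param path File path.
#' @param header Optional `#` header comment.
#' @param name Signature name for the GMT export.
#' @return `read_signature()` returns a `disease_signature`; the writers
#'   return the path invisibly.
#' @export
write_signature <- function(signature, path, header = NULL) {
  stopifnot(inherits(signature, "disease_signature"))
  df <- data.frame(
    gene_id = c(signature$up_tags, signature$down_tags),
    direction = rep(c("up", "down"),
                    c(length(signature$up_tags), length(signature$down_tags))),
    stringsAsFactors = FALSE)
  write_table_with_header(df, path, header = header, sep = "\t")
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  df <- utils::read.delim(text = lines[keep], stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% colnames(df))) {
    stop_input("parse error: signature TSV needs columns gene_id, direction")
  }
  dir <- tolower(trimws(df$direction))
  dir[dir == "dn"] <- "down"
  bad <- which(!dir %in% c("up", "down"))
  if (length(bad)) {
    # +1 header line, + leading comment lines, to report the file line number
    line_no <- bad[1L] + 1L + sum(!keep)
    stop_input("parse error: invalid direction token '%s' at line %d",
               df$direction[bad[1L]], line_no)
  }
  disease_signature(up_tags = df$gene_id[dir == "up"],
                    down_tags = df$gene_id[dir == "down"])
}

#' @rdname write_signature
#' @export
write_signature_gmt <- function(signature, path, name = "QUERY") {
  stopifnot(inherits(signature, "disease_signature"))
  lines <- c(
    paste(c(paste0(name, "_UP"), "up-regulated tags", signature$up_tags),
          collapse = "\t"),
    paste(c(paste0(name, "_DN"), "down-regulated tags", signature$down_tags),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
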