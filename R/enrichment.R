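#' Read / write gene sets in GMT format
#'
#' One set per line, tab-separated: name, description, then member genes.
#'
#' @param path File path.
#' @param sets Named list of character vectors (or a `gene_set_collection`).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt()` returns a named list of class
#'   `gene_set_collection`; `write_gmt()` returns the path invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop_input("parse error: GMT line %d has fewer than 3 fields", bad[1L])
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop_input("parse error: duplicate gene-set names in GMT")
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop_input("input error: gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a ranked gene list from a differential expression table
#'
#' Orders genes by a signed per-gene metric, descending; ties are broken
#' lexicographically by gene ID so the ranking is total. The default metric
#' is the moderated/Welch t-statistic, which folds both the fold change and
#' its evidence into one signed quantity; `metric = "log2fc"` ranks by raw
#' fold change instead.
#'
#' @param table Data.frame from [differential_expression()].
#' @param metric `"tstat"` or `"log2fc"`.
#' @return A data.frame of class `ranked_list` with columns `gene_id`,
#'   `metric`, ordered by metric descending.
#' @export
ranked_list <- function(table, metric = c("tstat", "log2fc")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(table), metric %in% colnames(table))
  if (anyDuplicated(table$gene_id)) {
    stop_input("input error: duplicate gene IDs in ranked list")
  }
  m <- table[[metric]]
  if (!all(is.finite(m))) stop_input("input error: non-finite ranking metric")
  ord <- order(-m, table$gene_id)
  structure(data.frame(gene_id = table$gene_id[ord], metric = m[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Weighted (exponent 1) running-sum ES via cumsum over the ranked list.
# `hit` is a logical vector aligned with the ranking.
running_sum_es <- function(metric, hit) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric[hit])
  tot <- sum(w)
  inc <- numeric(n)
  # degenerate all-zero hit metrics: fall back to equal weights
  inc[hit] <- if (tot > 0) w / tot else 1 / nh
  if (nh < n) inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  mx <- max(rs)
  mn <- min(rs)
  if (mx >= -mn) mx else mn
}

#' Pre-ranked enrichment score for one gene set
#'
#' Weighted Kolmogorov-Smirnov-style running sum with weight exponent 1:
#' walking down the ranked list, genes in the set increment the sum by
#' `|metric| / sum(|metric| over hits)` and genes outside decrement it by
#' `1 / (N - N_hits)`; the enrichment score is the signed maximum deviation
#' from zero. Genes of the set absent from the ranking are ignored; an
#' empty overlap returns `NA` with a warning (the set is skipped).
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of gene IDs.
#' @return Enrichment score in `[-1, 1]`, or `NA` for an empty overlap.
#' @export
preranked_es <- function(ranked, gene_set) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) {
    warning("gene set has no overlap with the ranked list; skipped",
            call. = FALSE)
    return(NA_real_)
  }
  running_sum_es(ranked$metric, hit)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' For each set: the enrichment score from [preranked_es()]; a null of
#' `n_perm` random same-size gene sets drawn from the ranked universe; the
#' normalized score `nes = es / mean(|null scores of matching sign|)`; and
#' the plus-one permutation p-value over same-sign null scores with
#' `|es_null| >= |es|`. Sets with no overlap are skipped with a warning.
#' Records are sorted by NES descending.
#'
#' @param ranked A [ranked_list()].
#' @param collection Named list of gene sets (e.g. from [read_gmt()] or
#'   [generate_gene_sets()]).
#' @param n_perm Number of null sets per gene set (>= 100).
#' @param seed Integer seed.
#' @return Data.frame with columns `set_name, es, nes, pvalue, n_hits`.
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!length(collection)) stop_input("input error: empty gene-set collection")
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  genes <- ranked$gene_id
  metric <- ranked$metric
  n <- length(genes)
  with_seed(seed, {
    rows <- lapply(names(collection), function(nm) {
      hit <- genes %in% collection[[nm]]
      n_hits <- sum(hit)
      if (n_hits == 0L) {
        warning("gene set '", nm, "' has no overlap with the ranked list; skipped",
                call. = FALSE)
        return(NULL)
      }
      es <- running_sum_es(metric, hit)
      null <- vapply(seq_len(n_perm), function(i) {
        h <- logical(n)
        h[sample.int(n, n_hits)] <- TRUE
        running_sum_es(metric, h)
      }, numeric(1))
      same <- null[sign(null) == sign(es)]
      if (es == 0 || !length(same)) {
        nes <- 0
        p <- 1
      } else {
        nes <- es / mean(abs(same))
        p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
      }
      data.frame(set_name = nm, es = es, nes = nes, pvalue = p,
                 n_hits = n_hits, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || !nrow(out)) {
      stop_input("input error: no gene set overlaps the ranked list")
    }
    out <- out[order(-out$nes, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a gene-set enrichment results table
#'
#' CSV with columns `set_name, es, nes, pvalue, n_hits`.
#'
#' @param records Data.frame from [preranked_gsea()].
#' @param path Output path.
#' @param header Optional `#` header comment.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(records, path, header = NULL) {
  write_table_with_header(records, path, header = header)
}
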