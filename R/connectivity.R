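#' Construct a perturbagen compendium
#'
#' A compendium holds one full gene ranking per perturbagen (rank 1 = gene
#' most up-regulated by the drug) over a shared gene universe, plus optional
#' cached reference connectivity scores used by the signed-percentile tau
#' normalization.
#'
#' @param universe Character vector of gene IDs.
#' @param profiles Named list; each element a permutation of `universe`.
#' @param reference_scores Optional numeric matrix, one row per perturbagen
#'   (rownames = perturbagen IDs), one column per stored reference query.
#' @return An object of class `perturbagen_compendium`.
#' @export
perturbagen_compendium <- function(universe, profiles, reference_scores = NULL) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop_input("input error: duplicate universe genes")
  if (!length(profiles) || is.null(names(profiles))) {
    stop_input("input error: 'profiles' must be a non-empty named list")
  }
  n <- length(universe)
  for (id in names(profiles)) {
    p <- profiles[[id]]
    if (length(p) != n || anyDuplicated(p) || !all(p %in% universe)) {
      stop_input("input error: profile '%s' is not a permutation of the universe", id)
    }
  }
  if (!is.null(reference_scores)) {
    reference_scores <- as.matrix(reference_scores)
    if (nrow(reference_scores) != length(profiles)) {
      stop_input("input error: reference_scores rows must match profiles")
    }
    rownames(reference_scores) <- names(profiles)
  }
  structure(list(universe = universe, profiles = profiles,
                 reference_scores = reference_scores),
            class = "perturbagen_compendium")
}

#' @export
print.perturbagen_compendium <- function(x, ...) {
  cat(sprintf("perturbagen_compendium: %d perturbagens over %d genes; %s\n",
              length(x$profiles), length(x$universe),
              if (is.null(x$reference_scores)) "no reference scores" else
                sprintf("%d reference scores each", ncol(x$reference_scores))))
  invisible(x)
}

# Core tag-set KS statistic from sorted-ready hit positions r (1-based ranks
# in a profile of n genes): a = max_i(i/t - r_i/n), b = max_i(r_i/n -
# (i-1)/t); ES = a if a >= b else -b (ties resolve to the positive branch).
ks_stat_positions <- function(r, n) {
  t <- length(r)
  r <- sort.int(r)
  i <- seq_len(t)
  a <- max(i / t - r / n)
  b <- max(r / n - (i - 1) / t)
  if (a >= b) a else -b
}

# Positions of each universe gene (by index) within one profile.
profile_positions <- function(profile, universe) {
  pos <- integer(length(universe))
  pos[match(profile, universe)] <- seq_along(profile)
  pos
}

resolve_profile <- function(profile) {
  if (inherits(profile, "perturbagen_profile")) return(profile$ranking)
  if (is.list(profile) && !is.null(profile$ranking)) return(profile$ranking)
  as.character(profile)
}

match_tags <- function(tags, profile, what = "tag") {
  pos <- match(tags, profile)
  if (anyNA(pos)) {
    unmatched <- tags[is.na(pos)]
    if (all(is.na(pos))) {
      stop_input("query error: no %s gene found in the profile universe (missing: %s)",
                 what, paste(utils::head(unmatched, 5L), collapse = ", "))
    }
    warning(length(unmatched), " query gene(s) missing from the universe dropped",
            call. = FALSE)
    pos <- pos[!is.na(pos)]
  }
  if (length(pos) < 10L) {
    warning("fewer than 10 ", what, " genes match the universe; ",
            "enrichment will be unstable", call. = FALSE)
  }
  pos
}

#' Kolmogorov-Smirnov enrichment of a tag set in a ranked profile
#'
#' The classic connectivity-map construction: with the `t` matched tag
#' positions `r(1) < ... < r(t)` in a profile of `n` genes,
#' `a = max_i (i/t - r(i)/n)` and `b = max_i (r(i)/n - (i-1)/t)`; the
#' enrichment score is `a` if `a >= b`, else `-b`. Tags concentrated at the
#' top of the profile give ES near +1, at the bottom near -1.
#'
#' @param tags Character vector of gene IDs (warning if fewer than 10 match
#'   the universe; error if none do).
#' @param profile A ranked character vector of gene IDs (or a list with a
#'   `ranking` element).
#' @return Enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(tags, profile) {
  ranking <- resolve_profile(profile)
  pos <- match_tags(as.character(tags), ranking)
  ks_stat_positions(pos, length(ranking))
}

combine_es <- function(es_up, es_down) {
  if ((es_up > 0 && es_down > 0) || (es_up < 0 && es_down < 0)) {
    return(0)
  }
  (es_up - es_down) / 2
}

#' Raw bidirectional connectivity between a signature and a profile
#'
#' Combines the up- and down-tag KS enrichment scores: when both share a
#' strict sign (the query's two halves disagree about the drug) the score is
#' defined as 0; otherwise it is `(es_up - es_down) / 2`, lying in
#' `[-1, 1]`. A drug that mimics the disease scores near +1; a drug that
#' reverses it scores near -1.
#'
#' @param signature A [disease_signature()].
#' @param profile Ranked gene-ID vector (see [ks_enrichment()]).
#' @return A list with `es_up`, `es_down`, `raw_score`.
#' @export
raw_connectivity <- function(signature, profile) {
  stopifnot(inherits(signature, "disease_signature"))
  ranking <- resolve_profile(profile)
  n <- length(ranking)
  es_up <- ks_stat_positions(match_tags(signature$up_tags, ranking, "up tag"), n)
  es_down <- ks_stat_positions(match_tags(signature$down_tags, ranking, "down tag"), n)
  list(es_up = es_up, es_down = es_down,
       raw_score = combine_es(es_up, es_down))
}

#' Signed-percentile tau normalization
#'
#' Places a raw connectivity score on the `[-100, 100]` scale by comparing
#' its magnitude with a stored set of reference-query scores for the same
#' perturbagen: `tau = sign(raw) * 100 * #\{|ref| < |raw|\} / n_ref`
#' (strict inequality), and `tau = 0` when `raw = 0`. The bounds are
#' attained: a score whose magnitude dominates every reference gets
#' `tau = +/-100`.
#'
#' @param raw_score Raw connectivity score in `[-1, 1]`.
#' @param reference_scores Numeric vector of at least 20 stored raw scores
#'   for this perturbagen.
#' @return Tau in `[-100, 100]`.
#' @export
tau_normalize <- function(raw_score, reference_scores) {
  if (length(reference_scores) < 20L) {
    stop_input("configuration error: tau needs >= 20 reference scores (got %d)",
               length(reference_scores))
  }
  if (raw_score == 0) return(0)
  sign(raw_score) * 100 * mean(abs(reference_scores) < abs(raw_score))
}

# Draw n random query signatures as disjoint index sets into a universe of
# size n_genes; returns a list of (up, down) integer vectors.
random_query_indices <- function(n, up_size, down_size, n_genes) {
  if (up_size + down_size > n_genes) {
    stop_input("input error: tag sizes exceed the universe")
  }
  lapply(seq_len(n), function(i) {
    idx <- sample.int(n_genes, up_size + down_size)
    list(up = idx[seq_len(up_size)], down = idx[up_size + seq_len(down_size)])
  })
}

raw_from_positions <- function(pos, up_idx, down_idx, n) {
  combine_es(ks_stat_positions(pos[up_idx], n),
             ks_stat_positions(pos[down_idx], n))
}

#' Permutation p-value for a connectivity score
#'
#' Draws `n_perm` random query signatures with the same tag-list sizes as
#' the query (tag sets sampled uniformly without replacement from the
#' universe, up and down disjoint), scores each against the profile, and
#' returns the plus-one estimator
#' `p = (1 + #\{|raw_perm| >= |raw|\}) / (n_perm + 1)`.
#'
#' @param signature A [disease_signature()].
#' @param profile Ranked gene-ID vector.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for reproducibility.
#' @return p-value in `(0, 1]`, never below `1/(n_perm + 1)`.
#' @export
permutation_pvalue <- function(signature, profile, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(signature, "disease_signature"))
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  ranking <- resolve_profile(profile)
  n <- length(ranking)
  obs <- raw_connectivity(signature, profile)$raw_score
  universe <- sort(ranking)
  pos <- profile_positions(ranking, universe)
  up_size <- sum(signature$up_tags %in% ranking)
  down_size <- sum(signature$down_tags %in% ranking)
  with_seed(seed, {
    queries <- random_query_indices(n_perm, up_size, down_size, n)
    perm <- vapply(queries, function(q) raw_from_positions(pos, q$up, q$down, n),
                   numeric(1))
    (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  })
}

#' Attach reference connectivity scores to a compendium
#'
#' Generates `n_ref` random reference queries (disjoint up/down tag sets of
#' the given sizes) and stores each perturbagen's raw connectivity against
#' them. These cached scores are the per-perturbagen yardstick for
#' [tau_normalize()].
#'
#' @param compendium A [perturbagen_compendium()].
#' @param n_ref Number of reference queries (>= 20; default 100).
#' @param up_size,down_size Reference tag-list sizes (default 100 each,
#'   matching the usual query size).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return The compendium with `reference_scores` filled in.
#' @export
build_reference_scores <- function(compendium, n_ref = 100L, up_size = 100L,
                                   down_size = 100L, seed = 1L) {
  stopifnot(inherits(compendium, "perturbagen_compendium"))
  n_ref <- check_count(n_ref, "n_ref", min = 20L)
  n <- length(compendium$universe)
  with_seed(seed, {
    queries <- random_query_indices(n_ref, up_size, down_size, n)
    scores <- t(vapply(compendium$profiles, function(profile) {
      pos <- profile_positions(profile, compendium$universe)
      vapply(queries, function(q) raw_from_positions(pos, q$up, q$down, n),
             numeric(1))
    }, numeric(n_ref)))
    compendium$reference_scores <- scores
    compendium
  })
}

#' Score a whole compendium against a disease signature
#'
#' Computes, for every perturbagen: the up/down KS enrichment scores, the
#' raw bidirectional connectivity, tau (signed percentile against that
#' perturbagen's cached reference scores), a permutation p-value (one shared
#' set of `n_perm` random queries, scored per profile), and the BH-adjusted
#' FDR over all perturbagens. Records are sorted by tau ascending — most
#' negative tau (strongest reversal candidate) first — with ties broken by
#' raw score ascending, then perturbagen ID, so output order is total and
#' reproducible.
#'
#' @param signature A [disease_signature()].
#' @param compendium A [perturbagen_compendium()] with reference scores.
#' @param n_perm Permutations per perturbagen (>= 100).
#' @param seed Integer seed.
#' @return Data.frame with columns `perturbagen_id, es_up, es_down,
#'   raw_score, tau, pvalue, fdr, rank`.
#' @export
score_compendium <- function(signature, compendium, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(signature, "disease_signature"),
            inherits(compendium, "perturbagen_compendium"))
  if (!length(compendium$profiles)) stop_input("input error: empty compendium")
  if (is.null(compendium$reference_scores)) {
    stop_input("configuration error: compendium has no reference scores; run build_reference_scores()")
  }
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  universe <- compendium$universe
  n <- length(universe)
  up_idx <- match(signature$up_tags, universe)
  down_idx <- match(signature$down_tags, universe)
  if (anyNA(up_idx) || anyNA(down_idx)) {
    dropped <- sum(is.na(up_idx)) + sum(is.na(down_idx))
    if (all(is.na(up_idx)) || all(is.na(down_idx))) {
      stop_input("query error: a tag list has no gene in the compendium universe")
    }
    warning(dropped, " query gene(s) missing from the universe dropped",
            call. = FALSE)
    up_idx <- up_idx[!is.na(up_idx)]
    down_idx <- down_idx[!is.na(down_idx)]
  }
  if (length(up_idx) < 10L || length(down_idx) < 10L) {
    warning("fewer than 10 matched tags in a direction; scores will be unstable",
            call. = FALSE)
  }
  queries <- with_seed(seed, {
    random_query_indices(n_perm, length(up_idx), length(down_idx), n)
  })
  ids <- names(compendium$profiles)
  res <- lapply(ids, function(id) {
    pos <- profile_positions(compendium$profiles[[id]], universe)
    es_up <- ks_stat_positions(pos[up_idx], n)
    es_down <- ks_stat_positions(pos[down_idx], n)
    raw <- combine_es(es_up, es_down)
    perm <- vapply(queries, function(q) raw_from_positions(pos, q$up, q$down, n),
                   numeric(1))
    c(es_up = es_up, es_down = es_down, raw_score = raw,
      tau = tau_normalize(raw, compendium$reference_scores[id, ]),
      pvalue = (1 + sum(abs(perm) >= abs(raw))) / (n_perm + 1))
  })
  df <- as.data.frame(do.call(rbind, res))
  df <- cbind(perturbagen_id = ids, df, stringsAsFactors = FALSE)
  df$fdr <- bh_adjust(df$pvalue)
  df <- df[order(df$tau, df$raw_score, df$perturbagen_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Keep the top reversal candidates
#'
#' Retains the first `min(k, nrow)` records of a ranked connectivity table
#' (most negative tau first). The default `k = 150` matches the usual size
#' of the candidate list taken forward to validation.
#'
#' @param records Ranked data.frame from [score_compendium()].
#' @param k Number of candidates to keep (>= 1).
#' @return The truncated data.frame.
#' @export
truncate_candidates <- function(records, k = 150L) {
  stopifnot(is.data.frame(records))
  k <- check_count(k, "k", min = 1L)
  utils::head(records, k)
}

#' Write / read a perturbagen compendium
#'
#' The compendium file is a TSV with one row per perturbagen: the
#' perturbagen ID followed by its full gene ranking. Cached reference
#' scores go to a sidecar CSV in long format
#' (`perturbagen_id, ref_index, raw_score`).
#'
#' @param compendium A [perturbagen_compendium()].
#' @param path Compendium TSV path.
#' @param ref_path Optional sidecar CSV path for reference scores.
#' @return `read_compendium()` returns a `perturbagen_compendium`; the
#'   writer returns the path invisibly.
#' @export
write_compendium <- function(compendium, path, ref_path = NULL) {
  stopifnot(inherits(compendium, "perturbagen_compendium"))
  lines <- vapply(names(compendium$profiles), function(id) {
    paste(c(id, compendium$profiles[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(ref_path)) {
    if (is.null(compendium$reference_scores)) {
      stop_input("input error: compendium has no reference scores to write")
    }
    rs <- compendium$reference_scores
    long <- data.frame(
      perturbagen_id = rep(rownames(rs), each = ncol(rs)),
      ref_index = rep(seq_len(ncol(rs)), times = nrow(rs)),
      raw_score = as.vector(t(rs)),
      stringsAsFactors = FALSE)
    utils::write.table(long, ref_path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path, ref_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  profiles <- lapply(parts, function(p) p[-1L])
  names(profiles) <- ids
  universe <- sort(profiles[[1L]])
  rs <- NULL
  if (!is.null(ref_path)) {
    long <- utils::read.csv(ref_path, stringsAsFactors = FALSE,
                            comment.char = "#")
    wide <- split(long$raw_score, long$perturbagen_id)
    rs <- do.call(rbind, wide[ids])
  }
  perturbagen_compendium(universe, profiles, reference_scores = rs)
}

#' Write a connectivity results table
#'
#' CSV mirroring the ranked score report: `perturbagen_id, es_up, es_down,
#' raw_score, tau, pvalue, fdr, rank` (tau on the -100..+100 scale).
#'
#' @param records Data.frame from [score_compendium()].
#' @param path Output path.
#' @param header Optional `#` header comment.
#' @return The path, invisibly.
#' @export
write_connectivity <- function(records, path, header = NULL) {
  write_table_with_header(records, path, header = header)
}
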