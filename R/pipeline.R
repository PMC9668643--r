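#' Pipeline configuration
#'
#' Collects the file paths and parameters of a full signature-reversal run.
#' Input paths must exist when [run_all()] executes; the seed and a short
#' configuration fingerprint are stamped into the header of every output
#' file so a run can be audited and reproduced.
#'
#' @param matrix_path,metadata_path Expression TSV and sample-metadata TSV
#'   (see [write_expression()]).
#' @param compendium_path Perturbagen compendium TSV (see
#'   [write_compendium()]).
#' @param reference_path Sidecar CSV of cached reference scores; `NULL` to
#'   compute fresh reference scores from `n_ref` random queries.
#' @param gene_sets_path GMT file of gene sets, or `NULL` to skip the
#'   enrichment stage.
#' @param annotation_path Drug-annotation CSV
#'   (`drug_id, supported, denied`), or `NULL` to skip validation
#'   counting.
#' @param out_dir Output directory (created if needed).
#' @param params A [signature_params()].
#' @param n_perm Permutations for connectivity p-values and GSEA nulls.
#' @param n_ref Reference queries when `reference_path` is `NULL`.
#' @param top_k Candidate-list size (default 150).
#' @param mode Differential expression mode, `"moderated"` or `"welch"`.
#' @param gsea_metric Ranking metric for the enrichment stage.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path, metadata_path, compendium_path,
                            reference_path = NULL, gene_sets_path = NULL,
                            annotation_path = NULL, out_dir = "revsig_out",
                            params = signature_params(), n_perm = 1000L,
                            n_ref = 100L, top_k = 150L,
                            mode = c("moderated", "welch"),
                            gsea_metric = c("tstat", "log2fc"), seed = 1L) {
  stopifnot(inherits(params, "signature_params"))
  structure(list(
    matrix_path = matrix_path, metadata_path = metadata_path,
    compendium_path = compendium_path, reference_path = reference_path,
    gene_sets_path = gene_sets_path, annotation_path = annotation_path,
    out_dir = out_dir, params = params,
    n_perm = check_count(n_perm, "n_perm", min = 100L),
    n_ref = check_count(n_ref, "n_ref", min = 20L),
    top_k = check_count(top_k, "top_k", min = 1L),
    mode = match.arg(mode), gsea_metric = match.arg(gsea_metric),
    seed = check_count(seed, "seed")
  ), class = "pipeline_config")
}

config_fingerprint <- function(config) {
  fields <- config[setdiff(names(config), "out_dir")]
  config_hash(paste(deparse(fields), collapse = ""))
}

#' Summarize validation annotations for a candidate list
#'
#' Applies the two-step evidence rule to each ranked candidate: a drug with
#' supporting evidence only is `validated`; with both supporting and
#' denying evidence it is `contradicted` (and excluded from the validated
#' count); with neither — or absent from the annotation table — it is
#' `untested`, i.e. a candidate for prospective validation.
#'
#' @param records Ranked candidate data.frame with a `perturbagen_id`
#'   column (e.g. from [truncate_candidates()]).
#' @param annotation A data.frame or CSV path with columns
#'   `drug_id, supported, denied` (flags in `\{0, 1\}`).
#' @return A list of class `validation_summary`: `n_candidates`,
#'   `n_validated`, `n_contradicted`, `n_untested`, and `status`
#'   (data.frame `drug_id`, `status`, in candidate rank order).
#' @export
annotate_validation <- function(records, annotation) {
  stopifnot(is.data.frame(records), "perturbagen_id" %in% colnames(records))
  if (is.character(annotation)) {
    annotation <- utils::read.csv(annotation, stringsAsFactors = FALSE,
                                  comment.char = "#")
  }
  if (!nrow(annotation)) {
    annotation <- data.frame(drug_id = character(), supported = integer(),
                             denied = integer())
  }
  if (!all(c("drug_id", "supported", "denied") %in% colnames(annotation))) {
    stop_input("parse error: annotation needs columns drug_id, supported, denied")
  }
  if (!all(unlist(annotation[c("supported", "denied")]) %in% c(0L, 1L))) {
    stop_input("parse error: supported/denied flags must be 0 or 1")
  }
  idx <- match(records$perturbagen_id, annotation$drug_id)
  supported <- ifelse(is.na(idx), 0L, annotation$supported[idx])
  denied <- ifelse(is.na(idx), 0L, annotation$denied[idx])
  status <- ifelse(supported == 1L & denied == 0L, "validated",
                   ifelse(supported == 1L & denied == 1L, "contradicted",
                          "untested"))
  structure(list(
    n_candidates = nrow(records),
    n_validated = sum(status == "validated"),
    n_contradicted = sum(status == "contradicted"),
    n_untested = sum(status == "untested"),
    status = data.frame(drug_id = records$perturbagen_id, status = status,
                        stringsAsFactors = FALSE)
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validated %d/%d candidates (%d contradicted, %d untested)\n",
              x$n_validated, x$n_candidates, x$n_contradicted, x$n_untested))
  invisible(x)
}

#' Run the full signature-reversal pipeline
#'
#' Executes the stages in order: read and validate the expression inputs,
#' auto-detect missing log transformation, differential expression, query
#' signature extraction, connectivity scoring of the compendium, candidate
#' truncation, pre-ranked gene-set enrichment (if a GMT is configured), and
#' validation counting (if an annotation CSV is configured). All stage
#' tables are written to `out_dir` as CSV/TSV with a `#` header carrying
#' the seed and configuration fingerprint, plus a JSON run manifest with
#' per-stage row counts. Re-running with identical config and inputs
#' reproduces every table byte-for-byte (the manifest timestamp aside).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results: `dge`,
#'   `signature`, `connectivity`, `candidates`, `enrichment`, `validation`,
#'   `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("matrix_path", "metadata_path", "compendium_path",
              "reference_path", "gene_sets_path", "annotation_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop_input("config error: %s '%s' does not exist", p, config[[p]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed=%d config=%s", config$seed, config_fingerprint(config))
  stage <- function(name, expr) {
    message("[revsig] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop_input("pipeline aborted at stage '%s': %s", name, conditionMessage(e))
    })
  }

  mat <- stage("read_expression",
               read_expression(config$matrix_path, config$metadata_path))
  mat <- stage("auto_log_check", auto_log_check(mat))
  dge <- stage("differential_expression",
               differential_expression(mat, mode = config$mode))
  write_dge(dge, file.path(config$out_dir, "dge.csv"), header = hdr)
  sig <- stage("extract_signature", extract_signature(dge, config$params))
  write_signature(sig, file.path(config$out_dir, "signature.tsv"), header = hdr)

  comp <- stage("read_compendium",
                read_compendium(config$compendium_path, config$reference_path))
  if (is.null(comp$reference_scores)) {
    comp <- stage("build_reference_scores",
                  build_reference_scores(comp, n_ref = config$n_ref,
                                         up_size = length(sig$up_tags),
                                         down_size = length(sig$down_tags),
                                         seed = child_seed(config$seed, 11L)))
  }
  conn <- stage("score_compendium",
                score_compendium(sig, comp, n_perm = config$n_perm,
                                 seed = child_seed(config$seed, 12L)))
  write_connectivity(conn, file.path(config$out_dir, "connectivity.csv"),
                     header = hdr)
  cand <- stage("truncate_candidates", truncate_candidates(conn, config$top_k))
  write_connectivity(cand, file.path(config$out_dir, "candidates.csv"),
                     header = hdr)

  enr <- NULL
  if (!is.null(config$gene_sets_path)) {
    sets <- stage("read_gmt", read_gmt(config$gene_sets_path))
    ranked <- ranked_list(dge, metric = config$gsea_metric)
    enr <- stage("preranked_gsea",
                 preranked_gsea(ranked, sets, n_perm = config$n_perm,
                                seed = child_seed(config$seed, 13L)))
    write_enrichment(enr, file.path(config$out_dir, "gsea.csv"), header = hdr)
  }

  val <- NULL
  if (!is.null(config$annotation_path)) {
    val <- stage("annotate_validation",
                 annotate_validation(cand, config$annotation_path))
    write_table_with_header(val$status,
                            file.path(config$out_dir, "validation.csv"),
                            header = hdr)
  }

  manifest <- list(
    seed = config$seed,
    config = config_fingerprint(config),
    package_version = as.character(utils::packageVersion("revsig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = config$mode,
    n_genes = nrow(dge),
    n_up_tags = length(sig$up_tags),
    n_down_tags = length(sig$down_tags),
    n_perturbagens = nrow(conn),
    n_candidates = nrow(cand),
    n_gene_sets = if (is.null(enr)) 0L else nrow(enr),
    n_validated = if (is.null(val)) NA else val$n_validated
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dge = dge, signature = sig, connectivity = conn,
                 candidates = cand, enrichment = enr, validation = val,
                 manifest = manifest))
}
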