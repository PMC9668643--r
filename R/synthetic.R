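#' Simulation configuration for the synthetic study inputs
#'
#' Defines the conditions emulated by the generators: a two-group microarray
#' series on the log2 scale with a planted subset of truly up/down-regulated
#' genes, a perturbagen rank-profile compendium containing planted reversers
#' and mimics, and a hallmark-style gene-set collection. Defaults describe
#' the desk-scale study used throughout: 5,000 gene probes, 20 + 20 samples
#' (tens per arm, as in the skin-biopsy series the generator emulates),
#' 500 perturbagens.
#'
#' @param n_genes Number of gene probes in the universe.
#' @param n_control,n_disease Samples per arm.
#' @param n_up_planted,n_down_planted Number of genes with a true positive /
#'   negative shift in the disease arm.
#' @param effect_size Mean log2 shift applied to planted genes in the
#'   disease arm (log2 units).
#' @param noise_sd Within-group standard deviation on the log2 scale.
#' @param n_perturbagens Compendium size.
#' @param n_reversers,n_mimics Planted profiles that oppose / copy the
#'   disease signature.
#' @param profile_noise Fraction in `[0, 1]`: `round(profile_noise * n_genes)`
#'   random adjacent transpositions are applied to each profile.
#' @param n_gene_sets,genes_per_set Gene-set collection shape (50 sets by
#'   default, emulating the hallmark collection).
#' @param seed Integer seed; identical config (including seed) gives
#'   bit-identical output from every generator.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_control = 20,
                              n_disease = 20,
                              n_up_planted = 150,
                              n_down_planted = 150,
                              effect_size = 2,
                              noise_sd = 0.5,
                              n_perturbagens = 500,
                              n_reversers = 10,
                              n_mimics = 10,
                              profile_noise = 0.02,
                              n_gene_sets = 50,
                              genes_per_set = 100,
                              seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_control = check_count(n_control, "n_control", min = 2L),
    n_disease = check_count(n_disease, "n_disease", min = 2L),
    n_up_planted = check_count(n_up_planted, "n_up_planted"),
    n_down_planted = check_count(n_down_planted, "n_down_planted"),
    effect_size = check_number(effect_size, "effect_size"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE),
    n_perturbagens = check_count(n_perturbagens, "n_perturbagens", min = 1L),
    n_reversers = check_count(n_reversers, "n_reversers"),
    n_mimics = check_count(n_mimics, "n_mimics"),
    profile_noise = check_number(profile_noise, "profile_noise", min = 0, max = 1),
    n_gene_sets = check_count(n_gene_sets, "n_gene_sets", min = 1L),
    genes_per_set = check_count(genes_per_set, "genes_per_set", min = 1L),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_up_planted + cfg$n_down_planted > cfg$n_genes) {
    stop_input("configuration error: n_up_planted + n_down_planted exceeds n_genes")
  }
  if (cfg$n_reversers + cfg$n_mimics > cfg$n_perturbagens) {
    stop_input("configuration error: n_reversers + n_mimics exceeds n_perturbagens")
  }
  if (cfg$genes_per_set > cfg$n_genes) {
    stop_input("configuration error: genes_per_set exceeds n_genes")
  }
  structure(cfg, class = "sim_config")
}

gene_universe <- function(n_genes) {
  sprintf("G%06d", seq_len(n_genes))
}

#' Generate a two-group expression matrix with planted truth
#'
#' Baseline expression for gene g is Gaussian on the log2 scale around a
#' gene-specific mean (drawn once per gene from N(8, 2), typical of
#' normalized array intensities) with standard deviation `noise_sd`. The
#' first `n_up_planted` planted genes get their disease-arm mean shifted by
#' `+effect_size`, the next `n_down_planted` by `-effect_size`; all other
#' genes are null.
#'
#' @param config A [simulation_config()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene_id`, `direction` in `up`/`down`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    genes <- gene_universe(config$n_genes)
    n_samp <- config$n_control + config$n_disease
    samples <- c(sprintf("normal_%02d", seq_len(config$n_control)),
                 sprintf("disease_%02d", seq_len(config$n_disease)))
    groups <- stats::setNames(
      rep(c("normal", "disease"), c(config$n_control, config$n_disease)),
      samples)
    base_mean <- stats::rnorm(config$n_genes, mean = 8, sd = 2)
    vals <- base_mean + matrix(stats::rnorm(config$n_genes * n_samp,
                                            sd = config$noise_sd),
                               nrow = config$n_genes)
    planted <- sample.int(config$n_genes,
                          config$n_up_planted + config$n_down_planted)
    up <- planted[seq_len(config$n_up_planted)]
    down <- setdiff(planted, up)
    disease_cols <- which(groups == "disease")
    vals[up, disease_cols] <- vals[up, disease_cols] + config$effect_size
    vals[down, disease_cols] <- vals[down, disease_cols] - config$effect_size
    dimnames(vals) <- list(genes, samples)
    truth <- data.frame(
      gene_id = c(genes[up], genes[down]),
      direction = rep(c("up", "down"),
                      c(config$n_up_planted, config$n_down_planted)),
      stringsAsFactors = FALSE)
    list(matrix = expression_matrix(vals, groups), truth = truth)
  })
}

# One random adjacent-transposition pass: round(noise * n) swaps of
# positions (j, j+1). Severity is monotone in `noise` in expectation.
apply_profile_noise <- function(ranking, noise) {
  n_swaps <- round(noise * length(ranking))
  if (n_swaps < 1L) return(ranking)
  pos <- sample.int(length(ranking) - 1L, n_swaps, replace = TRUE)
  for (j in pos) {
    tmp <- ranking[j]
    ranking[j] <- ranking[j + 1L]
    ranking[j + 1L] <- tmp
  }
  ranking
}

#' Generate a perturbagen rank-profile compendium with planted truth
#'
#' Each perturbagen is a full ranking of the gene universe (rank 1 = gene
#' most up-regulated by the drug). Planted *reversers* place the query
#' signature's up-tags at the very bottom and its down-tags at the very top
#' (a perfect expression-reversing drug); planted *mimics* do the opposite;
#' the remaining profiles are uniform random permutations. A fraction
#' `profile_noise` of `n_genes` random adjacent transpositions is then
#' applied to every profile. Per-perturbagen reference connectivity scores
#' for the signed-percentile tau normalization are computed against `n_ref`
#' random reference queries of the same tag sizes as `signature`.
#'
#' @param config A [simulation_config()].
#' @param signature A [disease_signature()] whose genes lie in the universe
#'   `G000001 ... G<n_genes>`.
#' @param n_ref Number of stored reference queries (default 100).
#' @return A list with `compendium` (class `perturbagen_compendium`: fields
#'   `universe`, `profiles` — named list of ranked gene-ID vectors — and
#'   `reference_scores`, a perturbagen-by-reference matrix) and `truth`
#'   (data.frame `perturbagen_id`, `role` in `reverser`/`mimic`/`null`).
#' @export
generate_compendium <- function(config, signature, n_ref = 100L) {
  stopifnot(inherits(config, "sim_config"),
            inherits(signature, "disease_signature"))
  universe <- gene_universe(config$n_genes)
  tags <- c(signature$up_tags, signature$down_tags)
  missing <- setdiff(tags, universe)
  if (length(missing)) {
    stop_input("input error: signature gene(s) not in universe: %s",
               paste(utils::head(missing, 5L), collapse = ", "))
  }
  with_seed(child_seed(config$seed, 2L), {
    n_p <- config$n_perturbagens
    ids <- sprintf("DRUG%04d", seq_len(n_p))
    roles <- rep("null", n_p)
    roles[seq_len(config$n_reversers)] <- "reverser"
    if (config$n_mimics > 0L) {
      roles[config$n_reversers + seq_len(config$n_mimics)] <- "mimic"
    }
    middle <- setdiff(universe, tags)
    profiles <- vector("list", n_p)
    for (i in seq_len(n_p)) {
      ranking <- switch(roles[i],
        reverser = c(signature$down_tags, sample(middle), signature$up_tags),
        mimic    = c(signature$up_tags, sample(middle), signature$down_tags),
        null     = sample(universe))
      profiles[[i]] <- apply_profile_noise(ranking, config$profile_noise)
    }
    names(profiles) <- ids
    comp <- structure(list(universe = universe, profiles = profiles,
                           reference_scores = NULL),
                      class = "perturbagen_compendium")
    comp <- build_reference_scores(comp, n_ref = n_ref,
                                   up_size = length(signature$up_tags),
                                   down_size = length(signature$down_tags),
                                   seed = NULL)
    list(compendium = comp,
         truth = data.frame(perturbagen_id = ids, role = roles,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a hallmark-style gene-set collection
#'
#' Samples `n_gene_sets` sets of `genes_per_set` genes, each without
#' replacement from the universe. The first set is a positive control built
#' from the planted up-regulated genes (topped up with random genes if fewer
#' planted genes than `genes_per_set` exist), so downstream pre-ranked
#' enrichment has a set that must score positive.
#'
#' @param config A [simulation_config()].
#' @param truth Optional planted-truth data.frame from
#'   [generate_expression()]; if supplied, set `SET_PLANTED_UP` is built
#'   from its up genes.
#' @return A named list of character vectors (class `gene_set_collection`).
#' @export
generate_gene_sets <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 3L), {
    universe <- gene_universe(config$n_genes)
    sets <- vector("list", config$n_gene_sets)
    names(sets) <- sprintf("SET_%03d", seq_len(config$n_gene_sets))
    for (i in seq_len(config$n_gene_sets)) {
      sets[[i]] <- sample(universe, config$genes_per_set)
    }
    if (!is.null(truth)) {
      up <- truth$gene_id[truth$direction == "up"]
      core <- utils::head(up, config$genes_per_set)
      if (length(core) < config$genes_per_set) {
        core <- c(core, sample(setdiff(universe, core),
                               config$genes_per_set - length(core)))
      }
      sets[[1L]] <- core
      names(sets)[1L] <- "SET_PLANTED_UP"
    }
    structure(sets, class = "gene_set_collection")
  })
}
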