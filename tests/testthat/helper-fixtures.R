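# Desk-scale simulation configs and hand-built objects shared across tests.

small_config <- function(...) {
  defaults <- list(n_genes = 1000, n_control = 10, n_disease = 10,
                   n_up_planted = 120, n_down_planted = 120,
                   effect_size = 2, noise_sd = 0.5,
                   n_perturbagens = 40, n_reversers = 4, n_mimics = 4,
                   profile_noise = 0, n_gene_sets = 10, genes_per_set = 50,
                   seed = 101)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A signature plus a noiseless mimic and reverser profile over a fresh
# universe; used by the tau-bound and symmetry tests.
toy_query <- function(n_genes = 2000, tag_size = 100, seed = 7) {
  universe <- sprintf("G%06d", seq_len(n_genes))
  idx <- withr_seed_sample(seed, n_genes, 2 * tag_size)
  sig <- disease_signature(up_tags = universe[idx[seq_len(tag_size)]],
                           down_tags = universe[idx[tag_size + seq_len(tag_size)]])
  middle <- setdiff(universe, c(sig$up_tags, sig$down_tags))
  list(universe = universe, signature = sig,
       mimic = c(sig$up_tags, middle, sig$down_tags),
       reverser = c(sig$down_tags, middle, sig$up_tags))
}

withr_seed_sample <- function(seed, n, k) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n, k)
}

# Null two-group matrix (no planted signal) for calibration tests.
null_matrix <- function(n_genes, n_per_group, sd = 1, seed = 1) {
  cfg <- small_config(n_genes = n_genes, n_control = n_per_group,
                      n_disease = n_per_group, n_up_planted = 0,
                      n_down_planted = 0, effect_size = 0, noise_sd = sd,
                      seed = seed)
  generate_expression(cfg)$matrix
}
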