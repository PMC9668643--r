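test_that("invalid configurations are rejected with the violated constraint named", {
  expect_error(small_config(n_up_planted = 600, n_down_planted = 600),
               "n_up_planted \\+ n_down_planted")
  expect_error(small_config(n_reversers = 30, n_mimics = 30),
               "n_reversers \\+ n_mimics")
  expect_error(small_config(genes_per_set = 5000), "genes_per_set")
  expect_error(small_config(noise_sd = 0), "noise_sd")
  expect_error(small_config(profile_noise = 1.5), "profile_noise")
})

test_that("expression generator is a pure function of the config", {
  cfg <- small_config(seed = 5)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c <- generate_expression(small_config(seed = 6))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("generated matrix has the requested shape and planted truth", {
  cfg <- small_config()
  out <- generate_expression(cfg)
  expect_equal(dim(out$matrix$values), c(1000, 20))
  expect_equal(sum(out$matrix$groups == "normal"), 10)
  expect_equal(nrow(out$truth), 240)
  expect_setequal(unique(out$truth$direction), c("up", "down"))
  expect_true(all(out$truth$gene_id %in% rownames(out$matrix$values)))
})

test_that("a strong planted effect forces the sign of every sample log2 fold change", {
  # effect 4 with sd 0.25 at 20+20: P(wrong sign) < 1e-10 per gene
  cfg <- small_config(n_control = 20, n_disease = 20, effect_size = 4,
                      noise_sd = 0.25, seed = 11)
  out <- generate_expression(cfg)
  g <- out$matrix$groups
  lfc <- rowMeans(out$matrix$values[, g == "disease"]) -
    rowMeans(out$matrix$values[, g == "normal"])
  up <- out$truth$gene_id[out$truth$direction == "up"]
  down <- out$truth$gene_id[out$truth$direction == "down"]
  expect_true(all(lfc[up] > 0))
  expect_true(all(lfc[down] < 0))
})

test_that("with zero effect size the planted table is emitted but carries no signal", {
  cfg <- small_config(n_control = 20, n_disease = 20, effect_size = 0,
                      noise_sd = 0.5, seed = 12)
  out <- generate_expression(cfg)
  expect_equal(nrow(out$truth), 240)
  g <- out$matrix$groups
  lfc <- rowMeans(out$matrix$values[, g == "disease"]) -
    rowMeans(out$matrix$values[, g == "normal"])
  # |lfc| > 3 * sd * sqrt(2/n) should occur at roughly the Gaussian tail rate
  thr <- 3 * 0.5 * sqrt(2 / 20)
  frac <- mean(abs(lfc[out$truth$gene_id]) > thr)
  expect_lt(frac, 0.02)  # 2 * pnorm(-3) ~ 0.0027, generous Monte-Carlo margin
})

test_that("compendium construction plants recoverable reversers and mimics", {
  q <- toy_query(n_genes = 500, tag_size = 40)
  cfg <- small_config(n_genes = 500, n_perturbagens = 12, n_reversers = 2,
                      n_mimics = 2, profile_noise = 0)
  out <- generate_compendium(cfg, q$signature, n_ref = 25)
  comp <- out$compendium
  expect_s3_class(comp, "perturbagen_compendium")
  expect_length(comp$profiles, 12)
  expect_equal(dim(comp$reference_scores), c(12, 25))
  # every profile is a permutation of the universe
  for (p in comp$profiles) expect_setequal(p, comp$universe)
  # noiseless reverser: up tags occupy exactly the last |U| ranks
  rev_id <- out$truth$perturbagen_id[out$truth$role == "reverser"][1]
  ranking <- comp$profiles[[rev_id]]
  expect_identical(utils::tail(ranking, 40), q$signature$up_tags)
  expect_identical(utils::head(ranking, 40), q$signature$down_tags)
  # mimic is the opposite
  mim_id <- out$truth$perturbagen_id[out$truth$role == "mimic"][1]
  expect_identical(utils::head(comp$profiles[[mim_id]], 40), q$signature$up_tags)
  # determinism
  out2 <- generate_compendium(cfg, q$signature, n_ref = 25)
  expect_identical(out$compendium$profiles, out2$compendium$profiles)
  expect_identical(out$compendium$reference_scores, out2$compendium$reference_scores)
})

test_that("a signature gene outside the universe is an input error", {
  q <- toy_query(n_genes = 200, tag_size = 20)
  bad <- disease_signature(c(q$signature$up_tags[-1], "NOT_A_GENE"),
                           q$signature$down_tags)
  cfg <- small_config(n_genes = 200, n_up_planted = 50, n_down_planted = 50,
                      genes_per_set = 50)
  expect_error(generate_compendium(cfg, bad), "NOT_A_GENE")
})

test_that("an all-null compendium has mean raw connectivity near zero", {
  q <- toy_query(n_genes = 800, tag_size = 50, seed = 3)
  cfg <- small_config(n_genes = 800, n_perturbagens = 60, n_reversers = 0,
                      n_mimics = 0, profile_noise = 0, seed = 21)
  comp <- generate_compendium(cfg, q$signature, n_ref = 20)$compendium
  raws <- vapply(comp$profiles, function(p) {
    raw_connectivity(q$signature, p)$raw_score
  }, numeric(1))
  # null raw scores are centred at 0; sd of each is well under 0.1
  expect_lt(abs(mean(raws)), 3 * stats::sd(raws) / sqrt(length(raws)) + 0.01)
})

test_that("gene-set generator emits the requested collection and round-trips GMT", {
  cfg <- small_config(n_gene_sets = 50, genes_per_set = 30)
  truth <- generate_expression(cfg)$truth
  sets <- generate_gene_sets(cfg, truth)
  expect_length(sets, 50)
  expect_true(all(lengths(sets) == 30))
  expect_true(all(vapply(sets, anyDuplicated, integer(1)) == 0))
  expect_equal(names(sets)[1], "SET_PLANTED_UP")
  expect_true(all(sets$SET_PLANTED_UP %in%
                    truth$gene_id[truth$direction == "up"]))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(unclass(back), lapply(unclass(sets), as.character))
  # determinism
  expect_identical(sets, generate_gene_sets(cfg, truth))
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_expression(small_config()))
  expect_identical(.Random.seed, before)
})
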