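test_that("ks_enrichment reproduces the analytic worked examples", {
  profile <- sprintf("g%03d", 1:100)
  expect_equal(ks_enrichment(profile[1:10], profile), 0.9)     # 1 - t/n
  expect_equal(ks_enrichment(profile[91:100], profile), -0.91) # -(1 - 9/100)
  p10 <- sprintf("g%02d", 1:10)
  expect_warning(es <- ks_enrichment(p10[c(2, 5, 9)], p10), "fewer than 10")
  expect_equal(es, -7 / 30)
})

test_that("ks_enrichment agrees exactly with the running-sum oracle", {
  set.seed(51)
  for (i in 1:400) {
    n <- sample(10:200, 1)
    t <- sample(1:min(30, n), 1)
    profile <- sprintf("g%04d", sample.int(9999, n))
    tags <- sample(profile, t)
    positions <- sort(match(tags, profile))
    expect_identical(suppressWarnings(ks_enrichment(tags, profile)),
                     ks_oracle(positions, n))
  }
})

test_that("enrichment scores stay within [-1, 1] on random inputs", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(5:300, 1)
    profile <- sample(sprintf("g%04d", 1:n))
    tags <- sample(profile, sample(seq_len(n), 1))
    es <- suppressWarnings(ks_enrichment(tags, profile))
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("query genes missing from the universe are dropped or rejected", {
  profile <- sprintf("g%02d", 1:50)
  expect_warning(ks_enrichment(c(profile[1:12], "absent"), profile), "dropped")
  expect_error(ks_enrichment(c("a1", "a2"), profile), "query error")
})

test_that("raw connectivity combines directions with the same-sign null rule", {
  q <- toy_query(n_genes = 400, tag_size = 40)
  mim <- raw_connectivity(q$signature, q$mimic)
  expect_equal(mim$es_up, 1 - 40 / 400)
  expect_equal(mim$raw_score, (mim$es_up - mim$es_down) / 2)
  expect_gt(mim$raw_score, 0.85)
  rev <- raw_connectivity(q$signature, q$reverser)
  expect_lt(rev$raw_score, -0.85)
  # same-sign pair scores zero: both tag lists at the top of the profile
  both_top <- c(q$signature$up_tags, q$signature$down_tags,
                setdiff(q$universe, c(q$signature$up_tags, q$signature$down_tags)))
  expect_equal(raw_connectivity(q$signature, both_top)$raw_score, 0)
})

test_that("swapping up and down tags negates raw connectivity exactly", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(100:400, 1)
    profile <- sample(sprintf("g%04d", 1:n))
    idx <- sample.int(n, 30)
    sig <- disease_signature(profile[idx[1:15]], profile[idx[16:30]])
    swapped <- disease_signature(sig$down_tags, sig$up_tags)
    a <- raw_connectivity(sig, profile)
    b <- raw_connectivity(swapped, profile)
    expect_identical(b$raw_score, -a$raw_score)
    expect_identical(b$es_up, a$es_down)
  }
})

test_that("tau is the signed percentile of the raw magnitude, bounds attained", {
  refs <- seq(-0.99, 0.99, length.out = 100)
  expect_equal(tau_normalize(1, refs), 100)
  expect_equal(tau_normalize(-1, refs), -100)
  expect_equal(tau_normalize(0, refs), 0)
  # 75 of 100 references with magnitude below 0.5 -> tau = -75
  refs75 <- c(seq(0.001, 0.499, length.out = 75), seq(0.51, 0.99, length.out = 25))
  expect_equal(tau_normalize(-0.5, refs75), -75)
  expect_error(tau_normalize(0.5, refs75[1:10]), ">= 20 reference")
})

test_that("tau magnitude is monotone in raw-score magnitude for fixed references", {
  set.seed(54)
  refs <- runif(100, -1, 1)
  raws <- sort(runif(50, 0, 1))
  taus <- vapply(raws, tau_normalize, numeric(1), reference_scores = refs)
  expect_true(all(diff(taus) >= 0))
  expect_identical(vapply(-raws, tau_normalize, numeric(1), reference_scores = refs),
                   -taus)
})

test_that("permutation p-values respect the plus-one bound and detect a perfect reverser", {
  q <- toy_query(n_genes = 500, tag_size = 30, seed = 2)
  p_rev <- permutation_pvalue(q$signature, q$reverser, n_perm = 1000, seed = 3)
  expect_equal(p_rev, 1 / 1001)
  # reproducible under the same seed
  expect_identical(p_rev,
                   permutation_pvalue(q$signature, q$reverser, n_perm = 1000, seed = 3))
  # a null profile yields an unremarkable p
  null_profile <- withr::with_seed(4, sample(q$universe))
  p_null <- permutation_pvalue(q$signature, null_profile, n_perm = 200, seed = 5)
  expect_gte(p_null, 1 / 201)
  expect_lte(p_null, 1)
})

test_that("permutation p-values are exactly calibrated under null queries", {
  # The same-sign->0 rule gives null queries an atom at raw = 0, which maps
  # to p = 1; off the atom the p-value is exactly uniform: P(p <= t) = t in
  # the rejection-relevant range.
  universe <- sprintf("g%04d", 1:800)
  profile <- withr::with_seed(6, sample(universe))
  set.seed(61)
  pvals <- vapply(1:150, function(i) {
    idx <- sample.int(800, 40)
    sig <- disease_signature(universe[idx[1:20]], universe[idx[21:40]])
    permutation_pvalue(sig, profile, n_perm = 100, seed = 1000 + i)
  }, numeric(1))
  expect_lt(abs(mean(pvals <= 0.4) - 0.4), 3 * sqrt(0.4 * 0.6 / 150))
  sub <- pvals[pvals <= 0.4]
  ks <- suppressWarnings(stats::ks.test(sub / 0.4, "punif"))
  expect_gt(ks$p.value, 0.01)
  # the zero-score atom maps to p = 1
  expect_gt(mean(pvals == 1), 0.3)
})

test_that("score_compendium ranks planted reversers first and mimics last", {
  q <- toy_query(n_genes = 600, tag_size = 40, seed = 8)
  cfg <- small_config(n_genes = 600, n_perturbagens = 30, n_reversers = 3,
                      n_mimics = 3, profile_noise = 0, seed = 71)
  out <- generate_compendium(cfg, q$signature, n_ref = 40)
  res <- score_compendium(q$signature, out$compendium, n_perm = 100, seed = 9)
  expect_equal(nrow(res), 30)
  expect_true(all(res$tau >= -100 & res$tau <= 100))
  expect_true(all(res$fdr >= res$pvalue))
  merged <- merge(res, out$truth)
  expect_true(all(merged$rank[merged$role == "reverser"] %in% 1:3))
  expect_true(all(merged$rank[merged$role == "mimic"] %in% 28:30))
  expect_true(all(merged$tau[merged$role == "reverser"] == -100))
  expect_true(all(merged$tau[merged$role == "mimic"] == 100))
  # raw_score = 0 whenever es_up and es_down share a strict sign
  same_sign <- with(res, (es_up > 0 & es_down > 0) | (es_up < 0 & es_down < 0))
  expect_true(all(res$raw_score[same_sign] == 0))
  # deterministic under a fixed seed
  expect_identical(res, score_compendium(q$signature, out$compendium,
                                         n_perm = 100, seed = 9))
})

test_that("tau distribution over null drugs is symmetric about zero", {
  q <- toy_query(n_genes = 500, tag_size = 30, seed = 12)
  cfg <- small_config(n_genes = 500, n_perturbagens = 80, n_reversers = 0,
                      n_mimics = 0, profile_noise = 0, seed = 73)
  out <- generate_compendium(cfg, q$signature, n_ref = 40)
  res <- score_compendium(q$signature, out$compendium, n_perm = 100, seed = 13)
  nz <- res$tau[res$tau != 0]
  bt <- stats::binom.test(sum(nz > 0), length(nz))
  expect_gt(bt$p.value, 0.01)
})

test_that("candidate truncation keeps the top of the ranking", {
  df <- data.frame(perturbagen_id = sprintf("D%03d", 1:40),
                   tau = seq(-100, 95, length.out = 40), rank = 1:40)
  expect_equal(nrow(truncate_candidates(df, k = 150)), 40)
  top <- truncate_candidates(df, k = 10)
  expect_equal(top$rank, 1:10)
  single <- truncate_candidates(df, k = 1)
  expect_equal(single$tau, -100)
  expect_error(truncate_candidates(df, k = 0), "'k'")
  expect_error(score_compendium(toy_query(100, 10)$signature,
                                perturbagen_compendium(letters, list(p = letters))),
               "reference scores")
})

test_that("compendium TSV and reference sidecar round-trip", {
  q <- toy_query(n_genes = 300, tag_size = 25, seed = 14)
  cfg <- small_config(n_genes = 300, n_perturbagens = 8, n_reversers = 1,
                      n_mimics = 1, profile_noise = 0.01, genes_per_set = 40,
                      seed = 75)
  comp <- generate_compendium(cfg, q$signature, n_ref = 20)$compendium
  path <- withr::local_tempfile(fileext = ".tsv")
  refp <- withr::local_tempfile(fileext = ".csv")
  write_compendium(comp, path, refp)
  back <- read_compendium(path, refp)
  expect_identical(back$profiles, comp$profiles)
  expect_identical(back$universe, comp$universe)
  expect_equal(back$reference_scores, comp$reference_scores)
})
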