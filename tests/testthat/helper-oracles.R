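# Independent brute-force oracles used to check the analytic implementations.
# All are deliberately written as literal walks/loops over definitions,
# sharing no code with the package internals.

# Benjamini-Hochberg step-up, quadratic time: for each p_i take the minimum
# of m * p_j / rank(p_j) over all p_j >= p_i, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    vals <- vapply(seq_len(m), function(j) {
      rank_j <- sum(p <= p[j])
      m * p[j] / rank_j
    }, numeric(1))
    min(1, vals[p >= pi])
  }, numeric(1))
}

# Tag-set KS enrichment as an O(n) running walk over every profile position.
ks_oracle <- function(positions, n) {
  t <- length(positions)
  is_hit <- logical(n)
  is_hit[positions] <- TRUE
  hits_so_far <- 0L
  a <- -Inf
  b <- -Inf
  for (j in seq_len(n)) {
    b <- max(b, j / n - hits_so_far / t)
    if (is_hit[j]) hits_so_far <- hits_so_far + 1L
    a <- max(a, hits_so_far / t - j / n)
  }
  if (a >= b) a else -b
}

# Weighted (exponent 1) running-sum enrichment score, literal accumulation.
es_oracle <- function(metric, hit) {
  n <- length(metric)
  nh <- sum(hit)
  tot <- sum(abs(metric[hit]))
  cur <- 0
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) {
      if (tot > 0) abs(metric[i]) / tot else 1 / nh
    } else {
      -1 / (n - nh)
    }
    mx <- max(mx, cur)
    mn <- min(mn, cur)
  }
  if (mx >= -mn) mx else mn
}
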