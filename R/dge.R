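#' Two-group differential expression
#'
#' Computes, per gene, the log2 fold change (disease mean minus normal
#' mean), a test statistic, a two-sided p-value, and a Benjamini-Hochberg
#' adjusted p-value. Two models are offered:
#'
#' * `mode = "moderated"` (default): a moderated t in the empirical-Bayes
#'   tradition of microarray analysis. Per-gene pooled residual variances
#'   are shrunk toward a prior variance `s0^2` with prior degrees of freedom
#'   `d0`, both estimated by method of moments on the log residual
#'   variances (the trigamma moment equation is solved numerically). The
#'   statistic is referred to a t distribution on `d0 + d` degrees of
#'   freedom.
#' * `mode = "welch"`: the ordinary Welch two-sample t with
#'   Welch-Satterthwaite degrees of freedom.
#'
#' Genes with zero variance in both groups get their variance floored at
#' `1e-3` times the smallest positive per-gene variance (with a warning)
#' rather than being dropped.
#'
#' @param matrix An [expression_matrix()] with at least two samples per
#'   group.
#' @param mode `"moderated"` or `"welch"`.
#' @return A data.frame (one row per input gene, input order preserved)
#'   with columns `gene_id`, `log2fc`, `tstat`, `pvalue`, `adj_pvalue`.
#' @export
differential_expression <- function(matrix, mode = c("moderated", "welch")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  mode <- match.arg(mode)
  x <- matrix$values
  g <- matrix$groups
  n1 <- sum(g == "normal")
  n2 <- sum(g == "disease")
  if (n1 < 2L || n2 < 2L) {
    stop_input("input error: each group needs >= 2 samples (got %d normal, %d disease)",
               n1, n2)
  }
  xn <- x[, g == "normal", drop = FALSE]
  xd <- x[, g == "disease", drop = FALSE]
  mn <- rowMeans(xn)
  md <- rowMeans(xd)
  vn <- rowSums((xn - mn)^2) / (n1 - 1)
  vd <- rowSums((xd - md)^2) / (n2 - 1)
  log2fc <- md - mn

  if (mode == "welch") {
    denom2 <- vn / n1 + vd / n2
    if (any(denom2 == 0)) {
      pos <- denom2[denom2 > 0]
      if (!length(pos)) stop_input("input error: all genes have zero variance")
      warning(sum(denom2 == 0), " zero-variance gene(s); variance floored",
              call. = FALSE)
      denom2[denom2 == 0] <- min(pos) * 1e-3
    }
    tstat <- log2fc / sqrt(denom2)
    df <- denom2^2 / ((vn / n1)^2 / (n1 - 1) + (vd / n2)^2 / (n2 - 1))
    df[!is.finite(df) | df <= 0] <- n1 + n2 - 2  # degenerate floored genes
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * vn + (n2 - 1) * vd) / d
    if (any(s2 == 0)) {
      pos <- s2[s2 > 0]
      if (!length(pos)) stop_input("input error: all genes have zero variance")
      warning(sum(s2 == 0), " zero-variance gene(s); variance floored",
              call. = FALSE)
      s2[s2 == 0] <- min(pos) * 1e-3
    }
    prior <- fit_variance_prior(s2, d)
    if (is.finite(prior$df_prior)) {
      s2_post <- (prior$df_prior * prior$var_prior + d * s2) /
        (prior$df_prior + d)
    } else {
      s2_post <- rep(prior$var_prior, length(s2))
    }
    tstat <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n2))
    df <- rep(d + prior$df_prior, length(tstat))
  }
  pvalue <- 2 * stats::pt(-abs(tstat), df = df)
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(x), log2fc = log2fc, tstat = tstat,
             pvalue = pvalue, adj_pvalue = bh_adjust(pvalue),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Method-of-moments fit of the scaled inverse chi-square prior on residual
# variances (prior df d0, prior variance s0^2), via the moments of
# log(s^2): with e = log(s2) - digamma(d/2) + log(d/2),
#   var(e) = trigamma(d/2) + trigamma(d0/2),
# solved for d0 by inverting the trigamma function (Newton iteration).
# var(e) <= trigamma(d/2) means no excess dispersion: d0 = Inf and all
# variances shrink completely to s0^2.
fit_variance_prior <- function(s2, d, df_prior = NULL) {
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (is.null(df_prior)) {
    n <- length(e)
    evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(d / 2)
    df_prior <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
  }
  var_prior <- if (is.finite(df_prior) && df_prior > 0) {
    exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(y) = x for y > 0 by Newton's method on 1/trigamma,
# monotone and well-conditioned over the full range.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, preserving input order and
#' clipping at 1. Thin validating wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || !length(pvalues)) {
    stop_input("input error: 'pvalues' must be a non-empty numeric vector")
  }
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop_input("input error: p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Write a differential expression table
#'
#' CSV with columns `gene_id, log2fc, tstat, pvalue, adj_pvalue`, preceded
#' by an optional `#` header comment.
#'
#' @param table Output of [differential_expression()].
#' @param path Output path.
#' @param header Optional header comment string.
#' @return The path, invisibly.
#' @export
write_dge <- function(table, path, header = NULL) {
  write_table_with_header(table, path, header = header)
}
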