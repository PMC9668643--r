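---
title: "Signature-reversal drug repurposing: methods and design notes"
author: "revsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repurposing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

## The reversal hypothesis

`revsig` implements a transcriptomic drug-repurposing pipeline built on a
simple premise: if a disease shifts a set of genes up and another set down,
a compound whose perturbation profile pushes those same genes in the
*opposite* directions is a candidate therapy. The pipeline was designed
around the psoriasis use case — two-arm skin-biopsy microarray series with
tens of samples per arm and \(10^4\)–\(10^5\) probes — but nothing in it is
disease-specific.

The stages are:

1. **Differential expression** (`differential_expression()`): per-gene
   log2 fold change (disease − normal), a moderated or Welch t-statistic,
   two-sided p-values, and Benjamini–Hochberg adjusted p-values.
2. **Query signature** (`extract_signature()`): genes with
   `adj_pvalue < 0.05` and `|log2fc| ≥ 1`, ranked by fold change, cut to
   the top 100 per direction.
3. **Connectivity scoring** (`score_compendium()`): every perturbagen in a
   rank-profile compendium is scored with a bidirectional
   Kolmogorov–Smirnov statistic, normalized to a signed percentile
   \(\tau \in [-100, 100]\), and ranked most-negative-first.
4. **Pre-ranked gene-set enrichment** (`preranked_gsea()`): pathway context
   for the disease signature.
5. **Validation counting** (`annotate_validation()`): a two-step evidence
   rule applied to an external annotation table.

A synthetic-data module generates all inputs with planted ground truth, so
the whole pipeline is testable without any network access.

## Differential expression model

For gene \(g\) with group means \(\bar{x}_{g,d}, \bar{x}_{g,n}\) the effect
is \(\mathrm{lfc}_g = \bar{x}_{g,d} - \bar{x}_{g,n}\) ("up-regulated in
disease" ⇔ positive). Two statistics are offered:

* **Moderated t** (default). Pooled per-gene variances \(s_g^2\) on
  \(d\) degrees of freedom are shrunk toward a prior:
  \(\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)\), with
  \((d_0, s_0^2)\) estimated by method of moments on \(\log s_g^2\): the
  excess variance of \(e_g = \log s_g^2 - \psi(d/2) + \log(d/2)\) over
  \(\psi'(d/2)\) equals \(\psi'(d_0/2)\), solved by Newton inversion of the
  trigamma function. The statistic is referred to a t distribution on
  \(d_0 + d\) df. When the log-variances show no excess dispersion the
  solution is \(d_0 = \infty\) and every gene uses \(s_0^2\). The test
  suite checks this implementation against the standard empirical-Bayes
  microarray implementation (limma) to \(10^{-10}\), and checks that as
  \(d_0 \to 0\) the statistic collapses to the ordinary pooled t.
* **Welch t** with Welch–Satterthwaite df, for users who prefer no
  variance sharing.

Genes with exactly zero variance are floored at \(10^{-3}\times\) the
smallest positive per-gene variance (with a warning) rather than dropped,
so the output always has one row per input gene. p-values are two-sided
throughout; BH adjustment is a validating wrapper over `stats::p.adjust`.

`auto_log_check()` mirrors the usual microarray front-end heuristic: a
matrix whose 99th percentile exceeds 50 is judged to be on the raw
intensity scale and replaced by \(\log_2(x+1)\).

### Signature thresholds

The fold-change filter is interpreted as an *exclusion* window: a DE call
requires \(|\mathrm{lfc}| \ge 1\), since keeping only genes inside
\((-1, 1)\) would contradict selecting "up- and down-regulated" genes. The
filter is applied first, then genes are ranked by fold change (p-values
only break ties, then gene ID), then cut to `top_n`. Both choices are
package defaults, not inferences about any particular dataset.

## Connectivity scoring

Each perturbagen is a full ranking of the gene universe, rank 1 = gene
most up-regulated by the drug. For a tag list with matched positions
\(r_{(1)} < \dots < r_{(t)}\) in a profile of \(n\) genes,

\[ a = \max_i \left(\tfrac{i}{t} - \tfrac{r_{(i)}}{n}\right), \qquad
   b = \max_i \left(\tfrac{r_{(i)}}{n} - \tfrac{i-1}{t}\right), \]

and \(ES = a\) if \(a \ge b\), else \(-b\) (ties resolve to the positive
branch). The bidirectional raw score is \((ES_{up} - ES_{down})/2\) when
the two directions disagree in sign, and **0 when they agree** — a drug
that pushes both halves of the query the same way carries no reversal
evidence. Queries with tags missing from the universe drop them with a
warning; fewer than 10 matched tags per direction warns, zero errors.

**Tau.** Raw scores are not comparable across perturbagens, so each is
normalized against that perturbagen's cached scores for `n_ref` stored
reference queries (the "touchstone" idea):
\(\tau = \mathrm{sign}(raw)\cdot 100 \cdot \#\{|ref| < |raw|\}/n_{ref}\),
strict inequality, \(\tau = 0\) for \(raw = 0\). \(\tau = \pm 100\) is
attained exactly when the observed magnitude dominates every reference;
the package default is `n_ref = 100` (a desk-scale stand-in for the
thousands of stored queries a production compendium would use; at least
20 are required). Candidates are ranked by \(\tau\) ascending — most
negative first — with a total tie order (raw score, then ID) so outputs
are bit-stable, and the list is truncated to `top_k = 150` candidates for
validation.

**Permutation p-values** draw `n_perm` random queries with the same tag
sizes (up/down disjoint, sampled without replacement from the universe)
and use the plus-one estimator
\(p = (1 + \#\{|raw_{perm}| \ge |raw|\})/(n_{perm}+1)\), so
\(p \ge 1/(n_{perm}+1)\) always. One subtlety is worth stating precisely:
because the same-sign rule maps a positive fraction \(q\) of null queries
to exactly \(raw = 0\) (empirically \(q \approx 0.5\)), the marginal null
law of \(p\) is *uniform on \((0, 1-q]\) with an atom \(q\) at 1* — every
zero-score query is maximally non-significant. The p-value is therefore
exactly calibrated where it matters, \(P(p \le t) = t\) for
\(t \le 1-q\), and conservative above; the test suite asserts exactly
that, rather than a literal U(0,1) fit that the zero rule makes
impossible. FDR across perturbagens is BH.

The weighting is the classic unweighted tag-set KS construction (no
rank-weighted variant), matching the statistic the pipeline is named for.

## Pre-ranked enrichment

Genes are ranked by a signed metric — default the moderated t, which folds
fold change and its evidence into one number; `metric = "log2fc"` is the
configurable alternative. For a set with \(N_h\) members in a list of
\(N\) genes the running sum gains \(|m_i|/\sum_{hits}|m|\) at hits and
loses \(1/(N-N_h)\) at misses (weight exponent 1); ES is the signed
maximum deviation. The null is gene-set permutation (`n_perm` random
same-size sets), NES is ES divided by the mean |null ES| of matching sign,
and the p-value is the plus-one fraction of same-sign nulls at least as
extreme. Sets with no overlap are skipped with a warning. The
implementation is checked exactly against a literal running-sum oracle and
against the reference GSEA statistic (fgsea) on random instances.

## What the generators emulate — and what they do not

`generate_expression()` simulates directly on the log2 scale: per-gene
baseline means \(\sim N(8, 2)\) (typical normalized array intensities),
within-group noise \(N(0, \texttt{noise\_sd}^2)\), and a planted shift of
\(\pm\texttt{effect\_size}\) in the disease arm for the chosen genes.
There is no raw-intensity, probe-level, or array-artifact model: the
pipeline consumes normalized matrices, so that is what is simulated.

`generate_compendium()` builds noiseless reversers (query up-tags at the
bottom of the ranking, down-tags at the top), mimics (the opposite), and
uniform random null profiles, then applies
`round(profile_noise * n_genes)` random adjacent transpositions — a
deliberately simple degradation that is monotone in severity, not a
parametric rank model. `generate_gene_sets()` samples sets without
replacement and plants one positive-control set inside the true
up-regulated genes.

Defaults are the study conditions used throughout the tests: 5,000 genes,
20 + 20 samples, 150 + 150 planted genes with `effect_size = 2` and
`noise_sd = 0.5` (a comfortably detectable microarray effect: per-gene
power at 20 + 20 is essentially 1, so the planted-recovery checks test the
ranking machinery, not borderline power), 500 perturbagens with 10
reversers and 10 mimics, `profile_noise = 0.02`, and 50 sets of 100 genes.
The properties this package is tested on are therefore
*structural*: signature sizes, tau bounds, rank order of planted drugs,
calibration of null p-values. Passing them says the machinery is correct;
it says nothing about noise regimes, probe-to-gene mapping, batch effects,
or replicate summarization in any real series.

## Numerical choices and degenerate inputs

* All sorts use a documented total order (tau, then raw score, then ID;
  fold change, then adjusted p, then ID), so identical inputs give
  byte-identical outputs.
* `a = b` ties in the KS statistic and max/min ties in the running sum
  resolve to the positive branch.
* Running sums are accumulated with `cumsum` (extended-precision in C);
  agreement with a literal double-precision loop is to machine rounding.
* Every generator and every stochastic stage takes an explicit seed and
  restores the caller's RNG state; the pipeline derives stage-specific
  child seeds from the run seed, so adding a stage never reshuffles
  another stage's draws.
* Degenerate cases: zero-variance genes are floored, not dropped;
  under-filled tag lists warn; empty directions, empty compendia, and
  gene sets with no overlap are hard errors or skip-with-warning as
  documented on each function.

## Scale of the shipped checks

The test suite runs at desk scale: 6,000-gene null calibrations, a
300-perturbagen × 1,000-permutation scoring run, the 5,000-gene ×
500-perturbagen planted-recovery study at `profile_noise = 0.05`, and
≥1,000 randomized oracle-equivalence instances, completing in under two
minutes on one core. The acceptance script
(`scripts/acceptance.R`) reconstructs the tau-bound experiment — perfect
mimic and reverser against 100 reference queries on a 2,000-gene universe
— from scratch at run time.

## Interface note

The pipeline is exposed as R functions (`run_all()` being the one-call
orchestrator) rather than a shell executable; an R session or `Rscript -e`
one-liner is the intended entry point, and every stage writes its CSV/TSV
artifacts with a seed- and config-stamped header for auditability.

## Known limitations

* Tau percentiles from 100 reference queries are coarse (resolution 1);
  production use against a real compendium should cache many more
  reference scores.
* No covariate adjustment, paired designs, batch correction, or
  probe-set summarization in the DE stage.
* No cell-line/dose/time collapsing of perturbagen replicates; one
  profile = one perturbagen.
* The validation stage implements only the evidence-counting rule over a
  user-supplied annotation table; it does not search literature or
  records.
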