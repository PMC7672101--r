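---
title: "Statistical methods and conventions in mutscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and conventions in mutscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

This vignette documents the conventions and derivations behind each analysis
module. Everything stated here is enforced by the test suite, usually against
a hand-worked or closed-form oracle.

## Coordinates and strand conventions

All positions are **1-based** and refer to the forward (reference) strand.
For an indel, `pos` is the first reference base of the event and `ref`/`alt`
share a one-base anchor, as in VCF.

Substitution channels are **pyrimidine-centric**: a mutation with a purine
reference base is reverse-complemented (together with its flanking context)
before classification, so `G>A` in an `ACT` right context and `C>T` in an
`AGT` left context land in the same SBS96 channel. The same rule defines the
78 canonical doublet channels: a doublet whose canonical form requires it is
reverse-complemented as a unit, and palindromic reference doublets (e.g. `TA`)
are oriented by the alternate allele.

For strand-asymmetry analyses, a mutation inside a gene is labelled
**untranscribed** when its pyrimidine partner lies on the coding strand
(equivalently: the purine of the mutated pair is on the template strand).
Mutations in genes annotated on both strands are discarded as ambiguous.

## ID83 channels

Indels are **left-aligned** before classification, so two representations of
the same event always map to the same channel. The 83 channels follow the
standard scheme, with these concrete rules:

* **1-bp deletion** `1:Del:<base>:<k>` — `base` is the pyrimidine
  representative (`C` or `T`) of the deleted base; `k = min(run - 1, 5)`
  where `run` is the full homopolymer length *including* the deleted base.
* **1-bp insertion** `1:Ins:<base>:<k>` — `k = min(run, 5)` where `run` is
  the length of the pre-existing homopolymer the base joins.
* **≥ 2-bp tandem events** `size:Del/Ins:R:min(copies, 5)` — `copies` counts
  additional whole copies of the indel sequence adjacent to the event;
  `size` is capped at 5 (all longer events share the `5:` prefix).
* **Deletions with microhomology** `size:Del:M:min(mh, size - 1, 5)` — used
  when the deletion is not in a tandem repeat (`copies == 0`) but has
  `mh ≥ 1` bases of flanking homology.
* Everything else is `size:Del/Ins:R:0`.

## KL-NMF signature extraction and identifiability

`nmf_extract()` minimizes the generalized Kullback–Leibler divergence
between the catalog matrix and a rank-*K* product using the standard
multiplicative updates, with multiple random restarts; the best run by
objective is returned, signatures normalized to probability vectors.
`refit_exposures()` solves per-sample non-negative least squares
(`pracma::lsqnonneg`) against fixed signatures, and
`bootstrap_exposures()` resamples mutations multinomially to attach
percentile intervals.

NMF is only identifiable up to permutation and scale, and mixtures are
recoverable only when the exposure matrix is well-conditioned. In practice
this means rank-*K* recovery should be demonstrated on designs that contain
**near-pure samples** for each signature (e.g. mixture fractions spanning
0.02–0.98): with every sample near the centroid, infinitely many
factorizations explain the data equally well. `rank_survey()` reports
residual sums of squares across candidate ranks; for data of exact rank
*K* the surveyed RSS drops to (numerically) zero at that rank.

```{r nmf, eval = TRUE}
sigs <- example_signatures()
fr <- seq(0.02, 0.98, length.out = 12)
m <- make_channel_matrix(sigs, cbind(fr, 1 - fr), n_mut = 3000, seed = 1)
fit <- nmf_extract(m, K = 2, n_runs = 5, seed = 2)
match_signatures(fit$signatures, sigs)$cosine
```

## Clustered mutations: the context-preserving null

Mutation clustering cannot be assessed against a uniform null, because
mutational processes concentrate on specific sequence contexts that are
themselves clustered in the genome. `mutscape` therefore simulates random
catalogs that preserve the observed **context spectrum**: for each replicate,
positions are drawn i.i.d. from the pool of genomic sites carrying each
trinucleotide (or pentanucleotide) context, with counts matching the observed
spectrum exactly; coincident draws contribute no distance and
cross-chromosome pairs never do.

The sampler is stratified by context and vectorized across replicates;
`context_site_index()` precomputes the per-context site pools once so that
many samples and replicates can share one index. Because the draws are
i.i.d., generating all replicates in one pass per context and cutting the
stream into consecutive blocks preserves the law of per-replicate sampling.
The tests verify that every replicate reproduces the requested spectrum
exactly and that, for context-free spectra, the number of inter-mutation
gaps below *d* matches the uniform-spacings law
\(E[\#\{S_i \le d\}] = (n-1)\,(1-(1-d/L)^n)\).

`cluster_scan()` compares observed counts of inter-mutation distances in
windows \([d, d+4]\) against the per-replicate simulated counts. For a single
sample the p-value is empirical (rank of the observed count among
replicates, two-sided, with the usual \(+1\) correction); across samples the
per-window statistic is an **exact Wilcoxon signed-rank test** of
observed-minus-expected across samples, Bonferroni-corrected over windows.
Windows in which no sample has any observed distance are reported as `NA`
rather than contributing spuriously certain p-values.

Two design notes for simulation studies with this machinery:

* The minimum attainable two-sided signed-rank p-value with *n* samples is
  \(2/2^n\); at least 20 samples are needed before Bonferroni correction
  over hundreds of windows can leave anything significant.
* Per-window observed counts should be kept sparse (expected count well
  below 0.5 per sample per window, e.g. a few hundred mutations on a
  megabase-scale region) so that the signed-rank differences are driven by
  genuine excesses rather than Poisson noise.

## Exact tests and the Fisher solvers

All p-values in the package are **exact**, not asymptotic:
`fisher_exact()` sums hypergeometric probabilities not exceeding that of the
observed table; `poisson_pair_test()` is the conditional binomial test of two
Poisson counts; `wilcoxon_signed_rank_exact()` and `mann_whitney_u()`
enumerate or convolve the exact null distributions. The tests cross-check
each against brute-force enumeration.

`fisher_exact()` offers two solvers for the conditional-MLE odds ratio and
its confidence interval. `solver = "bisect"` solves the score equation and
inverts the two one-sided exact tests by bisection on the log-odds scale.
`solver = "classic"` reproduces the exact conventions of the widely used
reference implementation (`stats::fisher.test`), so published intervals can
be matched digit for digit:

```{r fisher}
unlist(fisher_exact(5, 1, 15, 185, solver = "classic"))
```

## Timing mutations against copy-number gains

In a segment with total copy number \(T\), major allele copy number \(m\),
and tumor purity \(p\), a clonal mutation present on \(m'\) copies has
expected variant allele frequency

\[ v(m') = \frac{p\,m'}{2(1-p) + p\,T}. \]

A mutation acquired **before** a gain of the major allele is carried on all
\(m\) copies (\(m' = m\)); one acquired **after** sits on a single copy
(\(m' = 1\)). `classify_epoch()` assigns each mutation to `before`, `after`
or `ambiguous` by comparing its VAF to \(v(m)\) and \(v(1)\) with a margin
expressed as a fraction of the gap \(v(m) - v(1)\) (margin 0 partitions at
the midpoint).

Because a pre-gain mutation is duplicated while a post-gain mutation is not,
raw counts must be normalized per copy: with \(n_b\) mutations called
`before` and \(n_a\) called `after`,

\[ \widehat{f}_{\text{before}} = \frac{n_b}{\,n_b + n_a / T\,}. \]

`cohort_timing_test()` then applies the exact signed-rank test of the
per-segment fractions against \(1/2\). The simulator draws each planted
mutation pre-gain with probability \(q = f / (T - f(T-1))\), which is the
count-level frequency implied by a per-copy fraction \(f\); the tests
confirm that the full pipeline returns \(f\), not \(q\).

## The synthetic-data generator: scope and mechanism

`make_genome()`, `make_tracks()` and `make_catalog()` exist so every
estimator can be validated on data with latent truth labels. The catalog
generator is **lesion-first**: damage is placed on purines on either strand
(weighted by the replication-timing surface when `timing_gradient > 1`),
lesions on the template strand of an expressed gene survive transcription-
coupled repair with probability \(1/\texttt{trb\_factor}\), and surviving
lesions convert to mutations more often on the lagging strand by
`replication_factor`. Strand asymmetries therefore *emerge from the
mechanism* rather than being painted onto the output, and every variant
carries its latent labels (`xsim_purine_strand`, `xsim_template`,
`xsim_lagging`, `xsim_cluster`) for verification.

Limitations to keep in mind: sequence is i.i.d. at a fixed GC content (no
repeats, no isochores), genes are single-exon and non-overlapping,
replication timing is a smooth deterministic surface with additive
cross-track noise, and read counts are binomial at a fixed mean depth. The
generator is a test harness with controllable, analytically tractable
structure — not a model of any real genome.

```{r session}
sessionInfo()
```
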