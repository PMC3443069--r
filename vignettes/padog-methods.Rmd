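---
title: "Down-weighting overlapping genes in gene set analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Down-weighting overlapping genes in gene set analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padog)
```

## The problem

Curated gene set collections overlap heavily: in KEGG-style pathway
collections roughly two-fifths of mapped genes belong to more than one
pathway, and a few hub genes belong to dozens. Set-scoring methods that treat
all member genes equally therefore struggle to tell *which* of several
overlapping sets is the perturbed one — differential expression in shared
genes lifts the score of every set that contains them. The method at the core
of this package (PADOG) counteracts that by weighting each gene's evidence by
how specific the gene is to the sets being scored.

## The statistic

Let $G$ be the set of genes measured on the array that map to at least one
analyzed gene set $GS_i$, $i = 1..N_{GS}$, and let $\mathcal{T}(g)$ be the
moderated t-score of gene $g$ between the two conditions. The frequency
$f(g)$ counts the sets containing $g$; frequencies above the 99th percentile
of the frequency distribution are capped at that percentile (an order
statistic, so capped frequencies stay integers). Weights are

$$w(g) = 1 + \left(\frac{f_{max} - f(g)}{f_{max} - f_{min}}\right)^{\alpha},$$

so the most ubiquitous gene gets $w = 1$ and set-specific genes get $w = 2$.
The raw set score is the weighted mean of absolute moderated t-scores,

$$S_0(GS_i) = \frac{1}{N(GS_i)} \sum_{g \in GS_i} |\mathcal{T}(g)| \, w(g),$$

standardized twice: first against the mean and standard deviation a *random*
set of the same size would attain (since $S_0$ is a mean, the central limit
theorem gives these in closed form — mean of all $|\mathcal{T}(g)|w(g)$
values over $G$ and their standard deviation divided by $\sqrt{N(GS_i)}$ —
with no random draws needed), then across the $N_{GS}$ sets of the
collection. Significance comes from permuting sample labels: the p-value of a
set is the fraction of permutations whose doubly standardized score is at
least the observed one. Each permutation is a complete re-analysis; in
particular the moderated-t variance prior is re-estimated inside every
permutation.

Two readings of the published weight formula are possible: the printed
expression is linear in frequency ($\alpha = 1$) while the surrounding text
asks for a curve that falls faster at low frequencies and the published
illustration is concave. We default to $\alpha = 0.5$ and expose `alpha_weight`
so the linear reading is one argument away. In the bundled simulation designs
frequencies take only the values 1 and 2, so this choice has no effect there.

The row-standardization denominator is read as
$\mathrm{sd}/\sqrt{N(GS_i)}$: the score is a mean of $N(GS_i)$ terms, and the
central limit theorem scales its standard deviation with the square root of
the set size. (A denominator linear in $N(GS_i)$ would make large sets'
standardized scores vanish.)

## Moderated t-scores

Gene-wise residual variances $s^2_g$ (pooled two-sample for unpaired designs,
within-block difference variance for paired ones) are shrunk toward a prior:
$\tilde{s}^2_g = (d_0 s_0^2 + d\, s^2_g) / (d_0 + d)$, with $(d_0, s_0^2)$
estimated by moment-matching the log sample variances to a scaled F
distribution — the mean and variance of $\log s^2$ relate to the prior
through digamma/trigamma functions, and the trigamma relation is inverted by
Newton iteration (tolerance $10^{-8}$, at most 50 iterations). When the
dispersion of $\log s^2$ is at or below its theoretical minimum the prior is
a point mass ($d_0 = \infty$) at the mean sample variance; with fewer than 10
usable variances the fit falls back to no shrinkage ($d_0 = 0$, logged).
Shrinkage is what keeps genes from reaching huge t-scores purely through
accidentally tiny sample variances; a zero-variance gene still gets a finite
moderated t. Per-gene p-values from the moderated t are deliberately not part
of the set scoring; they can be had from the `tidy()` output for diagnostics.

## Comparators

**Maxmean with restandardization.** Each set is scored by
$\max(\sum_j z_j^{(+)}, \sum_j |z_j^{(-)}|)/n$ over its genes' ordinary
t-scores (both sums divided by the full set size $n$). The score is then
restandardized by the mean and standard deviation the statistic would attain
on a random gene set of the same size. We compute both moments analytically:
the positive-part and negative-part set means of a random set are
asymptotically bivariate normal (finite-population-corrected CLT, with exact
cross-covariance $-m_+ m_-/n$), and the mean and variance of the maximum of a
bivariate normal pair follow Clark's formulas. An alternative is to estimate
the spread from a few hundred random set draws per permutation; the analytic
route is deterministic, orders of magnitude cheaper across a thousand
permutations, and any residual approximation error applies identically to
observed and permuted scores, so it cancels from the permutation p-value.
The permutation test is one-sided on the restandardized score, which is
non-negative-scale, so shifts in either direction register.

**Weighted Kolmogorov–Smirnov enrichment.** Genes are ranked by a
signal-to-noise ratio (moderated t available by flag; paired designs use the
paired t); a running sum gains $|m|^{p_w}/\sum_{hits}|m|^{p_w}$ at set
members and loses $1/(N - n)$ elsewhere; the enrichment score is the maximal
deviation from zero, normalized against same-signed permutation scores. This
is a faithful implementation of the classic algorithm, not a line-by-line
port of any particular distribution of it, and its p-values are nominal
permutation p-values (no FDR-by-histogram machinery).

Both comparators consume the identical permutation stream as the main method
when run with the same seed, so p-value differences between methods are
attributable to the statistic rather than Monte-Carlo noise.

## Permutation engine

Unpaired designs resample group labels uniformly while preserving group
sizes; paired designs flip case/control labels independently within blocks.
The identity labeling is excluded; when the space of distinct non-identity
labelings is no larger than the requested permutation count the engine
enumerates it exhaustively instead of sampling (logged). The p-value is the
literal fraction of permutations at or above the observed score — it can be
exactly zero — with `add_one = TRUE` switching to $(b+1)/(K+1)$ for
downstream-FDR safety. Comparisons use a $10^{-9}$ relative tolerance so
mathematically tied permutations (for equal group sizes, the complement
labeling produces identical absolute t-scores) count as ties regardless of
floating-point noise, and ties count against significance.

## What the simulations emulate

`make_null_dataset()` draws i.i.d. $N(0,1)$ expression for 1000 genes and
two groups of 50 — the standard two-group microarray simulation. The five
sensitivity scenarios inject mean shifts into the first genes of the target
set `GS1` (15 up by 0.3; 10 up/5 down by 0.3; 8 up/7 down by 0.3; 7 up/3 down
by 0.4; 5 up/5 down by 0.4), and three overlap setups control whether `GS1`'s
DE genes (setup II) or non-DE genes (setup III) are additionally placed in
`GS50`, or neither (setup I). Frequency capping is disabled inside these
simulations: with frequencies only in $\{1, 2\}$ the 99th percentile is 1 and
capping would erase the very overlap the setups construct.

The specificity study generates data entirely from $N(0,1)$ against a fixed
overlap-bearing collection, so every null is true and the fraction of set
p-values below $\alpha$ estimates the false positive rate. Since the real
pathway collection cannot be bundled, `make_overlap_collection()` draws a
synthetic stand-in with heavy-tailed gene popularity (Pareto tail), giving a
large overlapping fraction and hub genes like a curated collection; it is
synthetic and carries no biological meaning. The per-replica sample sizes are
drawn from 10–60 per group, a typical range for public two-group microarray
studies.

What these simulations do *not* emulate: inter-gene correlation,
heteroscedastic genes, batch structure, or realistic effect-size
distributions. Passing them shows the statistic's operating characteristics
under clean exchangeability — uniform null p-values and the documented
sensitivity ordering — not performance on real data, which is what the
target-pathway benchmark framework (`target_rank()`, `summarize_benchmark()`,
`compare_to_reference()`) is for once real datasets are supplied.

A note on permutation counts and thresholds: with $K$ permutations the
p-value grid is $\{0, 1/K, ..., 1\}$, and $P(p < \alpha)$ under the null is
$\lceil \alpha K \rceil / (K+1)$. Specificity runs therefore use $K = 500$,
where both 0.05 and 0.01 lie on the grid and the null rate equals the nominal
level; coarser grids bias the rate upward by construction.

## Problem sizes used in the packaged studies

The acceptance script (`scripts/acceptance.R`) runs the full study design: 50
replicates with 1000 permutations per sensitivity cell and 100 random
replicas with 500 permutations for specificity. The test suite exercises the
same code paths at reduced size (25 replicates with 500 permutations; 40
replicas over a 60-set collection), with Monte-Carlo tolerances computed from
the replicate spread of the runs themselves.

## Degenerate inputs and tie-breaks

* Sets losing all (or all but a couple of) genes on restriction to the
  measured universe are dropped with a warning; the minimum analyzable size
  defaults to 3 to avoid degenerate variance in the standardization.
* A collection whose row-standardized scores are constant yields all-zero
  standardized scores with a warning rather than NaNs.
* Zero-variance genes get infinite ordinary t (flagged), finite moderated t
  whenever $d_0 > 0$.
* Percentile ranks use average ranks on ties; this touches only benchmark
  summaries, never the p-values.
* The geometric mean of benchmark p-values floors exact zeros at
  $1/(2 N_{ite})$, logged.
* Duplicate-probe resolution (keeping the probe with the smallest p-value per
  gene) happens upstream of this package's inputs: callers supply one row per
  gene identifier.

## Known limitations

* The gene-frequency weighting defends against overlap-driven score leakage,
  not against correlated but disjoint sets.
* Gene-label (row) permutation nulls are deliberately not offered; the null
  model is sample permutation only.
* The mixed-effects rank comparison delegates to `lme4` and reports a
  normal-approximation one-tailed p for the method coefficient; for the small
  dataset panels this framework targets, the self-contained Wilcoxon path is
  the primary comparison.
* Whether frequencies should be capped before or after restricting the
  collection to measured genes is not settled by the published description;
  here capping happens after restriction, so frequencies describe the
  analyzed universe.
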