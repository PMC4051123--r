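---
title: "Methods: population analysis of deletion CNV genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of deletion CNV genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

## The data and its assumptions

cnvpop analyses *deletion-type* CNV genotype tables: one row per CNV with
its genomic interval, one column per animal with a diploid deletion
genotype — `0/0`, `0/1`, `1/1` for zero, one, or two deleted alleles, and
`./.` for a missing call. Such tables are the downstream product of
population-scale structural-variant callers (Genome STRiP and kin); cnvpop
deliberately starts *after* discovery and genotyping, so caller-internal
quality filters are out of scope. The only filter applied here is
genotype completeness: a CNV whose genotype could not be determined in
every sampled animal carries no usable population information and is
dropped (`complete_genotype_filter()`).

Coordinates are 1-based inclusive internally — the convention of Ensembl
gene exports, Animal QTLdb, and the genotype tables this package was built
around. Whether a given supplementary table is 0- or 1-based is rarely
documented; cnvpop assumes 1-based and converts only at BED boundaries
(0-based half-open), where the convention is unambiguous. CNV length is
`end − start + 1` under this convention; a `length_mode = "span"` switch
(`end − start`) is available in `summarize_callset()` because source
tables generated under the other convention would otherwise be biased by
one base per CNV.

## Gene deletion scores

Each CNV contributes its number of *carrier* individuals — animals with at
least one deleted allele — and a gene's score is the sum over all CNVs
overlapping its span:

$$\mathrm{score}(g) = \sum_{n=1}^{l} \#\mathrm{Deletion}(\mathrm{CNV}_n),
\qquad \#\mathrm{Deletion} \in \{0, \dots, N\}.$$

Counting carriers rather than alleles is forced by the stated 0..N range
of the per-CNV count with N animals; an allele-dosage mode (range 0..2N)
is available via `score_mode = "allele"` for sensitivity analysis. Genes
are taken as whole loci (start to end), not exon unions, since deletion
burden in introns is part of the signal of interest. A CNV spanning k
genes contributes to all k — the score is a per-gene definition, and
de-duplicating would silently redefine it.

Significance uses the score distribution itself: a normal with the sample
mean and sample standard deviation (denominator n − 1; at n in the
hundreds-plus the choice is immaterial) is fitted to the genome-wide score
vector and each gene receives the upper-tail probability
$1 - \Phi((s - \hat\mu)/\hat\sigma)$. Genes with p < 0.01 form the
candidate set. This is a *distribution-fit* tail probability, not a
rank-based empirical p-value; a rank option would differ in the extreme
tail (granularity 1/n) and is intentionally not the default, because the
normal fit is the procedure this pipeline standardises. Degenerate inputs
(< 3 scored genes, zero spread) make the fit meaningless:
`normal_tail_pvalues()` refuses them, and `gene_deletion_scores()`
degrades to NA p-values with a warning so small exploratory runs still
return scores.

## QTL deletion density

QTL lengths span 1 kb to > 100 Mb, and longer QTL accumulate deletion
score in proportion to length, so raw scores cannot rank QTL. The density
statistic is therefore the *average distance between deletions*:

$$\mathrm{avg\_distance} = \frac{\mathrm{QTL\ length}}{\mathrm{deletion\ score}},$$

in bases per carrier-deletion; small values mean dense burden. The score
in the denominator reuses the gene formula unchanged. No distributional
significance model is attached: the heavy, length-driven tail of this
statistic does not admit a usable null here, so a fixed top-k (default
k = 30, smallest distances first, ties broken by larger score then id) is
reported instead. QTL overlapping no CNV are excluded rather than given
infinite distance.

## The F_ST selection scan

Differentiation between the two breeds is measured per CNV with Nei's
heterozygosity form of Wright's fixation index. With deletion-allele
frequency $p_j$ in breed $j$, $q_j = 1 - p_j$, and subpopulation weights
$c_j$:

$$H_\mathrm{obs} = \sum_j c_j \, 2 p_j q_j, \qquad
  H_\mathrm{exp} = 2 \bar p \bar q, \qquad
  F = \frac{H_\mathrm{exp} - H_\mathrm{obs}}{H_\mathrm{exp}}.$$

Design choices, each exposed as an argument:

* **Weights** $c_j = n_j / N$ (22/32 and 10/32 by default): the relative
  sizes of the sampled subpopulations are the only sizes available.
  `weights = "equal"` gives $c_j = 1/2$.
* **$\bar p$ is the $c$-weighted mean** of the $p_j$. With the weighted
  mean, $H_\mathrm{exp} - H_\mathrm{obs} = 2\,\mathrm{Var}_c(p)$ exactly,
  so $F = \mathrm{Var}_c(p) / (\bar p \bar q) \in [0, 1]$ — an identity
  the test suite checks to 1e−12 on random inputs as an independent
  oracle. An unweighted-mean option exists for sensitivity but can place
  F outside [0, 1] when weights are uneven.
* **Monomorphic CNVs** ($H_\mathrm{exp} = 0$) have undefined F. They are
  flagged and *excluded from the p-value pool* rather than assigned p = 1,
  so they cannot distort the fitted null.

Significance mirrors the deletion-score procedure: by default a normal
fit to the defined F vector with upper-tail p-values, then
Benjamini–Hochberg adjustment and a significant set at q ≤ 0.01
("less than 0.01" is honoured as ≤ at machine precision; strict <
differs only on exact ties). A `method = "rank"` alternative defines
$p_i = \#\{F \ge F_i\} / n$. A caveat worth stating plainly: rank
p-values of this form satisfy $p_{(i)} \ge i/n$ for the $i$-th order
statistic, so every BH-adjusted value is ≥ 1 and the rank-method
significant set is empty at any FDR level below 1, on any data. The rank
option is therefore useful for p-value diagnostics, not for FDR-gated
selection; the normal method is the operational default and is what the
planted-signal recovery checks exercise.

## Breed-specific CNVs

A CNV is *putatively* breed-specific when its deletion allele is observed
in exactly one breed — an observed-genotype criterion over the sampled
animals, deliberately not an inference about the population. Because a
small sample easily misses a low-frequency allele in the other breed, a
confirmation filter retains only calls whose deletion frequency in the
carrier breed strictly exceeds 0.1. "Frequency" defaults to allele
frequency (alleles / 2n), the same $p_j$ as the F_ST stage — one shared
implementation — with a carrier-fraction mode (carriers / n) behind
`freq_mode` since the threshold's intended scale is not self-evident.
Gene assignment defaults to direct overlap (flank = 0), with a
configurable flank for nearby-gene reporting; the restrictive default
reflects that only a minority of breed-specific CNVs are expected to be
genic.

## The synthetic-data generator

`simulate_callset()` emulates the two-breed study design so every stage
has a no-download test surface with known truth:

* **Sample sizes** default to 22 + 10 (Hanwoo/Holstein).
* **Genotypes** are Hardy–Weinberg draws within breed: dosage ~
  Binomial(2, p) given the breed's true deletion frequency. HWE within
  breed is the minimal standard null and matches the allele-frequency
  definitions used by the F_ST stage; it is an assumption, not an
  observation about real call sets.
* **Background CNVs** share one Beta(0.8, 0.8)-distributed frequency
  across breeds (mildly U-shaped, as allele-frequency spectra tend to
  be); **differentiated** CNVs get a planted gap |p₁ − p₂| = delta
  (default 0.8, the gap used by the recovery checks); **breed-specific**
  CNVs have frequency 0 in one breed and uniform in [0.02, 0.6] in the
  other, straddling the 0.1 confirmation threshold so both outcomes are
  exercised; **monomorphic** CNVs are fixed `1/1`. Default planted
  fractions (1.5% differentiated, 11% / 3% specific, 0.03% monomorphic)
  echo the composition reported for real two-breed cattle call sets of
  this size.
* **Intervals**: lengths are log-normal with mean 2,732 bp (sdlog 0.75) —
  parameterised on the mean, the moment reported for the motivating call
  set — placed uniformly on 29 approximate cattle autosomes (~2.51 Gbp);
  at the default 6,811 CNVs this reproduces the ~18.6 Mbp / ~0.74%-of-
  genome scale. No overlap constraint is imposed; real CNV calls can
  overlap.
* **Missingness** is independent per cell (default 0: the emulated table
  is post-completeness-filter).
* **Seeding**: one integer seed drives named sub-streams (frequencies,
  genotypes, intervals, missingness, features), so enlarging one
  component does not perturb the others and fixtures stay stable.

`simulate_features()` places genes/QTL so that planned features overlap
exactly their planned CNVs (the minimal covering interval, randomly
padded up to the nearest conflicting CNV; unsatisfiable plans error) and
all other features fall in CNV-free gaps, yielding an exact truth map for
overlap tests.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
between CNVs, genotyping error correlated with depth or length,
deviations from HWE (inbreeding is plausible in breed populations),
overlap structure between CNVs and real gene density. Recovery results on
synthetic data are statements about the estimators under the stated
model.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes —
call sets of 200–2,000 CNVs for property checks, the full default 6,811
for the study-scale summary, 20 seeds for recovery rates, 10⁴ random
configurations for the algebraic F oracle — sizes at which every check
completes in seconds while binomial sampling error is still well below
the effects being detected. Ties in `top_qtl` and
`select_significant_genes` break deterministically (score, then id) so
outputs are stable across platforms. The pipeline writes a manifest with
md5 checksums of all inputs and the parameter set, making reruns
verifiable byte-for-byte.

## Known limitations

* Two breeds only in the F_ST reporting path (the `nei_fst()` core
  accepts J subpopulations, but scan and breed-specific stages require
  exactly two labels).
* Deletions only: the genotype model has no amplification states.
* The normal fit for score and F tails is a pragmatic standardisation,
  not a claim that either statistic is normal; extreme-tail p-values
  inherit the fit's inaccuracy there, which is why selection thresholds
  (0.01) sit well inside the calibrated range.
* No significance model for QTL density (by design, see above).
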