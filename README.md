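# cnvpop

Population-level analysis of **deleted copy number variants (CNVs)** in two
breeds, starting from a per-sample deletion genotype table of the kind
produced by population-scale callers such as Genome STRiP. The motivating
use case is contrasting a beef breed (Hanwoo, n = 22) against a dairy breed
(Holstein, n = 10) to find genes, QTL and individual CNVs shaped by
domestication and breed formation — but any two-subpopulation deletion
call set in the same layout works.

Each CNV carries one genotype per animal: `0/0` (no deleted allele), `0/1`
(single deletion), `1/1` (double deletion), or `./.` (missing). From a
filtered call set the package computes:

* **Call-set summaries** — counts, mean/total length, percent of genome,
  CNVs shared between breeds, one-breed CNVs, monomorphic CNVs.
* **Gene deletion scores** — for gene *g* overlapped by CNVs 1..*l*,

  ```
  score(g) = Σₙ₌₁..ₗ  #Deletion(CNVₙ)
  ```

  where `#Deletion` is the number of carrier individuals (genotype `0/1`
  or `1/1`, range 0..N). Tail probabilities come from a normal
  distribution fitted to the genome-wide score vector; genes with
  p < 0.01 are flagged as candidate domestication targets.
* **QTL deletion density** — the *average distance between deletions*,
  QTL length / deletion score; the top 30 densest QTL are reported.
* **F_ST selection scan** — Nei's heterozygosity form per CNV:

  ```
  H_obs = Σⱼ cⱼ · 2 pⱼ qⱼ ,   H_exp = 2 p̄ q̄ ,   F = (H_exp − H_obs) / H_exp
  ```

  with deletion-allele frequencies pⱼ, subpopulation weights
  cⱼ = nⱼ / N, and p̄ the c-weighted mean frequency. Upper-tail p-values
  (normal fit by default, rank-based optionally) are FDR-adjusted by
  Benjamini–Hochberg; CNVs with q ≤ 0.01 form the putative selective-sweep
  set.
* **Breed-specific CNVs** — deletion allele observed in exactly one breed
  (putative), confirmed when its allele frequency there exceeds 0.1, with
  optional gene assignment within a configurable flank.
* **A synthetic-data generator** — Hardy–Weinberg genotypes per breed with
  planted differentiated / breed-specific / monomorphic CNVs and gene/QTL
  tracks with planned overlaps, returning the ground truth for recovery
  testing.

## Worked example

The selection scan on a single CNV where 13 of 22 Hanwoo are `1/1`, 9 are
`0/1`, and 3 of 10 Holstein are `0/1` (the rest `0/0`):

```r
library(cnvpop)
geno <- c(rep(2L, 13), rep(1L, 9), rep(1L, 3), rep(0L, 7))
cs <- CallSet(
  records   = data.frame(cnv_id = "cnv_galk2", chrom = "chr10",
                         start = 20000000, end = 20003000),
  samples   = data.frame(sample_id = sprintf("s%02d", 1:32),
                         breed = rep(c("Hanwoo", "Holstein"), c(22, 10))),
  genotypes = matrix(geno, nrow = 1))
fst_scan(cs)
#>      cnv_id chrom start      end p_Hanwoo p_Holstein    H_obs    H_exp      fst
#> 1 cnv_galk2 chr10 2e+07 20003000 0.795455       0.15 0.303409 0.482422 0.371071
```

The Hanwoo deletion frequency is (2·13 + 9)/44 = 0.795, Holstein is
3/20 = 0.15, and the breed contrast yields F = 0.371 — strong
differentiation relative to a genome-wide null concentrated near 0.

A full synthetic study under the default design (6,811 CNVs, 22 + 10
samples, 29 autosomes):

```r
sim <- simulate_callset(sim_config(seed = 42))
cs  <- complete_genotype_filter(sim$callset)
summarize_callset(cs, with(cattle_autosomes(), setNames(length, chrom)))
#> CNV call-set summary
#>   CNVs:            6811
#>   mean length:     2715.0 bp
#>   total:           18.49 Mbp
#>   % of genome:     0.74%
#>   shared (all breeds):  5356
#>   one breed only:       1255
#>   zero carriers:        200
#>   monomorphic:          354
```

`run_pipeline("config.yaml")` chains every stage (filter → summary → gene
scores → QTL density → F_ST → breed-specific) and writes TSV/BED outputs
plus a checksummed manifest; `inst/scripts/cnvpop.R` wraps `simulate` and
`run` for shell use.

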