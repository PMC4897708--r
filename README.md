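# largv

LD-Adjusted Regional Genetic Variance: estimate the phenotypic variance
explained by a genomic region from GWAS summary statistics, accounting for
linkage disequilibrium (LD).

## The problem

Complex-trait variance is spread over many weak associations that cluster in
regions, but regional (multi-SNP) variance cannot be read off GWAS summary
statistics directly: correlated SNPs share signal, so the naive sum of
squared effects counts the same variance many times. `largv` implements a
summary-statistic estimator for regional variance that deflates each SNP's
contribution by its local LD. For a SNP *d* with standardized univariate
effect *b<sub>d</sub>* and LD adjustment

&nbsp;&nbsp;&nbsp;&nbsp;η<sub>d</sub> = Σ<sub>|k−d| ≤ w</sub> r²<sub>d,k</sub>
(*w* = 100 SNPs by default, self term included),

the variance explained by a region *R* is estimated as

&nbsp;&nbsp;&nbsp;&nbsp;ρ̂²<sub>R</sub> = Σ<sub>d∈R</sub> b<sub>d</sub>²/η<sub>d</sub> − σ̂²<sub>e</sub> Σ<sub>d∈R</sub> 1/(η<sub>d</sub>(N−1)),

where the second term centres the estimate at zero under the null and
σ̂²<sub>e</sub> is the trait's residual variance estimated from the full
table. Genome-wide this equals 1 − (1 − Σb²/η)(N−1)/(N−1−m<sub>eff</sub>):
the expected adjusted R² of a joint regression, with the SNP count replaced
by the effective marker count m<sub>eff</sub> = Σ 1/η<sub>d</sub>. The
estimator is asymptotically equivalent to summing per-block multiple-
regression adjusted R² (which needs individual-level data) when effects are
strictly additive, and it is exactly invariant to duplicating SNPs in
perfect LD.

The package also provides:

- a greedy partitioner that cuts each chromosome arm into contiguous SNP
  blocks (e.g. 85–95 SNPs) minimizing the maximal cross-boundary r²;
- the individual-level comparator (per-block OLS adjusted R², phenotype
  residualization, genetic principal components);
- a resampling enrichment test for excess regional variance around a locus
  (e.g. ±7.5 Mb of a linkage peak) against SNP-count-matched random windows;
- a genotype/phenotype simulator with controllable LD (independent, AR(1),
  blockwise) for end-to-end validation;
- PLINK bed/bim/fam and VCF readers, QC filters (missingness, MAF,
  Hardy-Weinberg exact test), TSV round-trips, and a CLI.

Intended users: statistical geneticists ranking genomic regions by variance
explained, or testing candidate regions, when only meta-analysis summary
statistics plus an LD reference panel are available.

## Worked example

Simulate a 2,000-individual, 300-SNP panel with strong local LD, a trait
with 20% regional heritability, run the GWAS, and estimate the variance
back from the summary statistics alone:

```r
library(largv)

panel <- simulate_genotypes(2000, 300, ld_ar1(0.8), seed = 42)
std   <- standardize_genotypes(panel)
ld    <- ld_windowed_r2(std, window = 100)
eta   <- ld_eta(ld)

trait <- simulate_trait(std, h2 = 0.2, seed = 7)
stats <- gwas(std, trait)                      # per-SNP b, se, p, N

aligned <- harmonize(stats, eta, panel_meta = panel$snp_meta)
estimate_region(aligned, region_id = "genome")
#> <regional_estimate> genome
#>   300 SNPs (m_eff 134.1), N = 2000
#>   variance explained: 0.2449  [0.1954, 0.2945] (analytic CI)
```

The estimate (0.24, 95% CI 0.20–0.29) recovers the simulated 0.20 within
its sampling noise, despite each causal SNP being counted through many
correlated neighbours. The individual-level comparator agrees:

```r
blocks <- partition_blocks(ld, min_size = 20, max_size = 30)
sum_adjusted_r2(std, blocks, trait$y)
#> <oracle_fit> 11 blocks, total adjusted R-squared 0.2035
```

Ranking blocks and testing a window for excess variance:

```r
rank_blocks(aligned, blocks) |> glance()
#> # A tibble: 1 x 4
#>   n_blocks total_estimate top25_share min_p_genome
#>      <int>          <dbl>       <dbl>        <dbl>
#> 1       11          0.245       0.434     6.27e-11

enrichment_test(aligned, "1", 750000, half_width = 1e5,
                n_resample = 999, seed = 1)
```

`tidy()`, `glance()` and `autoplot()` methods are available on estimates,
rankings, enrichment tests and oracle fits. A command-line wrapper lives at
`system.file("cli", "largv", package = "largv")` with subcommands
`simulate`, `adjust`, `make-blocks`, `estimate`, `oracle`, `enrich`.

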