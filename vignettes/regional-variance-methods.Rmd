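---
title: "Estimating regional genetic variance from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating regional genetic variance from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(largv)
```

## The model

Let $X$ be an $n \times m$ genotype matrix with columns standardized to
mean 0 and SD 1 (population-SD convention, denominator $n$, so that
$X'X/n$ is exactly the sample correlation matrix), and let the trait $Y$
be standardized with unit variance. Under a strictly additive model
$Y = X\beta + \varepsilon$ — no interaction or haplotype effects — with
random SNP effects $\beta_i$ of mean zero and variance $\sigma^2$ on the
order of $1/M$ for $M$ genome-wide SNPs, the univariate GWAS coefficient
of SNP $d$ is $b_d = x_d'y/n$, the quantity reported (with its standard
error and $N$) in summary-statistics files.

Squaring $b_d$ and summing over a region overcounts: every causal signal
is picked up by each of its LD partners. The LD adjustment for SNP $d$ is

$$\eta_d \;=\; \sum_{k:\,|k-d| \le w} r^2_{d,k},$$

the sum of squared correlations with every SNP at most $w$ positions away
on the same chromosome arm, *including the self term* $r^2_{d,d}=1$ (so
$\eta_d \ge 1$, with equality in linkage equilibrium). The default window
$w = 100$ SNPs assumes loci more than 100 SNPs apart are effectively
unlinked; it is a tunable parameter. Pairs that span a chromosome (or
arm) boundary are treated as unlinked. The key identity is that, within
the window, the diagonal of $R^2$ equals $\eta$: for the infinitesimal
model, $E\!\left[\sum_d (R\beta)_d^2/\eta_d\right] = \sigma^2 \sum_d
(R^2)_{dd}/\eta_d = \sigma^2 m$, exactly the expected genetic variance.
This is why the per-SNP contribution $b_d^2/\eta_d$ sums to an unbiased
regional variance no matter how strong the LD — and why duplicating every
SNP (each $\eta$ doubles, each $b$ is copied) leaves the sum unchanged.

## The noise centring and its degrees-of-freedom form

$E[b_d^2]$ exceeds the true squared marginal effect by the sampling
variance of $b_d$, which for a variance-1 trait is exactly $1/(n-1)$
under the null and $\sigma^2_e/(n-1)$ in general, where $\sigma^2_e$ is
the trait's *residual* (non-genetic) variance. The centred estimator is

$$\hat\rho^2_R \;=\; \sum_{d \in R} \frac{b_d^2}{\eta_d}
  \;-\; \hat\sigma^2_e \sum_{d \in R} \frac{1}{\eta_d\,(n_d-1)},$$

with $\hat\sigma^2_e = (1 - \mathrm{raw})/(1 - C)$ estimated once from
the full table ($\mathrm{raw}$ the genome-wide LD-adjusted sum, $C =
\sum_d 1/(\eta_d (n_d - 1))$). Three consequences:

* **Exact null centring.** $E[b_d^2] = E[\hat\sigma^2_e]/(n-1)$ under the
  null, so the genome-wide null expectation is exactly zero — mirroring
  the fact that the expected adjusted $R^2$ of a null block is zero.
* **The adjusted-$R^2$ form.** Genome-wide the estimator collapses to
  $1 - (1-\mathrm{raw})\frac{N-1}{N-1-m_\mathrm{eff}}$ with
  $m_\mathrm{eff} = \sum_d 1/\eta_d$: the Wherry adjusted-$R^2$ formula
  with the number of regressors replaced by the effective number of
  markers. $m_\mathrm{eff}$ equals $m$ without LD and is strictly smaller
  under any LD.
* **Exact additivity.** Because $\hat\sigma^2_e$ is shared, estimates over
  disjoint SNP sets of the same table sum exactly to the estimate of
  their union; per-block estimates telescope to the genome-wide value.

A flat correction $m_\mathrm{eff}/N$ (i.e. $\sigma^2_e \equiv 1$) is what
one obtains from the null alone; it over-subtracts by
$h^2 m_\mathrm{eff}/N$ when signal is present. We measured this directly:
at $h^2=0.2$, $N=5000$, $m=500$ under blockwise LD, the flat form biases
the estimate by $-0.005$ while the residual-scaled form is unbiased to
within one Monte-Carlo SE. Supplying `sigma2_e = 1` to
`estimate_region()` restores the flat behaviour.

### Debiased $\eta$

A sample $r^2$ between two truly unlinked SNPs has expectation
$\approx 1/n$, and $\eta_d$ sums up to $2w$ such terms, inflating it by
$\approx 2w/n$ (4% at $n = 5000$, $w = 100$) and deflating every
contribution correspondingly. `ld_eta()` therefore subtracts the null
bias per pair, flooring at zero:
$\max\{0,\; r^2 - (1-r^2)/(n-2)\}$. The floor keeps $\eta \ge 1$ and
leaves exact values untouched (a perfect proxy still contributes 1, an
exactly orthogonal pair still contributes 0). `debias = FALSE` gives the
plain sum. The banded $r^2$ store itself is never modified.

## Variance bound and confidence intervals

The sampling variance of the regional estimate is bounded by

$$\widehat{\mathrm{Var}} \;\le\;
  \frac{2\,m_\mathrm{eff}/N^2 + 4\max(\hat\rho^2, 0)/N}
       {(1 - m_\mathrm{eff}/(N-1))^2}.$$

The first numerator term is near-exact for Gaussian nulls in linkage
equilibrium (it equals $2\sum 1/\eta_d / N^2 \ge 2\sum 1/\eta_d^2 / N^2$,
the actual null variance, with equality only when all $\eta = 1$) and
conservative under LD; the second covers the signal–noise cross term; the
denominator propagates the degrees-of-freedom rescaling. Analytic 95%
intervals are $\hat\rho^2 \pm 1.96\sqrt{\widehat{\mathrm{Var}}}$; they are
conservative by construction (null coverage measured ≥ 95%).

For genome-wide sums a delete-one-block jackknife over a partition is
available (`ci = "jackknife"`, ≥ 30 blocks). The jackknife targets the
*total*; over $J$ independent, identically distributed blocks its
absolute width grows as $\sqrt{J}$ while the width per block shrinks as
$1/\sqrt{J}$ — the latter is what the scaling test checks. Both the
analytic and the resampling construction are provided and labelled, and
neither is claimed to replicate any previously published interval
construction exactly.

## Block partitioning

Regional sums need region boundaries that do not cut through LD, or
signal "spills" between neighbouring blocks. The partitioner is greedy:
starting from the low-coordinate end of each arm, every admissible
cut-point (block sizes between `min_size` and `max_size`) is scored by
the maximal $r^2$ over stored SNP pairs straddling the boundary, and the
cut with the smallest maximum wins, ties going to the smallest index so
partitions are byte-reproducible. The procedure repeats until the arm is
exhausted; a terminal remainder shorter than `min_size` is merged into
the last block (which may therefore exceed `max_size` by less than
`min_size`). Typical operating points are 85–95 or 195–205 SNPs per
block. The greedy first cut provably coincides with exhaustive
enumeration over admissible cuts (it *is* exhaustive per boundary); this
is re-verified against an independent brute-force enumeration in the
tests. Global (dynamic-programming) optimality is a non-goal: the
sequential algorithm is the reference behaviour.

## The individual-level comparator

With genotypes in hand, the variance explained by a block is the adjusted
$R^2$ of the OLS regression of the (residualized) trait on all its SNPs,
$1 - (1-R^2)(n-1)/(n-m-1)$, whose null expectation is zero; the genome
total is the sum over blocks. Rank-deficient blocks (perfect within-block
LD) drop redundant columns, with $m$ counted as retained columns so the
null centring is preserved. Phenotype preparation mirrors standard GWAS
practice: percentile trimming (default 1st–99th) against outliers, then a
single regression on covariates (age, sex, genetic principal components —
eigenvectors of $XX'/m$ with a deterministic sign convention), then
z-scoring. Residualizing once, rather than inside every block model, is
an approximation that keeps per-block fits cheap; it is exact when
covariates are orthogonal to genotypes.

The summary-statistic estimator and this comparator are asymptotically
equivalent in expectation. Per *realization* the two need not converge
under extreme LD: with strongly equicorrelated blocks the summary sum
weighs the block's leading principal component while the joint fit
captures the whole realized block variance, so their difference retains
an $O(h^2)$ spread at any $N$ even though the means agree. Under
moderate LD (e.g. AR(1) with $\rho = 0.5$) the mean absolute gap shrinks
roughly as $1/N$: 0.040 at $N = 2{,}000$, 0.014 at $5{,}000$, 0.0054 at
$20{,}000$ for $h^2 = 0.2$, $m = 500$ (quantities the acceptance script
recomputes).

## Enrichment of extended regions

`enrichment_test()` asks whether a window (default ±7.5 Mb around a
locus, e.g. a linkage-peak marker) carries more variance than a typical
stretch of genome. The null reference resamples contiguous windows with
the *same SNP count* at random genome positions — SNP-count matching
equalizes the null because the estimator's variance scales with
$m_\mathrm{eff}$, which tracks SNP count. The excess is the window
estimate minus the reference mean; the two-sided p-value uses the
$(r+1)/(R+1)$ tail correction; the CI shifts reference quantiles to the
excess scale. Resampling is seeded and the seed stored. Null p-values are
uniform up to the discreteness of the resampling grid.

## The simulator: what it emulates, and what it does not

`simulate_genotypes()` draws haplotypes by thresholding a latent Gaussian
with one of three correlation structures — independent, AR(1) (geometric
decay, no block boundaries), equicorrelated blocks (clean boundaries at
known positions) — at per-SNP frequency quantiles (MAF uniform on
0.05–0.5 by default), and sums two haplotypes per genotype. This gives
exact control of LD shape and allele frequency at $O(nm)$ cost. It does
*not* emulate coalescent genealogies, recombination hotspot fine
structure, rare variants, population stratification (beyond a
two-population check for the PC code), or genotyping error — so passing
tests demonstrate correctness of the estimator under its stated model,
not robustness to every property of real cohort data.

`simulate_trait()` draws Gaussian effects for the causal SNPs (all SNPs
by default — the infinitesimal model matching the random-effects
derivation), rescales them so the realized $\mathrm{Var}(X\beta)$ equals
`h2` exactly, and builds the residual orthogonal to the genetic value
with realized variance exactly $1 - h^2$. Recovery tests therefore
compare against a noiseless "realized truth". One subtlety found while
validating: conditioning $\beta$ on its realized variance adds a small
$N$-independent Jensen-type offset ($\approx -0.002$ at $h^2 = 0.2$) to
the summary-vs-oracle comparison under strong blockwise LD; it is
invisible under moderate LD and irrelevant to estimator bias against
realized truth.

Monomorphic columns, possible at small $n$, are redrawn as independent
Bernoulli(maf) columns so every simulated SNP is polymorphic.

## Numerical and interface choices

* Standardization uses the population-SD convention throughout; missing
  dosages are mean-imputed before standardization (QC defaults cap
  missingness at 2%, bounding the impact).
* The banded LD store keeps lags $1..w$ per SNP; for $m \le 4000$ a
  single `crossprod` fills it, above that a per-lag loop bounds memory.
* Monomorphic SNPs are rejected with the offending SNP named; QC
  (`apply_qc()`) filters in a fixed order — individual missingness, SNP
  missingness, MAF ≥ 0.02, Hardy-Weinberg exact test $p \ge 10^{-6}$ —
  with per-criterion counts reported. The HWE test is the exact
  conditional (full enumeration) test, mid-p off.
* Harmonization matches by SNP id, aligns alleles against the LD panel
  (sign flips for swapped alleles, drops for mismatches, optional drop of
  strand-ambiguous A/T and C/G SNPs), and supports three effect scales:
  standardized (`beta`), per-allele (`raw`, rescaled by
  $\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}/\mathrm{sd}_Y$), and `z`
  ($b = z/\sqrt{n}$ — the recommended mode for meta-analysis input with
  unknown trait units, for which the noise term reduces exactly to
  $m_\mathrm{eff}/N$).
* With per-SNP sample sizes the noise term is summed SNP-wise,
  $\sum \hat\sigma^2_e / (\eta_d (n_d - 1))$.
* Chromosome arms default to whole chromosomes; an optional
  centromere table splits them, and LD pairs never span an arm boundary.

## Problem sizes used in the validation suite

The test suite and acceptance script run at desk scale on one CPU: null
calibration with $n = 2000$, $m = 300$, 500 replicates; recovery with
$n = 5000$, $m = 500$, 200 replicates per heritability; equivalence at
$N \in \{2000, 5000, 20000\}$ (100 replicates each) plus a per-block
correlation check at $N = 10{,}000$; variance-bound dominance with
$2 \times 10^4$ null replicates (the bound is near-exact at independence,
so the empirical comparison needs that precision); enrichment calibration
over 500 null draws of a 1200-SNP genome and power over 100 replicates at
$N = 5000$. A full run takes a few minutes.

## Known limitations

* Continuous traits only; no liability-scale conversion for binary
  traits.
* LD must come from a panel matching the GWAS population; the method is
  robust to moderate misspecification but not immune. η can be computed
  from any genotype panel read via PLINK/VCF.
* Effects reported on unknown or heterogeneous scales should use the
  `z` mode; the `beta` mode assumes standardized-trait effects.
* Regions are sets of SNPs *with summary statistics*; SNPs absent from
  the GWAS are excluded from sums (and counted in messages), not imputed.
* Joint/conditional re-estimation of effect sizes from summary statistics
  is deliberately out of scope: regional variance estimated that way is
  highly sensitive to LD misspecification.
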