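---
title: "Region-region interaction testing by LD contrast: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-region interaction testing by LD contrast: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Exhaustive SNP-by-SNP interaction scans in case-control GWAS pay a brutal
multiple-testing price: with $10^6$ genotyped SNPs there are $\sim 5\times
10^{11}$ pairs, pushing the Bonferroni threshold to the order of $10^{-13}$
and leaving moderate epistatic effects undetectable. Genes and regulatory
units, however, span many SNPs, and nearby SNPs are strongly correlated
through linkage disequilibrium (LD). `regionepi` tests interaction at the
level of *region pairs*: it aggregates all cross-region SNP-pair
interaction statistics into one region-level p-value, cutting the number
of tests by orders of magnitude while exploiting — rather than ignoring —
the LD among the pair statistics.

## The pair-level statistic: LD contrast

For two SNPs coded additively ($0/1/2$ = minor-allele dose), composite LD
is the phase-free surrogate for gametic LD; operationally it is
proportional to the sample covariance of the genotype codes, and after
standardization it equals their Pearson correlation. If two loci
contribute jointly to disease, their association pattern differs between
affected and unaffected individuals, so the package contrasts composite
LD across the two phenotype groups:

$$\Delta LD_{XY} = \widehat{cov}(X, Y \mid case) -
  \widehat{cov}(X, Y \mid control), \qquad
  T_{XY} = \frac{\Delta LD_{XY}}{\sqrt{\widehat{Var}(\Delta LD_{XY})}},$$

and $T_{XY}^2$ is referred to a 1-df $\chi^2$ distribution. Any constant
rescaling of the LD measure (e.g. covariance versus half-covariance
conventions) cancels in $T$, which is why the package works directly with
the unbiased sample covariance of the codes and never phases haplotypes.

The denominator is computed analytically, not by resampling. For
independent samples of size $n$,

$$cov\left[\widehat{cov}(X,Y), \widehat{cov}(U,V)\right]
  = \frac{1}{n}\left(\delta_4 - \delta_2 +
    \frac{\sigma_2 + \tau_2}{n-1}\right),$$

with $\delta_4 = E[(X-EX)(Y-EY)(U-EU)(V-EV)]$, $\delta_2 =
cov(X,Y)\,cov(U,V)$, $\sigma_2 = cov(X,U)\,cov(Y,V)$, $\tau_2 =
cov(X,V)\,cov(Y,U)$. Setting $(U,V) = (X,Y)$ gives the variance of one
sample covariance; the general form gives the covariance between the
$\Delta LD$ statistics of two different SNP pairs. Because cases and
controls are independent, the covariance of two $\Delta LD$s is the sum of
the case-group and control-group terms, each with its own group size and
group-centered moments. The test suite validates this formula against
brute-force Monte-Carlo (the empirical covariance of sample covariances
over $10^5$ replicates) for three generating distributions, including a
shared-variable case, and against the bivariate-Gaussian closed form
$(\sigma_x^2\sigma_y^2 + \sigma_{xy}^2)/(n-1)$.

### Moment estimation choices

* $\delta_4$ uses the plug-in sample mean with sample-mean centering. Its
  finite-sample expectation is a known mixture
  $a_n\delta_4 + b_n(\delta_2+\sigma_2+\tau_2)$ with $a_n \to 1$; the
  package does not invert it by default because the estimator is already
  asymptotically unbiased at GWAS sample sizes, but
  `bias_correct_delta4 = TRUE` performs the inversion for sensitivity
  checks.
* $\delta_2, \sigma_2, \tau_2$ use unbiased ($n-1$) sample covariances,
  group-wise.
* The per-group variance in the test denominator uses each group's own
  plug-in moments (no pooling under the null). A null-pooled variant would
  also be defensible; per-group estimation keeps the variance and the
  $\Sigma$ matrix below internally consistent — both are entries of the
  same analytic covariance evaluated on the same group splits.

## The region-level test

For regions with $k_1$ and $k_2$ usable SNPs, all $m = k_1 k_2$
cross-region pair statistics are computed, along with their $m \times m$
correlation matrix $\Sigma$ from the formula above (unit variances make
covariances equal correlations). The observed minimum pair p-value is
mapped to the threshold $T = |\Phi^{-1}(\min_i p_i / 2)|$ — through the
p-values rather than the raw statistics, which matters when the estimated
variances differ across pairs — and the region-level p-value is

$$p_{region} = 1 - \Pr\left[\,|z_i| < T,\ i = 1..m \;\middle|\;
  z \sim MVN(0, \Sigma)\right].$$

The rectangle probability is evaluated with the Genz–Bretz randomized
quasi-Monte-Carlo integrator (`mvtnorm::pmvnorm`) under a fixed,
user-supplied seed, so identical inputs reproduce identical p-values to
the last bit. Defaults: absolute tolerance $10^{-4}$; when a first pass
returns $p < 10^{-3}$ with an error estimate above 10% of $p$, the
tolerance is tightened adaptively ($\approx p/20$) and the integration
repeated. Simulation drivers disable the adaptive pass — a rejection
decision at $\alpha \ge 0.01$ never needs 10% relative error at
$p = 10^{-8}$ — and run at tolerance $10^{-3}$ with a bounded point
budget, which keeps a 1000-replicate calibration run under ten minutes on
one core.

### Numerical safeguards

* **Degenerate SNPs.** A SNP monomorphic within either phenotype group has
  an undefined pair statistic; such SNPs are excluded from the region with
  a message, and a region left empty raises an error.
* **PSD repair.** The estimated $\Sigma$ is symmetrized, entries clipped
  to $[-1, 1]$, and — if its smallest eigenvalue falls below $-10^{-8}$ —
  repaired by clipping negative eigenvalues at zero and re-normalizing to
  unit diagonal. Eigenvalue clipping (rather than an iterative
  nearest-correlation algorithm) is deterministic, cheap, and sufficient:
  the MVN integral only needs a valid covariance. The pre-repair minimum
  eigenvalue and a repair flag are recorded on the result.
* **Underflow.** Pair p-values at or below the double floor are clamped to
  the smallest positive double with a message before the quantile map.
* **Ties** in the minimum p-value break to the lowest pair index; the pair
  ordering is row-major (region-1 SNP outer, region-2 SNP inner) and
  documented, so $\Sigma$ indices are reproducible.
* **Dimension-1 short-circuit.** $m = 1$ uses the closed form
  $2\Phi(-T)$, making a $1 \times 1$ region pair exactly the SNP-pair
  test.

Closed-form reductions anchor the integrator: $\Sigma = I$ must give the
Šidák value $1 - (1 - p')^m$, an all-ones $\Sigma$ must give the
single-statistic value $2\Phi(-T)$, and on small fixtures the analytic
p-value is checked against a label-permutation oracle.

The corrected family-wise error rate reported alongside each region pair
is plain Bonferroni, $\min(1, p_{region} \times n_{tests})$, with
$n_{tests}$ defaulting to the number of region pairs actually tested in
the run and always recorded in the output header — the multiplicity base
is a reporting decision, not something the package can guess. Values
whose product exceeds 1 render as `">1"`.

### Selection caveat

$\Sigma$ is estimated from the same data whose minimum p-value it
corrects, and the MVN form of the null is itself asymptotic. Neither
selection effect is modeled; the type-I calibration experiment below is
the empirical check that at realistic scales the approximation holds.

## Region construction

Regions usually come from screening: an exhaustive fast SNP-pair scan
(BOOST-family tools) is run first, pairs below a suggestive threshold
(default $5 \times 10^{-10}$, deliberately lenient) are kept, and each
surviving anchor SNP seeds a window of 200 kbp — roughly a gene — centered
on the anchor. Overlapping windows on a chromosome are merged, so merged
regions can exceed 200 kbp; this mirrors how overlapping hits naturally
describe one locus. All genotyped SNPs inside a final region join it; a
region holding more than 31 SNPs (so $m < 1000$) is represented by a
seeded uniform random subset. The window placement (center vs. start),
window size, cap, and threshold are all arguments, not constants. Regions
can instead be supplied directly as BED intervals (0-based half-open,
converted on read; all internal coordinates are 1-based inclusive), e.g.
from pathway or protein-interaction knowledge.

## Data handling

Only the additive $0/1/2$ coding is implemented: the composite-LD algebra
that drives everything downstream is stated under the additive model, and
dominant/recessive codings would change the statistic's meaning. Every SNP
is oriented at load time so code 2 means two *minor* alleles; orientation
flips the sign of $\Delta LD$ but never changes $\chi^2$ or any p-value.
Missing genotypes are mean-imputed, pooled across phenotype groups, before
testing: pairwise-complete deletion would give different entries of
$\Sigma$ different effective sample sizes, quietly breaking the covariance
formula, whereas pooled mean imputation keeps one $n$ per group
everywhere (at the price of slightly attenuating covariances when
missingness is heavy). Both PLINK 1 binary (SNP-major `.bed/.bim/.fam`)
and a plain-text TSV are read; phenotypes accept the PLINK 1/2 and the 0/1
dialects, with missing-phenotype samples dropped and logged. A
configurable MAF filter is deliberately not imposed — inputs are assumed
to be post-QC — but per-SNP summaries (`snp_summary`) expose MAF,
Hardy-Weinberg disequilibrium, and variance for callers that want one.

## The synthetic-data generator

The simulation harness emulates the two standard experiment designs on
fully synthetic data.

**Genotypes.** Haplotypes are drawn blockwise from a first-order
correlated-Bernoulli chain: within a block, adjacent alleles have
correlation $\rho$ (conditional probabilities clamped to $[0,1]$, which
can shave the realized correlation when adjacent MAFs differ strongly);
blocks are independent. Two haplotypes sum to a genotype. Defaults used
throughout the documented experiments: MAF 0.3 per SNP, $\rho = 0.7$ for
calibration and $0.8$ for power (dense LD typical of a gene-sized block),
two blocks of 10 SNPs (calibration) or 6 SNPs (power), $n = 1000$ samples
for calibration. These are one-time choices of realistic conditions, not
tuning knobs.

**Type-I design.** Genotypes are held fixed (preserving their LD);
each of 1000 replicates redraws the phenotype as Bernoulli(0.5) and runs
the region test. Empirical rejection rates at $\alpha = 0.05$ and $0.01$
are reported with 3-binomial-SE bands; `scripts/acceptance.R` reruns
exactly this experiment.

**Power design.** Disease status is assigned with penetrance
$f_0 \cdot RR(g_1, g_2)$ at one causal cross-region pair: $RR = 1$ unless
both causal genotypes carry a risk allele, otherwise
$RR = rr_{base} \cdot rr_{inc}^{(g_1-1)+(g_2-1)}$ with defaults
$rr_{base} = 2$ and $rr_{inc} = \sqrt{2}$ (combinations 1/1, 1/2, 2/1,
2/2 thus have risks $2, 2\sqrt2, 2\sqrt2, 4$), prevalence 0.1. The
baseline $f_0$ is solved from the prevalence by bisection against a
simulated genotype pool; infeasible models (penetrance above 1) error
out. Cases and controls are rejection-sampled to quota. The causal SNPs
sit mid-block and are withheld from the analysis set, so the test sees
them only through LD with the flanking tag SNPs — the tag-SNP regime in
which region aggregation earns its keep. Three methods are scored per
replicate at a common threshold: the region p-value, the best pair
p-value Bonferroni-corrected for $k_1k_2$ pairs (the SNP-level baseline),
and one pre-chosen single pair. The documented experiment uses sample
sizes 1000/2000/3000 with 200 replicates per cell.

**What the generator does not emulate.** Real haplotype mosaics (long-range
LD, recombination hotspots), allele-frequency spectra, genotyping error,
population structure, and covariates. Passing calibration and power checks
on these synthetic conditions therefore demonstrates the statistical
machinery — not robustness to structure or confounding, which should be
handled upstream (matching, PCs) as in any LD-based analysis. Absolute
power values depend on the simulated LD and are not comparable to
published figures obtained from real haplotype pools; the qualitative
orderings (region $\ge$ pairwise baseline; power increasing in $n$) are
the reproducible claims.

## Problem sizes and runtime

The documented experiment sizes — 1000 calibration replicates on a
$10\times10$-SNP region pair at $n = 1000$; $10^5$ Monte-Carlo replicates
for the covariance oracle; 5000 null replicates for the $\Sigma$ oracle;
200 power replicates per cell — run in roughly a quarter hour total on a
single core, with the calibration experiment dominating
(~0.4 s per replicate, almost entirely the 100-dimensional QMC
integral).

## Known limitations

* Building $\Sigma$ is $O(m^2 n)$ per region pair; genome-wide all-pairs
  scanning is out of reach by design — screening (or prior knowledge)
  chooses the region pairs.
* The MVN null and the covariance formula are asymptotic; very small
  groups (tens of samples) or near-monomorphic SNPs will strain them.
* Dosage/imputed-probability formats, X-chromosome conventions, and
  haplotype-phased analyses are not supported.
* The single causal-pair disease model is the classic benchmark design;
  polygenic backgrounds or multiple interacting pairs are not generated.
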