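---
title: "The generalized correlation coefficient for twin GWAS: model, calibration and design choices"
author: "gcctwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The generalized correlation coefficient for twin GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcctwin)
```

## The problem

Standard GWAS models regress a quantitative phenotype on allele dosage and
therefore test only the additive, linear component of a genotype-phenotype
relationship; they further assume a normal phenotype and, in family samples,
need an explicit correction for relatedness. `gcctwin` implements an
assumption-free alternative — the generalized correlation coefficient (GCC)
— alongside the two conventional twin-aware linear comparators, so that a
scan can be run under all three models on the same data and the results
compared.

## The GCC model

For a genotype-phenotype pair $(x, y)$ the **independence null** models the
joint density as the product of the marginal kernel estimates,
$P(x)\,P(y)$. The **alternative** is a mixture of a dependent component
$P_d(x, y)$ and the independent component,

$$P_{\mathrm{alt}}(x, y) = w\,P_d(x, y) + (1 - w)\,P(x)P(y),
  \qquad w \in [0, 1].$$

All densities are evaluated out-of-fold: the sample is split into $k$
cross-validation folds (10 by default, seeded shuffle), each fold's
densities are trained on the remaining folds, and the held-out
log-likelihoods are summed. The mixture weight $w$ — and the dependent
component's bandwidth configuration — are chosen on a grid
($w \in \{0, 0.1, \dots, 1\}$) to maximize the held-out log-likelihood of
the alternative. Association strength is the generalized $R^2$

$$A \;=\; 1 - \prod_{i=1}^{n}
  \left[\frac{P(x_i, y_i \mid \mathrm{null})}
             {P(x_i, y_i \mid \mathrm{alt})}\right]^{2/n},$$

clamped to $[0, 1]$; and significance is carried by the cross-validation
likelihood-ratio statistic

$$\mathrm{CVLRS} = -2 \log \frac{L_{cv}(\mathrm{Null})}{L_{cv}(\mathrm{Alt})},$$

so that $A = 1 - \exp(-\mathrm{CVLRS}/n)$. Because the weight grid contains
$w = 0$, the alternative can collapse onto the null, which forces
$\mathrm{CVLRS} = 0$ and $A = 0$ exactly; $A$ approximates the squared
Pearson correlation for bivariate Gaussian data (equitability) but also
responds to purely non-linear dependence, where the squared Pearson
correlation stays near zero.

### Preprocessing: jitter and normal scores

Hard-call genotypes (values on $\{0,1,2\}$) are degenerate for kernel
density estimation; they receive a small seeded uniform jitter (amplitude
0.05), while their class labels are retained (next section). Both variables
are then mapped to **normal scores**, $\Phi^{-1}(r_i/(n+1))$ with $r_i$ the
rank. This copula transform has four consequences that we rely on:

* the marginals become the *same* fixed multiset in every dataset of size
  $n$, so the null model cannot misfit the marginals and the statistic
  measures departure from independence only — without it we found the
  CVLRS dominated by marginal misfit of the rule-of-thumb bandwidth on
  jittered genotype spikes;
* a null distribution calibrated on one dataset transfers exactly (in the
  marginals) to any other dataset of the same size, which is what makes the
  shared-null machinery of the simulation studies valid;
* $A$ is exactly invariant under strictly monotone rescaling of either
  variable; and
* extreme phenotype values cannot dominate the fit, so the statistic is
  insensitive to outliers and skewness (Box-Cox normalization is never
  *required* for the GCC; the scan offers it for the linear models).

The transform can be disabled (`transform = "none"`).

### The dependent component

Two families of candidate dependent components compete by held-out
likelihood, jointly with $w$:

1. **Product-kernel joint estimates.** Gaussian product kernels with
   per-dimension bandwidths $h_x s_x$, $h_y s_y$, where $h$ is Silverman's
   rule on the training part and $(s_x, s_y)$ ranges over all pairs from
   `scale_grid` (default $\{0.3, 0.5, 1, 2\}$). Anisotropic pairs matter:
   a strong dependence ridge needs undersmoothing across the ridge, while a
   weak signal needs oversmoothing to control estimation variance. A pure
   Silverman joint ($s_x = s_y = 1$ only) underestimates $A$ for strong
   dependence (about 0.93 instead of > 0.95 for $y = x$ at $n = 500$) and
   has almost no power against weak effects.
2. **Genotype-class conditional estimates.** When a variable is hard-call
   discrete, $P_d(x, y) = P(x)\, \hat f(y \mid \mathrm{class}(x))$ with a
   per-class kernel estimate of the phenotype (per-class Silverman
   bandwidth, scale options $\{0.75, 1, 1.5\}$; classes with fewer than 5
   training members fall back to the marginal). This is the estimator
   analogue of genotype-specific phenotype density ("bean") plots, and it
   is far more efficient for class-structured dependence than a 2-D kernel:
   in our simulations it roughly triples the power against a 4%-variance
   effect at $\alpha = 10^{-3}$. The marginal factor $P(x)$ cancels in the
   density ratio, so only the conditional part carries signal.

The fitted object reports which component won (`fit$component`).

## Significance: permutation and the twin null

P-values come from re-fitting the statistic under permutations that break
the genotype-phenotype link while preserving everything else:

* `perm_unit = "individual"` permutes single observations — correct for
  exchangeable samples.
* `perm_unit = "pair"` permutes intact twin pairs among pairs (stratified
  by zygosity), and singletons among singletons. For twin data this is the
  correct unit: co-twins share genotype (always for MZ, half the time for
  DZ) *and* phenotype (environmentally), so under independence the data
  contain near-duplicate points. Individual-level permutation destroys that
  duplication, producing a null of too-small statistics — we measured
  type-I error near 0.5 at a within-pair phenotype correlation of 0.3.
  Pair-level permutation keeps the duplication in the null, so the test is
  conditional on the correlated structure of the sample; this is also why
  no explicit kinship correction is needed for the GCC.

The empirical p-value is $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$.
Genome-wide scans must resolve p-values near $5\times10^{-8}$, far beyond
any realistic permutation count, so a generalized-Pareto distribution is
fitted by maximum likelihood to the top decile of null statistics and the
tail probability extrapolated (`tail_method = "gpd_tail"`). Quantile lookups
beyond the raw resolution fail loudly under `tail_method = "empirical"`.

For repeated tests with identical marginal structure — every replication of
a simulation study, or a fixed-MAF null scan — `gcc_null_calibration()`
builds one reusable null distribution. Each null draw takes a fresh
genotype vector from a user-supplied sampler; since the sampler is
independent of the phenotype by construction, the phenotype is left
untouched in these draws (`perm_unit = "none"`). Leaving it untouched
matters: it matches the conditioning of the observed statistics exactly.
(We first permuted pairs in the null draws as well; the residual mismatch —
which phenotype pairs face MZ versus DZ genotype positions — made the
scan-level genomic inflation factor wobble visibly. With the sampler-only
null, a 1,000-SNP null scan gives $\lambda_{GC}$ between roughly 0.99 and
1.08 across simulation seeds.)

## The linear comparators

* **Kinship GLS** (`kinship_gls()`): $y = X\alpha + g\beta + \epsilon$ with
  $\mathrm{Var}(\epsilon) = \sigma_g^2 K + \sigma_e^2 I$. $K$ is the
  expected additive relationship matrix (diagonal 1, MZ co-twin 1, DZ
  co-twin 0.5) — the scaling convention makes $\sigma_g^2$ an additive
  genetic variance, and scaling does not affect the Wald test. Variance
  components are estimated by REML, by default once under the
  covariate-only model and reused across SNPs (two-step GWAS practice;
  `varcomp_mode = "per_snp"` refits). The twin-pair block structure gives a
  closed-form eigendecomposition (within-pair sums and differences), so a
  REML fit is linear-time and a 1,000-SNP scan takes about a second.
* **Pair LME** (`lme_pair()`): a random intercept per twin pair, maximum
  likelihood via `lme4::lmer()`, Wald z test on the dosage coefficient.

Both report signed effects; the GCC reports none — direction is undefined
for a non-linear relationship, and the scan output leaves `beta`/`se`
missing for the GCC model by design.

## The twin simulator

`simulate_twin_genotypes()` draws parental genotypes under Hardy-Weinberg
equilibrium at the configured MAF and transmits alleles by Mendelian
sampling: MZ twins share one transmitted genotype, DZ twins get independent
transmissions from the same parents (expected within-pair dosage
correlation 0.5), singletons come directly from HWE.
`simulate_phenotype()` builds

$$y = \beta f(g) + \text{shared pair component} + \text{unique noise},$$

with the background scaled to unit variance and $f$ the *raw* coded genetic
score (additive $g$, carrier indicator, homozygote indicator, or squared
centred dosage), centred. Keeping $f$ unstandardized makes the regression
coefficient on the additive coding equal `effect_size` exactly, which is
what the parameter-recovery checks assert; `effect_size_for_r2()` converts
a target variance-explained fraction into this scale with the closed-form
HWE score variance. MZ and DZ pairs share the same pair-component variance
— environmental sharing only — to isolate how the models handle phenotype
correlation from how they handle genetic relatedness.

Default study conditions, used by the calibration studies and chosen once:
300 DZ pairs + 100 MZ pairs (800 individuals, a Danish-like composition at
desk scale), MAF 0.3, within-pair phenotype correlation 0.3, standard
normal phenotype under the null. The type-I-error study (`type1_error_study()`)
runs 1,000 replications by default and reports exact binomial confidence
intervals; with the shared GCC null it completes in a few minutes on one
CPU. The power study grid (`power_study()`) uses 200 replications per cell
at $\alpha = 10^{-3}$.

What the simulator does *not* emulate: linkage disequilibrium between SNPs,
genotyping or imputation error (simulated dosages are exact allele counts),
ascertainment, age/sex effects on the phenotype (covariates are pure
noise), or an A/C/E decomposition of the twin covariance. Passing tests on
these data therefore demonstrate calibration and power under a clean twin
design, not robustness to those real-data complications.

## Scan engine choices

* Covariates (default age and sex) enter the linear models as design
  columns; for the GCC — a bivariate statistic with no covariate slot — the
  phenotype is residualized on them first. Residualization is the only
  coherent way to adjust a two-variable dependence measure.
* Box-Cox normalization (profile likelihood over $\lambda \in [-2, 2]$,
  step 0.01, automatic shift for non-positive values) is off by default and
  applies to the whole scan when requested, so that all three models see
  the same phenotype.
* Variant filters: MAF $\ge$ 0.05 and imputation INFO $> 0.6$; variants
  without an INFO value (hard-typed) pass the INFO filter. Autosomes only
  when chromosome information is present. Missing dosages are dropped
  pairwise per SNP (`n_used` records the count); monomorphic SNPs are
  skipped with a logged reason.
* GCC p-values at genome scale use a two-stage per-SNP scheme by default
  (99-permutation screen, full 999-permutation GPD-tailed calibration only
  for SNPs at the screen's floor); `gcc_calibration = "shared"` pools one
  null across SNPs and is the right choice for simulation scans where all
  SNPs share marginal structure.
* $\lambda_{GC}$ is computed identically for all models:
  $\mathrm{median}(\chi^2_1\text{-quantiles of } p)/0.4549$.
* Fixed significance thresholds only ($5\times10^{-8}$ genome-wide,
  $10^{-5}$ suggestive); no SNP-level FDR.

## Numerical details and degenerate inputs

Held-out densities are floored at the smallest positive double before
taking logs. Zero-variance inputs, non-finite values, and samples below
n = 20 raise classed errors; fewer than 19 permutations cannot resolve
$\alpha = 0.05$ and are rejected. The GPD tail fit falls back to the
empirical p-value when the fit fails or the observed statistic is below the
tail threshold. REML optimizes the profile criterion over
$\log \delta \in [\log 10^{-6}, \log 10^{3}]$ ($\delta = \sigma^2_g/\sigma^2_e$)
and explicitly compares the boundary $\delta = 0$, so a zero genetic
variance reduces the GLS to OLS exactly. All stochastic functions take
explicit seeds and restore the caller's RNG state; sub-seeds stay within
32-bit range.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run: the 1,000-replication
type-I study at the default twin design; equitability at $n = 2000$ over
$\rho \in \{0, 0.3, 0.6, 0.9\}$; a 200-replication power contrast
(quadratic, 4% variance, 300 DZ pairs, $\alpha = 10^{-3}$); three
independent 1,000-SNP $\times$ 300-pair null scans under all three models,
with $\lambda_{GC}$ averaged across scans because a single scan estimates
it with sd $\approx 0.08$ (median sampling noise plus the
phenotype-conditional wobble of any shared-phenotype scan); 200-dataset
p-value uniformity; and 200-replication recovery of an additive effect of
0.30. These sizes were chosen as the smallest at which the Monte-Carlo
intervals are informative for the quantities being checked.

## Known limitations

* The GCC's A statistic has no direction of effect; use the linear-model
  coefficient for orientation when the relationship is monotone.
* The class-conditional dependent component activates only for hard-call
  variables (at most three distinct integer values); heavily discretized
  continuous dosages fall back to the product-kernel candidates.
* The shared-null calibration assumes the tested SNPs share marginal
  structure; for real scans with heterogeneous MAFs the per-SNP two-stage
  scheme is the default for that reason.
* P-values far below the permutation resolution rest on the
  generalized-Pareto tail model; they are extrapolations, as any
  sub-resolution permutation p-value must be.
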