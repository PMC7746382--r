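# gcctwin

Nonparametric genome-wide association testing for twin cohorts with the
**generalized correlation coefficient (GCC)**, next to the two conventional
twin-aware linear models (kinship-covariance GLS and a pair-level
random-intercept LME).

## Why

Linear GWAS models test only the additive, linear part of a
genotype–phenotype relationship, assume a normal phenotype, and need an
explicit relatedness correction in family samples. The GCC is an
assumption-free measure of dependence between a SNP dosage `x` and a
phenotype `y`:

- the **null** models the joint density as the product of kernel marginal
  estimates, `P(x)P(y)`;
- the **alternative** is a mixture `w·P_d(x,y) + (1−w)·P(x)P(y)` of a
  dependent density estimate and the independent component;
- association strength is the generalized R²

  `A = 1 − ∏ᵢ [P(xᵢ,yᵢ|null)/P(xᵢ,yᵢ|alt)]^(2/n) ∈ [0, 1]`,

  estimated entirely from held-out (cross-validated) likelihoods, with the
  mixture weight chosen by held-out likelihood on a grid;
- significance comes from the cross-validation likelihood-ratio statistic
  `CVLRS = −2 log(Lcv(Null)/Lcv(Alt))`, calibrated by permutation — intact
  twin pairs are the permutation unit on twin data — with a
  generalized-Pareto tail fit for p-values below the permutation
  resolution.

`A` approximates the squared Pearson correlation for bivariate Gaussian
data but also detects purely non-linear effects (dominant, recessive,
U-shaped) that additive models miss, has no distributional requirements on
the phenotype, and handles twin correlation through its marginal-based
permutation null rather than an explicit covariance model.

The package also provides: dosage VCF / text-matrix / phenotype readers
with the standard post-imputation filters (MAF ≥ 5%, INFO > 0.6); a scan
engine with covariate adjustment, optional Box-Cox normalization, genomic
inflation factors and QQ/Manhattan/genotype-density tables; a twin
simulator (HWE founders, Mendelian transmission, MZ/DZ sharing, shared
pair environment) with type-I-error and power study harnesses; and a CLI.

## Worked example

Simulate a twin cohort (100 MZ + 300 DZ pairs) where one SNP has a purely
non-additive (quadratic) effect explaining 4% of phenotype variance, then
test it under the GCC and the kinship model:

```r
library(gcctwin)

cfg <- twin_sim_config(effect_model = "quadratic",
                       effect_size = effect_size_for_r2(0.04, "quadratic", 0.3),
                       seed = 42)
sim <- simulate_twin_genotypes(cfg)
ph  <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg)
g   <- sim$dosage$values[, 1]

t <- gcc_test(g, ph$phenotype, n_perm = 999, tail_method = "gpd_tail",
              perm_unit = "pair", pair_id = ph$family_id, seed = 1)
print(t); t$fit$component

kinship_gls(ph$phenotype, g, kinship = build_kinship(ph))
```

```
GCC permutation test: A = 0.01588, CVLRS = 12.81, p = 0.016 (999 permutations, empirical)
[1] "genotype-class conditional y|x (bw scale 1.5)"

Kinship-covariance GLS fit (n = 800)
  beta = 0.0972  se = 0.06032  z = 1.611  p = 0.1071
  variance components: genetic = 0.5301, residual = 0.5193
```

The GCC flags the SNP (p = 0.016 against the pair-permutation null), while
the additive kinship model sees only the small linear component of the
quadratic effect (p = 0.11). `t$fit$component` shows that the winning
dependent component is the genotype-class conditional density — the
estimator analogue of the genotype-specific density plots used to
visualize non-additive effects. A single dataset at 4% explained variance
is deliberately a hard case; over 200 such replications at α = 10⁻³ the
GCC rejects about 63% of the time versus 22% for the kinship model (see
the power study in the test suite).

A genome-wide scan works the same way from files:

```r
dm  <- read_dosage_vcf("chr2.dose.vcf.gz")            # or read_dosage_matrix()
phe <- read_pheno("cohort.pheno.tsv")
rep <- run_scan(dm, phe, scan_config(model = "gcc", covariates = c("age", "sex")))
rep$lambda_gc; rep$n_gw_significant
write_assoc(rep$results, "cohort.gcc.assoc.tsv")
```

or from the shell:

```sh
gcctwin scan --vcf chr2.dose.vcf.gz --pheno cohort.pheno.tsv \
  --model gcc --covar age,sex --maf-min 0.05 --info-min 0.6 \
  --perm 999 --seed 7 --out cohort.gcc
gcctwin study type1 --reps 1000 --alpha 0.05 --models gcc,kinship,lme \
  --seed 7 --out type1.tsv
```

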