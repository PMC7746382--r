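# Twin-structured genotype/phenotype simulator and the type-I-error and
# power study harness.

#' Twin simulation configuration
#'
#' Defaults describe the study design used throughout the package's
#' calibration work: 300 DZ pairs plus 100 MZ pairs, one SNP at MAF 0.3,
#' within-pair phenotype correlation 0.3 from a shared environmental
#' component, standard-normal phenotype under the null.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons sample composition.
#' @param maf minor allele frequency in (0, 0.5].
#' @param n_snps number of independent SNPs to simulate.
#' @param effect_model `"null"`, `"additive"`, `"dominant"`, `"recessive"`
#'   or `"quadratic"`.
#' @param effect_size effect in phenotypic SD units per unit of the
#'   standardized genetic score (ignored under `"null"`); see
#'   [effect_size_for_r2()] to target a variance-explained fraction.
#' @param pair_phenotype_correlation shared-environment within-pair
#'   phenotype correlation in \[0, 1).
#' @param phenotype_family `"normal"` or `"skewed"` (exp-transformed then
#'   restandardized).
#' @param seed integer seed.
#' @return a `twin_sim_config` list.
#' @export
twin_sim_config <- function(n_mz_pairs = 100, n_dz_pairs = 300,
                            n_singletons = 0, maf = 0.3, n_snps = 1,
                            effect_model = c("null", "additive", "dominant",
                                             "recessive", "quadratic"),
                            effect_size = 0,
                            pair_phenotype_correlation = 0.3,
                            phenotype_family = c("normal", "skewed"),
                            seed = 1L) {
  effect_model <- match.arg(effect_model)
  phenotype_family <- match.arg(phenotype_family)
  if (maf <= 0 || maf > 0.5)
    stop_gcctwin("config_error", "maf must lie in (0, 0.5]")
  n_total <- 2 * (n_mz_pairs + n_dz_pairs) + n_singletons
  if (n_total < 20)
    stop_gcctwin("config_error", "total sample size must be at least 20")
  if (pair_phenotype_correlation < 0 || pair_phenotype_correlation >= 1)
    stop_gcctwin("config_error", "pair_phenotype_correlation must lie in [0, 1)")
  if (n_snps < 1) stop_gcctwin("config_error", "n_snps must be positive")
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_singletons = n_singletons, maf = maf, n_snps = n_snps,
                 effect_model = effect_model, effect_size = effect_size,
                 pair_phenotype_correlation = pair_phenotype_correlation,
                 phenotype_family = phenotype_family,
                 seed = as.integer(seed)),
            class = "twin_sim_config")
}

#' Effect size targeting a variance-explained fraction
#'
#' The simulator adds `effect_size` times the raw coded genetic score to a
#' unit-variance background, so a SNP explaining a fraction `r2` of
#' phenotypic variance needs `effect_size^2 * var(f) = r2 / (1 - r2)`, with
#' `var(f)` the Hardy-Weinberg variance of the coded score at the given MAF.
#'
#' @param r2 target variance-explained fraction in \[0, 1).
#' @param effect_model the genetic coding (see [twin_sim_config()]).
#' @param maf minor allele frequency.
#' @return the `effect_size` to pass to [twin_sim_config()].
#' @export
effect_size_for_r2 <- function(r2, effect_model = "additive", maf = 0.3) {
  stopifnot(r2 >= 0, r2 < 1)
  v <- hwe_score_var(effect_model, maf)
  if (v == 0) stop_gcctwin("config_error", "genetic score has zero variance")
  sqrt(r2 / (1 - r2)) / sqrt(v)
}

# variance of the coded genetic score under HWE at allele frequency q
hwe_score_var <- function(effect_model, q) {
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)   # P(g = 0, 1, 2)
  g <- 0:2
  f <- switch(effect_model,
              additive = g,
              dominant = as.numeric(g >= 1),
              recessive = as.numeric(g == 2),
              quadratic = (g - 2 * q)^2,
              null = return(0))
  sum(pg * f^2) - sum(pg * f)^2
}

# One Mendelian transmission from a parent with allele pair (a1, a2).
transmit <- function(a1, a2) ifelse(runif(length(a1)) < 0.5, a1, a2)

#' Simulate twin-structured genotypes
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at the
#' configured MAF; MZ twins share one transmitted genotype, DZ twins receive
#' independent Mendelian transmissions from the same parents (expected
#' within-pair dosage correlation 0.5), singletons are drawn directly from
#' HWE. Ages (shared within pair) and sexes (identical for MZ pairs) are
#' generated as pure noise covariates.
#'
#' @param cfg a [twin_sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `dosage` (a `dosage_matrix` of hard allele counts) and
#'   `pheno` (a `pheno_table` skeleton with `phenotype = NA`).
#' @export
simulate_twin_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "twin_sim_config"))
  n_pairs <- cfg$n_mz_pairs + cfg$n_dz_pairs
  n <- 2 * n_pairs + cfg$n_singletons
  q <- cfg$maf
  with_seed(seed, {
    G <- matrix(NA_real_, n, cfg$n_snps)
    for (s in seq_len(cfg$n_snps)) {
      g <- numeric(n)
      if (n_pairs > 0) {
        # parental allele pairs for each twin family
        p1a <- rbinom(n_pairs, 1, q); p1b <- rbinom(n_pairs, 1, q)
        p2a <- rbinom(n_pairs, 1, q); p2b <- rbinom(n_pairs, 1, q)
        t1 <- transmit(p1a, p1b) + transmit(p2a, p2b)
        is_mz <- seq_len(n_pairs) <= cfg$n_mz_pairs
        t2 <- ifelse(is_mz, t1, transmit(p1a, p1b) + transmit(p2a, p2b))
        g[seq(1, 2 * n_pairs, by = 2)] <- t1
        g[seq(2, 2 * n_pairs, by = 2)] <- t2
      }
      if (cfg$n_singletons > 0)
        g[(2 * n_pairs + 1):n] <- rbinom(cfg$n_singletons, 2, q)
      G[, s] <- g
    }
    fam_pair <- sprintf("fam%04d", rep(seq_len(n_pairs), each = 2))
    fam_single <- if (cfg$n_singletons > 0)
      sprintf("fam%04d", n_pairs + seq_len(cfg$n_singletons)) else character(0)
    family_id <- c(fam_pair, fam_single)
    sample_id <- paste0(family_id, "_",
                        c(rep(1:2, n_pairs), rep(1, cfg$n_singletons)))
    zygosity <- c(rep(c("MZ", "DZ"), c(2 * cfg$n_mz_pairs, 2 * cfg$n_dz_pairs)),
                  rep("singleton", cfg$n_singletons))
    age_fam <- rnorm(n_pairs + cfg$n_singletons, mean = 56, sd = 8)
    age <- c(rep(age_fam[seq_len(n_pairs)], each = 2),
             age_fam[seq_len(cfg$n_singletons) + n_pairs])
    sex_pair <- sample(c("male", "female"), n_pairs, replace = TRUE)
    sex <- c(as.vector(rbind(
      sex_pair,
      ifelse(seq_len(n_pairs) <= cfg$n_mz_pairs, sex_pair,
             sample(c("male", "female"), n_pairs, replace = TRUE)))),
      sample(c("male", "female"), cfg$n_singletons, replace = TRUE))
    snps <- data.frame(
      snp_id = sprintf("sim%d", seq_len(cfg$n_snps)), chrom = "1",
      pos = seq_len(cfg$n_snps) * 1000L, ref_allele = "A", alt_allele = "G",
      maf = apply(G, 2, maf_from_dosage), info = NA_real_,
      stringsAsFactors = FALSE)
    pheno <- data.frame(sample_id = sample_id, phenotype = NA_real_,
                        age = round(age, 1), sex = sex,
                        family_id = family_id, zygosity = zygosity,
                        stringsAsFactors = FALSE)
    list(dosage = new_dosage_matrix(sample_id, snps, G),
         pheno = as_pheno_table(pheno))
  })
}

# Raw coded genetic score (centred so the phenotype keeps mean ~0, but not
# rescaled: the regression coefficient on the additive coding equals
# effect_size exactly).
genetic_score <- function(g, effect_model) {
  f <- switch(effect_model,
              null = rep(0, length(g)),
              additive = g,
              dominant = as.numeric(g >= 1),
              recessive = as.numeric(g == 2),
              quadratic = (g - mean(g))^2)
  f - mean(f)
}

#' Simulate a twin phenotype with known genetic truth
#'
#' `y = effect_size * f(g) + shared pair component + unique noise`, with the
#' background (shared + unique) scaled to unit variance so the coefficient
#' on the coded genetic score equals `effect_size` exactly. `f` is the raw
#' coded score of the configured effect model (additive: dosage; dominant:
#' carrier indicator; recessive: homozygote indicator; quadratic: squared
#' centred dosage), centred to mean zero. MZ and DZ pairs share the same
#' pair-component variance (environmental sharing only), so within-pair
#' phenotype correlation equals `pair_phenotype_correlation` under the
#' null. The `"skewed"` family exp-transforms and restandardizes.
#'
#' @param genotypes dosage vector for the causal (or null) SNP.
#' @param pheno_skeleton `pheno_table` skeleton from
#'   [simulate_twin_genotypes()].
#' @param cfg a [twin_sim_config()].
#' @param seed optional override (defaults to `cfg$seed + 1` stream).
#' @return the `pheno_table` with the phenotype filled in.
#' @export
simulate_phenotype <- function(genotypes, pheno_skeleton, cfg,
                               seed = derive_seed(cfg$seed, 2L)) {
  stopifnot(inherits(cfg, "twin_sim_config"))
  n <- nrow(pheno_skeleton)
  if (length(genotypes) != n)
    stop_gcctwin("input_error", "genotype and phenotype lengths differ")
  rho <- cfg$pair_phenotype_correlation
  beta <- if (cfg$effect_model == "null") 0 else cfg$effect_size
  with_seed(seed, {
    fam <- as.character(pheno_skeleton$family_id)
    shared_fam <- rnorm(length(unique(fam)), sd = sqrt(rho))
    names(shared_fam) <- unique(fam)
    e <- shared_fam[fam] + rnorm(n, sd = sqrt(1 - rho))
    y <- beta * genetic_score(genotypes, cfg$effect_model) + e
    if (cfg$phenotype_family == "skewed") {
      y <- exp(y)
      y <- (y - mean(y)) / sd(y)
    }
    pheno_skeleton$phenotype <- unname(y)
    pheno_skeleton
  })
}

sim_binom_ci <- function(k, n) {
  ci <- binom.test(k, n)$conf.int
  c(low = ci[1], high = ci[2])
}

#' Type-I-error study for the three association models
#'
#' Replicates the null calibration experiment: each replication simulates
#' one SNP's genotypes on the configured twin structure and an independent
#' phenotype, tests genotype-phenotype association under each model, and
#' rejects at `alpha`. The GCC test uses a shared permutation null by
#' default (one calibration reused across replications, valid because the
#' replications share marginal structure); `"per_replication"` runs a full
#' permutation test in every replication.
#'
#' @param cfg a [twin_sim_config()] with `effect_model = "null"`.
#' @param models subset of `c("gcc", "kinship", "lme")`.
#' @param n_replications number of replications (>= 100).
#' @param alpha nominal significance level.
#' @param calibration `"shared_null"` or `"per_replication"` (GCC only).
#' @param n_perm permutations for the GCC null.
#' @param folds,weight_grid,scale_grid GCC fit settings.
#' @return An object of class `sim_study`: per-model rejection rates with
#'   exact binomial 95\% confidence intervals.
#' @export
type1_error_study <- function(cfg = twin_sim_config(),
                              models = c("gcc", "kinship", "lme"),
                              n_replications = 1000, alpha = 0.05,
                              calibration = c("shared_null",
                                              "per_replication"),
                              n_perm = 999, folds = 10,
                              weight_grid = seq(0, 1, by = 0.1),
                              scale_grid = c(0.3, 0.5, 1, 2)) {
  calibration <- match.arg(calibration)
  models <- match.arg(models, c("gcc", "kinship", "lme"), several.ok = TRUE)
  if (cfg$effect_model != "null")
    stop_gcctwin("misuse_error",
                 "type-I-error study requires effect_model = \"null\"")
  if (n_replications < 100)
    stop_gcctwin("misuse_error", "need at least 100 replications")

  base <- simulate_twin_genotypes(cfg, seed = cfg$seed)
  kin <- if ("kinship" %in% models) build_kinship(base$pheno) else NULL

  shared_null <- NULL
  if ("gcc" %in% models && calibration == "shared_null") {
    y_ref <- simulate_phenotype(base$dosage$values[, 1], base$pheno, cfg,
                                seed = derive_seed(cfg$seed, 5L))$phenotype
    sampler_cfg <- cfg
    x_sampler <- local({
      counter <- 0L
      function() {
        counter <<- counter + 1L
        simulate_twin_genotypes(
          sampler_cfg, seed = derive_seed(sampler_cfg$seed, 50000L + counter)
        )$dosage$values[, 1]
      }
    })
    shared_null <- gcc_null_calibration(
      x_sampler, y_ref, n_perm = n_perm, folds = folds,
      weight_grid = weight_grid, scale_grid = scale_grid,
      perm_unit = "none",
      seed = derive_seed(cfg$seed, 9L))
  }

  reject <- matrix(FALSE, n_replications, length(models),
                   dimnames = list(NULL, models))
  for (r in seq_len(n_replications)) {
    seed_r <- derive_seed(cfg$seed, 100000L + r)
    sim <- simulate_twin_genotypes(cfg, seed = seed_r)
    ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg,
                             seed = derive_seed(seed_r, 3L))
    g <- sim$dosage$values[, 1]
    y <- ph$phenotype
    for (mo in models) {
      p <- switch(mo,
        gcc = {
          if (calibration == "shared_null") {
            fit <- gcc(g, y, folds = folds, weight_grid = weight_grid,
                       scale_grid = scale_grid, seed = derive_seed(seed_r, 4L))
            null_pvalue(shared_null, fit$cvlrs)
          } else {
            gcc_test(g, y, folds = folds, weight_grid = weight_grid,
                     scale_grid = scale_grid,
                     n_perm = max(19, ceiling(2 / alpha) - 1),
                     perm_unit = "pair", pair_id = ph$family_id,
                     perm_strata = ph$zygosity,
                     seed = derive_seed(seed_r, 4L))$pvalue
          }
        },
        kinship = kinship_gls(y, g, kinship = kin)$pvalue,
        lme = lme_pair(y, g, pair_id = ph$family_id)$pvalue)
      reject[r, mo] <- p < alpha
    }
  }
  rates <- colMeans(reject)
  cis <- t(vapply(models, function(mo)
    sim_binom_ci(sum(reject[, mo]), n_replications), numeric(2)))
  structure(list(study = "type1", rejection_rate = rates,
                 ci95 = cis, n_replications = n_replications, alpha = alpha,
                 calibration = calibration, config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, digits = 4, ...) {
  cat(if (x$study == "type1") "Type-I-error study" else "Power study",
      " (", x$n_replications, " replications, alpha = ", x$alpha, ")\n",
      sep = "")
  df <- data.frame(model = names(x$rejection_rate),
                   rejection_rate = unname(x$rejection_rate),
                   ci_low = x$ci95[, 1], ci_high = x$ci95[, 2])
  print(df, row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
as.data.frame.sim_study <- function(x, ...) {
  data.frame(study = x$study, model = names(x$rejection_rate),
             rejection_rate = unname(x$rejection_rate),
             ci_low = unname(x$ci95[, 1]), ci_high = unname(x$ci95[, 2]),
             n_replications = x$n_replications, alpha = x$alpha,
             stringsAsFactors = FALSE)
}

#' Power study over effect models and effect sizes
#'
#' Simulates replications under each (effect model, effect size) grid cell,
#' tests under the requested models and reports rejection rates with exact
#' binomial confidence intervals. GCC p-values use a shared permutation null
#' per cell (the null draws condition on that cell's phenotype marginal).
#'
#' @param cfg base [twin_sim_config()] (its `effect_model`/`effect_size` are
#'   overridden per cell).
#' @param effect_models character vector of non-null effect models.
#' @param effect_sizes numeric vector of effect sizes (all non-zero).
#' @param models subset of `c("gcc", "kinship", "lme")`.
#' @param n_replications replications per cell.
#' @param alpha significance level.
#' @param n_perm permutations for the GCC shared null; must resolve `alpha`.
#' @inheritParams type1_error_study
#' @return data frame of rejection rates per cell and model.
#' @export
power_study <- function(cfg = twin_sim_config(),
                        effect_models = "additive", effect_sizes,
                        models = c("gcc", "kinship", "lme"),
                        n_replications = 200, alpha = 0.001,
                        n_perm = NULL, folds = 10,
                        weight_grid = seq(0, 1, by = 0.1),
                        scale_grid = c(0.3, 0.5, 1, 2)) {
  models <- match.arg(models, c("gcc", "kinship", "lme"), several.ok = TRUE)
  if (length(effect_models) == 0 || length(effect_sizes) == 0)
    stop_gcctwin("config_error", "empty study grid")
  if (any(effect_models == "null") || any(effect_sizes == 0))
    stop_gcctwin("misuse_error",
                 "null cells belong in type1_error_study, not power_study")
  if (is.null(n_perm)) n_perm <- max(999, ceiling(2 / alpha) - 1)
  if (1 / (n_perm + 1) > alpha)
    stop_gcctwin("resolution_error",
                 sprintf("%d permutations cannot resolve alpha = %g",
                         n_perm, alpha))
  out <- list()
  for (em in effect_models) for (es in effect_sizes) {
    cell <- cfg
    cell$effect_model <- em
    cell$effect_size <- es
    cell$seed <- derive_seed(cfg$seed,
                             match(em, c("additive", "dominant", "recessive",
                                         "quadratic")) * 1000L +
                               round(es * 100))
    base <- simulate_twin_genotypes(cell, seed = cell$seed)
    kin <- if ("kinship" %in% models) build_kinship(base$pheno) else NULL
    shared_null <- NULL
    if ("gcc" %in% models) {
      y_ref <- simulate_phenotype(base$dosage$values[, 1], base$pheno, cell,
                                  seed = derive_seed(cell$seed, 5L))$phenotype
      x_sampler <- local({
        counter <- 0L
        cellc <- cell
        function() {
          counter <<- counter + 1L
          simulate_twin_genotypes(
            cellc, seed = derive_seed(cellc$seed, 70000L + counter)
          )$dosage$values[, 1]
        }
      })
      shared_null <- gcc_null_calibration(
        x_sampler, y_ref, n_perm = n_perm, folds = folds,
        weight_grid = weight_grid, scale_grid = scale_grid,
        perm_unit = "none",
        seed = derive_seed(cell$seed, 9L))
    }
    reject <- matrix(FALSE, n_replications, length(models),
                     dimnames = list(NULL, models))
    for (r in seq_len(n_replications)) {
      seed_r <- derive_seed(cell$seed, 200000L + r)
      sim <- simulate_twin_genotypes(cell, seed = seed_r)
      ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cell,
                               seed = derive_seed(seed_r, 3L))
      g <- sim$dosage$values[, 1]
      y <- ph$phenotype
      for (mo in models) {
        p <- switch(mo,
          gcc = {
            fit <- gcc(g, y, folds = folds, weight_grid = weight_grid,
                       scale_grid = scale_grid,
                       seed = derive_seed(seed_r, 4L))
            null_pvalue(shared_null, fit$cvlrs)
          },
          kinship = kinship_gls(y, g, kinship = kin)$pvalue,
          lme = lme_pair(y, g, pair_id = ph$family_id)$pvalue)
        reject[r, mo] <- p < alpha
      }
    }
    for (mo in models) {
      k <- sum(reject[, mo])
      ci <- sim_binom_ci(k, n_replications)
      out[[length(out) + 1L]] <- data.frame(
        effect_model = em, effect_size = es, model = mo,
        power = k / n_replications, ci_low = ci[1], ci_high = ci[2],
        n_replications = n_replications, alpha = alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
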