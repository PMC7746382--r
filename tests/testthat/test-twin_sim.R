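test_that("MZ co-twins always share their genotype", {
  cfg <- twin_sim_config(n_mz_pairs = 200, n_dz_pairs = 0, seed = 1)
  g <- unname(simulate_twin_genotypes(cfg)$dosage$values[, 1])
  expect_equal(g[seq(1, 399, 2)], g[seq(2, 400, 2)])
})

test_that("singleton genotype frequencies match HWE expectations", {
  cfg <- twin_sim_config(n_mz_pairs = 0, n_dz_pairs = 0,
                         n_singletons = 20000, maf = 0.3, seed = 2)
  g <- simulate_twin_genotypes(cfg)$dosage$values[, 1]
  freq <- table(factor(g, levels = 0:2)) / length(g)
  expect_lt(abs(freq[["0"]] - 0.49), 0.01)
  expect_lt(abs(freq[["1"]] - 0.42), 0.01)
  expect_lt(abs(freq[["2"]] - 0.09), 0.01)
})

test_that("DZ within-pair dosage correlation is near 0.5", {
  cfg <- twin_sim_config(n_mz_pairs = 0, n_dz_pairs = 10000, maf = 0.3,
                         seed = 3)
  g <- simulate_twin_genotypes(cfg)$dosage$values[, 1]
  r <- cor(g[seq(1, length(g), 2)], g[seq(2, length(g), 2)])
  expect_lt(abs(r - 0.5), 0.03)
})

test_that("null phenotypes with no pair sharing are standard normal", {
  cfg <- twin_sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 5000,
                         pair_phenotype_correlation = 0, seed = 4)
  sim <- simulate_twin_genotypes(cfg)
  y <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg)$phenotype
  expect_gt(ks.test(y, "pnorm")$p.value, 0.01)
})

test_that("within-pair phenotype correlation matches its target", {
  cfg <- twin_sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500,
                         pair_phenotype_correlation = 0.4, seed = 5)
  sim <- simulate_twin_genotypes(cfg)
  y <- simulate_phenotype(sim$dosage$values[, 1] * 0, sim$pheno, cfg)$phenotype
  r <- cor(y[seq(1, length(y), 2)], y[seq(2, length(y), 2)])
  expect_lt(abs(r - 0.4), 0.04)
})

test_that("an additive SNP explains its targeted variance fraction", {
  cfg <- twin_sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 10000,
                         effect_model = "additive",
                         effect_size = effect_size_for_r2(0.05, "additive", 0.3),
                         maf = 0.3, seed = 6)
  sim <- simulate_twin_genotypes(cfg)
  ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg)
  r2 <- summary(lm(ph$phenotype ~ sim$dosage$values[, 1]))$r.squared
  expect_lt(abs(r2 - 0.05), 0.01)
})

test_that("skewed phenotypes are skewed but standardized", {
  cfg <- twin_sim_config(phenotype_family = "skewed", seed = 7)
  sim <- simulate_twin_genotypes(cfg)
  y <- simulate_phenotype(sim$dosage$values[, 1] * 0, sim$pheno, cfg)$phenotype
  expect_lt(abs(mean(y)), 1e-10)
  expect_equal(sd(y), 1, tolerance = 1e-10)
  expect_gt(mean(((y - mean(y)) / sd(y))^3), 0.5)  # right-skew
})

test_that("simulator output is reproducible from (config, seed)", {
  cfg <- twin_sim_config(seed = 8)
  a <- simulate_twin_genotypes(cfg)
  b <- simulate_twin_genotypes(cfg)
  expect_identical(a$dosage$values, b$dosage$values)
  expect_identical(simulate_phenotype(a$dosage$values[, 1], a$pheno, cfg),
                   simulate_phenotype(b$dosage$values[, 1], b$pheno, cfg))
  c <- simulate_twin_genotypes(cfg, seed = 9)
  expect_false(identical(a$dosage$values, c$dosage$values))
})

test_that("study harness rejects misconfigured designs", {
  expect_error(twin_sim_config(maf = 0.6), class = "gcctwin_config_error")
  expect_error(twin_sim_config(n_mz_pairs = 2, n_dz_pairs = 2),
               class = "gcctwin_config_error")
  cfg_eff <- twin_sim_config(effect_model = "additive", effect_size = 0.3)
  expect_error(type1_error_study(cfg_eff, n_replications = 100),
               class = "gcctwin_misuse_error")
  expect_error(type1_error_study(twin_sim_config(), n_replications = 50),
               class = "gcctwin_misuse_error")
  expect_error(power_study(twin_sim_config(), effect_models = "additive",
                           effect_sizes = 0),
               class = "gcctwin_misuse_error")
  expect_error(power_study(twin_sim_config(), effect_models = character(0),
                           effect_sizes = 0.3),
               class = "gcctwin_config_error")
  expect_error(power_study(twin_sim_config(), effect_models = "additive",
                           effect_sizes = 0.3, alpha = 1e-4, n_perm = 999),
               class = "gcctwin_resolution_error")
})

test_that("type-I error is calibrated at a second alpha level", {
  cfg <- twin_sim_config(n_mz_pairs = 20, n_dz_pairs = 50, seed = 10)
  st <- type1_error_study(cfg, models = c("kinship", "lme"),
                          n_replications = 400, alpha = 0.01)
  for (m in c("kinship", "lme")) {
    ci <- st$ci95[m, ]
    expect_true(ci[1] <= 0.01 && 0.01 <= ci[2],
                label = paste(m, "CI covers 0.01"))
  }
})

test_that("shared-null and per-replication GCC calibration agree", {
  cfg <- twin_sim_config(n_mz_pairs = 20, n_dz_pairs = 50, seed = 11)
  st_shared <- type1_error_study(cfg, models = "gcc", n_replications = 200,
                                 alpha = 0.05, calibration = "shared_null",
                                 n_perm = 399)
  st_perrep <- type1_error_study(cfg, models = "gcc", n_replications = 200,
                                 alpha = 0.05,
                                 calibration = "per_replication")
  expect_lt(abs(st_shared$rejection_rate[["gcc"]] -
                  st_perrep$rejection_rate[["gcc"]]), 0.1)
})
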