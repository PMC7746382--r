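test_that("kinship matrix encodes MZ 1, DZ 0.5, singletons identity", {
  ph <- as_pheno_table(data.frame(
    sample_id = c("m1", "m2", "d1", "d2", "s1", "s2"),
    phenotype = rnorm(6), age = 50, sex = "female",
    family_id = c("fm", "fm", "fd", "fd", "fs1", "fs2"),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "singleton", "singleton")))
  K <- as.matrix(build_kinship(ph))
  expect_equal(unname(diag(K)), rep(1, 6))
  expect_equal(K["m1", "m2"], 1)
  expect_equal(K["d1", "d2"], 0.5)
  expect_equal(K["s1", "s2"], 0)
  expect_equal(K["m1", "d1"], 0)
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), 0)
})

test_that("families larger than a twin pair are rejected", {
  df <- data.frame(sample_id = c("a", "b", "c"), phenotype = 0, age = 1,
                   sex = "male", family_id = "f", zygosity = "DZ")
  expect_error(as_pheno_table(df), class = "gcctwin_integrity_error")
})

test_that("kinship GLS with K = I reproduces OLS to 1e-8 relative", {
  set.seed(5)
  for (i in 1:5) {
    n <- 50 + 10 * i
    y <- rnorm(n); g <- rnorm(n); X <- cbind(rnorm(n))
    ph <- as_pheno_table(data.frame(
      sample_id = paste0("s", 1:n), phenotype = y, age = 50, sex = "male",
      family_id = paste0("f", 1:n), zygosity = "singleton"))
    fit <- kinship_gls(y, g, X, build_kinship(ph))
    ols <- summary(lm(y ~ X + g))$coefficients["g", ]
    expect_lt(abs(fit$beta - ols[1]) / abs(ols[1]), 1e-8)
    expect_lt(abs(fit$se - ols[2]) / ols[2], 1e-8)
    fit2 <- kinship_gls(y, g, X, build_kinship(ph),
                        varcomp_mode = "per_snp")
    expect_lt(abs(fit2$beta - ols[1]) / abs(ols[1]), 1e-8)
  }
})

test_that("zero genetic variance collapses the GLS onto OLS exactly", {
  set.seed(6)
  d <- toy_twin_data(n_mz = 10, n_dz = 20, seed = 3)
  y <- rnorm(nrow(d$pheno))  # iid phenotype: REML should pick delta = 0
  g <- d$dosage$values[, 1]
  fit <- kinship_gls(y, g, kinship = build_kinship(d$pheno))
  if (fit$delta == 0) {
    ols <- summary(lm(y ~ g))$coefficients["g", ]
    expect_equal(fit$beta, unname(ols[1]), tolerance = 1e-12)
    expect_equal(fit$se, unname(ols[2]), tolerance = 1e-12)
  }
  # forcing delta = 0 always reproduces OLS
  fit0 <- kinship_gls(y, g, kinship = build_kinship(d$pheno), delta = 0)
  ols <- summary(lm(y ~ g))$coefficients["g", ]
  expect_equal(fit0$beta, unname(ols[1]), tolerance = 1e-12)
  expect_equal(fit0$se, unname(ols[2]), tolerance = 1e-12)
})

test_that("swapping the members of every pair leaves the fit unchanged", {
  d <- toy_twin_data(n_mz = 30, n_dz = 30, seed = 7,
                     effect_model = "additive", effect_size = 0.2)
  n <- nrow(d$pheno)
  swap <- seq_len(n)
  swap[seq(1, 2 * 60, by = 2)] <- seq(2, 2 * 60, by = 2)
  swap[seq(2, 2 * 60, by = 2)] <- seq(1, 2 * 60, by = 2)
  y <- d$pheno$phenotype; g <- d$dosage$values[, 1]
  kin <- build_kinship(d$pheno)
  kin_sw <- build_kinship(d$pheno[swap, , drop = FALSE])
  f1 <- kinship_gls(y, g, kinship = kin)
  f2 <- kinship_gls(y[swap], g[swap], kinship = kin_sw)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("non-PSD covariance matrices are rejected", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 2
  expect_error(kinship_gls(rnorm(4), rnorm(4), kinship = K),
               class = "gcctwin_matrix_error")
})

test_that("both linear models recover an additive effect of 0.30", {
  cfg <- twin_sim_config(effect_model = "additive", effect_size = 0.3,
                         seed = 13)
  bk <- bl <- numeric(40)
  for (r in 1:40) {
    s <- 500 + r
    sim <- simulate_twin_genotypes(cfg, seed = s)
    ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg,
                             seed = s + 7)
    g <- sim$dosage$values[, 1]
    bk[r] <- kinship_gls(ph$phenotype, g,
                         kinship = build_kinship(ph))$beta
    bl[r] <- lme_pair(ph$phenotype, g, pair_id = ph$family_id)$beta
  }
  expect_lt(abs(mean(bk) - 0.3), 0.02)
  expect_lt(abs(mean(bl) - 0.3), 0.02)
})

test_that("LME with uncorrelated pairs matches OLS and finds ~zero pair variance", {
  set.seed(30)
  d <- toy_twin_data(n_mz = 0, n_dz = 150, seed = 9,
                     pair_phenotype_correlation = 0)
  y <- d$pheno$phenotype; g <- d$dosage$values[, 1]
  fit <- lme_pair(y, g, pair_id = d$pheno$family_id)
  expect_lt(fit$varcomp_genetic, 0.05)
  ols <- summary(lm(y ~ g))$coefficients["g", ]
  expect_lt(abs(fit$beta - ols[1]), 0.02)
})

test_that("LME and kinship GLS agree on DZ-only data", {
  # the two corrections model the same 2x2 block covariance
  set.seed(31)
  cfg <- twin_sim_config(n_mz_pairs = 0, n_dz_pairs = 150, seed = 17)
  sim <- simulate_twin_genotypes(cfg)
  lp_l <- lp_k <- numeric(60)
  for (i in 1:60) {
    simg <- simulate_twin_genotypes(cfg, seed = 900 + i)
    ph <- simulate_phenotype(simg$dosage$values[, 1] * 0, simg$pheno, cfg,
                             seed = 2000 + i)
    g <- simg$dosage$values[, 1]
    lp_k[i] <- -log10(kinship_gls(ph$phenotype, g,
                                  kinship = build_kinship(ph))$pvalue)
    lp_l[i] <- -log10(lme_pair(ph$phenotype, g,
                               pair_id = ph$family_id)$pvalue)
  }
  rel <- abs(lp_l - lp_k) / pmax(lp_k, 0.1)
  expect_lt(median(rel), 0.2)
})

test_that("group sizes above two are rejected by the pair LME", {
  expect_error(lme_pair(rnorm(6), rnorm(6), pair_id = c(1, 1, 1, 2, 2, 3)),
               class = "gcctwin_structure_error")
})
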