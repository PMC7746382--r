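test_that("phenotype adjustment yields covariate-orthogonal residuals", {
  set.seed(1)
  n <- 200
  ph <- as_pheno_table(data.frame(
    sample_id = paste0("s", 1:n),
    phenotype = 3 + rnorm(n),
    age = runif(n, 40, 80), sex = sample(c("male", "female"), n, TRUE),
    family_id = paste0("f", 1:n), zygosity = "singleton"))
  # zero age effect: residuals equal centred noise
  r0 <- adjust_phenotype(ph, covariates = "age")
  noise <- ph$phenotype - mean(ph$phenotype)
  expect_lt(max(abs(lm(r0 ~ ph$age)$coefficients[2])), 1e-10)
  # injected slope recovered: residual-age slope is 0
  ph2 <- ph
  ph2$phenotype <- 2 * ph$age + rnorm(n)
  r2 <- adjust_phenotype(ph2, covariates = c("age", "sex"))
  expect_lt(abs(cor(r2, ph2$age)), 1e-10)
  # oracle: direct normal-equations residuals match
  X <- cbind(1, ph2$age, as.integer(ph2$sex == "male"))
  beta <- solve(crossprod(X), crossprod(X, ph2$phenotype))
  expect_equal(r2, unname(ph2$phenotype - X %*% beta)[, 1], tolerance = 1e-8)
  # collinear covariates error
  ph3 <- ph
  ph3$age2 <- ph3$age
  expect_error(adjust_phenotype(ph3, covariates = c("age", "age2")),
               class = "gcctwin_rank_error")
})

test_that("Box-Cox finds near-identity and log transforms as appropriate", {
  set.seed(2)
  y <- rnorm(500, mean = 10)
  bc <- boxcox_transform(y)
  expect_gte(bc$lambda, 0.7); expect_lte(bc$lambda, 1.3)
  expect_gt(cor(bc$y, y), 0.99)
  expect_equal(bc$shift, 0)

  y2 <- exp(rnorm(2000))
  bc2 <- boxcox_transform(y2)
  expect_lt(abs(bc2$lambda), 0.2)

  y3 <- c(0, runif(99, 0, 5))
  expect_equal(boxcox_transform(y3)$shift, 1)
  expect_error(boxcox_transform(rep(2, 50)),
               class = "gcctwin_degenerate_error")
})

test_that("genomic inflation matches its construction", {
  expect_equal(round(genomic_inflation(rep(0.5, 11)), 4), 1)
  set.seed(3)
  expect_lt(abs(genomic_inflation(runif(100000)) - 1), 0.02)
  stats <- qchisq(runif(100000), df = 1, lower.tail = FALSE) * 1.2
  p <- pchisq(stats, df = 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p) - 1.2), 0.03)
  expect_error(genomic_inflation(numeric(0)), class = "gcctwin_input_error")
  expect_error(genomic_inflation(c(0.5, 0)), class = "gcctwin_input_error")
})

test_that("QQ, Manhattan and genotype-density tables follow their conventions", {
  qt1 <- qq_table(0.1)
  expect_equal(qt1$expected, -log10(1 / 2))
  expect_equal(qt1$observed, 1)
  set.seed(4)
  qt <- qq_table(runif(10000))
  d <- abs(qt$observed - qt$expected)
  expect_gt(mean(d < 0.5), 0.99)

  res <- data.frame(snp_id = c("a", "b", "c"), chrom = c("2", "1", "1"),
                    pos = c(5L, 10L, 2L), pvalue = c(0.1, 0.01, 0.5))
  mt <- manhattan_table(res)
  expect_equal(mt$snp_id, c("c", "b", "a"))
  expect_equal(mt$neglog10p[2], 2)

  gd <- genotype_density_table(c(0.1, 0.9, 1.2, 2.0, 1.8), rnorm(5))
  expect_equal(names(gd), c("0", "1", "2"))
  expect_equal(lengths(gd), c(`0` = 1L, `1` = 2L, `2` = 2L))
})

test_that("null scans report ~no significant SNPs for every model", {
  cfg <- twin_sim_config(n_mz_pairs = 20, n_dz_pairs = 40, n_snps = 50,
                         seed = 5)
  sim <- simulate_twin_genotypes(cfg)
  ph <- simulate_phenotype(sim$dosage$values[, 1] * 0, sim$pheno, cfg)
  for (m in c("kinship", "lme", "gcc")) {
    sc <- run_scan(sim$dosage, ph,
                   scan_config(model = m, gcc_calibration = "shared",
                               n_perm = 199, seed = 6))
    expect_equal(nrow(sc$results), 50)
    expect_lte(sc$n_gw_significant, 1)
    expect_true(all(sc$results$model == m))
    if (m == "gcc") expect_true(all(is.na(sc$results$beta)))
    else expect_true(all(is.finite(sc$results$beta)))
  }
})

test_that("an injected effect SNP attains the smallest p-value in all models", {
  cfg <- twin_sim_config(n_mz_pairs = 100, n_dz_pairs = 200, n_snps = 20,
                         seed = 7, effect_model = "additive",
                         effect_size = effect_size_for_r2(0.08))
  sim <- simulate_twin_genotypes(cfg)
  ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg)
  for (m in c("kinship", "lme", "gcc")) {
    sc <- run_scan(sim$dosage, ph,
                   scan_config(model = m, gcc_calibration = "shared",
                               n_perm = 199, seed = 8))
    expect_equal(sc$results$snp_id[which.min(sc$results$pvalue)], "sim1",
                 label = paste("top SNP under", m))
  }
})

test_that("rare SNPs are excluded by the default MAF filter", {
  set.seed(9)
  vals <- cbind(rbinom(100, 2, 0.01), rbinom(100, 2, 0.3))
  dm <- toy_dosage_matrix(vals)
  ph <- as_pheno_table(data.frame(
    sample_id = paste0("s", 1:100), phenotype = rnorm(100),
    age = runif(100, 40, 80), sex = sample(c("male", "female"), 100, TRUE),
    family_id = paste0("f", 1:100), zygosity = "singleton"))
  sc <- run_scan(dm, ph, scan_config(model = "kinship"))
  expect_false("snp1" %in% sc$results$snp_id)
  expect_true("snp2" %in% sc$results$snp_id)
})

test_that("scan results are invariant to sample order", {
  d <- toy_twin_data(n_mz = 15, n_dz = 30, seed = 10, n_snps = 5)
  cfg <- scan_config(model = "kinship", seed = 11)
  sc1 <- run_scan(d$dosage, d$pheno, cfg)
  perm <- sample(nrow(d$pheno))
  sc2 <- run_scan(d$dosage, d$pheno[perm, , drop = FALSE], cfg)
  expect_equal(sc1$results$pvalue, sc2$results$pvalue, tolerance = 1e-10)
})

test_that("disjoint sample sets raise a join error", {
  d <- toy_twin_data(n_mz = 10, n_dz = 10, seed = 12)
  ph <- d$pheno
  ph$sample_id <- paste0("other_", ph$sample_id)
  expect_error(run_scan(d$dosage, ph, scan_config(model = "kinship")),
               class = "gcctwin_join_error")
})

test_that("monomorphic SNPs are skipped with a logged reason", {
  d <- toy_twin_data(n_mz = 15, n_dz = 30, seed = 13)
  vals <- cbind(d$dosage$values[, 1], 0)
  dm <- toy_dosage_matrix(vals, maf = c(0.3, 0))
  dm$samples <- d$dosage$samples
  rownames(dm$values) <- dm$samples
  sc <- run_scan(dm, d$pheno, scan_config(model = "kinship", maf_min = 0))
  expect_equal(nrow(sc$results), 1)
  expect_match(sc$skipped, "snp2")
})

test_that("Box-Cox on already-normal phenotypes barely changes the ranking", {
  d <- toy_twin_data(n_mz = 30, n_dz = 60, seed = 14, n_snps = 40)
  p1 <- run_scan(d$dosage, d$pheno,
                 scan_config(model = "kinship", seed = 15))$results$pvalue
  p2 <- run_scan(d$dosage, d$pheno,
                 scan_config(model = "kinship", boxcox = TRUE,
                             seed = 15))$results$pvalue
  expect_gt(cor(-log10(p1), -log10(p2)), 0.99)
})
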