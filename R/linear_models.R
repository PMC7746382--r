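# Twin-aware linear comparators: kinship-covariance GLS and a pair-level
# random-intercept mixed model.

#' Build the expected relationship (kinship) matrix for a twin sample
#'
#' Expected additive relationship convention: diagonal 1, MZ co-twins 1,
#' DZ co-twins 0.5, unrelated 0 (twice the kinship coefficient, so the
#' genetic variance component is interpretable as additive genetic
#' variance). The matrix is block-diagonal by family; its eigenstructure is
#' carried analytically (pair blocks rotate to within-pair sums and
#' differences), which keeps repeated REML fits linear-time.
#'
#' @param pheno a `pheno_table` (or validated data frame) with `sample_id`,
#'   `family_id`, `zygosity`.
#' @return An object of class `kinship_matrix`.
#' @export
build_kinship <- function(pheno) {
  pheno <- if (inherits(pheno, "pheno_table")) pheno else as_pheno_table(pheno)
  n <- nrow(pheno)
  fam <- split(seq_len(n), pheno$family_id)
  sizes <- lengths(fam)
  if (any(sizes > 2))
    stop_gcctwin("structure_error", "family with more than 2 members: twin design only")
  pairs <- fam[sizes == 2]
  i <- vapply(pairs, `[`, integer(1), 1L)
  j <- vapply(pairs, `[`, integer(1), 2L)
  zyg <- as.character(pheno$zygosity)[i]
  r <- ifelse(zyg == "MZ", 1, ifelse(zyg == "DZ", 0.5, 0))
  structure(list(samples = pheno$sample_id, n = n,
                 pair_i = unname(i), pair_j = unname(j), pair_r = unname(r),
                 singles = unname(unlist(fam[sizes == 1]))),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("Kinship (expected relationship) matrix: ", x$n, " samples, ",
      length(x$pair_i), " twin pairs (", sum(x$pair_r == 1), " MZ, ",
      sum(x$pair_r == 0.5), " DZ), ", length(x$singles), " singletons\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  K <- diag(x$n)
  if (length(x$pair_i)) {
    K[cbind(x$pair_i, x$pair_j)] <- x$pair_r
    K[cbind(x$pair_j, x$pair_i)] <- x$pair_r
  }
  dimnames(K) <- list(x$samples, x$samples)
  K
}

# Eigen machinery: rotate() maps vectors/matrices into the eigenbasis of K,
# d holds the eigenvalues in the rotated coordinate order.
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_matrix")) {
    d <- rep(1, K$n)
    if (length(K$pair_i)) {
      d[K$pair_i] <- 1 + K$pair_r
      d[K$pair_j] <- 1 - K$pair_r
    }
    i <- K$pair_i; j <- K$pair_j
    rotate <- function(M) {
      M <- as.matrix(M)
      if (!length(i)) return(M)
      Z <- M
      Z[i, ] <- (M[i, , drop = FALSE] + M[j, , drop = FALSE]) / sqrt(2)
      Z[j, ] <- (M[i, , drop = FALSE] - M[j, , drop = FALSE]) / sqrt(2)
      Z
    }
    list(rotate = rotate, d = d, n = K$n)
  } else {
    K <- as.matrix(K)
    if (!isSymmetric(unname(K), tol = 1e-8))
      stop_gcctwin("matrix_error", "kinship matrix must be symmetric")
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -1e-8)
      stop_gcctwin("matrix_error", "kinship matrix is not positive semidefinite")
    U <- e$vectors
    list(rotate = function(M) crossprod(U, as.matrix(M)),
         d = pmax(e$values, 0), n = nrow(K))
  }
}

# REML profile criterion for V = sigma_e^2 (delta * D + I) on rotated data.
reml_nll <- function(delta, zy, ZX, d) {
  w <- 1 / (delta * d + 1)
  XtWX <- crossprod(ZX * w, ZX)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(ZX * w, zy)))
  r <- zy - ZX %*% beta
  rss <- sum(w * r * r)
  np <- length(zy) - ncol(ZX)
  0.5 * (np * log(rss / np) + sum(log(delta * d + 1)) +
           2 * sum(log(diag(ch))))
}

reml_delta <- function(zy, ZX, d, upper = 1e3) {
  f <- function(ld) reml_nll(exp(ld), zy, ZX, d)
  opt <- tryCatch(optimize(f, interval = c(log(1e-6), log(upper))),
                  error = function(e)
                    stop_gcctwin("convergence_error",
                                 paste("REML optimization failed:",
                                       conditionMessage(e))))
  cand <- c(0, exp(opt$minimum))
  vals <- c(reml_nll(0, zy, ZX, d), opt$objective)
  delta <- cand[which.min(vals)]
  if (!is.finite(min(vals)))
    stop_gcctwin("convergence_error", "REML criterion non-finite at optimum")
  delta
}

gls_wald <- function(zy, ZXf, d, delta, coef_idx) {
  w <- 1 / (delta * d + 1)
  XtWX <- crossprod(ZXf * w, ZXf)
  XtWXi <- tryCatch(solve(XtWX), error = function(e)
    stop_gcctwin("rank_error", "singular design in GLS fit"))
  beta <- XtWXi %*% crossprod(ZXf * w, zy)
  r <- zy - ZXf %*% beta
  np <- length(zy) - ncol(ZXf)
  s2 <- sum(w * r * r) / np
  se <- sqrt(s2 * diag(XtWXi))
  list(beta = beta[coef_idx], se = se[coef_idx], s2 = s2)
}

new_twin_assoc <- function(model, beta, se, varcomp_genetic, varcomp_residual,
                           n, extra = list()) {
  z <- beta / se
  structure(c(list(model = model, beta = unname(beta), se = unname(se),
                   wald_z = unname(z),
                   pvalue = 2 * pnorm(-abs(unname(z))),
                   varcomp_genetic = varcomp_genetic,
                   varcomp_residual = varcomp_residual, n = n), extra),
            class = "twin_assoc")
}

#' @export
print.twin_assoc <- function(x, digits = 4, ...) {
  cat(switch(x$model,
             kinship = "Kinship-covariance GLS fit",
             lme = "Pair random-intercept mixed model"),
      " (n = ", x$n, ")\n", sep = "")
  cat("  beta = ", format(x$beta, digits = digits), "  se = ",
      format(x$se, digits = digits), "  z = ",
      format(x$wald_z, digits = digits), "  p = ",
      format(x$pvalue, digits = digits), "\n", sep = "")
  cat("  variance components: ",
      if (x$model == "kinship") "genetic" else "pair", " = ",
      format(x$varcomp_genetic, digits = digits), ", residual = ",
      format(x$varcomp_residual, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.twin_assoc <- function(object, ...) {
  c(beta = object$beta, se = object$se, z = object$wald_z,
    pvalue = object$pvalue)
}

#' Kinship-covariance generalized least squares association test
#'
#' Fits the model \eqn{y = X\alpha + g\beta + \epsilon} with
#' \eqn{\mathrm{Var}(\epsilon) = \sigma^2_g K + \sigma^2_e I}, where K is the
#' expected relationship matrix, and tests the SNP dosage coefficient by a
#' Wald test under the estimated covariance. Variance components are
#' estimated by REML; with `varcomp_mode = "null_once"` they are estimated
#' under the covariate-only model (the standard two-step GWAS practice,
#' reusable across SNPs), with `"per_snp"` under the full model.
#'
#' @param y numeric phenotype vector.
#' @param g numeric dosage vector.
#' @param X optional covariate matrix (an intercept is always added).
#' @param kinship a `kinship_matrix` from [build_kinship()], or a plain
#'   symmetric PSD matrix.
#' @param varcomp_mode `"null_once"` or `"per_snp"`.
#' @param delta optional fixed variance ratio \eqn{\sigma^2_g/\sigma^2_e}
#'   (skips REML; used internally when scanning many SNPs).
#' @return a `twin_assoc` object with `beta`, `se`, `wald_z`, `pvalue` and
#'   variance components.
#' @export
kinship_gls <- function(y, g, X = NULL, kinship,
                        varcomp_mode = c("null_once", "per_snp"),
                        delta = NULL) {
  varcomp_mode <- match.arg(varcomp_mode)
  n <- length(y)
  if (length(g) != n)
    stop_gcctwin("input_error", "y and g must have the same length")
  eig <- kinship_eigen(kinship)
  if (eig$n != n)
    stop_gcctwin("input_error", "kinship dimension does not match data")
  X0 <- cbind(`(Intercept)` = rep(1, n), X)
  if (qr(X0)$rank < ncol(X0))
    stop_gcctwin("rank_error", "collinear covariates")
  Xf <- cbind(X0, dosage = g)
  zy <- eig$rotate(matrix(y, ncol = 1))
  ZX0 <- eig$rotate(X0)
  ZXf <- eig$rotate(Xf)
  if (is.null(delta)) {
    delta <- if (varcomp_mode == "null_once") reml_delta(zy, ZX0, eig$d)
             else reml_delta(zy, ZXf, eig$d)
  }
  fit <- gls_wald(zy, ZXf, eig$d, delta, coef_idx = ncol(ZXf))
  new_twin_assoc("kinship", fit$beta, fit$se,
                 varcomp_genetic = delta * fit$s2,
                 varcomp_residual = fit$s2, n = n,
                 extra = list(delta = delta, varcomp_mode = varcomp_mode))
}

# REML variance ratio under the covariate-only model, for reuse across SNPs.
kinship_null_delta <- function(y, X = NULL, kinship) {
  n <- length(y)
  eig <- kinship_eigen(kinship)
  X0 <- cbind(`(Intercept)` = rep(1, n), X)
  reml_delta(eig$rotate(matrix(y, ncol = 1)), eig$rotate(X0), eig$d)
}

#' Pair random-intercept mixed-model association test
#'
#' Fits \eqn{y = X\alpha + g\beta + b_{pair} + \epsilon} with a random
#' intercept per twin pair (maximum likelihood via [lme4::lmer()]) and tests
#' the dosage coefficient with a Wald z test. Within-pair phenotype
#' correlation is absorbed by the random intercept regardless of zygosity.
#'
#' @param y numeric phenotype vector.
#' @param g numeric dosage vector.
#' @param X optional covariate matrix.
#' @param pair_id grouping vector (family/pair id per sample); every group
#'   must have at most 2 members.
#' @return a `twin_assoc` object.
#' @export
lme_pair <- function(y, g, X = NULL, pair_id) {
  n <- length(y)
  if (length(g) != n || length(pair_id) != n)
    stop_gcctwin("input_error", "y, g and pair_id must have the same length")
  if (any(table(pair_id) > 2))
    stop_gcctwin("structure_error", "group with more than 2 members: twin design only")
  dat <- data.frame(y = y, g = g, pair = as.factor(pair_id))
  form <- y ~ g + (1 | pair)
  if (!is.null(X)) {
    X <- as.matrix(X)
    colnames(X) <- paste0("c", seq_len(ncol(X)))
    dat <- cbind(dat, X)
    form <- stats::as.formula(
      paste("y ~ g +", paste(colnames(X), collapse = " + "), "+ (1 | pair)"))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e)
      stop_gcctwin("rank_error", paste("mixed-model fit failed:",
                                       conditionMessage(e))))
  fe <- lme4::fixef(fit)
  if (!"g" %in% names(fe))
    stop_gcctwin("rank_error", "dosage term dropped from mixed-model design")
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["g"]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_pair <- vc$vcov[vc$grp == "pair"][1]
  v_res <- vc$vcov[vc$grp == "Residual"][1]
  new_twin_assoc("lme", fe[["g"]], se,
                 varcomp_genetic = v_pair, varcomp_residual = v_res, n = n)
}
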