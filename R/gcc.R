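#' Gaussian-kernel marginal density estimate
#'
#' Fits a one-dimensional Gaussian kernel density with a rule-of-thumb
#' bandwidth and returns a model that can be evaluated at arbitrary points
#' with [density_eval()]. This is the marginal building block of the GCC
#' independence null, whose joint density is the product of the two marginal
#' estimates.
#'
#' @param x numeric vector of at least 10 finite observations.
#' @param bandwidth_rule `"silverman"` (Silverman's rule of thumb,
#'   [stats::bw.nrd0()]) or `"scott"` ([stats::bw.nrd()]).
#' @return An object of class `gcc_density` with fields `kind`, `bandwidth`
#'   and `training_points`.
#' @examples
#' m <- estimate_marginal(rnorm(200))
#' density_eval(m, 0)
#' @export
estimate_marginal <- function(x, bandwidth_rule = c("silverman", "scott")) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (!is.numeric(x) || length(x) < 10)
    stop_gcctwin("sample_size_error", "need at least 10 observations for a marginal density")
  if (any(!is.finite(x)))
    stop_gcctwin("input_error", "non-finite values in density input")
  if (var(x) == 0)
    stop_gcctwin("degenerate_error", "zero-variance input: marginal density is degenerate")
  bw <- switch(bandwidth_rule, silverman = bw.nrd0(x), scott = stats::bw.nrd(x))
  structure(list(kind = "marginal", bandwidth = bw, bandwidth_rule = bandwidth_rule,
                 training_points = x),
            class = "gcc_density")
}

#' Evaluate a fitted kernel density
#'
#' @param model a `gcc_density` object from [estimate_marginal()].
#' @param at numeric vector of evaluation points.
#' @return numeric vector of density values (strictly positive).
#' @export
density_eval <- function(model, at) {
  stopifnot(inherits(model, "gcc_density"))
  # floored at the smallest positive double: Gaussian kernels are strictly
  # positive analytically, but the exponential underflows far in the tails
  pmax(kde1_eval_cpp(as.numeric(at), model$training_points, model$bandwidth),
       .Machine$double.xmin)
}

#' @export
print.gcc_density <- function(x, ...) {
  cat("Gaussian kernel density (", x$bandwidth_rule, " bandwidth ",
      format(x$bandwidth, digits = 4), ", n = ", length(x$training_points),
      ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# GCC fit

gcc_check_xy <- function(x, y, min_n = 20L) {
  if (length(x) != length(y))
    stop_gcctwin("input_error", "x and y must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_gcctwin("input_error", "non-finite values in x or y")
  if (length(x) < min_n)
    stop_gcctwin("sample_size_error",
                 sprintf("need at least %d paired observations, got %d", min_n, length(x)))
  if (var(x) == 0 || var(y) == 0)
    stop_gcctwin("degenerate_error", "zero-variance input")
  invisible(TRUE)
}

# Preprocessing shared by gcc(), gcc_test() and the shared-null machinery:
# seeded jitter de-degenerates hard-call genotypes (their class labels are
# kept for the stratified dependent component), and the normal-scores
# (copula) transform maps each variable onto the fixed multiset
# qnorm(i/(n+1)), i = 1..n. The transform leaves dependence intact while
# removing marginal shape entirely, so the kernel null model cannot misfit
# the marginals and the statistic measures departure from independence only.
gcc_prepare <- function(x, y, jitter, transform, seed) {
  cls_x <- if (is_hard_calls(x)) round(x) else NULL
  cls_y <- if (is_hard_calls(y)) round(y) else NULL
  if (jitter == "auto") {
    if (!is.null(cls_x))
      x <- x + with_seed(derive_seed(seed, 11L), runif(length(x), -0.05, 0.05))
    if (!is.null(cls_y))
      y <- y + with_seed(derive_seed(seed, 13L), runif(length(y), -0.05, 0.05))
  }
  if (transform == "normal_scores") {
    n <- length(x)
    x <- qnorm(rank(x, ties.method = "average") / (n + 1))
    y <- qnorm(rank(y, ties.method = "average") / (n + 1))
  }
  list(x = x, y = y, cls_x = cls_x, cls_y = cls_y)
}

# y-bandwidth scale factors for the stratified (genotype-class conditional)
# dependent component; per-class Silverman bandwidths are rescaled by these.
gcc_cond_scales <- c(0.75, 1, 1.5)

# Class-conditional density of held-out v given the discrete classes of the
# other variable: per class, a KDE trained on that class's training members
# only. Classes with fewer than 5 training points fall back to the marginal
# (no dependence contribution for those points).
cond_density_fold <- function(v_te, v_tr, cls_te, cls_tr, f_marg_te, sc) {
  out <- f_marg_te
  for (cl in unique(cls_te)) {
    trc <- v_tr[cls_tr == cl]
    idx <- which(cls_te == cl)
    if (length(trc) >= 5) {
      bwc <- bw.nrd0(trc)
      if (bwc <= 0) bwc <- max(sd(trc), 1e-3)
      out[idx] <- kde1_eval_cpp(v_te[idx], trc, bwc * sc)
    }
  }
  out
}

# Cross-validated fit of the independence null and the mixture alternative.
# Candidate dependent components: product-kernel joint estimates at every
# per-dimension bandwidth scale pair from scale_grid, plus stratified
# class-conditional estimates when a variable is hard-call discrete.
gcc_fit_core <- function(x, y, folds, weight_grid, scale_grid, seed,
                         cls_x = NULL, cls_y = NULL) {
  n <- length(x)
  folds <- as.integer(folds)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  m <- length(scale_grid)
  n_joint <- m * m
  n_cx <- if (!is.null(cls_x)) length(gcc_cond_scales) else 0L
  n_cy <- if (!is.null(cls_y)) length(gcc_cond_scales) else 0L
  p0 <- numeric(n)
  pd <- matrix(0, n, n_joint + n_cx + n_cy)
  for (k in seq_len(folds)) {
    te <- which(fold_id == k)
    if (!length(te)) next
    tr <- which(fold_id != k)
    hx <- bw.nrd0(x[tr])
    hy <- bw.nrd0(y[tr])
    if (hx <= 0 || hy <= 0)
      stop_gcctwin("degenerate_error", "degenerate bandwidth within a CV fold")
    D <- gcc_fold_density_cpp(x[te], y[te], x[tr], y[tr], hx, hy, scale_grid)
    fx <- D[, 1]
    fy <- D[, 2]
    p0[te] <- fx * fy
    pd[te, seq_len(n_joint)] <- D[, -(1:2), drop = FALSE]
    if (n_cx > 0) for (si in seq_len(n_cx)) {
      fyc <- cond_density_fold(y[te], y[tr], cls_x[te], cls_x[tr], fy,
                               gcc_cond_scales[si])
      pd[te, n_joint + si] <- fx * fyc
    }
    if (n_cy > 0) for (si in seq_len(n_cy)) {
      fxc <- cond_density_fold(x[te], x[tr], cls_y[te], cls_y[tr], fx,
                               gcc_cond_scales[si])
      pd[te, n_joint + n_cx + si] <- fxc * fy
    }
  }
  tiny <- .Machine$double.xmin
  p0 <- pmax(p0, tiny)
  pd <- pmax(pd, tiny)
  ll0 <- sum(log(p0))
  best <- list(ll = ll0, w = 0, cand = 0L)
  for (ci in seq_len(ncol(pd))) {
    pj <- pd[, ci]
    for (w in weight_grid) {
      if (w == 0) next
      ll <- sum(log(w * pj + (1 - w) * p0))
      if (ll > best$ll) best <- list(ll = ll, w = w, cand = ci)
    }
  }
  component <- if (best$cand == 0L) {
    "none (alternative collapsed onto null)"
  } else if (best$cand <= n_joint) {
    k <- (best$cand - 1L) %/% m
    l <- (best$cand - 1L) %% m
    sprintf("joint kernel (sx=%g, sy=%g)", scale_grid[k + 1L],
            scale_grid[l + 1L])
  } else if (best$cand <= n_joint + n_cx) {
    sprintf("genotype-class conditional y|x (bw scale %g)",
            gcc_cond_scales[best$cand - n_joint])
  } else {
    sprintf("genotype-class conditional x|y (bw scale %g)",
            gcc_cond_scales[best$cand - n_joint - n_cx])
  }
  cvlrs <- -2 * (ll0 - best$ll)
  A_raw <- 1 - exp(-cvlrs / n)
  list(A = max(0, min(1, A_raw)), clamped = (A_raw < 0 || A_raw > 1),
       mixture_weight = best$w, component = component,
       cv_loglik_null = ll0, cv_loglik_alt = best$ll, cvlrs = cvlrs,
       n = n, folds = folds)
}

#' Fit the generalized correlation coefficient
#'
#' Measures the dependence between two variables with a density-ratio
#' generalized R-squared. The independence null models the joint density as
#' the product of Gaussian-kernel marginal estimates, \eqn{P(x)P(y)}; the
#' alternative is a mixture \eqn{w\,P(x,y) + (1-w)\,P(x)P(y)} of a dependent
#' joint kernel estimate and the independent component. Densities are always
#' evaluated out-of-fold: the data are split into `folds` cross-validation
#' folds by a seeded shuffle, each fold's densities are trained on the
#' remaining folds, and the mixture weight (together with the dependent
#' component's bandwidth configuration) maximizes the summed held-out
#' log-likelihood. The association strength is
#'
#' \deqn{A = 1 - \prod_i \left[\frac{P(x_i, y_i \mid \mathrm{null})}
#'   {P(x_i, y_i \mid \mathrm{alt})}\right]^{2/n},}
#'
#' clamped to \eqn{[0, 1]}: 0 when the variables are independent, approaching
#' 1 under perfect association, and approximately the squared Pearson
#' correlation for bivariate Gaussian data. The cross-validation
#' likelihood-ratio statistic is
#' \eqn{\mathrm{CVLRS} = -2 \log(L_{cv}(\mathrm{Null}) / L_{cv}(\mathrm{Alt}))}.
#'
#' Hard-call genotype vectors (values on \{0, 1, 2\}) are de-degenerated by a
#' small seeded uniform jitter (amplitude 0.05) before density estimation;
#' imputed dosages are used as-is. By default both variables are then mapped
#' to normal scores (`qnorm(rank/(n+1))`), a copula transform that leaves
#' dependence intact while fixing each marginal to the same near-Gaussian
#' multiset: the null model cannot misfit the marginals, A becomes exactly
#' invariant under strictly monotone rescaling of either variable, and the
#' statistic is insensitive to outliers and skewness.
#'
#' @param x,y numeric vectors of equal length, n >= 20.
#' @param folds number of cross-validation folds (>= 2).
#' @param weight_grid candidate mixture weights; must contain 0 so the
#'   alternative can collapse onto the null.
#' @param scale_grid candidate bandwidth scale factors, relative to the
#'   per-dimension Silverman bandwidth, for the dependent joint kernel;
#'   every (sx, sy) pair from the grid is a candidate, chosen by held-out
#'   likelihood together with the mixture weight. For hard-call genotype
#'   variables the candidate set additionally contains stratified
#'   genotype-class conditional estimates (the density analogue of
#'   genotype-specific phenotype densities), which are far more efficient
#'   for class-structured dependence.
#' @param jitter `"auto"` jitters hard-call variables only; `"none"` disables.
#' @param transform `"normal_scores"` (default) or `"none"`.
#' @param seed integer seed for fold assignment (and jitter).
#' @return An object of class `gcc` with components `A`, `mixture_weight`,
#'   `component`, `cv_loglik_null`, `cv_loglik_alt`, `cvlrs`, `n`,
#'   `folds`, `seed`, `clamped`.
#' @examples
#' set.seed(1)
#' x <- rnorm(300); y <- x^2 + rnorm(300, sd = 0.5)
#' fit <- gcc(x, y, seed = 1)
#' fit$A                      # detects the non-linear dependence
#' cor(x, y)^2                # which Pearson largely misses
#' @seealso [gcc_test()] for permutation p-values.
#' @export
gcc <- function(x, y, folds = 10, weight_grid = seq(0, 1, by = 0.1),
                scale_grid = c(0.3, 0.5, 1, 2), jitter = c("auto", "none"),
                transform = c("normal_scores", "none"), seed = 1L) {
  jitter <- match.arg(jitter)
  transform <- match.arg(transform)
  x <- as.numeric(x); y <- as.numeric(y)
  gcc_check_xy(x, y)
  if (folds < 2) stop_gcctwin("config_error", "folds must be >= 2")
  if (!any(weight_grid == 0))
    stop_gcctwin("config_error", "weight_grid must contain 0")
  if (any(weight_grid < 0 | weight_grid > 1))
    stop_gcctwin("config_error", "weight_grid must lie in [0, 1]")
  if (any(scale_grid <= 0))
    stop_gcctwin("config_error", "scale_grid must be positive")
  pr <- gcc_prepare(x, y, jitter, transform, seed)
  fit <- gcc_fit_core(pr$x, pr$y, folds, weight_grid, scale_grid, seed,
                      cls_x = pr$cls_x, cls_y = pr$cls_y)
  fit$seed <- as.integer(seed)
  fit$call <- match.call()
  class(fit) <- "gcc"
  fit
}

#' @export
print.gcc <- function(x, digits = 4, ...) {
  cat("Generalized correlation coefficient fit (n = ", x$n, ", ",
      x$folds, "-fold CV)\n", sep = "")
  cat("  A      = ", format(x$A, digits = digits),
      if (x$clamped) "  [clamped]" else "", "\n", sep = "")
  cat("  CVLRS  = ", format(x$cvlrs, digits = digits), "\n", sep = "")
  cat("  mixture weight = ", format(x$mixture_weight, digits = digits),
      ", dependent component: ", x$component,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.gcc <- function(object, ...) {
  out <- object
  class(out) <- c("summary.gcc", "gcc")
  out
}

#' @export
print.summary.gcc <- function(x, digits = 4, ...) {
  print.gcc(x, digits = digits, ...)
  cat("  held-out log-likelihood: null = ",
      format(x$cv_loglik_null, digits = digits + 2), ", alternative = ",
      format(x$cv_loglik_alt, digits = digits + 2), "\n", sep = "")
  invisible(x)
}

#' @export
coef.gcc <- function(object, ...) {
  c(A = object$A, mixture_weight = object$mixture_weight,
    cvlrs = object$cvlrs)
}

# ---------------------------------------------------------------------------
# Generalized Pareto upper tail for p-values below permutation resolution

fit_gpd_tail <- function(stats, tail_frac = 0.1) {
  n <- length(stats)
  k <- max(10L, ceiling(tail_frac * n))
  if (k >= n) return(NULL)
  u <- sort(stats, decreasing = TRUE)[k + 1L]
  z <- stats[stats > u] - u
  if (length(z) < 10 || all(z == 0)) return(NULL)
  nll <- function(par) {
    sigma <- exp(par[1]); xi <- par[2]
    w <- 1 + xi * z / sigma
    if (any(w <= 0)) return(1e10)
    if (abs(xi) < 1e-9) sum(par[1] + z / sigma)
    else sum(par[1] + (1 / xi + 1) * log(w))
  }
  o <- try(optim(c(log(mean(z)), 0.1), nll), silent = TRUE)
  if (inherits(o, "try-error") || !is.finite(o$value)) return(NULL)
  list(u = u, k = length(z), n = n, sigma = exp(o$par[1]), xi = o$par[2])
}

gpd_tail_prob <- function(gpd, q) {
  # P(stat > q) for q above the threshold, via the fitted exceedance law
  z <- q - gpd$u
  if (z <= 0) return(gpd$k / gpd$n)
  s <- if (abs(gpd$xi) < 1e-9) {
    exp(-z / gpd$sigma)
  } else {
    w <- 1 + gpd$xi * z / gpd$sigma
    if (w <= 0) 0 else w^(-1 / gpd$xi)
  }
  (gpd$k / gpd$n) * s
}

gpd_tail_quantile <- function(gpd, p_upper) {
  # stat value with upper-tail probability p_upper (p_upper < k/n)
  s <- p_upper * gpd$n / gpd$k
  z <- if (abs(gpd$xi) < 1e-9) -gpd$sigma * log(s)
       else gpd$sigma * (s^(-gpd$xi) - 1) / gpd$xi
  gpd$u + z
}

# ---------------------------------------------------------------------------
# Permutation test

# Permutation index for the y side: individual-level, or whole twin pairs
# permuted among pairs of the same size and stratum (zygosity), singletons
# among singletons. Stratifying by zygosity keeps the set of phenotype
# pairs confronting MZ genotype positions identical between the observed
# statistic and its permutation null.
permute_idx <- function(n, perm_unit, pair_id, strata = NULL) {
  if (perm_unit == "none") return(seq_len(n))
  if (perm_unit == "individual") return(sample.int(n))
  idx <- split(seq_len(n), pair_id)
  sizes <- lengths(idx)
  keys <- if (is.null(strata)) as.character(sizes)
          else paste(sizes, vapply(idx, function(i) as.character(strata[i[1]]),
                                   character(1)))
  out <- seq_len(n)
  for (s in unique(keys)) {
    grp <- idx[keys == s]
    if (length(grp) > 1) {
      shuffled <- grp[sample(length(grp))]
      out[unlist(grp)] <- unlist(shuffled)
    }
  }
  out
}

permute_y <- function(y, perm_unit, pair_id, strata = NULL) {
  y[permute_idx(length(y), perm_unit, pair_id, strata)]
}

#' Permutation p-value for the GCC test
#'
#' Calibrates the cross-validation likelihood-ratio statistic by refitting the
#' GCC on `(x, permuted y)`: permutation preserves both marginal distributions
#' exactly, so the null distribution is conditional on the observed marginals
#' (including the marginal structure induced by correlated twin samples). The
#' empirical p-value is `(1 + #\{null >= observed\}) / (n_perm + 1)`. With
#' `tail_method = "gpd_tail"`, a generalized-Pareto fit to the upper tail of
#' the permutation statistics extrapolates p-values beyond the permutation
#' resolution, which a genome-wide scan needs to resolve p near 5e-8.
#'
#' For twin samples, supply `pair_id` and use `perm_unit = "pair"`: whole
#' pairs of phenotype values are permuted against whole pairs of genotypes,
#' so the within-pair phenotype correlation stays in the null distribution
#' and only the genotype-phenotype link is broken. Individual-level
#' permutation on paired data destroys the co-twin duplication that is
#' present under the null and anti-conservatively inflates the test.
#'
#' @inheritParams gcc
#' @param n_perm number of permutations (>= 19 to resolve alpha = 0.05).
#' @param tail_method `"empirical"` or `"gpd_tail"`.
#' @param perm_unit `"individual"` (exchangeable observations) or `"pair"`
#'   (permutes intact twin pairs; needs `pair_id`).
#' @param pair_id grouping vector when `perm_unit = "pair"`.
#' @param perm_strata optional per-sample stratum labels (zygosity); pairs
#'   are then permuted only within a stratum.
#' @param keep_perm_stats retain the permutation statistics in the result.
#' @return An object of class `gcc_test`: the observed `fit`, `pvalue`,
#'   `n_perm`, `tail_method`, and optionally `perm_stats`.
#' @export
gcc_test <- function(x, y, folds = 10, weight_grid = seq(0, 1, by = 0.1),
                     scale_grid = c(0.3, 0.5, 1, 2), n_perm = 199,
                     tail_method = c("empirical", "gpd_tail"),
                     perm_unit = c("individual", "pair"), pair_id = NULL,
                     perm_strata = NULL, jitter = c("auto", "none"),
                     transform = c("normal_scores", "none"), seed = 1L,
                     keep_perm_stats = FALSE) {
  tail_method <- match.arg(tail_method)
  perm_unit <- match.arg(perm_unit)
  jitter <- match.arg(jitter)
  transform <- match.arg(transform)
  if (n_perm < 19)
    stop_gcctwin("resolution_error",
                 "n_perm must be >= 19 to resolve alpha = 0.05")
  if (perm_unit == "pair" && is.null(pair_id))
    stop_gcctwin("config_error", "perm_unit = \"pair\" requires pair_id")
  x <- as.numeric(x); y <- as.numeric(y)
  gcc_check_xy(x, y)
  pr <- gcc_prepare(x, y, jitter, transform, seed)
  fit <- gcc_fit_core(pr$x, pr$y, folds, weight_grid, scale_grid, seed,
                      cls_x = pr$cls_x, cls_y = pr$cls_y)
  fit$seed <- as.integer(seed)
  class(fit) <- "gcc"
  null_stats <- with_seed(derive_seed(seed, 101L), {
    vapply(seq_len(n_perm), function(b) {
      idx <- permute_idx(length(pr$y), perm_unit, pair_id, perm_strata)
      gcc_fit_core(pr$x, pr$y[idx], folds, weight_grid, scale_grid,
                   seed = derive_seed(seed, 200L + b),
                   cls_x = pr$cls_x, cls_y = pr$cls_y[idx])$cvlrs
    }, numeric(1))
  })
  n_ge <- sum(null_stats >= fit$cvlrs)
  pvalue <- (1 + n_ge) / (n_perm + 1)
  used_tail <- "empirical"
  if (tail_method == "gpd_tail" && n_ge < 10) {
    gpd <- fit_gpd_tail(null_stats)
    if (!is.null(gpd) && fit$cvlrs > gpd$u) {
      p_gpd <- gpd_tail_prob(gpd, fit$cvlrs)
      if (is.finite(p_gpd) && p_gpd > 0) {
        pvalue <- min(pvalue, p_gpd)
        used_tail <- "gpd_tail"
      }
    }
  }
  structure(list(fit = fit, pvalue = pvalue, n_perm = as.integer(n_perm),
                 tail_method = used_tail,
                 perm_stats = if (keep_perm_stats) null_stats else NULL),
            class = "gcc_test")
}

#' @export
print.gcc_test <- function(x, digits = 4, ...) {
  cat("GCC permutation test: A = ", format(x$fit$A, digits = digits),
      ", CVLRS = ", format(x$fit$cvlrs, digits = digits),
      ", p = ", format(x$pvalue, digits = digits),
      " (", x$n_perm, " permutations, ", x$tail_method, ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Shared null calibration

#' Reusable permutation null for repeated GCC tests
#'
#' Builds one permutation-null distribution of the CVLRS for a family of
#' tests that share the same marginal structure (for example the replications
#' of a simulation study, where every replication draws genotypes at the same
#' allele frequency under the same twin design, or a null scan at a fixed
#' simulated MAF). Each null draw takes a fresh `x` from `x_sampler` and a
#' permutation of `y`, refits the GCC, and records the statistic; a
#' generalized-Pareto fit to the top decile supports tail quantiles below the
#' raw permutation resolution.
#'
#' @param x_sampler zero-argument function returning a fresh x vector drawn
#'   from the marginal distribution of the genotypes under test.
#' @param y numeric phenotype vector whose marginal the null conditions on.
#' @param n_perm number of null draws (>= 199).
#' @param perm_unit,pair_id,perm_strata permutation unit for y: `"pair"`
#'   with the family grouping (and zygosity as strata) permutes intact twin
#'   pairs (see [gcc_test()]); `"none"` leaves y untouched, relying on the
#'   sampler's independence alone — the tightest choice when `x_sampler`
#'   genuinely draws from the genotype marginal independently of y, as it
#'   does in simulation studies and null scans.
#' @inheritParams gcc
#' @return An object of class `gcc_null` with sorted null statistics and GPD
#'   tail parameters; use [null_pvalue()] and [null_quantile()].
#' @export
gcc_null_calibration <- function(x_sampler, y, n_perm = 999, folds = 10,
                                 weight_grid = seq(0, 1, by = 0.1),
                                 scale_grid = c(0.3, 0.5, 1, 2),
                                 perm_unit = c("individual", "pair", "none"),
                                 pair_id = NULL, perm_strata = NULL,
                                 jitter = c("auto", "none"),
                                 transform = c("normal_scores", "none"),
                                 seed = 1L) {
  jitter <- match.arg(jitter)
  transform <- match.arg(transform)
  perm_unit <- match.arg(perm_unit)
  if (perm_unit == "pair" && is.null(pair_id))
    stop_gcctwin("config_error", "perm_unit = \"pair\" requires pair_id")
  if (n_perm < 199)
    stop_gcctwin("resolution_error", "shared null needs n_perm >= 199")
  n <- length(y)
  cls_y <- if (is_hard_calls(y)) round(y) else NULL
  ys <- if (transform == "normal_scores")
    qnorm(rank(y, ties.method = "average") / (n + 1)) else as.numeric(y)
  stats <- with_seed(derive_seed(seed, 301L), {
    vapply(seq_len(n_perm), function(b) {
      xb <- as.numeric(x_sampler())
      cls_xb <- if (is_hard_calls(xb)) round(xb) else NULL
      if (jitter == "auto" && !is.null(cls_xb))
        xb <- xb + runif(length(xb), -0.05, 0.05)
      if (transform == "normal_scores")
        xb <- qnorm(rank(xb, ties.method = "average") / (length(xb) + 1))
      idx <- permute_idx(n, perm_unit, pair_id, perm_strata)
      gcc_fit_core(xb, ys[idx], folds, weight_grid, scale_grid,
                   seed = derive_seed(seed, 400L + b),
                   cls_x = cls_xb, cls_y = cls_y[idx])$cvlrs
    }, numeric(1))
  })
  structure(list(stats = sort(stats), n_perm = as.integer(n_perm),
                 gpd = fit_gpd_tail(stats),
                 folds = folds, weight_grid = weight_grid,
                 scale_grid = scale_grid, seed = as.integer(seed)),
            class = "gcc_null")
}

#' @export
print.gcc_null <- function(x, ...) {
  cat("Shared GCC permutation null: ", x$n_perm, " draws, CVLRS range [",
      format(min(x$stats), digits = 4), ", ", format(max(x$stats), digits = 4),
      "]", if (!is.null(x$gpd)) ", GPD tail fitted", "\n", sep = "")
  invisible(x)
}

#' P-value lookup against a shared permutation null
#'
#' @param null a `gcc_null` object.
#' @param stat observed CVLRS value(s).
#' @param tail_method `"gpd_tail"` (default) extrapolates below the
#'   permutation resolution when the observed statistic lies beyond the
#'   fitted tail threshold; `"empirical"` never does.
#' @return p-values in (0, 1].
#' @export
null_pvalue <- function(null, stat, tail_method = c("gpd_tail", "empirical")) {
  stopifnot(inherits(null, "gcc_null"))
  tail_method <- match.arg(tail_method)
  vapply(stat, function(s) {
    n_ge <- sum(null$stats >= s)
    p <- (1 + n_ge) / (null$n_perm + 1)
    if (tail_method == "gpd_tail" && n_ge < 10 && !is.null(null$gpd) &&
        s > null$gpd$u) {
      p_gpd <- gpd_tail_prob(null$gpd, s)
      if (is.finite(p_gpd) && p_gpd > 0) p <- min(p, p_gpd)
    }
    p
  }, numeric(1))
}

#' Rejection threshold from a shared permutation null
#'
#' @param null a `gcc_null` object.
#' @param prob cumulative probability of the required CVLRS quantile (e.g.
#'   0.95 for an alpha = 0.05 threshold).
#' @param tail_method `"empirical"` raises a resolution error when `1 - prob`
#'   is below `1 / (n_perm + 1)`; `"gpd_tail"` extrapolates via the fitted
#'   generalized-Pareto tail.
#' @return the CVLRS threshold.
#' @export
null_quantile <- function(null, prob, tail_method = c("empirical", "gpd_tail")) {
  stopifnot(inherits(null, "gcc_null"), prob > 0, prob < 1)
  tail_method <- match.arg(tail_method)
  p_upper <- 1 - prob
  if (p_upper >= 1 / (null$n_perm + 1))
    return(unname(quantile(null$stats, prob, type = 1)))
  if (tail_method == "empirical")
    stop_gcctwin("resolution_error",
                 sprintf("quantile %g is beyond the resolution of %d permutations",
                         prob, null$n_perm))
  if (is.null(null$gpd))
    stop_gcctwin("resolution_error", "no GPD tail available for extrapolation")
  gpd_tail_quantile(null$gpd, p_upper)
}
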