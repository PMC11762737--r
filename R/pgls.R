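# Weighted generalized least squares under a Pagel-lambda phylogenetic
# correlation structure, with maximum-likelihood profiling of lambda and
# likelihood-ratio tests against the lambda = 0 and lambda = 1 boundaries.
#
# Model: y = X beta + e,  e ~ N(0, sigma^2 * V(lambda)),
#        V(lambda) = D^{1/2} C_lambda D^{1/2},  D = diag(1 / weights),
# where C_lambda multiplies the off-diagonals of the Brownian covariance C
# by lambda.  Weighting by the number of individuals measured per species
# gives each species a residual variance proportional to 1/n_i.
#
# Implementation: write C = A^{1/2} K A^{1/2} with A = diag(C) and K the
# unit-diagonal phylogenetic correlation matrix.  Then
#   V(lambda) = B^{1/2} (lambda K + (1-lambda) I) B^{1/2},  B = A D,
# and a single symmetric eigendecomposition K = Q L Q' makes every
# fixed-lambda evaluation O(n p^2): whiten once with Q' B^{-1/2}, then each
# lambda only changes the diagonal weights 1 / (lambda*L + 1 - lambda).

#' Standardize a numeric vector to zero mean and unit sample SD
#'
#' @param values Numeric vector with at least two distinct values.
#' @return `(values - mean) / sd`, preserving names.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (!is.finite(s) || s < 1e-300) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

# Precompute the whitened representation for a model (C, X, y, weights).
# Returns everything needed to evaluate the profile likelihood at any lambda.
gls_setup <- function(y, X, C, weights = NULL) {
  n <- length(y)
  stopifnot(is.matrix(X), nrow(X) == n, is.matrix(C), nrow(C) == n,
            ncol(C) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  a <- diag(C)
  if (any(a <= 0)) stop("zero tip depth in covariance matrix", call. = FALSE)
  b <- a / weights
  K <- C / sqrt(outer(a, a))
  eig <- eigen(K, symmetric = TRUE)
  sb <- sqrt(b)
  u <- drop(crossprod(eig$vectors, y / sb))
  Z <- crossprod(eig$vectors, X / sb)
  list(n = n, p = ncol(X), logdetB = sum(log(b)), ev = eig$values,
       u = u, Z = Z, colnames = colnames(X))
}

# Profile log-likelihood and GLS quantities at a fixed lambda.
gls_profile <- function(setup, lambda) {
  m <- lambda * setup$ev + (1 - lambda)
  if (any(m < 1e-12)) {
    return(list(loglik = -Inf, singular = TRUE))
  }
  w <- 1 / m
  n <- setup$n
  Zw <- setup$Z * w
  XtVX <- crossprod(setup$Z, Zw)
  XtVy <- crossprod(Zw, setup$u)
  beta <- drop(solve(XtVX, XtVy))
  r <- setup$u - drop(setup$Z %*% beta)
  rss <- sum(w * r^2)
  sigma2 <- rss / n
  logdetV <- setup$logdetB + sum(log(m))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  list(loglik = ll, beta = beta, rss = rss, sigma2 = sigma2,
       XtVX = XtVX, w = w, singular = FALSE)
}

#' Profile log-likelihood of a phylogenetic GLS model at fixed lambda
#'
#' Multivariate-normal log-likelihood with the GLS coefficient estimate and
#' the ML residual variance (`rss / n`) plugged in.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column).
#' @param C Phylogenetic covariance matrix aligned with `y`.
#' @param lambda Fixed Pagel's lambda in `[0, 1]`.
#' @param weights Per-observation positive weights (residual variance is
#'   proportional to `1/weights`); default all 1.
#' @return The profile log-likelihood (scalar).
#' @export
gls_loglik <- function(y, X, C, lambda, weights = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  pr <- gls_profile(gls_setup(y, X, C, weights), lambda)
  if (pr$singular) stop("V(lambda) is singular", call. = FALSE)
  pr$loglik
}

# ML estimate of lambda on [0,1]: bounded scalar optimization plus explicit
# boundary checks so a maximum at 0 or 1 is returned exactly.
optimize_lambda <- function(setup, tol = 1e-8) {
  f <- function(l) gls_profile(setup, l)$loglik
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  list(lambda = cand[best], loglik = ll[best], ll0 = ll[2], ll1 = ll[3])
}

#' Fit a phylogenetic generalized least-squares regression
#'
#' Estimates Pagel's lambda by maximum likelihood on `[0, 1]` (unless fixed),
#' then reports GLS coefficients, standard errors, t statistics with
#' `df = n - p`, two-sided p-values, R-squared in the whitened space (plus
#' its adjusted variant), and likelihood-ratio tests of the fitted lambda
#' against the boundaries 0 and 1 (chi-squared with 1 df, conservative at
#' the boundary).
#'
#' @param y Named response vector (names are species labels) or plain vector
#'   accompanied by `species`.
#' @param X Design matrix with intercept; rows in the same order as `y`.
#' @param tree A `"phylo"` object covering all species in `y`.
#' @param weights Optional per-species weights (e.g. number of individuals
#'   measured); residual variance scales as `1/weights`.
#' @param lambda Fix lambda at this value instead of estimating it.
#' @param species Species labels when `y` is unnamed.
#' @return Object of class `"pgls_fit"`: `lambda, coefficients, se, t, p,
#'   df, r2, r2_adj, sigma2, loglik, lrt_p_lambda0, lrt_p_lambda1, n,
#'   lambda_fixed, flat_likelihood`.
#' @export
fit_pgls <- function(y, X, tree, weights = NULL, lambda = NULL,
                     species = names(y)) {
  if (is.null(species)) stop("species labels required (name y)", call. = FALSE)
  species <- normalize_taxon(species)
  stopifnot(length(species) == length(y))
  if (length(y) < ncol(X) + 2L) {
    stop("need at least p + 2 species to fit PGLS", call. = FALSE)
  }
  miss <- setdiff(species, tree$tip.label)
  if (length(miss)) {
    stop("species absent from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr <- if (length(species) < ape::Ntip(tree)) {
    prune_to_taxa(tree, species)
  } else tree
  C <- vcv_matrix(tr)[species, species, drop = FALSE]
  setup <- gls_setup(y, X, C, weights)

  if (is.null(lambda)) {
    op <- optimize_lambda(setup)
    lam_hat <- op$lambda
    ll_hat <- op$loglik
    ll0 <- op$ll0
    ll1 <- op$ll1
    lambda_fixed <- FALSE
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
    lam_hat <- lambda
    ll_hat <- gls_profile(setup, lambda)$loglik
    ll0 <- gls_profile(setup, 0)$loglik
    ll1 <- gls_profile(setup, 1)$loglik
    lambda_fixed <- TRUE
  }
  pr <- gls_profile(setup, lam_hat)
  n <- setup$n
  p <- setup$p
  covb <- solve(pr$XtVX) * pr$sigma2 * n / (n - p)
  se <- sqrt(diag(covb))
  tstat <- pr$beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)

  # R^2 in the whitened space, against the GLS intercept-only mean
  w <- pr$w
  z1 <- setup$Z[, 1]
  mu0 <- sum(w * z1 * setup$u) / sum(w * z1^2)
  tss <- sum(w * (setup$u - mu0 * z1)^2)
  r2 <- if (tss > 0) 1 - pr$rss / tss else NA_real_
  r2_adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p)

  lrt0 <- max(0, 2 * (ll_hat - ll0))
  lrt1 <- max(0, 2 * (ll_hat - ll1))
  flat <- is.finite(ll0) && is.finite(ll1) &&
    (max(ll_hat - ll0, ll_hat - ll1) < 1e-6) && !lambda_fixed

  nm <- setup$colnames
  if (is.null(nm)) nm <- paste0("b", seq_len(p) - 1L)
  names(pr$beta) <- names(se) <- names(tstat) <- names(pval) <- nm

  structure(list(lambda = lam_hat, coefficients = pr$beta, se = se,
                 t = tstat, p = pval, df = n - p, r2 = r2, r2_adj = r2_adj,
                 sigma2 = pr$sigma2, loglik = ll_hat,
                 lrt_p_lambda0 = stats::pchisq(lrt0, 1, lower.tail = FALSE),
                 lrt_p_lambda1 = stats::pchisq(lrt1, 1, lower.tail = FALSE),
                 loglik_lambda0 = ll0, loglik_lambda1 = ll1,
                 n = n, lambda_fixed = lambda_fixed, flat_likelihood = flat),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d): lambda = %.4g%s, logLik = %.3f\n",
              x$n, x$lambda, if (x$lambda_fixed) " [fixed]" else "",
              x$loglik))
  cat(sprintf("  LRT p vs lambda=0: %.4g; vs lambda=1: %.4g\n",
              x$lrt_p_lambda0, x$lrt_p_lambda1))
  tab <- data.frame(beta = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 5))
  cat(sprintf("  R2 = %.4f (adjusted %.4f), df = %d\n", x$r2, x$r2_adj, x$df))
  if (x$flat_likelihood) cat("  note: likelihood flat in lambda\n")
  invisible(x)
}

#' Likelihood-ratio tests of the fitted lambda against the boundaries
#'
#' `2 * (logLik(lambda_hat) - logLik(fixed))` referred to chi-squared with
#' 1 df; the statistic is clamped at zero so a fit at a boundary gives
#' p = 1 against that boundary.  The plain chi-squared reference is
#' conservative for the boundary null.
#'
#' @param fit A `"pgls_fit"` object.
#' @return Named vector `c(p_lambda0, p_lambda1)`.
#' @export
lambda_lrt <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  c(p_lambda0 = fit$lrt_p_lambda0, p_lambda1 = fit$lrt_p_lambda1)
}

#' Phylogenetic paired t-test of left versus right sizes
#'
#' Models per-species differences `d = left - right` as multivariate normal
#' with mean `mu * 1` and covariance `sigma^2 * C(lambda_d)`, estimating
#' `lambda_d` by maximum likelihood on `[0, 1]` (or fixing it).  The test
#' statistic is the GLS mean over its standard error, with `df = n - 1` and
#' the bias-corrected residual variance (`rss / (n - 1)`).
#'
#' @param left,right Named vectors of per-species log10 sizes (same names).
#' @param tree A `"phylo"` object covering the species.
#' @param lambda Optional fixed lambda.
#' @return Object of class `"phylo_ttest"`: `mean_diff, lambda, t, df, p,
#'   se, n, degenerate`.
#' @export
phylo_paired_ttest <- function(left, right, tree, lambda = NULL) {
  stopifnot(length(left) == length(right))
  sp <- normalize_taxon(names(left))
  if (is.null(sp) || !identical(sp, normalize_taxon(names(right)))) {
    stop("left and right must be named by the same species", call. = FALSE)
  }
  n <- length(left)
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  d <- as.numeric(left) - as.numeric(right)
  tr <- if (n < ape::Ntip(tree)) prune_to_taxa(tree, sp) else tree
  C <- vcv_matrix(tr)[sp, sp, drop = FALSE]
  X <- matrix(1, n, 1)

  degenerate <- FALSE
  if (max(abs(d - d[1])) < 1e-14) {
    # constant differences: no sampling variance to estimate
    degenerate <- TRUE
    if (abs(d[1]) < 1e-14) {
      return(structure(list(mean_diff = 0, lambda = NA_real_, t = 0,
                            df = n - 1L, p = 1, se = NA_real_, n = n,
                            degenerate = TRUE), class = "phylo_ttest"))
    }
  }
  setup <- gls_setup(d, X, C)
  if (is.null(lambda)) {
    op <- optimize_lambda(setup)
    lam <- op$lambda
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
    lam <- lambda
  }
  pr <- gls_profile(setup, lam)
  mu <- pr$beta[1]
  s2 <- pr$rss / (n - 1)
  info <- sum(pr$w * setup$Z[, 1]^2)  # 1' C_lambda^{-1} 1
  if (s2 < 1e-28) {
    degenerate <- TRUE
    tstat <- if (abs(mu) < 1e-14) 0 else sign(mu) * Inf
    pv <- if (tstat == 0) 1 else 0
    se <- 0
  } else {
    se <- sqrt(s2 / info)
    tstat <- mu / se
    pv <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  structure(list(mean_diff = mu, lambda = lam, t = tstat, df = n - 1L,
                 p = pv, se = se, n = n, degenerate = degenerate),
            class = "phylo_ttest")
}

#' @export
print.phylo_ttest <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic paired t-test (n = %d): mean diff = %.5g, lambda = %.3g\n",
    x$n, x$mean_diff, x$lambda))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g%s\n", x$t, x$df, x$p,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' ANCOVA for species differences in relative brain size
#'
#' Tests the species factor in `log10(brain) ~ log10(SVL) + species` at the
#' individual level, with the standard partial-F degrees of freedom
#' `(k - 1, N - k - 1)` for `k` species and `N` individuals.
#'
#' @param log10_brain Individual-level log10 total brain volumes.
#' @param species Species label per individual.
#' @param log10_svl Individual-level log10 snout-vent lengths.
#' @return List of class `"ancova_result"`: `f, df_num, df_den, p`.
#' @export
ancova_species_effect <- function(log10_brain, species, log10_svl) {
  species <- factor(normalize_taxon(species))
  stopifnot(length(log10_brain) == length(species),
            length(log10_svl) == length(species))
  if (nlevels(species) < 2L) stop("need >= 2 species", call. = FALSE)
  fit <- stats::lm(log10_brain ~ log10_svl + species)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient ANCOVA design (collinear SVL/species)", call. = FALSE)
  }
  # suppressed warning: anova warns on near-perfect fits, which we report
  # as the degenerate F = 0 case below
  an <- suppressWarnings(stats::anova(fit))
  i <- which(rownames(an) == "species")
  f <- an$`F value`[i]
  p <- an$`Pr(>F)`[i]
  # exact-fit degenerate case: both mean squares vanish, report F = 0
  if (an$`Sum Sq`[i] < 1e-20 * sum(an$`Sum Sq`)) {
    f <- 0
    p <- 1
  }
  structure(list(f = f, df_num = an$Df[i],
                 df_den = an$Df[nrow(an)], p = p),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA species effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$f, x$p))
  invisible(x)
}
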