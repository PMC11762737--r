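test_that("standardize meets its contract", {
  expect_equal(standardize(1:3), c(-1, 0, 1))
  z <- standardize(rnorm(20, 5, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  set.seed(41)
  x <- rnorm(15)
  expect_equal(standardize(3 * x - 7), standardize(x), tolerance = 1e-12)
  expect_equal(standardize(-2 * x), -standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(1, 5)), "constant")
})

test_that("gls_loglik at lambda=0 with unit depths equals OLS likelihood", {
  set.seed(42)
  n <- 12
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  C <- vcv_matrix(star)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  X <- cbind(1, x)
  ll <- gls_loglik(y, X, C, lambda = 0)
  expect_equal(ll, as.numeric(logLik(lm(y ~ x))), tolerance = 1e-9)
})

test_that("fixed-lambda PGLS matches the dense-algebra oracle", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tr <- random_tree(n)
    C <- vcv_matrix(tr)
    x <- rnorm(n)
    X <- cbind(1, x)
    y <- rmvn_test(1 + 0.3 * x, 0.5 * C)
    names(y) <- tr$tip.label
    w <- sample(1:5, n, replace = TRUE)
    lam <- runif(1)
    fit <- fit_pgls(y, X, tr, weights = w, lambda = lam)
    orc <- dense_gls_oracle(y, X, C, lam, w)
    expect_equal(unname(fit$coefficients), orc$beta, tolerance = 1e-10)
    expect_equal(unname(fit$se), orc$se, tolerance = 1e-10)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-8)
  }
})

test_that("scaling all weights leaves coefficients unchanged", {
  set.seed(44)
  n <- 10
  tr <- random_tree(n)
  x <- rnorm(n)
  y <- rmvn_test(2 - x, vcv_matrix(tr))
  names(y) <- tr$tip.label
  X <- cbind(1, x)
  w <- sample(1:6, n, replace = TRUE)
  f1 <- fit_pgls(y, X, tr, weights = w, lambda = 0.6)
  f2 <- fit_pgls(y, X, tr, weights = 2 * w, lambda = 0.6)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f2$sigma2, 2 * f1$sigma2, tolerance = 1e-10)
})

test_that("star tree reduces PGLS to (weighted) OLS", {
  set.seed(45)
  n <- 15
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  x <- rnorm(n)
  y <- 1 + 0.4 * x + rnorm(n)
  names(y) <- star$tip.label
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_pgls(y, X, star, lambda = 0.3)  # lambda irrelevant on a star
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(fit$t), unname(summary(ols)$coefficients[, 3]),
               tolerance = 1e-10)

  w <- sample(1:4, n, replace = TRUE)
  fw <- fit_pgls(y, X, star, weights = w, lambda = 0.9)
  wls <- lm(y ~ x, weights = w)
  expect_equal(unname(fw$coefficients), unname(coef(wls)), tolerance = 1e-10)
})

test_that("perfect linear response gives R2 = 1 and zero residual", {
  set.seed(46)
  tr <- random_tree(10)
  x <- rnorm(10)
  y <- 2 + 3 * x
  names(y) <- tr$tip.label
  fit <- fit_pgls(y, cbind(1, x), tr, lambda = 0.5)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("ML lambda bookkeeping: optimum beats both boundaries", {
  set.seed(47)
  for (i in 1:10) {
    n <- 30
    tr <- simulate_yule_tree(n, 1)
    C <- vcv_matrix(tr)
    lam_true <- runif(1)
    Cl <- lambda_transform(C, lam_true)
    x <- rnorm(n)
    y <- rmvn_test(0.5 * x, Cl)
    names(y) <- tr$tip.label
    fit <- fit_pgls(y, cbind(1, x), tr)
    expect_gte(fit$loglik, max(fit$loglik_lambda0, fit$loglik_lambda1) - 1e-8)
    expect_gte(fit$lambda, 0)
    expect_lte(fit$lambda, 1)
  }
})

test_that("boundary lambda estimates give LRT p = 1 against that boundary", {
  set.seed(48)
  n <- 40
  star_ish <- simulate_yule_tree(n, 1)
  # iid data: lambda-hat should hit 0
  y <- rnorm(n)
  names(y) <- star_ish$tip.label
  x <- rnorm(n)
  fit <- fit_pgls(y, cbind(1, x), star_ish)
  expect_lt(fit$lambda, 1e-6)
  expect_equal(fit$lrt_p_lambda0, 1)
})

test_that("ML fit agrees with nlme::gls + corPagel on a reference instance", {
  set.seed(49)
  n <- 40
  tr <- simulate_yule_tree(n, 1)
  C <- vcv_matrix(tr)
  x <- rnorm(n)
  y <- rmvn_test(1 + 0.5 * x, 0.8 * lambda_transform(C, 0.6))
  names(y) <- tr$tip.label
  dat <- data.frame(y = y, x = x, sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = dat, method = "ML",
                   correlation = ape::corPagel(0.5, tr, form = ~sp))
  fit <- fit_pgls(y, cbind(1, x), tr)
  lam_ref <- attr(ref$modelStruct$corStruct, "fixed")
  lam_ref <- coef(ref$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(fit$lambda, unname(lam_ref), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("input validation errors are informative", {
  tr <- simulate_yule_tree(6, 1, seed = 50)
  y <- rnorm(6)
  names(y) <- c(tr$tip.label[-1], "nope")
  expect_error(fit_pgls(y, cbind(1, rnorm(6)), tr), "nope")
  y2 <- rnorm(6)
  names(y2) <- tr$tip.label
  X_bad <- cbind(1, 2, rnorm(6))  # collinear columns
  expect_error(fit_pgls(y2, X_bad, tr), "rank")
})
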