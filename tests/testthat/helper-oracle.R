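# Independent brute-force oracles used across tests.  These deliberately use
# plain dense linear algebra (solve/determinant) and never touch the
# package's whitened-eigendecomposition code path.

# Dense GLS at fixed lambda: coefficients, SEs (with the n/(n-p) correction),
# ML sigma2 and profile log-likelihood.
dense_gls_oracle <- function(y, X, C, lambda, weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Dh <- diag(sqrt(1 / weights), n)
  V <- Dh %*% Cl %*% Dh
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  sigma2 <- rss / n
  covb <- solve(XtVX) * sigma2 * n / (n - ncol(X))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                  determinant(V, logarithm = TRUE)$modulus + n)
  list(beta = unname(drop(beta)), se = unname(sqrt(diag(covb))),
       sigma2 = sigma2, loglik = as.numeric(ll))
}

# Random tree with strictly positive branch lengths.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# MVN draw given a covariance matrix (test-side, independent of the package).
rmvn_test <- function(mu, V) {
  mu + drop(t(chol(V)) %*% rnorm(length(mu)))
}

# A minimal individuals data frame built from explicit per-side volumes.
# vols: named list region -> c(left, right) volumes; replicated per
# individual id supplied.
build_individuals <- function(species, vols, svl = 50, ids = "i1",
                              aspect = c(1, 1, 1)) {
  rows <- list()
  for (sp in species) {
    for (id in ids) {
      row <- list(species = sp, individual_id = paste(sp, id, sep = "_"),
                  sex = "unknown", svl_mm = svl)
      for (r in names(vols)) {
        for (k in 1:2) {
          side <- c("left", "right")[k]
          v <- vols[[r]][k]
          s <- (v * 6 * 1.43 / (pi * prod(aspect)))^(1 / 3)
          row[[paste(r, side, "length_mm", sep = "_")]] <- aspect[1] * s
          row[[paste(r, side, "width_mm", sep = "_")]] <- aspect[2] * s
          row[[paste(r, side, "height_mm", sep = "_")]] <- aspect[3] * s
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, rows)
}
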