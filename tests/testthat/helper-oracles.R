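# Independent oracles kept deliberately separate from the package's own
# computational paths: brute-force normal equations, a hand-written IRLS
# loop, a cluster bootstrap, and a weighted through-origin regression.

# Brute-force least squares via the pseudo-inverse (no QR).
oracle_ols <- function(X, y) {
  drop(MASS::ginv(t(X) %*% X) %*% t(X) %*% y)
}

# Hand-rolled IRLS for logistic regression.
oracle_irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(t(X) %*% (X * w), t(X) %*% (w * z))
    if (max(abs(b_new - b)) < tol) {
      b <- drop(b_new)
      break
    }
    b <- drop(b_new)
  }
  se <- sqrt(diag(solve(t(X) %*% (X * (mu * (1 - mu))))))
  list(coef = drop(b), se = se)
}

# Nonparametric cluster bootstrap SE of the pooled-OLS exposure term.
oracle_cluster_boot_se <- function(X, y, cluster, B = 2000, seed = 1,
                                   term = "exposure") {
  cl <- unique(cluster)
  idx_by <- split(seq_along(cluster), cluster)
  i_term <- match(term, colnames(X))
  set.seed(seed)
  ests <- replicate(B, {
    pick <- sample(cl, length(cl), replace = TRUE)
    ix <- unlist(idx_by[as.character(pick)], use.names = FALSE)
    qr.coef(qr(X[ix, , drop = FALSE]), y[ix])[i_term]
  })
  sd(ests)
}

# Weighted least squares through the origin, written out longhand.
oracle_wls_origin <- function(x, y, w) {
  list(estimate = sum(w * x * y) / sum(w * x^2),
       se = sqrt(1 / sum(w * x^2)))
}

# Closed-form exposure estimate for a balanced two-wave random-intercept
# model with a between-person exposure: GLS reduces to OLS on the person
# means.
oracle_balanced_gls <- function(y_w1, y_w2, x) {
  ybar <- (y_w1 + y_w2) / 2
  unname(coef(lm(ybar ~ x))["x"])
}

# A small structured cohort used across test files (cheap to build).
tiny_cohort <- function(seed = 42, n = 400, sites = 60, signal = 15,
                        tau = -0.3, theta_direct = 0.5, theta_med = 0,
                        case_fraction = 0.12, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_sites = sites,
                             n_signal_sites = signal, tau = tau,
                             theta_direct = theta_direct,
                             theta_med = theta_med,
                             case_fraction = case_fraction,
                             seed = seed, ...))
}
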