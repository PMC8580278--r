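# Surrogate variables, linear and logistic scans, significance rules.

test_that("residual-SVD surrogate variables recover a planted batch vector", {
  set.seed(31)
  n <- 200; p <- 500
  exposure <- rnorm(n)
  batch <- rbinom(n, 1, 0.5)
  m <- outer(rnorm(p, sd = 0.05), exposure) +        # weak exposure signal
    outer(rnorm(p, sd = 0.4), batch - 0.5) +          # strong latent batch
    matrix(rnorm(p * n, sd = 0.2), p, n)
  beta <- m_to_beta(m)
  svs <- estimate_surrogate_variables(beta, exposure, k = 5)
  expect_gt(abs(cor(svs[, 1], batch)), 0.95)
  # orthonormal columns
  expect_equal(crossprod(svs), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pure-noise residual matrices show no dominant surrogate component", {
  set.seed(32)
  n <- 150; p <- 600
  beta <- m_to_beta(matrix(rnorm(p * n, sd = 0.3), p, n))
  exposure <- rnorm(n)
  X <- cbind(1, exposure)
  R <- t(beta) - X %*% qr.coef(qr(X), t(beta))
  R <- t(scale(t(R), scale = FALSE))
  d <- svd(R)$d
  # iid noise: top singular value stays near the Marchenko-Pastur bulk
  expect_lt(d[1] / median(d), 2)
})

test_that("k = 0 returns an empty matrix and leaves the scan unchanged", {
  coh <- tiny_cohort(seed = 33, n = 120, sites = 20, signal = 5)
  svs0 <- estimate_surrogate_variables(coh$meth_w1, coh$phenotypes$phenotype_w1,
                                       k = 0)
  expect_identical(dim(svs0), c(120L, 0L))
  a <- run_linear_ewas(coh$meth_w1, coh$phenotypes$phenotype_w1)
  b <- run_linear_ewas(coh$meth_w1, coh$phenotypes$phenotype_w1, svs = svs0)
  expect_equal(a$coef, b$coef)
})

test_that("an exact linear site yields an exact coefficient and underflowed p", {
  set.seed(34)
  n <- 60
  exposure <- rep(0:5, each = 10)
  beta <- matrix(0.2 + 0.05 * exposure, nrow = 1)
  beta <- rbind(beta, matrix(runif(3 * n, 0.2, 0.8), 3, n))
  rownames(beta) <- paste0("s", 1:4)
  scan <- run_linear_ewas(beta, exposure)
  expect_equal(scan$coef[1], 0.05, tolerance = 1e-12)
  expect_lte(scan$p[1], 1e-50)
  expect_gt(scan$p[1], 0)  # underflow reported as tiny positive, never 0
})

test_that("linear scan equals the brute-force normal-equations oracle", {
  set.seed(35)
  for (n in c(20, 35, 50)) {
    p <- 8
    exposure <- sample(0:6, n, replace = TRUE)
    covs <- data.frame(sex = sample(c("F", "M"), n, replace = TRUE),
                       age = runif(n, 40, 70))
    svs <- matrix(rnorm(n * 2), n, 2)
    beta <- matrix(runif(p * n, 0.1, 0.9), p, n,
                   dimnames = list(paste0("s", 1:p), NULL))
    scan <- run_linear_ewas(beta, exposure, covs, svs)
    X <- cbind(1, exposure, covs$sex == "M", covs$age, svs)
    for (j in 1:p) {
      expect_equal(scan$coef[j], oracle_ols(X, beta[j, ])[2],
                   tolerance = 1e-8)
    }
  }
})

test_that("type-I error of the correctly-adjusted scan is nominal over 1000 null sites", {
  # without latent per-person structure the sites are conditionally
  # independent given the design and the binomial error bound is exact;
  # latent-structure leakage through estimated SVs is checked separately
  coh <- tiny_cohort(seed = 36, n = 300, sites = 1000, signal = 0,
                     tau = 0, subject_sd = 0)
  ph <- coh$phenotypes
  covs <- data.frame(sex = ph$sex, age = ph$age_w1,
                     coh$cell_props_w1[, -1], batch = coh$batch)
  scan <- run_linear_ewas(coh$meth_w1, ph$phenotype_w1, covs)
  frac <- mean(scan$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("SVA adjustment removes most of the batch-driven inflation", {
  coh <- tiny_cohort(seed = 46, n = 300, sites = 600, signal = 0,
                     tau = 0, subject_sd = 0, batch_effect_sd = 0.4)
  ph <- coh$phenotypes
  covs <- data.frame(sex = ph$sex, age = ph$age_w1,
                     coh$cell_props_w1[, -1])
  svs <- estimate_surrogate_variables(coh$meth_w1, ph$phenotype_w1, covs,
                                      k = 12)
  adj <- run_linear_ewas(coh$meth_w1, ph$phenotype_w1, covs, svs)
  frac <- mean(adj$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.04)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  set.seed(37)
  n <- 40
  exposure <- rnorm(n)
  covs <- data.frame(dup = exposure)  # exactly collinear with the exposure
  beta <- matrix(runif(2 * n, 0.3, 0.7), 2, n)
  expect_error(run_linear_ewas(beta, exposure, covs), "collinear")
})

test_that("logistic scan agrees with an independent IRLS oracle to 1e-6", {
  set.seed(38)
  n <- 200
  beta <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
                 dimnames = list(paste0("s", 1:5), NULL))
  covs <- data.frame(age = runif(n, 40, 70))
  y <- rbinom(n, 1, plogis(-1 + 2 * beta[1, ]))
  scan <- run_logistic_ewas(y, beta, covariates = covs)
  for (j in 1:5) {
    X <- cbind(1, beta[j, ], covs$age)
    o <- oracle_irls_logistic(X, y)
    expect_equal(scan$coef[j], o$coef[2], tolerance = 1e-6)
    expect_equal(scan$se[j], o$se[2], tolerance = 1e-6)
  }
})

test_that("a permuted methylation site shows no cancer association", {
  coh <- tiny_cohort(seed = 39, n = 1000, sites = 10, signal = 5,
                     tau = rep(-0.5, 5), theta_direct = 0.5,
                     case_fraction = 0.3)
  ph <- coh$phenotypes
  set.seed(40)
  bperm <- coh$meth_w1$beta[, sample(ncol(coh$meth_w1$beta)), drop = FALSE]
  rownames(bperm) <- rownames(coh$meth_w1$beta)
  scan <- run_logistic_ewas(ph$case, bperm)
  # a permuted null: no extreme association, few nominally small p-values
  expect_true(all(scan$p > 1e-4))
  expect_lte(sum(scan$p < 0.05), 3)
})

test_that("a planted methylation-to-cancer effect is recovered with the right sign", {
  coh <- tiny_cohort(seed = 41, n = 3000, sites = 30, signal = 10,
                     tau = rep(-0.8, 10), theta_direct = 0,
                     theta_med = -0.8, case_fraction = 0.3,
                     residual_sd = 0.5)
  ph <- coh$phenotypes
  sig <- coh$truth$signal_sites
  scan <- run_logistic_ewas(ph$case, coh$meth_w1)
  hits <- scan[match(sig, scan$site_id), ]
  # theta_med < 0 on the mean mediator M-value: higher methylation at the
  # planted sites lowers risk, so logistic coefficients are negative
  expect_gt(mean(hits$coef < 0), 0.8)
})

test_that("perfect separation yields a flagged site, not a crash", {
  n <- 60
  beta <- matrix(c(sort(runif(n, 0.1, 0.9)), runif(n, 0.4, 0.6)), 2, n,
                 byrow = TRUE, dimnames = list(c("sep", "ok"), NULL))
  y <- as.integer(beta[1, ] > median(beta[1, ]))
  scan <- run_logistic_ewas(y, beta)
  expect_false(scan$converged[1])
  expect_true(is.na(scan$coef[1]))
  expect_true(scan$converged[2])
})

test_that("significance flags follow the 5e-8 and Bonferroni x m rules", {
  res <- data.frame(p = c(1e-8, 7e-4, 6e-4))
  out <- apply_thresholds(res, bonferroni_m = 76)
  expect_identical(out$genomewide, c(TRUE, FALSE, FALSE))
  expect_identical(out$bonferroni, c(TRUE, FALSE, TRUE))  # 0.0532 vs 0.0456
})

test_that("surrogate variables orthogonal to the design leave estimates unchanged", {
  set.seed(43)
  n <- 80
  exposure <- rnorm(n)
  X <- cbind(1, exposure)
  # build SVs exactly orthogonal to [1, exposure]
  raw <- matrix(rnorm(n * 3), n, 3)
  svs <- raw - X %*% qr.coef(qr(X), raw)
  svs <- qr.Q(qr(svs))
  beta <- matrix(runif(6 * n, 0.2, 0.8), 6, n,
                 dimnames = list(paste0("s", 1:6), NULL))
  a <- run_linear_ewas(beta, exposure)
  b <- run_linear_ewas(beta, exposure, svs = svs)
  expect_equal(a$coef, b$coef, tolerance = 1e-10)
})

test_that("the sign split of significant hits matches the planted 80/20 split", {
  coh <- tiny_cohort(seed = 44, n = 600, sites = 100, signal = 40,
                     tau = -0.5, residual_sd = 0.3, subject_sd = 0,
                     batch_effect_sd = 0, cell_effect_sd = 0,
                     mqtl_effect_sd = 0)
  scan <- run_linear_ewas(coh$meth_w1, coh$phenotypes$phenotype_w1)
  hits <- scan[scan$genomewide, ]
  expect_gt(nrow(hits), 20)
  # planted: 80% negative tau, 20% positive
  expect_equal(mean(hits$coef < 0), 0.8, tolerance = 0.12)
})

test_that("permuting site order permutes results identically", {
  coh <- tiny_cohort(seed = 45, n = 150, sites = 30, signal = 10)
  scan <- run_linear_ewas(coh$meth_w1, coh$phenotypes$phenotype_w1)
  perm <- sample(30)
  mm <- methylation_matrix(coh$meth_w1$beta[perm, ],
                           coh$meth_w1$annotation[perm, ])
  scan_p <- run_linear_ewas(mm, coh$phenotypes$phenotype_w1)
  reord <- scan[match(scan_p$site_id, scan$site_id), ]
  expect_equal(scan_p$coef, reord$coef)
  expect_equal(scan_p$p, reord$p)
})
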