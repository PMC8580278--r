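# Genetic scores, instrument strength, 2SLS, Wald ratio, IVW,
# harmonization and the second-step screen.

test_that("the genetic score is the weighted dosage sum", {
  g <- matrix(c(0, 2, 2, 0, 2, 1, 0, 2, 2), 3, 3, byrow = TRUE,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  expect_equal(unname(build_genetic_score(g)), c(4, 3, 4))
  expect_equal(unname(build_genetic_score(g[1, , drop = FALSE])), 4)
  expect_equal(unname(build_genetic_score(
    matrix(c(2, 1, 2), 1, dimnames = list(NULL, c("rs1", "rs2", "rs3"))),
    weights = c(0.5, 1, 0))), 2.0)
  expect_equal(unname(build_genetic_score(
    matrix(0, 1, 3, dimnames = list(NULL, c("rs1", "rs2", "rs3"))))), 0)
  expect_error(build_genetic_score(g, snp_ids = "rs9"), "rs9")
})

test_that("instrument strength matches the ANOVA F from a brute-force regression", {
  set.seed(90)
  n <- 300
  score <- rbinom(n, 6, 0.3)
  exposure <- 0.2 * score + rnorm(n)
  s <- instrument_strength(score, exposure)
  a <- anova(lm(exposure ~ score))
  expect_equal(s$f_statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(s$r_squared, summary(lm(exposure ~ score))$r.squared,
               tolerance = 1e-12)
  # degenerate cases
  expect_true(is.infinite(
    suppressWarnings(instrument_strength(score, score))$f_statistic))
  expect_error(instrument_strength(rep(1, n), exposure), "constant")
  s0 <- instrument_strength(rnorm(1e4), rnorm(1e4))
  expect_lt(s0$r_squared, 0.002)
  expect_lt(s0$f_statistic, 6)
})

test_that("2SLS with a single instrument equals the reduced-form/first-stage ratio", {
  set.seed(91)
  n <- 500
  z <- rbinom(n, 1, 0.4)
  x <- 0.8 * z + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  r <- two_stage_least_squares(z, x, y)
  wald <- coef(lm(y ~ z))[2] / coef(lm(x ~ z))[2]
  expect_equal(r$estimate, unname(wald), tolerance = 1e-10)
})

test_that("2SLS is unbiased under confounding where OLS is biased", {
  set.seed(92)
  n <- 1e4
  z <- rbinom(n, 2, 0.3)
  u <- rnorm(n)                       # unmeasured confounder
  x <- 0.3 * z + 1.0 * u + rnorm(n)
  tau_true <- -0.4
  y <- tau_true * x + 1.0 * u + rnorm(n)
  ols <- coef(lm(y ~ x))[2]
  r <- two_stage_least_squares(z, x, y)
  expect_gt(abs(ols - tau_true), 0.2)               # OLS badly biased
  expect_lt(abs(r$estimate - tau_true), 2 * r$se)   # 2SLS recovers tau
  expect_false(r$weak_instrument)
})

test_that("weak instruments are flagged but still reported", {
  set.seed(93)
  n <- 2000
  z <- rbinom(n, 2, 0.3)
  x <- 0.03 * z + rnorm(n)
  y <- 0.2 * x + rnorm(n)
  r <- two_stage_least_squares(z, x, y)
  expect_true(r$weak_instrument)
  expect_true(is.finite(r$estimate))
})

test_that("the Wald ratio follows its closed form", {
  r <- wald_ratio(gamma = 0.5, Gamma = 0.1, se_Gamma = 0.05)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.1)
  r0 <- wald_ratio(gamma = 0.5, Gamma = 0, se_Gamma = 0.05)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$or, 1)
  # harmonization invariance: flipping both signs leaves the estimate
  rf <- wald_ratio(gamma = -0.5, Gamma = -0.1, se_Gamma = 0.05)
  expect_equal(rf$estimate, r$estimate)
  expect_error(wald_ratio(0, 1, 0.1), "nonzero")
})

test_that("IVW reduces to the Wald ratio with one instrument and averages constants exactly", {
  w <- wald_ratio(0.4, 0.12, 0.03)
  i <- ivw(0.4, 0.12, 0.03)
  expect_equal(i$estimate, w$estimate)
  expect_equal(i$se, w$se)
  expect_equal(i$p, w$p)
  # all per-instrument ratios equal to c: the estimate is c
  gamma <- c(0.2, 0.5, -0.3)
  c0 <- -0.7
  i2 <- ivw(gamma, c0 * gamma, c(0.05, 0.08, 0.02))
  expect_equal(i2$estimate, c0, tolerance = 1e-12)
})

test_that("IVW equals the weighted through-origin regression oracle to 1e-10", {
  set.seed(94)
  for (rep in 1:3) {
    k <- 5
    gamma <- rnorm(k, sd = 0.3)
    Gamma <- 0.25 * gamma + rnorm(k, sd = 0.05)
    se_G <- runif(k, 0.02, 0.1)
    r <- ivw(gamma, Gamma, se_G)
    o <- oracle_wls_origin(gamma, Gamma, 1 / se_G^2)
    expect_equal(r$estimate, o$estimate, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
  }
})

test_that("IVW is invariant to sign flips of instrument subsets", {
  set.seed(95)
  gamma <- rnorm(6, sd = 0.3)
  Gamma <- 0.3 * gamma + rnorm(6, sd = 0.04)
  se_G <- runif(6, 0.02, 0.08)
  base <- ivw(gamma, Gamma, se_G)
  flip <- c(1, -1, 1, -1, -1, 1)
  flipped <- ivw(flip * gamma, flip * Gamma, se_G)
  expect_equal(flipped$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(flipped$se, base$se, tolerance = 1e-12)
})

test_that("cis filtering keeps same-chromosome instruments within the window, inclusive", {
  inst <- data.frame(snp = paste0("rs", 1:4),
                     chr = c(3, 3, 3, 7),
                     pos = c(1e6, 2e6 + 1, 2e6, 1e6))
  out <- filter_cis(inst, cpg_chr = 3, cpg_pos = 1e6, window = 1e6)
  expect_setequal(out$snp, c("rs1", "rs3"))  # exactly at the window: kept
  expect_warning(filter_cis(inst, cpg_chr = 12, cpg_pos = 1e6), "no cis")
})

test_that("the cg19859270-style chromosome pattern leaves exactly one cis instrument", {
  # seven instruments on chromosomes 7,3,9,4,4,4,2 against a CpG on chr 3:
  # only the chromosome-3 instrument can ever be cis
  inst <- data.frame(snp = paste0("rs", 1:7),
                     chr = c(7, 3, 9, 4, 4, 4, 2),
                     pos = rep(5e7, 7))
  for (win in c(1e5, 1e6, 1e7)) {
    out <- filter_cis(inst, cpg_chr = 3, cpg_pos = 5e7, window = win)
    expect_identical(out$snp, "rs2")
  }
})

test_that("allele harmonization aligns, strand-flips and drops ambiguous palindromes", {
  inst <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "T"),
                     eaf = c(0.3, 0.3, 0.2, 0.49),
                     beta = c(0.5, 0.5, 0.5, 0.5),
                     se = rep(0.1, 4))
  outc <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "G", "A", "A"),
                     other_allele = c("G", "A", "T", "T"),
                     eaf = c(0.3, 0.7, 0.2, 0.5),
                     beta = c(0.2, 0.2, 0.2, 0.2),
                     se = rep(0.05, 4))
  expect_warning(h <- harmonize_instruments(inst, outc), "rs4")
  expect_equal(h$Gamma[h$snp == "rs1"], 0.2)    # same orientation
  expect_equal(h$Gamma[h$snp == "rs2"], -0.2)   # swapped alleles: flip
  expect_equal(h$Gamma[h$snp == "rs3"], 0.2)    # palindrome, frequencies agree
  expect_false("rs4" %in% h$snp)                # ambiguous palindrome dropped
})

test_that("the second-step screen dispatches Wald vs IVW and reports untestable sites", {
  inst1 <- data.frame(snp = "rs1", gamma = 0.4, se_gamma = 0.05,
                      Gamma = 0.05, se_Gamma = 0.03)
  inst2 <- data.frame(snp = c("rs2", "rs3"), gamma = c(0.3, -0.2),
                      se_gamma = c(0.05, 0.05), Gamma = c(0.02, -0.02),
                      se_Gamma = c(0.03, 0.04))
  res <- mr_second_step_screen(c("cgA", "cgB", "cgC"),
                               list(cgA = inst1, cgB = inst2, cgC = NULL),
                               bonferroni_m = 13)
  expect_identical(res$method, c("wald", "ivw", NA_character_))
  expect_identical(res$testable, c(TRUE, TRUE, FALSE))
  expect_equal(res$estimate[1], 0.05 / 0.4)
  expect_identical(res$n_instruments, c(1L, 2L, 0L))
})

test_that("mQTL variance explained follows 2f(1-f)gamma^2", {
  expect_equal(mqtl_variance_explained(0.5, 0.2, var_m = 1),
               2 * 0.5 * 0.5 * 0.04)
  expect_equal(mqtl_variance_explained(c(0.2, 0.3), c(0.1, -0.2),
                                       var_m = 2),
               (2 * 0.2 * 0.8 * 0.01 + 2 * 0.3 * 0.7 * 0.04) / 2)
})

test_that("second-step type-I error is nominal over null replicates", {
  set.seed(96)
  nrep <- 1500
  pvals <- vapply(seq_len(nrep), function(i) {
    k <- sample(1:9, 1)
    gamma <- rnorm(k, sd = 0.3)
    se_G <- runif(k, 0.02, 0.08)
    Gamma <- rnorm(k, sd = se_G)      # no causal effect
    (if (k == 1) wald_ratio(gamma, Gamma, se_G) else
      ivw(gamma, Gamma, se_G))$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("a planted causal site is detected by the screen with high power", {
  set.seed(97)
  b_true <- 0.5
  hits <- vapply(1:200, function(i) {
    k <- 5
    gamma <- rnorm(k, mean = 0.4, sd = 0.1)
    se_G <- runif(k, 0.02, 0.05)
    Gamma <- b_true * gamma + rnorm(k, sd = se_G)
    ivw(gamma, Gamma, se_G)$p * 13 < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
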