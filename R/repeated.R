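# Repeated-measures confirmation: pooled regression with cluster-robust
# standard errors (LMRSE), a random-intercept mixed-model cross-check, and
# the change-in-smoking vs change-in-methylation analysis.

#' Build a stacked two-wave panel for repeated-measures analysis
#'
#' One row per sample-wave with the individual id as the cluster.  The
#' exposure is the wave-1 smoking phenotype for both waves' rows (the
#' confirmation analysis relates both waves' methylation to baseline
#' smoking); set \code{wave_varying_exposure = TRUE} to use each wave's
#' own phenotype instead.
#'
#' @param cohort a \code{cohort} with both waves simulated, or NULL when
#'   the matrices are supplied directly.
#' @param ids individual ids (used when \code{cohort} is NULL).
#' @param beta_w1,beta_w2 sites x samples beta matrices per wave.
#' @param exposure_w1,exposure_w2 numeric phenotype per wave.
#' @param covariates_w1,covariates_w2 per-wave covariate data.frames
#'   (same columns), or NULL.
#' @param wave_varying_exposure use each wave's own phenotype.
#' @param include_wave add the wave indicator as a covariate (default
#'   TRUE; absorbs secular/ageing drift between waves).
#' @return list with \code{data} (cluster, wave, exposure + covariates)
#'   and \code{beta} (sites x stacked-samples).
#' @export
build_panel <- function(cohort = NULL, ids = NULL, beta_w1 = NULL,
                        beta_w2 = NULL, exposure_w1 = NULL,
                        exposure_w2 = NULL, covariates_w1 = NULL,
                        covariates_w2 = NULL,
                        wave_varying_exposure = FALSE,
                        include_wave = TRUE) {
  if (!is.null(cohort)) {
    ph <- cohort$phenotypes
    ids <- ph$id
    beta_w1 <- cohort$meth_w1$beta
    beta_w2 <- cohort$meth_w2$beta
    exposure_w1 <- ph$phenotype_w1
    exposure_w2 <- ph$phenotype_w2
    covariates_w1 <- data.frame(sex = ph$sex, age = ph$age_w1)
    covariates_w2 <- data.frame(sex = ph$sex, age = ph$age_w2)
  }
  keep <- !is.na(exposure_w1) & (wave_varying_exposure == FALSE |
                                   !is.na(exposure_w2))
  exposure <- if (wave_varying_exposure) {
    c(exposure_w1[keep], exposure_w2[keep])
  } else {
    rep(exposure_w1[keep], 2)
  }
  dat <- data.frame(cluster = rep(ids[keep], 2),
                    wave = rep(c(0L, 1L), each = sum(keep)),
                    exposure = exposure,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates_w1)) {
    dat <- cbind(dat, rbind(as.data.frame(covariates_w1)[keep, , drop = FALSE],
                            as.data.frame(covariates_w2)[keep, , drop = FALSE]))
  }
  beta <- cbind(beta_w1[, keep, drop = FALSE], beta_w2[, keep, drop = FALSE])
  list(data = dat, beta = beta, include_wave = include_wave)
}

# Model matrix for a panel: [1, exposure, wave?, covariates].
panel_design <- function(panel) {
  dat <- panel$data
  covs <- dat[, setdiff(names(dat), c("cluster", "wave", "exposure")),
              drop = FALSE]
  X <- cbind(`(Intercept)` = 1, exposure = dat$exposure)
  if (isTRUE(panel$include_wave)) X <- cbind(X, wave = dat$wave)
  if (ncol(covs) > 0) X <- cbind(X, covariate_matrix(covs))
  X
}

#' Pooled OLS with cluster-robust (CR1) standard errors
#'
#' Point estimates are ordinary least squares over the stacked panel; the
#' variance is the cluster sandwich
#' \deqn{(X'X)^{-1} \left[\sum_g X_g' e_g e_g' X_g\right] (X'X)^{-1}}
#' with the CR1 small-sample factor \eqn{G/(G-1) \cdot (N-1)/(N-K)} and
#' p-values from a t distribution on \eqn{G-1} degrees of freedom, where
#' G is the number of clusters.  With singleton clusters this reduces to
#' the HC1 heteroscedasticity-robust estimator.
#'
#' @param panel output of \code{\link{build_panel}}.
#' @param sites site ids (default: all rows of \code{panel$beta}).
#' @param bonferroni_m family size for the Bonferroni flag.
#' @return data.frame per site: \code{site_id}, \code{coef}, \code{se},
#'   \code{p}, \code{n_clusters}, \code{bonferroni}.
#' @export
fit_lmrse <- function(panel, sites = NULL, bonferroni_m = NULL) {
  X <- panel_design(panel)
  cl <- panel$data$cluster
  G <- length(unique(cl))
  if (G < 2) stop("at least 2 clusters required", call. = FALSE)
  if (is.null(sites)) sites <- rownames(panel$beta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design not full rank", call. = FALSE)
  N <- nrow(X); K <- ncol(X)
  XtX_inv <- chol2inv(qr.R(qrX))
  cr1 <- G / (G - 1) * (N - 1) / (N - K)
  cl_idx <- split(seq_len(N), cl)
  iexp <- match("exposure", colnames(X))
  Y <- t(panel$beta[sites, , drop = FALSE])
  B <- qr.coef(qrX, Y)
  E <- Y - X %*% B
  # meat for the exposure coefficient only would suffice, but the full
  # sandwich is cheap at panel scale and used by the PSD invariant
  out <- data.frame(site_id = sites, coef = NA_real_, se = NA_real_,
                    p = NA_real_, n_clusters = G, stringsAsFactors = FALSE)
  Xg <- lapply(cl_idx, function(ix) X[ix, , drop = FALSE])
  for (s in seq_along(sites)) {
    e <- E[, s]
    meat <- matrix(0, K, K)
    for (g in seq_along(cl_idx)) {
      u <- crossprod(Xg[[g]], e[cl_idx[[g]]])
      meat <- meat + tcrossprod(u)
    }
    V <- cr1 * XtX_inv %*% meat %*% XtX_inv
    out$coef[s] <- B[iexp, s]
    out$se[s] <- sqrt(V[iexp, iexp])
    out$p[s] <- 2 * pt(abs(out$coef[s] / out$se[s]), df = G - 1,
                       lower.tail = FALSE)
  }
  out$bonferroni <- out$p * (bonferroni_m %||% nrow(out)) < 0.05
  out
}

# Full CR1 covariance for one site; exported for variance-matrix checks.
#' Cluster-robust CR1 covariance matrix of a pooled OLS fit
#'
#' @param X model matrix; @param y response; @param cluster cluster ids.
#' @return K x K covariance matrix (symmetric positive semidefinite).
#' @export
lmrse_vcov <- function(X, y, cluster) {
  qrX <- qr(X)
  N <- nrow(X); K <- ncol(X); G <- length(unique(cluster))
  XtX_inv <- chol2inv(qr.R(qrX))
  b <- qr.coef(qrX, y)
  e <- y - X %*% b
  meat <- matrix(0, K, K)
  for (ix in split(seq_len(N), cluster)) {
    u <- crossprod(X[ix, , drop = FALSE], e[ix])
    meat <- meat + tcrossprod(u)
  }
  cr1 <- G / (G - 1) * (N - 1) / (N - K)
  V <- cr1 * XtX_inv %*% meat %*% XtX_inv
  (V + t(V)) / 2
}

#' Random-intercept linear mixed model per site
#'
#' REML fit (via \code{lme4::lmer}) of each site's beta-values on the
#' panel design with a per-individual random intercept; the
#' computationally heavier cross-check of \code{\link{fit_lmrse}}.
#'
#' @param panel output of \code{\link{build_panel}}.
#' @param sites site ids (default all).
#' @return data.frame per site: \code{site_id}, \code{coef}, \code{se},
#'   \code{sigma_u} (random-intercept SD), \code{sigma_e},
#'   \code{converged}.
#' @export
fit_lmem_random_intercept <- function(panel, sites = NULL) {
  if (is.null(sites)) sites <- rownames(panel$beta)
  X <- panel_design(panel)
  dat <- as.data.frame(X[, -1, drop = FALSE])
  dat$cluster <- panel$data$cluster
  out <- data.frame(site_id = sites, coef = NA_real_, se = NA_real_,
                    sigma_u = NA_real_, sigma_e = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  rhs <- paste(c(colnames(X)[-1], "(1 | cluster)"), collapse = " + ")
  for (s in seq_along(sites)) {
    dat$y <- panel$beta[sites[s], ]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = dat,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    se <- sqrt(diag(as.matrix(vcov(fit))))
    out$coef[s] <- cf[["exposure"]]
    out$se[s] <- se[[match("exposure", names(cf))]]
    out$sigma_u[s] <- vc$sdcor[vc$grp == "cluster"][1]
    out$sigma_e[s] <- vc$sdcor[vc$grp == "Residual"][1]
    out$converged[s] <- TRUE
  }
  out
}

#' Pearson correlation between two sets of per-site coefficients
#'
#' @param fitsA,fitsB data.frames with \code{site_id} and \code{coef}
#'   over the same site set (at least 3 sites).
#' @return scalar Pearson r.
#' @export
compare_estimates <- function(fitsA, fitsB) {
  m <- merge(fitsA[, c("site_id", "coef")], fitsB[, c("site_id", "coef")],
             by = "site_id")
  if (nrow(m) < 3) stop("need at least 3 common sites", call. = FALSE)
  if (sd(m$coef.x) == 0 || sd(m$coef.y) == 0) {
    stop("zero variance in coefficients", call. = FALSE)
  }
  cor(m$coef.x, m$coef.y)
}

#' Change-in-smoking versus change-in-methylation analysis
#'
#' Per site, OLS of the wave-2 minus wave-1 beta-value difference on the
#' 3-level smoking-change variable entered linearly (0 decrease, 1 no
#' change, 2 increase), with a Bonferroni flag at \code{p * m < 0.05}.
#'
#' @param delta_beta sites x samples matrix of beta differences
#'   (wave 2 minus wave 1).
#' @param smoking_change integer vector 0/1/2 per sample.
#' @param covariates optional covariate data.frame (default: unadjusted).
#' @param bonferroni_m Bonferroni family size (default 76-site family is
#'   the number of rows).
#' @return data.frame per site: \code{site_id}, \code{coef}, \code{se},
#'   \code{p}, \code{bonferroni}.
#' @export
run_change_analysis <- function(delta_beta, smoking_change,
                                covariates = NULL, bonferroni_m = NULL) {
  delta_beta <- as.matrix(delta_beta)
  if (length(unique(smoking_change)) < 2) {
    stop("smoking change is constant; nothing to regress on", call. = FALSE)
  }
  n <- ncol(delta_beta)
  X <- build_design(n, exposure = as.numeric(smoking_change),
                    covariates = covariates, svs = NULL)
  qrX <- qr(X)
  Y <- t(delta_beta)
  B <- qr.coef(qrX, Y)
  E <- Y - qr.fitted(qrX, Y)
  df <- n - ncol(X)
  sigma2 <- colSums(E^2) / df
  v <- diag(chol2inv(qr.R(qrX)))[match("exposure", colnames(X))]
  est <- B[match("exposure", colnames(X)), ]
  se <- sqrt(sigma2 * v)
  p <- 2 * pt(abs(est / se), df, lower.tail = FALSE)
  out <- data.frame(site_id = rownames(delta_beta) %||%
                      paste0("site", seq_len(nrow(delta_beta))),
                    coef = unname(est), se = unname(se), p = unname(p),
                    stringsAsFactors = FALSE)
  out$bonferroni <- out$p * (bonferroni_m %||% nrow(out)) < 0.05
  out
}
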