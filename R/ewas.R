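# Per-site association scans: linear EWAS of methylation on the smoking
# phenotype, logistic EWAS of lung cancer on methylation, with
# surrogate-variable adjustment and the epigenome-wide / Bonferroni
# significance rules.

#' Estimate surrogate variables by residual singular value decomposition
#'
#' Residualizes each site's beta-values on the exposure and covariates,
#' row-centers the residual matrix and returns its top-k right singular
#' vectors as sample-level surrogate variables capturing latent batch or
#' technical structure.  The result is deterministic: each column's sign
#' is fixed by making its largest-magnitude element positive.
#'
#' @param meth a \code{\link{methylation_matrix}} or a plain sites x
#'   samples beta matrix.
#' @param exposure numeric exposure per sample.
#' @param covariates data.frame or matrix of adjustment covariates (may be
#'   NULL).
#' @param k number of surrogate variables (default 12).
#' @return samples x k matrix with orthonormal columns (empty matrix when
#'   \code{k = 0}).
#' @export
estimate_surrogate_variables <- function(meth, exposure, covariates = NULL,
                                         k = 12) {
  beta <- if (inherits(meth, "methylation_matrix")) meth$beta else
    as.matrix(meth)
  n <- ncol(beta)
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- build_design(n, exposure, covariates, svs = NULL)
  if (n <= k + ncol(X)) {
    stop("k too large for the number of samples and model terms",
         call. = FALSE)
  }
  qrX <- qr(X)
  # residualize all sites at once: R = Y - Y P_X  (Y is n x p)
  Y <- t(beta)
  R <- Y - qr.fitted(qrX, Y)
  R <- t(scale(t(R), center = TRUE, scale = FALSE))  # row-center sites
  sv <- svd(t(R), nu = 0, nv = k)
  V <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |element| of each column made positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("sv", seq_len(k))
  V
}

# Assemble the model matrix [1, exposure, covariates, SVs].
build_design <- function(n, exposure, covariates, svs) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(exposure)) X <- cbind(X, exposure = as.numeric(exposure))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- covariate_matrix(covariates)
    X <- cbind(X, cm)
  }
  if (!is.null(svs) && NCOL(svs) > 0) X <- cbind(X, as.matrix(svs))
  X
}

# Expand a covariate table to numeric columns (factors/characters dummied,
# one level dropped).
covariate_matrix <- function(covariates) {
  covariates <- as.data.frame(covariates)
  mm <- model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]
}

#' Linear EWAS of methylation on a numeric exposure
#'
#' Per CpG site, ordinary least squares of beta-values on
#' \code{[1, exposure, covariates, SVs]}; the reported coefficient is the
#' exposure term (beta-value units per exposure level), with a two-sided
#' t-test p-value and significance flags from
#' \code{\link{apply_thresholds}}.
#'
#' @param meth \code{\link{methylation_matrix}} or sites x samples matrix.
#' @param exposure numeric exposure (e.g. the 7-level smoking phenotype).
#' @param covariates adjustment covariates (data.frame/matrix or NULL).
#' @param svs surrogate-variable matrix (samples x k) or NULL.
#' @param genomewide_alpha epigenome-wide threshold (default 5e-8).
#' @param bonferroni_m family size for the Bonferroni flag (default: the
#'   number of sites scanned).
#' @return data.frame (one row per site): \code{site_id}, \code{chr},
#'   \code{pos}, \code{gene}, \code{coef}, \code{se}, \code{p},
#'   \code{genomewide}, \code{bonferroni}.
#' @export
run_linear_ewas <- function(meth, exposure, covariates = NULL, svs = NULL,
                            genomewide_alpha = 5e-8, bonferroni_m = NULL) {
  beta <- if (inherits(meth, "methylation_matrix")) meth$beta else
    as.matrix(meth)
  ann <- if (inherits(meth, "methylation_matrix")) meth$annotation else
    data.frame(site_id = rownames(beta) %||% paste0("site", seq_len(nrow(beta))),
               chr = NA, pos = NA, gene = NA, stringsAsFactors = FALSE)
  n <- ncol(beta)
  X <- build_design(n, exposure, covariates, svs)
  if (n - ncol(X) < 10) {
    stop("fewer than 10 residual degrees of freedom", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  Y <- t(beta)                                  # n x p
  coefs <- qr.coef(qrX, Y)                      # k x p
  res <- Y - qr.fitted(qrX, Y)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtX_inv_diag <- diag(chol2inv(qr.R(qrX)))
  iexp <- match("exposure", colnames(X))
  est <- coefs[iexp, ]
  se <- sqrt(sigma2 * XtX_inv_diag[iexp])
  tval <- est / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)            # report underflow as tiny, not 0
  out <- data.frame(site_id = ann$site_id, chr = ann$chr, pos = ann$pos,
                    gene = ann$gene, coef = unname(est), se = unname(se),
                    p = unname(p), stringsAsFactors = FALSE)
  apply_thresholds(out, genomewide_alpha = genomewide_alpha,
                   bonferroni_m = bonferroni_m %||% nrow(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logistic EWAS of case status on methylation
#'
#' Per CpG site, maximum-likelihood logistic regression (iteratively
#' reweighted least squares via \code{stats::glm}) of case status on
#' \code{[1, beta, covariates, SVs (+ smoking when \code{adjust_smoking})]}.
#' The coefficient is reported per full beta-value change (0 to 1);
#' \code{or_per_percent} gives the odds ratio per 1 percentage point.
#' Sites with perfect separation or non-convergence are flagged with
#' missing estimates rather than crashing the scan.
#'
#' @param case_status 0/1 outcome per sample.
#' @param meth \code{\link{methylation_matrix}} or sites x samples matrix.
#' @param covariates adjustment covariates or NULL.
#' @param svs surrogate variables or NULL.
#' @param smoking numeric smoking phenotype, required when
#'   \code{adjust_smoking = TRUE}.
#' @param adjust_smoking include smoking in the model (mediator-screen
#'   models leave it out; direct-effect models put it in).
#' @param genomewide_alpha,bonferroni_m significance thresholds as in
#'   \code{\link{run_linear_ewas}}.
#' @param epsilon IRLS convergence tolerance passed to \code{glm.control}.
#' @return data.frame per site: \code{site_id}, \code{chr}, \code{pos},
#'   \code{gene}, \code{coef}, \code{se}, \code{p}, \code{or_per_percent},
#'   \code{converged}, \code{genomewide}, \code{bonferroni}.
#' @export
run_logistic_ewas <- function(case_status, meth, covariates = NULL,
                              svs = NULL, smoking = NULL,
                              adjust_smoking = FALSE,
                              genomewide_alpha = 5e-8, bonferroni_m = NULL,
                              epsilon = 1e-8) {
  beta <- if (inherits(meth, "methylation_matrix")) meth$beta else
    as.matrix(meth)
  ann <- if (inherits(meth, "methylation_matrix")) meth$annotation else
    data.frame(site_id = rownames(beta) %||% paste0("site", seq_len(nrow(beta))),
               chr = NA, pos = NA, gene = NA, stringsAsFactors = FALSE)
  y <- as.integer(case_status)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (adjust_smoking && is.null(smoking)) {
    stop("`smoking` required when adjust_smoking = TRUE", call. = FALSE)
  }
  n <- ncol(beta)
  Xbase <- build_design(n, exposure = NULL, covariates = covariates,
                        svs = svs)
  if (adjust_smoking) Xbase <- cbind(Xbase, smoking = as.numeric(smoking))
  p <- nrow(beta)
  est <- se <- pval <- rep(NA_real_, p)
  conv <- logical(p)
  for (j in seq_len(p)) {
    X <- cbind(Xbase[, 1, drop = FALSE], meth_beta = beta[j, ],
               Xbase[, -1, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial(),
                               control = glm.control(epsilon = epsilon,
                                                     maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    cf <- fit$coefficients["meth_beta"]
    # detect (quasi-)separation: fitted probabilities at the boundary
    if (any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)) {
      next
    }
    XtWX <- crossprod(X * sqrt(fit$weights))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(vc)) next
    i <- match("meth_beta", colnames(X))
    est[j] <- cf
    se[j] <- sqrt(vc[i, i])
    pval[j] <- 2 * pnorm(abs(cf) / se[j], lower.tail = FALSE)
    conv[j] <- TRUE
  }
  pval <- pmax(pval, .Machine$double.xmin)
  out <- data.frame(site_id = ann$site_id, chr = ann$chr, pos = ann$pos,
                    gene = ann$gene, coef = est, se = se, p = pval,
                    or_per_percent = or_per_percent(est),
                    converged = conv, stringsAsFactors = FALSE)
  apply_thresholds(out, genomewide_alpha = genomewide_alpha,
                   bonferroni_m = bonferroni_m %||% nrow(out))
}

#' Apply epigenome-wide and Bonferroni significance flags
#'
#' The genome-wide flag marks \code{p < genomewide_alpha} (default 5e-8);
#' the Bonferroni flag marks \code{p * m < 0.05}.
#'
#' @param results data.frame with a \code{p} column.
#' @param genomewide_alpha epigenome-wide threshold.
#' @param bonferroni_m number of tests in the Bonferroni family.
#' @return \code{results} with logical columns \code{genomewide} and
#'   \code{bonferroni} (re)computed.
#' @export
apply_thresholds <- function(results, genomewide_alpha = 5e-8,
                             bonferroni_m = nrow(results)) {
  stopifnot(bonferroni_m >= 1)
  results$genomewide <- !is.na(results$p) & results$p < genomewide_alpha
  results$bonferroni <- !is.na(results$p) & results$p * bonferroni_m < 0.05
  results
}
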