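# Counterfactual mediation of the smoking - lung cancer relationship by
# single CpG sites and by a weighted methylation score: natural direct and
# indirect effects by the product method, percentile bootstrap intervals,
# and the relative-indirect-effect summary.

#' Specify a mediation analysis
#'
#' @param exposure numeric exposure (smoking phenotype 0-6).
#' @param mediator continuous mediator (a site's beta-values or a score).
#' @param outcome 0/1 case status.
#' @param covariates data.frame of covariates entering both models, or
#'   NULL.
#' @param contrast exposure contrast \code{c(a, a_star)}; default
#'   \code{c(1, 0)}, i.e. effects per one phenotype level.
#' @param boot number of bootstrap replicates (>= 100; default 1000).
#' @param conf CI level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{mediation_spec}.
#' @export
mediation_spec <- function(exposure, mediator, outcome, covariates = NULL,
                           contrast = c(1, 0), boot = 1000, conf = 0.95,
                           seed = 1L) {
  if (contrast[1] == contrast[2]) stop("contrast levels must differ",
                                       call. = FALSE)
  if (boot < 100) stop("boot must be at least 100", call. = FALSE)
  structure(list(exposure = as.numeric(exposure),
                 mediator = as.numeric(mediator),
                 outcome = as.integer(outcome),
                 covariates = covariates,
                 contrast = contrast, boot = as.integer(boot),
                 conf = conf, seed = as.integer(seed)),
            class = "mediation_spec")
}

#' Fit the mediator model (OLS of mediator on exposure and covariates)
#'
#' @param spec a \code{\link{mediation_spec}}.
#' @return list with \code{coef} (named vector; \code{exposure} is the
#'   exposure slope) and the \code{lm} fit.
#' @export
fit_mediator_model <- function(spec) {
  X <- build_design(length(spec$exposure), spec$exposure, spec$covariates,
                    NULL)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient mediator model",
                               call. = FALSE)
  b <- qr.coef(qrX, spec$mediator)
  list(coef = b, qr = qrX)
}

# Logistic outcome model: case ~ exposure + mediator (+ covariates).
fit_outcome_model <- function(spec) {
  X <- build_design(length(spec$exposure), spec$exposure, spec$covariates,
                    NULL)
  X <- cbind(X[, 1, drop = FALSE], mediator = spec$mediator,
             X[, -1, drop = FALSE])
  fit <- suppressWarnings(glm.fit(X, spec$outcome, family = binomial(),
                                  control = glm.control(epsilon = 1e-8,
                                                        maxit = 100)))
  fit$coefficients
}

#' Estimate natural direct, indirect and total effects
#'
#' Product-method counterfactual decomposition without exposure-mediator
#' interaction: with mediator-model exposure slope \eqn{\beta_1} and
#' outcome-model terms \eqn{\theta_A} (exposure) and \eqn{\theta_M}
#' (mediator), over the contrast \eqn{(a, a^*)}:
#' \deqn{NIE = \theta_M \beta_1 (a - a^*), \quad
#'       NDE = \theta_A (a - a^*), \quad TE = NDE + NIE}
#' all on the log-odds-ratio scale.  Confidence intervals are percentile
#' bootstrap over jointly refitted models (nonparametric resampling of
#' individuals).  The relative indirect effect is NIE/TE, undefined when
#' |TE| is below tolerance.
#'
#' @param spec a \code{\link{mediation_spec}}.
#' @param te_tol total effects smaller than this in absolute value make
#'   the relative effect undefined (default 1e-10).
#' @return object of class \code{mediation_result}: a one-row data.frame
#'   with \code{te}, \code{nde}, \code{nie}, their CIs, \code{relative}
#'   (+ CI) and \code{identified} (NIE CI excludes 0).
#' @export
estimate_natural_effects <- function(spec, te_tol = 1e-10) {
  point <- natural_effects_once(spec$exposure, spec$mediator, spec$outcome,
                                spec$covariates, spec$contrast)
  n <- length(spec$exposure)
  boots <- with_seed(spec$seed, {
    vapply(seq_len(spec$boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      cv <- if (is.null(spec$covariates)) NULL else
        as.data.frame(spec$covariates)[ix, , drop = FALSE]
      tryCatch(natural_effects_once(spec$exposure[ix], spec$mediator[ix],
                                    spec$outcome[ix], cv, spec$contrast),
               error = function(e) c(te = NA_real_, nde = NA_real_,
                                     nie = NA_real_))
    }, c(te = 0, nde = 0, nie = 0))
  })
  alpha <- (1 - spec$conf) / 2
  qs <- function(x) unname(quantile(x, c(alpha, 1 - alpha), na.rm = TRUE))
  te_ci <- qs(boots["te", ]); nde_ci <- qs(boots["nde", ])
  nie_ci <- qs(boots["nie", ])
  rel_boot <- boots["nie", ] / boots["te", ]
  rel_boot[abs(boots["te", ]) < te_tol] <- NA
  rel <- relative_indirect(point["te"], point["nie"], te_tol = te_tol)
  res <- data.frame(te = point[["te"]], te_lo = te_ci[1], te_hi = te_ci[2],
                    nde = point[["nde"]], nde_lo = nde_ci[1],
                    nde_hi = nde_ci[2],
                    nie = point[["nie"]], nie_lo = nie_ci[1],
                    nie_hi = nie_ci[2],
                    relative = rel, rel_lo = qs(rel_boot)[1],
                    rel_hi = qs(rel_boot)[2],
                    identified = nie_ci[1] > 0 | nie_ci[2] < 0)
  class(res) <- c("mediation_result", "data.frame")
  res
}

natural_effects_once <- function(exposure, mediator, outcome, covariates,
                                 contrast) {
  sp <- list(exposure = exposure, mediator = mediator, outcome = outcome,
             covariates = covariates)
  beta1 <- fit_mediator_model(structure(sp, class = "mediation_spec"))$coef[["exposure"]]
  th <- fit_outcome_model(structure(sp, class = "mediation_spec"))
  d <- contrast[1] - contrast[2]
  nie <- th[["mediator"]] * beta1 * d
  nde <- th[["exposure"]] * d
  c(te = nde + nie, nde = nde, nie = nie)
}

#' Relative indirect effect (indirect divided by total)
#'
#' @param total,indirect effects on the log-odds scale.
#' @param digits rounding for reporting (default 2); NULL to skip.
#' @param te_tol totals below this magnitude return \code{NA} (undefined
#'   ratio), never infinity.
#' @return the ratio \code{indirect / total}.
#' @export
#' @examples
#' relative_indirect(0.74, 0.45)  # 0.61
relative_indirect <- function(total, indirect, digits = 2, te_tol = 1e-10) {
  r <- ifelse(abs(total) < te_tol, NA_real_, indirect / total)
  if (!is.null(digits)) r <- round(r, digits)
  unname(r)
}

#' Weighted methylation score
#'
#' Per-individual sum of beta-values at the mediator sites, each weighted
#' by its effect size with lung cancer (the per-site logistic coefficient
#' from the smoking-unadjusted cancer EWAS).
#'
#' @param beta sites x samples beta matrix.
#' @param weights named numeric vector of per-site weights; names must
#'   all be present among \code{rownames(beta)}.
#' @return numeric score per sample.
#' @export
weighted_methylation_score <- function(beta, weights) {
  beta <- as.matrix(beta)
  missing_sites <- setdiff(names(weights), rownames(beta))
  if (length(missing_sites) > 0) {
    stop("site(s) absent from beta matrix: ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  drop(crossprod(beta[names(weights), , drop = FALSE], weights))
}

#' Screen candidate CpG sites as mediators and analyze the weighted score
#'
#' Each candidate (the intersection of smoking-EWAS and cancer-EWAS hits)
#' is analyzed as a single mediator; a site is "identified" when its NIE
#' percentile bootstrap CI excludes zero.  Identified sites are combined
#' into the weighted methylation score (weights = their cancer-EWAS
#' coefficients), which is then analyzed as one mediator.
#'
#' @param candidates character vector of candidate site ids.
#' @param beta sites x samples beta matrix containing the candidates.
#' @param exposure,outcome,covariates as in \code{\link{mediation_spec}}.
#' @param weights named per-site weights for the score (typically the
#'   smoking-unadjusted cancer-EWAS coefficients); defaults to the
#'   identified sites with unit weights when NULL.
#' @param boot,conf,seed bootstrap settings.
#' @return list with \code{per_site} (data.frame of
#'   \code{mediation_result} rows), \code{identified} (site ids) and
#'   \code{score} (the score-level \code{mediation_result}, or NULL when
#'   nothing was identified).
#' @export
run_mediation_screen <- function(candidates, beta, exposure, outcome,
                                 covariates = NULL, weights = NULL,
                                 boot = 1000, conf = 0.95, seed = 1L) {
  if (length(candidates) == 0) {
    warning("empty candidate set; nothing to screen")
    return(list(per_site = data.frame(), identified = character(0),
                score = NULL))
  }
  per_site <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    s <- candidates[i]
    sp <- mediation_spec(exposure, beta[s, ], outcome, covariates,
                         boot = boot, conf = conf,
                         seed = sub_seed(seed, i))
    cbind(site_id = s, estimate_natural_effects(sp))
  }))
  identified <- per_site$site_id[per_site$identified]
  score_res <- NULL
  if (length(identified) > 0) {
    w <- if (is.null(weights)) {
      setNames(rep(1, length(identified)), identified)
    } else {
      weights[intersect(names(weights), identified)]
    }
    score <- weighted_methylation_score(beta, w)
    sp <- mediation_spec(exposure, score, outcome, covariates,
                         boot = boot, conf = conf,
                         seed = sub_seed(seed, 0))
    score_res <- estimate_natural_effects(sp)
  }
  list(per_site = per_site, identified = identified, score = score_res)
}
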