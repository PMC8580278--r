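# Two-step Mendelian randomization: one-sample 2SLS of methylation on
# smoking via a 3-SNP genetic score, and two-sample Wald ratio / IVW of
# lung cancer on methylation via mQTL instruments, with strength
# diagnostics and cis-only filtering.

#' Build an allele-count genetic score
#'
#' Weighted sum of risk-allele dosages over the smoking SNPs; default
#' weights are 1 per risk allele (unweighted score).  Individuals with a
#' missing dosage at any requested SNP are excluded (NA score) with a
#' message giving the count.
#'
#' @param genotypes individuals x SNPs dosage matrix (0/1/2).
#' @param snp_ids columns to use (default all).
#' @param weights per-SNP weights (default 1).
#' @return numeric score per individual.
#' @export
build_genetic_score <- function(genotypes, snp_ids = NULL, weights = NULL) {
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  missing_snps <- setdiff(snp_ids, colnames(genotypes))
  if (length(missing_snps) > 0) {
    stop("SNP(s) not in genotype matrix: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  G <- genotypes[, snp_ids, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, length(snp_ids))
  score <- drop(G %*% weights)
  n_missing <- sum(is.na(score))
  if (n_missing > 0) {
    message(sprintf("%d individual(s) with missing genotypes excluded",
                    n_missing))
  }
  score
}

#' Instrument strength: variance explained and F statistic
#'
#' OLS of the exposure on the score; \code{F = (R2 / (1 - R2)) *
#' (n - 2)} for the single score term.
#'
#' @param score genetic score per individual.
#' @param exposure numeric exposure (smoking phenotype).
#' @return list with \code{r_squared}, \code{f_statistic} (\code{Inf}
#'   when R2 = 1), and \code{n}.
#' @export
instrument_strength <- function(score, exposure) {
  keep <- !is.na(score) & !is.na(exposure)
  score <- score[keep]; exposure <- exposure[keep]
  n <- length(score)
  if (n <= 2) stop("need more than 2 observations", call. = FALSE)
  if (sd(score) == 0) stop("score is constant", call. = FALSE)
  fit <- lm(exposure ~ score)
  r2 <- summary(fit)$r.squared
  f <- if (r2 >= 1 - 1e-14) Inf else (r2 / (1 - r2)) * (n - 2)
  list(r_squared = r2, f_statistic = f, n = n)
}

#' One-sample MR by two-stage least squares
#'
#' Stage 1 regresses the exposure on the instrument (+ covariates); stage
#' 2 regresses the outcome (a methylation site, on the chosen scale) on
#' the fitted exposure (+ covariates).  Standard errors use stage-2
#' residuals recomputed with the observed exposure (standard 2SLS
#' variance).  Weak instruments (first-stage F below \code{f_floor}) are
#' flagged but still reported.
#'
#' @param score instrument (genetic score).
#' @param exposure observed exposure.
#' @param outcome outcome vector (e.g. one site's M-values).
#' @param covariates optional covariate data.frame.
#' @param f_floor weak-instrument flag threshold (default 10).
#' @return one-row data.frame of class \code{mr_result}: \code{method},
#'   \code{estimate}, \code{se}, \code{p}, \code{n_instruments},
#'   \code{f_statistic}, \code{r_squared}, \code{weak_instrument}.
#' @export
two_stage_least_squares <- function(score, exposure, outcome,
                                    covariates = NULL, f_floor = 10) {
  keep <- stats::complete.cases(score, exposure, outcome)
  score <- score[keep]; exposure <- exposure[keep]; outcome <- outcome[keep]
  cv <- if (is.null(covariates)) NULL else
    as.data.frame(covariates)[keep, , drop = FALSE]
  if (sd(score) == 0 || sd(exposure) == 0) {
    stop("instrument and exposure must be nonconstant", call. = FALSE)
  }
  n <- length(score)
  Z <- build_design(n, score, cv, NULL)        # [1, score, covs]
  X1 <- qr(Z)
  xhat <- qr.fitted(X1, exposure)
  W <- build_design(n, xhat, cv, NULL)         # [1, xhat, covs]
  qrW <- qr(W)
  b <- qr.coef(qrW, outcome)
  # residuals with the OBSERVED exposure at the 2SLS coefficients
  Wobs <- build_design(n, exposure, cv, NULL)
  e <- outcome - Wobs %*% b
  k <- ncol(W)
  sigma2 <- sum(e^2) / (n - k)
  V <- sigma2 * chol2inv(qr.R(qrW))
  i <- match("exposure", colnames(W))
  est <- b[[i]]; se <- sqrt(V[i, i])
  strength <- instrument_strength(score, exposure)
  res <- data.frame(method = "tsls", estimate = est, se = se,
                    p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                    n_instruments = 1L,
                    f_statistic = strength$f_statistic,
                    r_squared = strength$r_squared,
                    weak_instrument = strength$f_statistic < f_floor,
                    stringsAsFactors = FALSE)
  class(res) <- c("mr_result", "data.frame")
  res
}

#' Wald ratio MR estimate from one instrument
#'
#' Estimate = \code{Gamma / gamma} (outcome association over exposure
#' association), first-order SE = \code{se_Gamma / |gamma|}, odds ratio
#' with normal CI.
#'
#' @param gamma instrument effect on the mediator (M-value per allele).
#' @param Gamma instrument effect on the outcome (log-OR per allele).
#' @param se_Gamma its standard error.
#' @param conf CI level (default 0.95).
#' @return one-row data.frame of class \code{mr_result} with
#'   \code{estimate} (log-OR per unit M-value), \code{se}, \code{p},
#'   \code{or}, \code{or_lo}, \code{or_hi}, \code{n_instruments = 1}.
#' @export
wald_ratio <- function(gamma, Gamma, se_Gamma, conf = 0.95) {
  if (gamma == 0) stop("instrument effect gamma must be nonzero",
                       call. = FALSE)
  if (se_Gamma <= 0) stop("se_Gamma must be positive", call. = FALSE)
  est <- Gamma / gamma
  se <- se_Gamma / abs(gamma)
  mr_result_row("wald", est, se, 1L, conf)
}

mr_result_row <- function(method, est, se, n_inst, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  res <- data.frame(method = method, estimate = est, se = se,
                    p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                    or = exp(est), or_lo = exp(est - z * se),
                    or_hi = exp(est + z * se),
                    n_instruments = as.integer(n_inst),
                    stringsAsFactors = FALSE)
  class(res) <- c("mr_result", "data.frame")
  res
}

#' Fixed-effect inverse-variance weighted MR estimate
#'
#' \deqn{\hat\beta_{IVW} = \frac{\sum_i \gamma_i \Gamma_i / se_i^2}
#'                              {\sum_i \gamma_i^2 / se_i^2}, \qquad
#'       SE = \sqrt{1 / \sum_i \gamma_i^2 / se_i^2}}
#' equivalently the weighted regression of Gamma on gamma through the
#' origin.  With a single instrument this reduces exactly to the Wald
#' ratio.
#'
#' @param gamma vector of instrument-mediator effects.
#' @param Gamma vector of instrument-outcome effects (log-OR).
#' @param se_Gamma their standard errors.
#' @param conf CI level.
#' @return one-row \code{mr_result} data.frame as in
#'   \code{\link{wald_ratio}}.
#' @export
ivw <- function(gamma, Gamma, se_Gamma, conf = 0.95) {
  k <- length(gamma)
  if (length(Gamma) != k || length(se_Gamma) != k) {
    stop("gamma, Gamma and se_Gamma must have equal length", call. = FALSE)
  }
  if (any(se_Gamma <= 0)) stop("all se_Gamma must be positive",
                               call. = FALSE)
  w <- 1 / se_Gamma^2
  est <- sum(gamma * Gamma * w) / sum(gamma^2 * w)
  se <- sqrt(1 / sum(gamma^2 * w))
  mr_result_row("ivw", est, se, k, conf)
}

#' Keep cis instruments only
#'
#' Retains instruments on the CpG's chromosome within \code{window} base
#' pairs of its position (inclusive bound).
#'
#' @param instruments data.frame with columns \code{snp}, \code{chr},
#'   \code{pos} (and any effect columns, carried through).
#' @param cpg_chr,cpg_pos the CpG's coordinates.
#' @param window distance in bp (default 1e6).
#' @return subset of \code{instruments}; zero rows allowed (with a
#'   warning).
#' @export
filter_cis <- function(instruments, cpg_chr, cpg_pos, window = 1e6) {
  keep <- instruments$chr == cpg_chr &
    abs(instruments$pos - cpg_pos) <= window
  out <- instruments[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no cis instruments within the window")
  out
}

#' Harmonize instrument and outcome summary statistics
#'
#' Matches by SNP id and aligns the outcome effect to the instrument's
#' effect allele: when the alleles are swapped the outcome effect sign is
#' flipped.  Palindromic SNPs (A/T or C/G) are resolved by effect-allele
#' frequency when both frequencies are away from 0.5
#' (\code{|eaf - 0.5| > 0.08}); ambiguous palindromes are dropped with a
#' warning.
#'
#' @param instruments data.frame: \code{snp}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}.
#' @param outcomes data.frame: \code{snp}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf} (optional), \code{beta}, \code{se}.
#' @return merged data.frame with columns \code{snp}, \code{gamma},
#'   \code{se_gamma}, \code{Gamma}, \code{se_Gamma}.
#' @export
harmonize_instruments <- function(instruments, outcomes) {
  m <- merge(instruments, outcomes, by = "snp",
             suffixes = c("_exp", "_out"))
  if (nrow(m) == 0) {
    stop("no SNPs shared between instrument and outcome sets",
         call. = FALSE)
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ea_e <- toupper(m$effect_allele_exp); oa_e <- toupper(m$other_allele_exp)
  ea_o <- toupper(m$effect_allele_out); oa_o <- toupper(m$other_allele_out)
  palindromic <- ea_e == comp[oa_e]
  same <- ea_o == ea_e & oa_o == oa_e
  swapped <- ea_o == oa_e & oa_o == ea_e
  flip_strand <- ea_o == comp[ea_e] & oa_o == comp[oa_e] & !palindromic
  swap_strand <- ea_o == comp[oa_e] & oa_o == comp[ea_e] & !palindromic
  sign_flip <- ifelse(same | flip_strand, 1,
                      ifelse(swapped | swap_strand, -1, NA))
  if ("eaf_out" %in% names(m)) {
    amb <- palindromic & (abs(m$eaf_exp - 0.5) <= 0.08 |
                            abs(m$eaf_out - 0.5) <= 0.08)
    # palindromes with informative frequencies: align by frequency
    pal_ok <- palindromic & !amb
    sign_flip[pal_ok] <- ifelse(
      (m$eaf_exp[pal_ok] > 0.5) == (m$eaf_out[pal_ok] > 0.5), 1, -1)
    sign_flip[amb] <- NA
  } else {
    sign_flip[palindromic & !same & !swapped] <- NA
  }
  dropped <- is.na(sign_flip)
  if (any(dropped)) {
    warning(sprintf("dropped %d unharmonizable SNP(s): %s", sum(dropped),
                    paste(m$snp[dropped], collapse = ", ")))
  }
  m <- m[!dropped, , drop = FALSE]
  sf <- sign_flip[!dropped]
  data.frame(snp = m$snp, gamma = m$beta_exp, se_gamma = m$se_exp,
             Gamma = sf * m$beta_out, se_Gamma = m$se_out,
             stringsAsFactors = FALSE)
}

#' Second-step MR screen over candidate mediator sites
#'
#' Per site: Wald ratio when exactly one harmonized instrument is
#' available, IVW otherwise; Bonferroni flag at \code{p * m < 0.05}.
#' Sites with no instrument or no outcome statistics are reported as
#' untestable rather than dropped.
#'
#' @param sites character vector of site ids.
#' @param instruments_by_site named list of harmonized data.frames (as
#'   returned by \code{\link{harmonize_instruments}}) per site; an entry
#'   may have zero rows or be NULL.
#' @param bonferroni_m Bonferroni family size (default: number of
#'   testable sites).
#' @param conf CI level.
#' @return data.frame per site: \code{site_id}, \code{method},
#'   \code{n_instruments}, \code{estimate}, \code{se}, \code{p},
#'   \code{or}, \code{or_lo}, \code{or_hi}, \code{testable},
#'   \code{bonferroni}.
#' @export
mr_second_step_screen <- function(sites, instruments_by_site,
                                  bonferroni_m = NULL, conf = 0.95) {
  rows <- lapply(sites, function(s) {
    ins <- instruments_by_site[[s]]
    if (is.null(ins) || nrow(ins) == 0) {
      return(data.frame(site_id = s, method = NA_character_,
                        n_instruments = 0L, estimate = NA_real_,
                        se = NA_real_, p = NA_real_, or = NA_real_,
                        or_lo = NA_real_, or_hi = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    r <- if (nrow(ins) == 1) {
      wald_ratio(ins$gamma, ins$Gamma, ins$se_Gamma, conf = conf)
    } else {
      ivw(ins$gamma, ins$Gamma, ins$se_Gamma, conf = conf)
    }
    data.frame(site_id = s, method = r$method,
               n_instruments = r$n_instruments, estimate = r$estimate,
               se = r$se, p = r$p, or = r$or, or_lo = r$or_lo,
               or_hi = r$or_hi, testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- bonferroni_m %||% sum(out$testable)
  out$bonferroni <- !is.na(out$p) & out$p * max(m, 1) < 0.05
  out
}

#' Variance in methylation explained by an mQTL from summary statistics
#'
#' \code{2 f (1 - f) gamma^2 / var_m}: the standard summary-statistic
#' approximation under Hardy-Weinberg.
#'
#' @param eaf effect-allele frequency.
#' @param gamma allelic effect on the M-value.
#' @param var_m variance of the M-values (default 1, i.e. standardized).
#' @return proportion of variance explained (summed over instruments).
#' @export
mqtl_variance_explained <- function(eaf, gamma, var_m = 1) {
  sum(2 * eaf * (1 - eaf) * gamma^2) / var_m
}
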