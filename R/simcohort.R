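# Synthetic nested case-control cohorts with two measurement waves and a
# fully known causal structure.  Every downstream stage (EWAS, repeated
# measures, mediation, MR) is testable against the planted truth without
# any external data.

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-cohort generator.  Defaults emulate a
#' two-wave (about 11 years apart) nested case-control study of smoking,
#' blood DNA methylation and lung cancer: ~280 subjects sampled as matched
#' case-control pairs, three smoking-associated SNPs whose unweighted score
#' explains ~1.8% of smoking-phenotype variance, per-CpG mQTLs (1-9 per
#' site), six blood cell types with Dirichlet-distributed proportions, a
#' two-level batch, and configurable direct (smoking to cancer) and
#' mediated (methylation to cancer) effects.  The mediated effect defaults
#' to zero: smoking affects methylation and cancer, but methylation does
#' not itself cause cancer.
#'
#' @param n_individuals source-cohort size from which cases and matched
#'   controls are drawn.
#' @param n_sites number of CpG sites.
#' @param n_signal_sites number of sites with a nonzero planted smoking
#'   effect.
#' @param n_smoking_snps number of smoking-associated SNPs (default 3).
#' @param mqtl_range integer range of mQTL instruments per site (default
#'   1 to 9).
#' @param allele_freqs effect-allele frequencies for the smoking SNPs;
#'   recycled to \code{n_smoking_snps}.
#' @param tau per-site smoking effect on the M-value scale per phenotype
#'   level, for signal sites; negative values plant hypomethylation.  A
#'   scalar is expanded with 80\% of signal sites taking \code{tau} and
#'   20\% taking \code{-tau} (smoking-associated sites are predominantly
#'   hypomethylated); a vector of length \code{n_signal_sites} is used
#'   as-is.
#' @param theta_direct smoking to cancer log-odds ratio per phenotype
#'   level.
#' @param theta_med methylation to cancer log-odds ratio per unit M-value
#'   of the mediator-set average (default 0).
#' @param smoking_r2 share of 7-level-phenotype variance explained by the
#'   genetic score (default 0.018).
#' @param n_cell_types number of blood cell types (default 6).
#' @param cell_conc Dirichlet concentration for cell proportions.
#' @param cell_effect_sd SD of per-site cell-composition coefficients
#'   (M-value units).
#' @param batch_effect_sd SD of the per-site batch effect (M-value units).
#' @param subject_sd SD of the per-individual random intercept shared by
#'   both waves (induces within-person correlation across waves).
#' @param residual_sd per-site residual SD on the M-value scale.
#' @param mqtl_effect_sd SD of mQTL allelic effects (M-value per allele).
#' @param wave_transition_probs 3x3 row-stochastic matrix over statuses
#'   (never, former, current) for wave-1 to wave-2 transitions; entries
#'   into "never" from ever-smoking states must be zero.
#' @param wave_gap_years calendar years between waves (default 11).
#' @param case_fraction target fraction of cases in the source cohort.
#' @param age_caliper matching caliper in years (default 3).
#' @param seed integer seed controlling all randomness.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_individuals = 2000,
                       n_sites = 500,
                       n_signal_sites = 76,
                       n_smoking_snps = 3,
                       mqtl_range = c(1L, 9L),
                       allele_freqs = c(0.20, 0.35, 0.08),
                       tau = -0.12,
                       theta_direct = 0.35,
                       theta_med = 0,
                       smoking_r2 = 0.018,
                       n_cell_types = 6,
                       cell_conc = c(12, 6, 4, 2, 1.5, 1),
                       cell_effect_sd = 0.15,
                       batch_effect_sd = 0.10,
                       subject_sd = 0.20,
                       residual_sd = 0.35,
                       mqtl_effect_sd = 0.15,
                       wave_transition_probs = default_transition_probs(),
                       wave_gap_years = 11,
                       case_fraction = 0.07,
                       age_caliper = 3,
                       seed = 1L) {
  allele_freqs <- rep_len(allele_freqs, n_smoking_snps)
  stopifnot_scalar_prob(allele_freqs, "allele_freqs")
  stopifnot_scalar_prob(case_fraction, "case_fraction")
  stopifnot_scalar_prob(smoking_r2, "smoking_r2")
  if (n_signal_sites > n_sites) {
    stop("n_signal_sites cannot exceed n_sites", call. = FALSE)
  }
  for (nm in c("cell_effect_sd", "batch_effect_sd", "subject_sd",
               "residual_sd", "mqtl_effect_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) {
      stop(sprintf("`%s` must be a nonnegative number", nm), call. = FALSE)
    }
  }
  validate_transition_matrix(wave_transition_probs)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_sites = as.integer(n_sites),
              n_signal_sites = as.integer(n_signal_sites),
              n_smoking_snps = as.integer(n_smoking_snps),
              mqtl_range = as.integer(mqtl_range),
              allele_freqs = allele_freqs,
              tau = tau, theta_direct = theta_direct, theta_med = theta_med,
              smoking_r2 = smoking_r2,
              n_cell_types = as.integer(n_cell_types),
              cell_conc = rep_len(cell_conc, n_cell_types),
              cell_effect_sd = cell_effect_sd,
              batch_effect_sd = batch_effect_sd,
              subject_sd = subject_sd,
              residual_sd = residual_sd,
              mqtl_effect_sd = mqtl_effect_sd,
              wave_transition_probs = wave_transition_probs,
              wave_gap_years = wave_gap_years,
              case_fraction = case_fraction,
              age_caliper = age_caliper,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals, %d CpG sites (%d with planted signal)\n",
              x$n_individuals, x$n_sites, x$n_signal_sites))
  cat(sprintf("  tau = %s (M per level), theta_direct = %.3g, theta_med = %.3g\n",
              paste(format(unique(x$tau)), collapse = "/"),
              x$theta_direct, x$theta_med))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

default_transition_probs <- function() {
  # Marginals loosely emulating an ageing cohort re-surveyed ~11 years on:
  # some quitting, a little initiation, no resurrection of never-smokers.
  m <- matrix(c(0.93, 0.05, 0.02,
                0.00, 0.88, 0.12,
                0.00, 0.45, 0.55),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("never", "former", "current"),
                              c("never", "former", "current")))
  m
}

validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3))) {
    stop("transition matrix must be 3x3 (never, former, current)",
         call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("transition matrix rows must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (m[2, 1] != 0 || m[3, 1] != 0) {
    stop("transitions former->never and current->never are impossible",
         call. = FALSE)
  }
  invisible(m)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each entry is the sum of two independent Bernoulli(f) allele draws, i.e.
#' Binomial(2, f) dosages in \{0, 1, 2\}.
#'
#' @param freqs per-SNP effect-allele frequencies, each strictly in (0, 1).
#' @param n number of individuals.
#' @param seed integer seed.
#' @param snp_ids optional column names.
#' @return integer matrix, \code{n} x \code{length(freqs)}.
#' @export
simulate_genotypes <- function(freqs, n, seed, snp_ids = NULL) {
  stopifnot_scalar_prob(freqs, "freqs")
  g <- with_seed(seed, {
    vapply(freqs, function(f) rbinom(n, 2L, f), integer(n))
  })
  g <- matrix(as.integer(g), nrow = n)
  colnames(g) <- if (is.null(snp_ids)) {
    paste0("rs", seq_along(freqs))
  } else snp_ids
  g
}

#' Simulate smoking status and pack-years from genotypes
#'
#' A latent liability (weighted allele count plus standard normal noise)
#' is cut at two thresholds into never/former/current.  The score weight
#' is calibrated by root-finding on a large internal pilot cohort so the
#' regression R-squared of the realized 7-level phenotype on the raw
#' genetic score matches \code{target_r2} (default 1.8\%, a weak
#' instrument by design).  Pack-years are Gamma-distributed for ever
#' smokers with mean increasing in the quantity-SNP dosage (SNP 2 by
#' convention) and higher for current than former smokers; never smokers
#' have exactly zero pack-years.
#'
#' @param genotypes dosage matrix from \code{\link{simulate_genotypes}}.
#' @param score_weights per-SNP weights for the latent score (default 1).
#' @param thresholds two strictly increasing liability cut points
#'   separating never/former/current.
#' @param target_r2 share of phenotype variance the genetic score should
#'   explain; 0 makes smoking independent of genotype.
#' @param seed integer seed.
#' @return data.frame with columns \code{status}, \code{pack_years},
#'   \code{phenotype} (the 7-level coding).
#' @export
simulate_smoking <- function(genotypes, score_weights = NULL,
                             thresholds = c(0.10, 0.85),
                             target_r2 = 0.018, seed = 1L) {
  n <- nrow(genotypes)
  if (is.null(score_weights)) score_weights <- rep(1, ncol(genotypes))
  if (length(score_weights) != ncol(genotypes)) {
    stop("one weight per SNP required", call. = FALSE)
  }
  if (diff(thresholds) <= 0) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  score <- drop(genotypes %*% score_weights)
  b <- calibrate_liability_weight(score_weights, colMeans(genotypes) / 2,
                                  thresholds, target_r2, seed)
  with_seed(sub_seed(seed, 1), {
    liability <- b * (score - mean(score)) + rnorm(n)
    status <- cut(liability, c(-Inf, thresholds, Inf),
                  labels = c("never", "former", "current"))
    status <- as.character(status)
    draw_packyears(status, genotypes, seed_used = FALSE)
  })
}

# Pack-years for ever smokers: Gamma with shape 2; mean scales with the
# quantity SNP (column 2 when present) and is higher for current smokers.
draw_packyears <- function(status, genotypes, seed_used = TRUE) {
  n <- length(status)
  qty <- if (ncol(genotypes) >= 2) genotypes[, 2] else rep(0, n)
  mean_py <- ifelse(status == "current", 18, 12) * (1 + 0.15 * qty)
  py <- numeric(n)
  ever <- status != "never"
  py[ever] <- rgamma(sum(ever), shape = 2, scale = mean_py[ever] / 2)
  data.frame(status = status, pack_years = py,
             phenotype = derive_smoking_phenotype(status, py))
}

# Find the liability weight b whose induced phenotype-scale R^2 matches the
# target, using a 20k-individual pilot cohort at a deterministic sub-seed.
calibrate_liability_weight <- function(score_weights, freqs, thresholds,
                                       target_r2, seed) {
  if (target_r2 == 0 || all(score_weights == 0)) return(0)
  n_pilot <- 20000L
  pilot_g <- simulate_genotypes(pmin(pmax(freqs, 0.01), 0.99), n_pilot,
                                sub_seed(seed, 901))
  score <- drop(pilot_g %*% score_weights)
  score_c <- score - mean(score)
  with_seed(sub_seed(seed, 902), {
    noise <- rnorm(n_pilot)
    phen_r2 <- function(b) {
      liab <- b * score_c + noise
      status <- as.character(cut(liab, c(-Inf, thresholds, Inf),
                                 labels = c("never", "former", "current")))
      ph <- draw_packyears(status, pilot_g)$phenotype
      summary(lm(ph ~ score))$r.squared
    }
    # R^2 is monotone in b up to MC noise; bracket and bisect.
    lo <- 0; hi <- 2
    while (phen_r2(hi) < target_r2 && hi < 32) hi <- hi * 2
    uniroot(function(b) phen_r2(b) - target_r2, c(lo, hi),
            tol = 1e-3)$root
  })
}

#' Simulate a methylation matrix from exposure, genotype and covariates
#'
#' Per site, the M-value is
#' \code{mu0 + tau * smoking + sum(gamma * mQTL dosage) + cell term +
#' batch term + subject intercept + Gaussian noise}, then stored as
#' beta-values \code{2^M / (2^M + 1)}, strictly in (0, 1).
#'
#' @param smoking numeric 7-level smoking phenotype per individual.
#' @param mqtl_geno list of per-site dosage matrices (individuals x
#'   instruments), as built by \code{\link{simulate_cohort}}; may be NULL.
#' @param truth a \code{cohort_truth} list carrying per-site intercepts,
#'   \code{tau}, mQTL effects, cell and batch coefficients.
#' @param cell_props individuals x cell-types proportion matrix.
#' @param batch integer batch indicator per individual (0/1).
#' @param subject_intercept per-individual scalar added to all sites'
#'   M-values (shared across waves).
#' @param residual_sd Gaussian noise SD on the M-value scale.
#' @param seed integer seed.
#' @return a \code{methylation_matrix}: see \code{\link{methylation_matrix}}.
#' @export
simulate_methylation <- function(smoking, mqtl_geno, truth, cell_props,
                                 batch, subject_intercept, residual_sd,
                                 seed) {
  n <- length(smoking)
  p <- length(truth$mu0)
  stopifnot(nrow(cell_props) == n, length(batch) == n,
            length(subject_intercept) == n)
  M <- matrix(0, nrow = p, ncol = n)
  cell_dev <- sweep(cell_props, 2, colMeans(cell_props))
  cell_term <- truth$cell_coef %*% t(cell_dev)        # p x n
  batch_term <- outer(truth$batch_coef, batch)        # p x n
  M <- truth$mu0 + outer(truth$tau, smoking) + cell_term + batch_term
  M <- sweep(M, 2, subject_intercept, `+`)
  if (!is.null(mqtl_geno)) {
    for (j in seq_len(p)) {
      if (length(truth$mqtl_effects[[j]]) > 0) {
        M[j, ] <- M[j, ] + drop(mqtl_geno[[j]] %*% truth$mqtl_effects[[j]])
      }
    }
  }
  if (residual_sd > 0) {
    M <- M + with_seed(seed, matrix(rnorm(p * n, sd = residual_sd), p, n))
  }
  beta <- m_to_beta(M)
  methylation_matrix(beta, truth$annotation)
}

#' Construct a methylation matrix container
#'
#' @param beta sites x samples matrix of beta-values in (0, 1).
#' @param annotation data.frame with columns \code{site_id}, \code{chr},
#'   \code{pos}, \code{gene}, \code{gene_region}; one row per site.
#' @return object of class \code{methylation_matrix} with components
#'   \code{beta} and \code{annotation}.
#' @export
methylation_matrix <- function(beta, annotation) {
  beta <- as.matrix(beta)
  if (any(beta <= 0 | beta >= 1)) {
    stop("beta-values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (nrow(beta) != nrow(annotation)) {
    stop("annotation rows must match beta rows", call. = FALSE)
  }
  if (anyDuplicated(annotation$site_id)) {
    stop("site ids must be unique", call. = FALSE)
  }
  rownames(beta) <- annotation$site_id
  structure(list(beta = beta, annotation = annotation),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d sites x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

# Draw per-site structural parameters (the planted truth).
make_truth <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 10), {
    p <- cfg$n_sites
    tau <- numeric(p)
    signal_idx <- seq_len(cfg$n_signal_sites)
    if (length(cfg$tau) == cfg$n_signal_sites) {
      tau[signal_idx] <- cfg$tau
    } else {
      # predominantly hypomethylation: 80% of signal sites carry tau,
      # the remaining 20% the opposite sign
      n_neg <- round(0.8 * cfg$n_signal_sites)
      tau[signal_idx] <- rep(c(cfg$tau, -cfg$tau),
                             c(n_neg, cfg$n_signal_sites - n_neg))
    }
    n_mqtl <- sample(seq(cfg$mqtl_range[1], cfg$mqtl_range[2]), p,
                     replace = TRUE)
    mqtl_effects <- lapply(n_mqtl, function(k) {
      rnorm(k, sd = cfg$mqtl_effect_sd)
    })
    mqtl_freqs <- lapply(n_mqtl, function(k) runif(k, 0.05, 0.95))
    chr <- sample(1:22, p, replace = TRUE)
    pos <- sample.int(2e8, p)
    annotation <- data.frame(
      site_id = sprintf("cg%08d", seq_len(p)),
      chr = chr, pos = pos,
      gene = ifelse(runif(p) < 0.6, sprintf("GENE%04d", seq_len(p)), ""),
      gene_region = sample(c("Body", "TSS1500", "5'UTR", ""), p,
                           replace = TRUE),
      stringsAsFactors = FALSE)
    list(mu0 = rnorm(p, 0, 1.5),
         tau = tau,
         signal_sites = annotation$site_id[signal_idx],
         mqtl_effects = mqtl_effects,
         mqtl_freqs = mqtl_freqs,
         cell_coef = matrix(rnorm(p * cfg$n_cell_types,
                                  sd = cfg$cell_effect_sd),
                            p, cfg$n_cell_types),
         batch_coef = rnorm(p, sd = cfg$batch_effect_sd),
         annotation = annotation)
  })
}

# Dirichlet draws via normalized Gamma variates.
rdirichlet <- function(n, conc) {
  g <- matrix(rgamma(n * length(conc), shape = conc), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate wave-2 phenotypes and methylation from a wave-1 cohort
#'
#' Smoking status transitions are sampled from the configured row-stochastic
#' matrix; pack-years accumulate for continuing smokers (one pack-year per
#' calendar year per smoking intensity unit), stay frozen on cessation, and
#' remain zero for never smokers.  Wave-2 methylation is regenerated from
#' the wave-2 exposure with the same per-individual random intercept as
#' wave 1, inducing within-person correlation across waves.
#'
#' @param cohort a \code{cohort} object (wave-1 fields populated).
#' @param transition_probs optional override of the config's transition
#'   matrix.
#' @param seed integer seed.
#' @return the cohort with wave-2 phenotype columns and \code{meth_w2}
#'   filled in.
#' @export
simulate_wave2 <- function(cohort, transition_probs = NULL, seed = NULL) {
  cfg <- cohort$config
  if (is.null(transition_probs)) transition_probs <- cfg$wave_transition_probs
  validate_transition_matrix(transition_probs)
  if (is.null(seed)) seed <- sub_seed(cfg$seed, 30)
  ph <- cohort$phenotypes
  n <- nrow(ph)
  states <- c("never", "former", "current")
  with_seed(seed, {
    s1 <- match(ph$status_w1, states)
    s2 <- vapply(s1, function(s) {
      sample.int(3L, 1L, prob = transition_probs[s, ])
    }, integer(1))
    ph$status_w2 <- states[s2]
    ph$age_w2 <- ph$age_w1 + cfg$wave_gap_years
    # pack-years: continuing current smokers accumulate roughly one pack a
    # day-equivalent scaled by prior intensity; quitters and never freeze
    ph$packyears_w2 <- ph$packyears_w1
    cont <- ph$status_w1 == "current" & ph$status_w2 == "current"
    ph$packyears_w2[cont] <- ph$packyears_w1[cont] +
      rgamma(sum(cont), shape = 2, scale = cfg$wave_gap_years * 0.4)
    starters <- ph$status_w1 == "never" & ph$status_w2 != "never"
    ph$packyears_w2[starters] <- rgamma(sum(starters), shape = 2, scale = 3)
    relapse <- ph$status_w1 == "former" & ph$status_w2 == "current"
    ph$packyears_w2[relapse] <- ph$packyears_w1[relapse] +
      rgamma(sum(relapse), shape = 2, scale = 2)
    ph$phenotype_w2 <- derive_smoking_phenotype(ph$status_w2, ph$packyears_w2)
  })
  cell_w2 <- with_seed(sub_seed(seed, 1),
                       rdirichlet(n, cfg$cell_conc))
  colnames(cell_w2) <- colnames(cohort$cell_props_w1)
  rownames(cell_w2) <- ph$id
  cohort$phenotypes <- ph
  cohort$cell_props_w2 <- cell_w2
  cohort$meth_w2 <- simulate_methylation(
    smoking = ph$phenotype_w2,
    mqtl_geno = cohort$mqtl_geno,
    truth = cohort$truth,
    cell_props = cell_w2,
    batch = cohort$batch,
    subject_intercept = cohort$truth$subject_intercept,
    residual_sd = cfg$residual_sd,
    seed = sub_seed(seed, 2))
  colnames(cohort$meth_w2$beta) <- ph$id
  cohort
}

#' Assign case status and draw a matched nested case-control sample
#'
#' Case probability is \code{plogis(alpha + theta_direct * smoking +
#' theta_med * mean mediator M-value)} with \code{alpha} solved so the
#' realized case fraction matches the configured target.  Each case is
#' greedily paired with the nearest-age unused control of the same sex
#' within the caliper; when none exists the caliper is widened once
#' (doubled), and the case is dropped with a warning if matching still
#' fails.
#'
#' @param cohort a \code{cohort} with wave-1 methylation available.
#' @param theta_direct,theta_med optional overrides of the config values.
#' @param caliper matching caliper in years (default from config).
#' @param seed integer seed.
#' @return the cohort with \code{case} and \code{matchset} columns filled
#'   and an index \code{sampled} of rows in the nested case-control set.
#' @export
simulate_outcome_and_sample <- function(cohort, theta_direct = NULL,
                                        theta_med = NULL, caliper = NULL,
                                        seed = NULL) {
  cfg <- cohort$config
  if (is.null(theta_direct)) theta_direct <- cfg$theta_direct
  if (is.null(theta_med)) theta_med <- cfg$theta_med
  if (is.null(caliper)) caliper <- cfg$age_caliper
  if (is.null(seed)) seed <- sub_seed(cfg$seed, 40)
  ph <- cohort$phenotypes
  n <- nrow(ph)
  smk <- ph$phenotype_w1
  smk[is.na(smk)] <- 0
  med_m <- if (theta_med != 0) {
    sig <- cohort$truth$signal_sites
    colMeans(beta_to_m(cohort$meth_w1$beta[sig, , drop = FALSE]))
  } else rep(0, n)
  lp0 <- theta_direct * smk + theta_med * med_m
  alpha <- uniroot(function(a) mean(plogis(a + lp0)) - cfg$case_fraction,
                   c(-30, 30))$root
  with_seed(seed, {
    ph$case <- rbinom(n, 1L, plogis(alpha + lp0))
  })
  ph$matchset <- NA_integer_
  cases <- which(ph$case == 1L)
  controls_pool <- which(ph$case == 0L)
  used <- rep(FALSE, n)
  set_id <- 0L
  dropped <- 0L
  for (i in cases) {
    elig <- controls_pool[!used[controls_pool] &
                            ph$sex[controls_pool] == ph$sex[i] &
                            abs(ph$age_w1[controls_pool] - ph$age_w1[i]) <=
                              caliper]
    if (length(elig) == 0) {  # widen once
      elig <- controls_pool[!used[controls_pool] &
                              ph$sex[controls_pool] == ph$sex[i] &
                              abs(ph$age_w1[controls_pool] - ph$age_w1[i]) <=
                                2 * caliper]
    }
    if (length(elig) == 0) {
      dropped <- dropped + 1L
      next
    }
    j <- elig[which.min(abs(ph$age_w1[elig] - ph$age_w1[i]))]
    set_id <- set_id + 1L
    ph$matchset[c(i, j)] <- set_id
    used[j] <- TRUE
  }
  if (dropped > 0) {
    warning(sprintf("%d case(s) dropped: no eligible control within twice the caliper",
                    dropped))
  }
  cohort$phenotypes <- ph
  cohort$sampled <- which(!is.na(ph$matchset))
  cohort
}

#' Simulate a complete two-wave nested case-control cohort
#'
#' Runs the full generative chain: genotypes (smoking SNPs and per-site
#' mQTLs), smoking phenotype, cell proportions, batch, wave-1 methylation,
#' wave-2 transitions and methylation, case status and matched sampling.
#' The returned object carries the planted truth for parameter-recovery
#' tests.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{cohort} with components \code{phenotypes}
#'   (data.frame), \code{genotypes}, \code{mqtl_geno}, \code{meth_w1},
#'   \code{meth_w2}, \code{cell_props_w1}, \code{cell_props_w2},
#'   \code{batch}, \code{truth}, \code{sampled}, \code{config}.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 200, n_sites = 50,
#'                                   n_signal_sites = 10, seed = 7))
#' table(coh$phenotypes$status_w1)
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  n <- cfg$n_individuals
  geno <- simulate_genotypes(cfg$allele_freqs, n, sub_seed(cfg$seed, 1),
                             snp_ids = c("rs6265", "rs1051730", "rs3025343")[
                               seq_len(min(3, cfg$n_smoking_snps))])
  smoking <- simulate_smoking(geno, target_r2 = cfg$smoking_r2,
                              seed = sub_seed(cfg$seed, 2))
  truth <- make_truth(cfg)
  truth$subject_intercept <- with_seed(sub_seed(cfg$seed, 3),
                                       rnorm(n, sd = cfg$subject_sd))
  mqtl_geno <- with_seed(sub_seed(cfg$seed, 4), {
    lapply(truth$mqtl_freqs, function(fr) {
      matrix(rbinom(n * length(fr), 2L, rep(fr, each = n)), nrow = n)
    })
  })
  ph <- with_seed(sub_seed(cfg$seed, 5), {
    data.frame(id = sprintf("S%05d", seq_len(n)),
               sex = sample(c("F", "M"), n, replace = TRUE,
                            prob = c(0.45, 0.55)),
               age_w1 = round(runif(n, 35, 70), 1),
               status_w1 = smoking$status,
               packyears_w1 = smoking$pack_years,
               phenotype_w1 = smoking$phenotype,
               stringsAsFactors = FALSE)
  })
  batch <- with_seed(sub_seed(cfg$seed, 6), rbinom(n, 1L, 0.5))
  cell_w1 <- with_seed(sub_seed(cfg$seed, 7), rdirichlet(n, cfg$cell_conc))
  colnames(cell_w1) <- paste0("cell", seq_len(cfg$n_cell_types))
  rownames(cell_w1) <- ph$id
  meth_w1 <- simulate_methylation(
    smoking = ph$phenotype_w1,
    mqtl_geno = mqtl_geno,
    truth = truth,
    cell_props = cell_w1,
    batch = batch,
    subject_intercept = truth$subject_intercept,
    residual_sd = cfg$residual_sd,
    seed = sub_seed(cfg$seed, 8))
  colnames(meth_w1$beta) <- ph$id
  rownames(geno) <- ph$id
  cohort <- structure(list(phenotypes = ph, genotypes = geno,
                           mqtl_geno = mqtl_geno, meth_w1 = meth_w1,
                           meth_w2 = NULL, cell_props_w1 = cell_w1,
                           cell_props_w2 = NULL, batch = batch,
                           truth = truth, sampled = NULL, config = cfg),
                      class = "cohort")
  cohort <- simulate_wave2(cohort)
  cohort <- simulate_outcome_and_sample(cohort)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf("<cohort> %d individuals, %d CpG sites, %d matched case-control pairs\n",
              nrow(ph), nrow(x$meth_w1$beta),
              sum(ph$case == 1 & !is.na(x$phenotypes$matchset))))
  invisible(x)
}
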