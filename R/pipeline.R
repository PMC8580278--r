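# Orchestration of the full chain (simulate -> smoking EWAS -> repeated
# confirmation -> cancer EWAS -> overlap -> mediation -> two-step MR) plus
# the plain-text readers and writers for every stage table.

#' Intersect smoking-EWAS and cancer-EWAS hit lists
#'
#' @param smoking_hits,cancer_hits character vectors of site ids.
#' @return sorted character vector of common site ids.
#' @export
overlap_sites <- function(smoking_hits, cancer_hits) {
  sort(intersect(smoking_hits, cancer_hits))
}

#' Write / read the phenotype table
#'
#' Column schema: id, sex, age_w1, age_w2, status_w1, status_w2,
#' packyears_w1, packyears_w2, phenotype_w1, phenotype_w2, case, matchset.
#'
#' @param phenotypes data.frame (the \code{cohort$phenotypes} slot).
#' @param path file path (CSV).
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a methylation matrix as TSV
#'
#' Site rows: site_id, chr, pos, gene, gene_region, then one column per
#' sample id.
#'
#' @param meth a \code{\link{methylation_matrix}}.
#' @param path file path (TSV).
#' @export
write_methylation <- function(meth, path) {
  df <- cbind(meth$annotation, as.data.frame(meth$beta))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   quote = "")
  ann_cols <- c("site_id", "chr", "pos", "gene", "gene_region")
  ann <- df[, ann_cols]
  ann$gene[is.na(ann$gene)] <- ""
  ann$gene_region[is.na(ann$gene_region)] <- ""
  beta <- as.matrix(df[, setdiff(names(df), ann_cols), drop = FALSE])
  methylation_matrix(beta, ann)
}

#' Write / read a genotype dosage table (TSV, id x rsID)
#'
#' @param genotypes individuals x SNPs matrix with row/column names.
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df$id
  g
}

#' Write a generic results table as TSV
#'
#' @param results data.frame; @param path file path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full causal-inference chain on a synthetic cohort
#'
#' Executes, in order: cohort simulation; linear EWAS of methylation on
#' smoking among controls; repeated-measures confirmation (LMRSE over the
#' smoking hits, plus the change-on-change analysis); logistic EWAS of
#' lung cancer on methylation without smoking adjustment; overlap of the
#' two hit lists; per-site and weighted-score mediation over the overlap;
#' one-sample 2SLS (first-step MR) over the smoking hits; and second-step
#' MR over the identified mediators using the simulated mQTL effects as
#' instruments with outcome associations from the case-control genotype
#' data.  A stage failure halts the run; the manifest records the stages
#' completed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param k_svs number of surrogate variables (default 12; capped below
#'   by the sample size).
#' @param boot mediation bootstrap replicates (default 200 at pipeline
#'   scale).
#' @param outdir optional directory; when given, every stage table is
#'   written there and the manifest records their checksums.
#' @return list of class \code{pipeline_result}: \code{cohort},
#'   \code{ewas_smoking}, \code{lmrse}, \code{change},
#'   \code{ewas_cancer}, \code{overlap}, \code{mediation},
#'   \code{mr_first_step}, \code{mr_second_step}, \code{manifest}.
#' @export
run_full_pipeline <- function(config = sim_config(), k_svs = 12,
                              boot = 200, outdir = NULL) {
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = character(0),
                   warnings = character(0), timings = numeric(0))
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("%s: %s", name,
                                        conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages <<- c(manifest$stages, name)
    manifest$timings[name] <<- as.numeric(Sys.time() - ts, units = "secs")
    res
  }

  cohort <- stage("simulate", simulate_cohort(config))
  ph <- cohort$phenotypes
  sampled <- cohort$sampled
  ctrl <- sampled[ph$case[sampled] == 0 & !is.na(ph$phenotype_w1[sampled])]

  covs_ctrl <- data.frame(sex = ph$sex[ctrl], age = ph$age_w1[ctrl],
                          cohort$cell_props_w1[ctrl, -1, drop = FALSE])
  beta_ctrl <- cohort$meth_w1$beta[, ctrl, drop = FALSE]
  k_eff <- min(k_svs, length(ctrl) - ncol(covs_ctrl) - 4)
  svs <- stage("sva", estimate_surrogate_variables(
    beta_ctrl, ph$phenotype_w1[ctrl], covs_ctrl, k = max(k_eff, 0)))
  ewas_smoking <- stage("ewas_smoking", {
    r <- run_linear_ewas(methylation_matrix(beta_ctrl,
                                            cohort$meth_w1$annotation),
                         ph$phenotype_w1[ctrl], covs_ctrl, svs)
    r
  })
  smoking_hits <- ewas_smoking$site_id[ewas_smoking$genomewide]

  lmrse <- stage("lmrse", {
    sub <- list(phenotypes = ph[ctrl, ],
                meth_w1 = list(beta = cohort$meth_w1$beta[, ctrl,
                                                          drop = FALSE]),
                meth_w2 = list(beta = cohort$meth_w2$beta[, ctrl,
                                                          drop = FALSE]))
    panel <- build_panel(ids = sub$phenotypes$id,
                         beta_w1 = sub$meth_w1$beta,
                         beta_w2 = sub$meth_w2$beta,
                         exposure_w1 = sub$phenotypes$phenotype_w1,
                         exposure_w2 = sub$phenotypes$phenotype_w2,
                         covariates_w1 = data.frame(sex = sub$phenotypes$sex,
                                                    age = sub$phenotypes$age_w1),
                         covariates_w2 = data.frame(sex = sub$phenotypes$sex,
                                                    age = sub$phenotypes$age_w2))
    sites <- if (length(smoking_hits) > 0) smoking_hits else
      rownames(panel$beta)[seq_len(min(10, nrow(panel$beta)))]
    fit_lmrse(panel, sites = sites,
              bonferroni_m = max(length(smoking_hits), 1))
  })

  change <- stage("change_analysis", {
    ch <- classify_smoking_change(ph$status_w1[ctrl], ph$status_w2[ctrl])
    dbeta <- cohort$meth_w2$beta[, ctrl, drop = FALSE] -
      cohort$meth_w1$beta[, ctrl, drop = FALSE]
    sites <- if (length(smoking_hits) > 0) smoking_hits else
      rownames(dbeta)[seq_len(min(10, nrow(dbeta)))]
    run_change_analysis(dbeta[sites, , drop = FALSE], ch,
                        bonferroni_m = max(length(smoking_hits), 1))
  })

  cc <- sampled
  covs_cc <- data.frame(sex = ph$sex[cc], age = ph$age_w1[cc])
  ewas_cancer <- stage("ewas_cancer", {
    run_logistic_ewas(ph$case[cc],
                      methylation_matrix(cohort$meth_w1$beta[, cc,
                                                             drop = FALSE],
                                         cohort$meth_w1$annotation),
                      covariates = covs_cc)
  })
  cancer_hits <- ewas_cancer$site_id[ewas_cancer$genomewide]

  candidates <- stage("overlap", overlap_sites(smoking_hits, cancer_hits))

  mediation <- stage("mediation", {
    cc_ok <- cc[!is.na(ph$phenotype_w1[cc])]
    w <- setNames(ewas_cancer$coef, ewas_cancer$site_id)[candidates]
    run_mediation_screen(candidates,
                         cohort$meth_w1$beta[, cc_ok, drop = FALSE],
                         exposure = ph$phenotype_w1[cc_ok],
                         outcome = ph$case[cc_ok],
                         covariates = data.frame(sex = ph$sex[cc_ok],
                                                 age = ph$age_w1[cc_ok]),
                         weights = w[!is.na(w)],
                         boot = boot, seed = sub_seed(config$seed, 60))
  })

  mr_first <- stage("mr_first_step", {
    score <- build_genetic_score(cohort$genotypes)
    ok <- !is.na(ph$phenotype_w1)
    strength <- instrument_strength(score[ok], ph$phenotype_w1[ok])
    sites <- if (length(smoking_hits) > 0) smoking_hits else
      rownames(cohort$meth_w1$beta)[1]
    fits <- do.call(rbind, lapply(sites, function(s) {
      m <- beta_to_m(cohort$meth_w1$beta[s, ok])
      r <- two_stage_least_squares(score[ok], ph$phenotype_w1[ok], m)
      cbind(site_id = s, r)
    }))
    list(strength = strength, fits = fits)
  })

  mr_second <- stage("mr_second_step", {
    med_sites <- mediation$identified
    if (length(med_sites) == 0) {
      data.frame()
    } else {
      inst <- lapply(med_sites, function(s) {
        j <- match(s, cohort$meth_w1$annotation$site_id)
        simulated_instruments(cohort, j)
      })
      names(inst) <- med_sites
      mr_second_step_screen(med_sites, inst,
                            bonferroni_m = length(med_sites))
    }
  })

  result <- list(cohort = cohort, ewas_smoking = ewas_smoking,
                 lmrse = lmrse, change = change,
                 ewas_cancer = ewas_cancer, overlap = candidates,
                 mediation = mediation, mr_first_step = mr_first,
                 mr_second_step = mr_second)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_phenotypes(ph, file.path(outdir, "phenotypes.csv"))
    write_methylation(cohort$meth_w1, file.path(outdir, "meth_w1.tsv"))
    write_methylation(cohort$meth_w2, file.path(outdir, "meth_w2.tsv"))
    write_genotypes(cohort$genotypes, file.path(outdir, "genotypes.tsv"))
    write_results(ewas_smoking, file.path(outdir, "ewas_smoking.tsv"))
    write_results(ewas_cancer, file.path(outdir, "ewas_cancer.tsv"))
    write_results(lmrse, file.path(outdir, "lmrse.tsv"))
    write_results(change, file.path(outdir, "change.tsv"))
    files <- list.files(outdir, full.names = TRUE)
    manifest$checksums <- tools::md5sum(files)
  }
  manifest$config_hash <- hash_config(config)
  manifest$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  result
}

# Estimate per-instrument summary statistics from the simulated data:
# gamma from the planted truth, outcome association from logistic
# regression of case status on each instrument dosage.
simulated_instruments <- function(cohort, site_index) {
  gam <- cohort$truth$mqtl_effects[[site_index]]
  G <- cohort$mqtl_geno[[site_index]]
  ph <- cohort$phenotypes
  ix <- cohort$sampled %||% seq_len(nrow(ph))
  rows <- lapply(seq_along(gam), function(k) {
    fit <- suppressWarnings(glm(ph$case[ix] ~ G[ix, k],
                                family = binomial()))
    s <- summary(fit)$coefficients
    data.frame(snp = sprintf("site%d_mqtl%d", site_index, k),
               gamma = gam[k], se_gamma = NA_real_,
               Gamma = s[2, 1], se_Gamma = s[2, 2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config), file = f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  smoking EWAS hits: %d\n", sum(x$ewas_smoking$genomewide)))
  cat(sprintf("  cancer  EWAS hits: %d\n", sum(x$ewas_cancer$genomewide,
                                               na.rm = TRUE)))
  cat(sprintf("  overlap candidates: %d; identified mediators: %d\n",
              length(x$overlap), length(x$mediation$identified)))
  cat(sprintf("  stages: %s\n", paste(x$manifest$stages, collapse = " -> ")))
  invisible(x)
}

#' Write the simulation truth as YAML
#'
#' @param cohort a \code{cohort}; @param path output file.
#' @export
write_truth <- function(cohort, path) {
  tr <- cohort$truth
  yaml::write_yaml(list(
    tau = as.numeric(tr$tau),
    signal_sites = tr$signal_sites,
    theta_direct = cohort$config$theta_direct,
    theta_med = cohort$config$theta_med,
    batch_coef = as.numeric(tr$batch_coef),
    mqtl_effects = lapply(tr$mqtl_effects, as.numeric)), path)
  invisible(path)
}
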