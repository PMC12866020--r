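#' Pipeline configuration
#'
#' Centralises the thresholds of the full analysis chain together with the
#' synthetic-data generator settings. All thresholds are validated at
#' construction.
#'
#' @param generator A [cohort_config()].
#' @param outcomes Liver outcomes to analyse; any of `"ggt"`, `"alt"`,
#'   `"ast"`, `"fli"` (analysed inverse-normal transformed) and
#'   `"steatosis"` (binary).
#' @param fdr FDR significance threshold (default 0.05).
#' @param min_cohorts Replication rule: minimum FDR-significant cohorts.
#' @param lambda_trigger Inflation threshold for empirical-null correction.
#' @param meqtl_sig meQTL genome-wide significance threshold (default 5e-8).
#' @param maf_min,hwe_min,miss_max Variant QC thresholds.
#' @param cis_window cis-meQTL window half-width in bp (default 1 Mb).
#' @param eqtm_window eQTM window half-width in bp (default 100 kb).
#' @param min_stratum_n Minimum per-stratum n for stratified mediation.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            outcomes = c("ggt", "fli"),
                            fdr = 0.05, min_cohorts = 2,
                            lambda_trigger = 1.1, meqtl_sig = 5e-8,
                            maf_min = 0.02, hwe_min = 1e-6, miss_max = 0.05,
                            cis_window = 1e6, eqtm_window = 1e5,
                            min_stratum_n = 100) {
  stopifnot(inherits(generator, "cohort_config"),
            all(outcomes %in% c("ggt", "alt", "ast", "fli", "steatosis")),
            fdr > 0, fdr < 1, min_cohorts >= 1,
            meqtl_sig > 0, meqtl_sig < 1,
            maf_min >= 0, maf_min <= 0.5, hwe_min >= 0, hwe_min <= 1,
            miss_max > 0, miss_max <= 1, cis_window > 0, eqtm_window > 0,
            lambda_trigger >= 0, min_stratum_n >= 10)
  structure(list(generator = generator, outcomes = outcomes, fdr = fdr,
                 min_cohorts = min_cohorts, lambda_trigger = lambda_trigger,
                 meqtl_sig = meqtl_sig, maf_min = maf_min, hwe_min = hwe_min,
                 miss_max = miss_max, cis_window = cis_window,
                 eqtm_window = eqtm_window, min_stratum_n = min_stratum_n),
            class = "pipeline_config")
}

# EWAS covariate table for a simulated cohort: age, sex, BMI, smoking,
# alcohol, 5 of the 6 cell-type proportions (one dropped: they sum to 1 and
# would be collinear with the intercept) and the technical PCs.
ewas_covariates <- function(cohort) {
  cv <- cohort$covariates
  cells <- c("cd4t", "cd8t", "bcell", "nk", "mono")  # 'neu' dropped
  pcs <- grep("^pc_", names(cv), value = TRUE)
  cv[, c("age", "sex", "bmi", "smoking", "alcohol_gday", cells, pcs)]
}

# Mediation covariate set: age, sex, smoking, 3-level alcohol category.
mediation_covariates <- function(cohort) {
  data.frame(age = cohort$covariates$age, sex = cohort$covariates$sex,
             smoking = cohort$covariates$smoking,
             alcohol_drinks_cat =
               categorize_alcohol_mediation(cohort$covariates$alcohol_gday))
}

outcome_vector <- function(cohort, outcome) {
  ph <- cohort$phenotypes
  switch(outcome,
         ggt = ph$ggt_int, alt = ph$alt_int, ast = ph$ast_int,
         fli = ph$fli_int, steatosis = ph$steatosis,
         stop("unknown outcome: ", outcome))
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes the complete chain on data generated under the configured study
#' conditions: three discovery cohorts and a three-generation validation set
#' are simulated; phenotypes are derived; each discovery cohort is analysed
#' by covariate-adjusted EWAS (with inflation-triggered empirical-null
#' correction and FDR); cohort results are pooled by inverse-variance
#' meta-analysis and filtered by the multi-cohort replication rule; the
#' replicated CpGs are re-examined in the three generations (age-trend
#' summary), conditioned on their top cis-meQTL, scanned for nearby eQTM
#' transcripts, and candidate CpG-transcript pairs are decomposed by
#' BMI-stratified mediation of the (inverse-normal transformed, per-stratum)
#' fatty liver index. Deterministic given the generator seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, result tables are written
#'   as TSV/JSON.
#' @return A `liver_pipeline` result list with elements `cohorts`,
#'   `generations`, `ewas`, `meta`, `replicated`, `cross_generation`,
#'   `variant_qc`, `meqtl`, `eqtm`, `mediation`, `log`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  note("simulating 3 discovery cohorts + 3 generations (seed %d)", gen$seed)
  cohorts <- lapply(simulate_discovery_cohorts(gen), derive_phenotypes)
  generations <- lapply(simulate_three_generations(gen), derive_phenotypes)

  ewas <- list(); meta <- list(); replicated <- list()
  for (oc in config$outcomes) {
    binary <- oc == "steatosis"
    res <- lapply(cohorts, function(ch)
      run_ewas(ch$methylation, outcome_vector(ch, oc), ewas_covariates(ch),
               binary = binary, lambda_trigger = config$lambda_trigger,
               outcome_name = oc))
    ewas[[oc]] <- res
    meta[[oc]] <- meta_analysis(res, min_cohorts = config$min_cohorts,
                                alpha = config$fdr)
    replicated[[oc]] <- replication_filter(res, k = config$min_cohorts,
                                           alpha = config$fdr)
    note("outcome %s: %d CpGs replicated in >= %d cohorts", oc,
         length(replicated[[oc]]), config$min_cohorts)
  }

  primary <- config$outcomes[1]
  rep_cpgs <- replicated[[primary]]

  note("validating %d CpGs across generations", length(rep_cpgs))
  gen_ewas <- lapply(generations, function(ch)
    run_ewas(ch$methylation, outcome_vector(ch, primary),
             ewas_covariates(ch), lambda_trigger = config$lambda_trigger,
             outcome_name = primary))
  cross_gen <- if (length(rep_cpgs))
    cross_generation_summary(gen_ewas,
                             mean_ages = vapply(generations, function(g)
                               g$truth$cohort_mean_age, numeric(1)),
                             cpg_ids = rep_cpgs)
  else NULL

  ref <- cohorts[[1]]
  qc <- variant_qc(ref$genotypes, maf_min = config$maf_min,
                   hwe_min = config$hwe_min, miss_max = config$miss_max)
  note("variant QC: %d of %d variants pass", sum(qc$pass), nrow(qc))
  passed <- which(qc$pass)

  meqtl <- list()
  y_ref <- outcome_vector(ref, primary)
  cov_ref <- ewas_covariates(ref)
  for (cg in rep_cpgs) {
    pos <- ref$annotation$cpg$pos[match(cg, ref$annotation$cpg$id)]
    scan <- cis_meqtl_scan(ref$methylation[cg, ], pos,
                           ref$genotypes[passed, , drop = FALSE],
                           ref$annotation$snp[passed, , drop = FALSE],
                           window = config$cis_window, sig = config$meqtl_sig)
    top <- scan[scan$is_top, , drop = FALSE]
    cond <- NULL
    if (nrow(top) == 1) {
      dosage <- ref$genotypes[match(top$snp_id, rownames(ref$genotypes)), ]
      cond <- conditional_association(y_ref, ref$methylation[cg, ], dosage,
                                      cov_ref)
    }
    meqtl[[cg]] <- list(scan = scan, top = top, conditional = cond)
  }
  note("meQTL conditioning done for %d CpGs", length(meqtl))

  eqtm <- list(); mediation <- list()
  med_cov <- mediation_covariates(ref)
  strata <- ref$phenotypes$bmi_stratum
  for (cg in rep_cpgs) {
    pos <- ref$annotation$cpg$pos[match(cg, ref$annotation$cpg$id)]
    sc <- eqtm_scan(ref$methylation[cg, ], pos, ref$expression,
                    ref$annotation$gene,
                    covariates = cbind(ewas_covariates(ref)[
                      c("age", "sex", "bmi", "smoking", "alcohol_gday")]),
                    window = config$eqtm_window)
    eqtm[[cg]] <- sc
    for (gid in sc$gene_id[sc$candidate]) {
      expr <- ref$expression[match(gid, rownames(ref$expression)), ]
      res_s <- list()
      for (lev in levels(strata)) {
        idx <- which(strata == lev)
        if (length(idx) < config$min_stratum_n) next
        # FLI transformed within the analysis stratum
        fli_s <- inverse_normal_transform(ref$phenotypes$fli[idx])
        cov_s <- med_cov[idx, , drop = FALSE]
        cov_s$alcohol_drinks_cat <- droplevels(cov_s$alcohol_drinks_cat)
        res_s[[lev]] <- fit_mediation(fli_s, ref$methylation[cg, idx],
                                      expr[idx], cov_s, stratum = lev)
      }
      mediation[[paste(cg, gid, sep = ":")]] <- res_s
    }
  }
  note("eQTM scans: %d CpGs; mediation pairs analysed: %d",
       length(eqtm), length(mediation))

  out <- structure(list(config = config, cohorts = cohorts,
                        generations = generations, ewas = ewas, meta = meta,
                        replicated = replicated,
                        cross_generation = cross_gen, gen_ewas = gen_ewas,
                        variant_qc = qc, meqtl = meqtl, eqtm = eqtm,
                        mediation = mediation, log = log),
                   class = "liver_pipeline")
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

#' @export
print.liver_pipeline <- function(x, ...) {
  cat("Liver-methylation analysis pipeline run\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (oc in names(result$ewas))
    for (lab in names(result$ewas[[oc]]))
      write.table(result$ewas[[oc]][[lab]]$table,
                  file.path(dir, sprintf("ewas_%s_%s.tsv", oc, lab)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  for (oc in names(result$meta))
    write.table(as.data.frame(result$meta[[oc]]),
                file.path(dir, sprintf("meta_%s.tsv", oc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$cross_generation))
    write.table(result$cross_generation,
                file.path(dir, "cross_generation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$variant_qc, file.path(dir, "variant_qc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  med <- lapply(result$mediation, function(byst)
    lapply(byst, function(m) list(
      stratum = m$stratum, n = m$n,
      total = unname(m$total["estimate"]), direct = unname(m$direct["estimate"]),
      indirect = unname(m$indirect["estimate"]),
      indirect_ci = m$indirect_ci,
      proportion_mediated = m$proportion_mediated$estimate,
      mediated = m$mediated)))
  jsonlite::write_json(med, file.path(dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
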