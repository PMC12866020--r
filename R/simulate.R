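#' Configuration for the synthetic cohort generator
#'
#' Collects the parameters that define the generated study conditions: cohort
#' size, array size, number of planted CpG-phenotype associations, genetic and
#' transcriptomic architecture, effect magnitudes and noise levels. The
#' returned object is validated and carries class `cohort_config`.
#'
#' Planted effects enter the liver phenotype on the log-GGT scale as
#' standardized slopes (change in log GGT per SD of methylation), and are
#' multiplicatively scaled by `(cohort mean age / reference_age)^age_modulation`
#' so that older cohorts show stronger associations. Each planted CpG carries a
#' cis-meQTL (an additive per-allele shift of `meqtl_effect` on the beta-value
#' scale) and the first `n_mediation` planted CpGs additionally drive the
#' expression of a nearby gene (slope `mediation_a` per SD methylation), which
#' in turn drives log GGT (`mediation_b` per expression unit) alongside a
#' direct path (`mediation_c_direct`).
#'
#' @param n_samples_per_cohort Samples per generated cohort.
#' @param n_cpgs Number of CpG probes.
#' @param n_true_cpgs Number of CpGs with planted phenotype associations.
#' @param n_snps Number of genetic variants.
#' @param n_genes Number of expression probes (genes).
#' @param n_mediation Number of planted CpG-gene-phenotype mediation triplets
#'   (at most `n_true_cpgs`).
#' @param age_range_per_cohort Default age range (years) of a cohort.
#' @param effect_size_base Standardized planted slope on log GGT.
#' @param age_modulation Exponent of the age scaling of planted slopes; 0
#'   disables modulation.
#' @param reference_age Cohort mean age (years) at which the planted slope
#'   equals `effect_size_base`.
#' @param mediation_a Slope of nearby-gene expression on standardized
#'   methylation for mediation triplets.
#' @param mediation_b Slope of log GGT on expression for mediation triplets.
#' @param mediation_c_direct Direct standardized slope of log GGT on
#'   methylation for mediation triplets.
#' @param meqtl_effect Per-allele shift of methylation beta-values at planted
#'   meQTLs.
#' @param noise_sd Residual SD of log GGT.
#' @param methylation_logit_sd Residual SD of methylation on the logit scale.
#' @param dosage_missingness Missing-completely-at-random rate of genotype
#'   dosages.
#' @param n_tech_pcs Number of technical (control-probe) principal components.
#' @param seed Master seed; fixes the shared CpG/SNP/gene architecture. Each
#'   cohort additionally takes its own sampling seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples_per_cohort = 1500,
                          n_cpgs = 5000,
                          n_true_cpgs = 20,
                          n_snps = 200,
                          n_genes = 100,
                          n_mediation = 5,
                          age_range_per_cohort = c(35, 55),
                          effect_size_base = 0.25,
                          age_modulation = 1,
                          reference_age = 45,
                          mediation_a = 0.5,
                          mediation_b = 0.4,
                          mediation_c_direct = 0.3,
                          meqtl_effect = 0.05,
                          noise_sd = 0.5,
                          methylation_logit_sd = 0.35,
                          dosage_missingness = 0.02,
                          n_tech_pcs = 5,
                          seed = 1L) {
  cfg <- list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
              n_cpgs = as.integer(n_cpgs),
              n_true_cpgs = as.integer(n_true_cpgs),
              n_snps = as.integer(n_snps),
              n_genes = as.integer(n_genes),
              n_mediation = as.integer(n_mediation),
              age_range_per_cohort = as.numeric(age_range_per_cohort),
              effect_size_base = effect_size_base,
              age_modulation = age_modulation,
              reference_age = reference_age,
              mediation_a = mediation_a,
              mediation_b = mediation_b,
              mediation_c_direct = mediation_c_direct,
              meqtl_effect = meqtl_effect,
              noise_sd = noise_sd,
              methylation_logit_sd = methylation_logit_sd,
              dosage_missingness = dosage_missingness,
              n_tech_pcs = as.integer(n_tech_pcs),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples_per_cohort < 10) stop("config error: n_samples_per_cohort too small")
    if (n_true_cpgs > n_cpgs) stop("config error: n_true_cpgs > n_cpgs")
    if (n_mediation > n_true_cpgs) stop("config error: n_mediation > n_true_cpgs")
    if (n_mediation > n_genes) stop("config error: n_mediation > n_genes")
    if (n_true_cpgs > n_snps) stop("config error: n_true_cpgs > n_snps (one meQTL per planted CpG)")
    if (noise_sd <= 0 || methylation_logit_sd <= 0) stop("config error: SDs must be > 0")
    if (dosage_missingness < 0 || dosage_missingness >= 1)
      stop("config error: dosage_missingness must be in [0, 1)")
    if (length(age_range_per_cohort) != 2 || diff(age_range_per_cohort) <= 0)
      stop("config error: age_range_per_cohort must be an increasing pair of years")
  })
  invisible(cfg)
}

#' Methylation beta-value from raw array intensities
#'
#' \eqn{\beta = M / (M + U + \alpha)}: the methylated signal divided by the
#' overall signal, regularised by a non-negative offset so the ratio is defined
#' and lies in \[0, 1) even for weak probes.
#'
#' @param M Non-negative methylated signal intensity.
#' @param U Non-negative unmethylated signal intensity.
#' @param alpha_offset Non-negative regularising offset (default 100).
#' @return Beta-values in \[0, 1).
#' @examples
#' beta_from_intensities(300, 600, 100)  # 0.3
#' @export
beta_from_intensities <- function(M, U, alpha_offset = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) ||
      any(alpha_offset < 0, na.rm = TRUE))
    stop("invalid intensity: M, U and alpha_offset must be non-negative")
  denom <- M + U + alpha_offset
  if (any(denom == 0, na.rm = TRUE))
    stop("invalid intensity: M + U + alpha_offset is zero")
  M / denom
}

# Deterministic shared architecture: CpG baselines and loadings, planted
# effects, SNP and gene placement. Drawn from config$seed only, so every
# cohort generated under one config shares the same genome and effect map.
cohort_architecture <- function(cfg) {
  with_seed(cfg$seed, {
    n_cpgs <- cfg$n_cpgs
    spacing <- 4000L
    cpg <- data.frame(id = sprintf("cg%07d", seq_len(n_cpgs)),
                      chrom = "chr1",
                      pos = seq_len(n_cpgs) * spacing,
                      stringsAsFactors = FALSE)
    mu <- 0.15 + 0.7 * rbeta(n_cpgs, 2, 2)
    cell_load <- matrix(rnorm(n_cpgs * 6, sd = 1.5), n_cpgs, 6)
    pc_load <- matrix(rnorm(n_cpgs * cfg$n_tech_pcs, sd = 0.15), n_cpgs, cfg$n_tech_pcs)

    planted_idx <- sort(sample.int(n_cpgs, cfg$n_true_cpgs))
    sign <- sample(c(-1, 1), cfg$n_true_cpgs, replace = TRUE)
    med_rows <- seq_len(cfg$n_mediation)
    sign[med_rows] <- 1  # mediation chain slopes are configured directly

    # one causal cis-SNP per planted CpG, well inside the 1 Mb window
    snp_pos <- integer(cfg$n_snps)
    snp_maf <- numeric(cfg$n_snps)
    snp_pos[seq_len(cfg$n_true_cpgs)] <-
      cpg$pos[planted_idx] + round(runif(cfg$n_true_cpgs, -1e5, 1e5))
    snp_maf[seq_len(cfg$n_true_cpgs)] <- runif(cfg$n_true_cpgs, 0.1, 0.4)
    extra <- setdiff(seq_len(cfg$n_snps), seq_len(cfg$n_true_cpgs))
    snp_pos[extra] <- sort(sample.int(max(cpg$pos) + spacing, length(extra)))
    snp_maf[extra] <- runif(length(extra), 0.05, 0.45)
    snp <- data.frame(id = sprintf("snp%05d", seq_len(cfg$n_snps)),
                      chrom = "chr1", pos = pmax(1L, snp_pos), maf = snp_maf,
                      stringsAsFactors = FALSE)

    # mediation genes within the 100 kb eQTM window of their CpG
    gene_start <- integer(cfg$n_genes)
    gene_start[med_rows] <- cpg$pos[planted_idx[med_rows]] +
      round(runif(cfg$n_mediation, -5e4, 5e4))
    other <- setdiff(seq_len(cfg$n_genes), med_rows)
    gene_start[other] <- sort(sample.int(max(cpg$pos) + spacing, length(other)))
    gene <- data.frame(id = sprintf("gene%04d", seq_len(cfg$n_genes)),
                       chrom = "chr1", start = pmax(1L, gene_start),
                       end = pmax(1L, gene_start) + 2000L,
                       stringsAsFactors = FALSE)

    planted <- data.frame(cpg_id = cpg$id[planted_idx],
                          cpg_index = planted_idx,
                          sign = sign,
                          base_slope = sign * cfg$effect_size_base,
                          is_mediation = seq_len(cfg$n_true_cpgs) %in% med_rows,
                          stringsAsFactors = FALSE)
    meqtl <- data.frame(cpg_id = planted$cpg_id,
                        snp_id = snp$id[seq_len(cfg$n_true_cpgs)],
                        snp_index = seq_len(cfg$n_true_cpgs),
                        beta_per_allele = rep(cfg$meqtl_effect, cfg$n_true_cpgs),
                        stringsAsFactors = FALSE)
    mediation <- data.frame(cpg_id = planted$cpg_id[med_rows],
                            cpg_index = planted_idx[med_rows],
                            gene_id = gene$id[med_rows],
                            gene_index = med_rows,
                            a = rep(cfg$mediation_a, cfg$n_mediation),
                            b = rep(cfg$mediation_b, cfg$n_mediation),
                            c_direct = rep(cfg$mediation_c_direct, cfg$n_mediation),
                            indirect = rep(cfg$mediation_a * cfg$mediation_b,
                                           cfg$n_mediation),
                            total = rep(cfg$mediation_c_direct +
                                          cfg$mediation_a * cfg$mediation_b,
                                        cfg$n_mediation),
                            stringsAsFactors = FALSE)
    list(cpg = cpg, snp = snp, gene = gene, mu = mu,
         cell_load = cell_load, pc_load = pc_load,
         planted = planted, meqtl = meqtl, mediation = mediation)
  })
}

# Draw one allele transmitted by a parent with the given additive dosage.
transmit_allele <- function(dosage) {
  het <- dosage == 1
  out <- as.integer(dosage == 2)
  out[het] <- rbinom(sum(het), 1, 0.5)
  out[is.na(dosage)] <- NA_integer_
  out
}

draw_genotypes <- function(maf, n) {
  t(vapply(maf, function(p) rbinom(n, 1, p) + rbinom(n, 1, p), integer(n)))
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate one synthetic cohort
#'
#' Draws a full cohort under the configured study conditions: bounded
#' methylation beta-values with cell-type and technical structure, additive
#' cis-genetics, nearby-gene expression partially driven by methylation,
#' age/sex/BMI-correlated liver phenotypes with planted CpG effects whose
#' magnitude grows with cohort mean age, and a fully populated ground-truth
#' block. All cohorts produced under one `config` share the same CpG/SNP/gene
#' architecture (drawn from `config$seed`), so per-CpG results are poolable
#' across cohorts.
#'
#' @param config A [cohort_config()].
#' @param cohort_mean_age Mean age (years) of the cohort; defaults to the
#'   midpoint of `config$age_range_per_cohort`.
#' @param seed Sampling seed for this cohort (defaults to `config$seed`).
#' @param label Cohort label.
#' @param age_range Age range; defaults to `config$age_range_per_cohort`
#'   re-centred on `cohort_mean_age`.
#' @param genotypes Optional pre-made dosage matrix (SNP x sample), used by
#'   [simulate_three_generations()] to impose parental transmission.
#' @return A `sim_cohort` list with elements `methylation` (CpG x sample
#'   beta-values), `genotypes` (SNP x sample dosages with NA for missing),
#'   `expression` (gene x sample), `covariates`, `phenotypes`, `annotation`
#'   (CpG/SNP/gene coordinates, 1-based) and `truth`.
#' @export
simulate_cohort <- function(config, cohort_mean_age = NULL, seed = config$seed,
                            label = "cohort", age_range = NULL,
                            genotypes = NULL) {
  validate_cohort_config(config)
  arch <- cohort_architecture(config)
  if (is.null(cohort_mean_age))
    cohort_mean_age <- mean(config$age_range_per_cohort)
  if (is.null(age_range)) {
    half <- diff(config$age_range_per_cohort) / 2
    age_range <- c(cohort_mean_age - half, cohort_mean_age + half)
  }
  n <- config$n_samples_per_cohort
  age_factor <- if (config$age_modulation == 0) 1 else
    (cohort_mean_age / config$reference_age)^config$age_modulation

  with_seed(seed, {
    sample_id <- sprintf("%s_S%04d", label, seq_len(n))

    age <- runif(n, age_range[1], age_range[2])
    sex <- rbinom(n, 1, 0.5)                      # 1 = female
    bmi <- pmax(16, 21 + 0.07 * (age - 45) + rnorm(n, 0, 3.5))
    waist <- ifelse(sex == 1, 80, 94) + 2.4 * (bmi - 25) + rnorm(n, 0, 4)
    smoking <- rbinom(n, 1, 0.25)
    drinks <- rbinom(n, 1, 0.7)                   # 30% abstainers
    alcohol <- drinks * rgamma(n, shape = 1.3,
                               scale = ifelse(sex == 1, 6, 11))
    cellp <- rdirichlet1(n, alpha = c(55, 17, 9, 5, 5, 8) * 1.2)
    colnames(cellp) <- c("neu", "cd4t", "cd8t", "bcell", "nk", "mono")
    pcs <- matrix(rnorm(n * config$n_tech_pcs), n, config$n_tech_pcs,
                  dimnames = list(NULL, paste0("pc_", seq_len(config$n_tech_pcs))))
    triglycerides <- exp(log(110) + 0.015 * (bmi - 25) + 0.003 * (age - 45) +
                           0.1 * smoking + rnorm(n, 0, 0.35))

    if (is.null(genotypes)) genotypes <- draw_genotypes(arch$snp$maf, n)
    stopifnot(nrow(genotypes) == config$n_snps, ncol(genotypes) == n)
    dos_complete <- genotypes
    if (config$dosage_missingness > 0) {
      miss <- matrix(runif(length(genotypes)) < config$dosage_missingness,
                     nrow(genotypes))
      genotypes[miss] <- NA_integer_
    }
    dimnames(genotypes) <- list(arch$snp$id, sample_id)

    # methylation: CpG-specific logit-normal with cell-type, technical and
    # cis-genetic structure; planted effects are added downstream of this so
    # beta-values always stay in (0, 1)
    cell_dev <- sweep(cellp, 2, colMeans(cellp))
    logit <- qlogis(arch$mu) +
      arch$cell_load %*% t(cell_dev) +
      arch$pc_load %*% t(pcs) +
      matrix(rnorm(config$n_cpgs * n, 0, config$methylation_logit_sd),
             config$n_cpgs, n)
    for (k in seq_len(nrow(arch$meqtl))) {
      j <- arch$planted$cpg_index[k]
      s <- arch$meqtl$snp_index[k]
      shift <- config$meqtl_effect / (arch$mu[j] * (1 - arch$mu[j]))
      logit[j, ] <- logit[j, ] + shift * dos_complete[s, ]
    }
    methylation <- plogis(logit)
    dimnames(methylation) <- list(arch$cpg$id, sample_id)

    zm <- function(j) {
      v <- methylation[j, ]
      (v - mean(v)) / sd(v)
    }

    # expression: mediation genes load on their CpG, all genes carry mild
    # covariate structure and unit residual noise
    expression <- matrix(rnorm(config$n_genes * n), config$n_genes, n,
                         dimnames = list(arch$gene$id, sample_id))
    cov_expr <- 0.01 * (age - 45) + 0.1 * sex + 0.02 * (bmi - 25) +
      0.1 * smoking + 0.004 * alcohol
    expression <- expression + matrix(rep(cov_expr, each = config$n_genes),
                                      config$n_genes, n)
    for (k in seq_len(nrow(arch$mediation))) {
      g <- arch$mediation$gene_index[k]
      j <- arch$mediation$cpg_index[k]
      expression[g, ] <- expression[g, ] + config$mediation_a * zm(j)
    }

    # planted methylation signal on the log-GGT scale
    slope <- arch$planted$base_slope * age_factor
    signal <- numeric(n)
    med_idx <- which(arch$planted$is_mediation)
    for (k in seq_len(nrow(arch$planted))) {
      j <- arch$planted$cpg_index[k]
      if (arch$planted$is_mediation[k]) {
        signal <- signal + config$mediation_c_direct * age_factor * zm(j)
      } else {
        signal <- signal + slope[k] * zm(j)
      }
    }
    med_term <- numeric(n)
    for (k in seq_len(nrow(arch$mediation))) {
      g <- arch$mediation$gene_index[k]
      med_term <- med_term + config$mediation_b * expression[g, ]
    }

    cov_ggt <- 0.006 * (age - 45) + 0.02 * (bmi - 25) - 0.15 * sex +
      0.2 * smoking + 0.004 * alcohol
    log_ggt <- log(25) + cov_ggt + signal + med_term + rnorm(n, 0, config$noise_sd)
    ggt <- exp(log_ggt)
    alt <- exp(log(22) + 0.004 * (age - 45) + 0.025 * (bmi - 25) - 0.2 * sex +
                 rnorm(n, 0, 0.45))
    ast <- exp(log(24) + 0.004 * (age - 45) + 0.012 * (bmi - 25) - 0.1 * sex +
                 rnorm(n, 0, 0.4))

    # steatosis risk from the same metabolic and methylation signal
    meth_signal <- signal
    for (k in med_idx) {
      j <- arch$planted$cpg_index[k]
      meth_signal <- meth_signal +
        config$mediation_a * config$mediation_b * zm(j)
    }
    linpred <- -2.4 + 0.13 * (bmi - 25) + 0.02 * (age - 45) - 0.3 * sex +
      0.25 * smoking + 1.2 * meth_signal
    steatosis <- rbinom(n, 1, plogis(linpred))

    covariates <- data.frame(sample_id = sample_id, age = age, sex = sex,
                             bmi = bmi, waist = waist,
                             triglycerides = triglycerides,
                             smoking = smoking, alcohol_gday = alcohol,
                             cellp, pcs, stringsAsFactors = FALSE)
    phenotypes <- data.frame(sample_id = sample_id, ggt = ggt, alt = alt,
                             ast = ast, steatosis = steatosis,
                             stringsAsFactors = FALSE)

    planted <- arch$planted
    planted$slope <- ifelse(planted$is_mediation,
                            config$mediation_c_direct * age_factor +
                              config$mediation_a * config$mediation_b,
                            planted$base_slope * age_factor)
    truth <- list(planted = planted,
                  meqtl = arch$meqtl,
                  mediation = arch$mediation,
                  outcome_scale = "log_ggt",
                  cohort_mean_age = cohort_mean_age,
                  age_factor = age_factor,
                  trios = NULL)

    structure(list(label = label, n = n,
                   methylation = methylation,
                   genotypes = genotypes,
                   expression = expression,
                   covariates = covariates,
                   phenotypes = phenotypes,
                   annotation = list(cpg = arch$cpg, snp = arch$snp,
                                     gene = arch$gene),
                   truth = truth),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort '", x$label, "': ", x$n, " samples\n", sep = "")
  cat("  ", nrow(x$methylation), " CpGs, ", nrow(x$genotypes), " SNPs, ",
      nrow(x$expression), " genes\n", sep = "")
  cat("  mean age ", round(x$truth$cohort_mean_age, 1),
      " y; ", nrow(x$truth$planted), " planted CpGs (",
      nrow(x$truth$mediation), " mediation triplets)\n", sep = "")
  invisible(x)
}

#' Generate three discovery cohorts
#'
#' Three cohorts under the shared architecture, differing in size only through
#' the config and in age structure: a younger cohort (33-50 y) and two older,
#' age-heterogeneous cohorts (39-88 y and 17-92 y), mirroring a typical
#' multi-cohort discovery setting.
#'
#' @param config A [cohort_config()].
#' @return Named list of three `sim_cohort` objects.
#' @export
simulate_discovery_cohorts <- function(config) {
  list(cohort_A = simulate_cohort(config, cohort_mean_age = 42,
                                  age_range = c(33, 50),
                                  seed = config$seed + 101L, label = "cohort_A"),
       cohort_B = simulate_cohort(config, cohort_mean_age = 63,
                                  age_range = c(39, 88),
                                  seed = config$seed + 102L, label = "cohort_B"),
       cohort_C = simulate_cohort(config, cohort_mean_age = 58,
                                  age_range = c(17, 92),
                                  seed = config$seed + 103L, label = "cohort_C"))
}

#' Generate a three-generation validation cohort set
#'
#' Produces grandparent (G0, 59-93 y), parent (G1, 43-58 y) and offspring
#' (G2, 6-36 y) cohorts under the shared architecture. Genotypes follow
#' Mendelian transmission: each G1 individual receives one allele from each of
#' two G0 parents, and each G2 individual from two G1 parents; the trio links
#' are recorded in `truth$trios` of the child cohorts. With a positive age
#' modulation the planted effect sizes are strictly ordered G0 > G1 > G2.
#'
#' @param config A [cohort_config()].
#' @return Named list with elements `G2`, `G1`, `G0` (young to old).
#' @export
simulate_three_generations <- function(config) {
  validate_cohort_config(config)
  arch <- cohort_architecture(config)
  n <- config$n_samples_per_cohort

  g0_geno <- with_seed(config$seed + 201L, draw_genotypes(arch$snp$maf, n))
  father <- seq_len(n)
  mother <- c(seq_len(n)[-1], 1L)
  g1_geno <- with_seed(config$seed + 202L, {
    t(vapply(seq_len(nrow(g0_geno)), function(s)
      transmit_allele(g0_geno[s, father]) + transmit_allele(g0_geno[s, mother]),
      integer(n)))
  })
  g2_geno <- with_seed(config$seed + 203L, {
    t(vapply(seq_len(nrow(g1_geno)), function(s)
      transmit_allele(g1_geno[s, father]) + transmit_allele(g1_geno[s, mother]),
      integer(n)))
  })

  g0 <- simulate_cohort(config, cohort_mean_age = 76, age_range = c(59, 93),
                        seed = config$seed + 211L, label = "G0",
                        genotypes = g0_geno)
  g1 <- simulate_cohort(config, cohort_mean_age = 50.5, age_range = c(43, 58),
                        seed = config$seed + 212L, label = "G1",
                        genotypes = g1_geno)
  g2 <- simulate_cohort(config, cohort_mean_age = 21, age_range = c(6, 36),
                        seed = config$seed + 213L, label = "G2",
                        genotypes = g2_geno)

  g1$truth$trios <- data.frame(child = colnames(g1$methylation),
                               father = colnames(g0$methylation)[father],
                               mother = colnames(g0$methylation)[mother],
                               stringsAsFactors = FALSE)
  g2$truth$trios <- data.frame(child = colnames(g2$methylation),
                               father = colnames(g1$methylation)[father],
                               mother = colnames(g1$methylation)[mother],
                               stringsAsFactors = FALSE)
  list(G2 = g2, G1 = g1, G0 = g0)
}

#' Check Mendelian consistency of child dosages against both parents
#'
#' A child dosage is consistent when it can be written as one allele
#' transmitted by each parent: for parental dosages f and m, the child dosage
#' must lie between `(f == 2) + (m == 2)` and `(f >= 1) + (m >= 1)`. Trios with
#' missing dosages at a variant are skipped at that variant.
#'
#' @param child,parents Either a child `sim_cohort` with `truth$trios` and the
#'   parent cohort, or plain dosage matrices (SNP x sample) with matching
#'   columns given via `father_idx`/`mother_idx`.
#' @param father_idx,mother_idx Column indices of each child's parents in
#'   `parents` (taken from `truth$trios` when cohorts are supplied).
#' @return Fraction of checkable (variant, trio) pairs that are consistent.
#' @export
mendelian_consistency <- function(child, parents,
                                  father_idx = NULL, mother_idx = NULL) {
  if (inherits(child, "sim_cohort")) {
    trios <- child$truth$trios
    if (is.null(trios)) stop("child cohort has no recorded trios")
    father_idx <- match(trios$father, colnames(parents$genotypes))
    mother_idx <- match(trios$mother, colnames(parents$genotypes))
    child_m <- child$genotypes
    parent_m <- parents$genotypes
  } else {
    child_m <- child
    parent_m <- parents
  }
  f <- parent_m[, father_idx, drop = FALSE]
  m <- parent_m[, mother_idx, drop = FALSE]
  lo <- (f == 2) + (m == 2)
  hi <- (f >= 1) + (m >= 1)
  ok <- child_m >= lo & child_m <= hi
  mean(ok, na.rm = TRUE)
}

#' Probe and sample quality-control filtering
#'
#' Removes samples whose call rate (fraction of probes detected at or below
#' the detection p-value threshold) falls below `call_rate_min`, then removes
#' probes whose fraction of failed samples (detection p above the threshold)
#' exceeds `max_failed_fraction`. The detection threshold defaults to 1e-15 (a
#' literal reading of the conventional "10e-16" filter; settable to 1e-16).
#'
#' @param beta CpG x sample matrix of beta-values.
#' @param detection_p Matrix of detection p-values, same shape as `beta`.
#' @param detection_threshold Probe detection p-value threshold.
#' @param call_rate_min Minimum per-sample call rate; samples below are removed.
#' @param max_failed_fraction Maximum tolerated fraction of failed samples per
#'   probe; probes above are removed.
#' @return List with the filtered `methylation` matrix, `removed_probes`,
#'   `removed_samples` and a `report` data.frame of counts per rule.
#' @export
apply_qc_filters <- function(beta, detection_p,
                             detection_threshold = 1e-15,
                             call_rate_min = 0.95,
                             max_failed_fraction = 0.01) {
  stopifnot(is.matrix(beta), is.matrix(detection_p),
            all(dim(beta) == dim(detection_p)))
  check_numeric(range(detection_p), "detection_p", lower = 0, upper = 1)

  call_rate <- colMeans(detection_p <= detection_threshold)
  bad_samples <- which(call_rate < call_rate_min)
  keep_s <- setdiff(seq_len(ncol(beta)), bad_samples)

  failed_frac <- rowMeans(detection_p[, keep_s, drop = FALSE] > detection_threshold)
  bad_probes <- which(failed_frac > max_failed_fraction)
  keep_p <- setdiff(seq_len(nrow(beta)), bad_probes)

  out <- beta[keep_p, keep_s, drop = FALSE]
  if (length(out) == 0)
    warning("all probes or samples removed by QC: result is empty")
  report <- data.frame(
    rule = c(sprintf("sample call rate < %g", call_rate_min),
             sprintf("probe failed fraction > %g (detection p > %g)",
                     max_failed_fraction, detection_threshold)),
    n_removed = c(length(bad_samples), length(bad_probes)))
  list(methylation = out,
       removed_samples = colnames(beta)[bad_samples] %||% bad_samples,
       removed_probes = rownames(beta)[bad_probes] %||% bad_probes,
       report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a minimal mediation dataset
#'
#' Draws the canonical linear mediation triple used for parameter-recovery
#' testing: exposure X (standard normal), mediator M = a X + covariate effects
#' + noise, outcome Y = c' X + b M + covariate effects + noise, with unit
#' residual SDs and age/sex/smoking/alcohol-category covariates.
#'
#' @param n Sample size.
#' @param a Exposure-to-mediator slope.
#' @param b Mediator-to-outcome slope.
#' @param c_direct Direct exposure-to-outcome slope.
#' @param seed Seed.
#' @return data.frame with `x`, `m`, `y` and the covariates.
#' @export
simulate_mediation_data <- function(n = 1500, a = 0.5, b = 0.4,
                                    c_direct = 0.3, seed = 1) {
  with_seed(seed, {
    age <- runif(n, 30, 60)
    sex <- rbinom(n, 1, 0.5)
    smoking <- rbinom(n, 1, 0.25)
    alc <- factor(sample(c("none", "up_to_one", "more_than_one"), n,
                         replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                  levels = c("none", "up_to_one", "more_than_one"))
    x <- rnorm(n)
    m <- a * x + 0.01 * (age - 45) + 0.1 * sex + 0.1 * smoking + rnorm(n)
    y <- c_direct * x + b * m + 0.02 * (age - 45) - 0.1 * sex +
      0.15 * smoking + 0.1 * (alc == "more_than_one") + rnorm(n)
    data.frame(x = x, m = m, y = y, age = age, sex = sex,
               smoking = smoking, alcohol_drinks_cat = alc)
  })
}
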