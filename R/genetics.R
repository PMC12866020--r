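#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts that are no more
#' probable than the observed one under the Hardy-Weinberg likelihood (the
#' standard exact test; no mid-p correction). Probabilities over the
#' heterozygote support are computed by the stable ratio recurrence.
#' Monomorphic variants return p = 1 by convention.
#'
#' @param n_aa Count of major-allele homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of minor-allele homozygotes.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  n_b <- n_ab + 2 * n_bb          # minor allele copies
  n_a <- n_ab + 2 * n_aa
  if (n_b == 0 || n_a == 0) return(1)
  rare <- min(n_a, n_b)
  # heterozygote support shares the parity of the rare allele count
  het_support <- seq(rare %% 2, rare, by = 2)
  # log-scale ratio recurrence (overflow-safe for large samples):
  # P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2)*(h+1)),
  # with hom_rare(h) = (rare - h)/2 and hom_common(h) = n - h - hom_rare(h)
  lp <- numeric(length(het_support))
  if (length(het_support) > 1) {
    for (i in seq_len(length(het_support) - 1)) {
      h <- het_support[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      lp[i + 1] <- lp[i] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, het_support)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele totals")
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Variant quality control
#'
#' Applies the genotype QC rules per variant: minor allele frequency at least
#' `maf_min`, exact Hardy-Weinberg p-value at least `hwe_min`, and missingness
#' strictly below `miss_max`. MAF and genotype counts are computed from
#' non-missing additive dosages.
#'
#' @param genotypes SNP x sample matrix of additive dosages in \{0, 1, 2\}
#'   with NA for missing.
#' @param maf_min Minimum minor allele frequency (default 0.02).
#' @param hwe_min Minimum Hardy-Weinberg exact p (default 1e-6).
#' @param miss_max Missingness threshold; variants with a missing fraction of
#'   `miss_max` or more fail (default 0.05, strict inequality to pass).
#' @return data.frame per variant: `snp_id`, `maf`, `hwe_p`, `missingness`,
#'   per-rule pass flags and overall `pass`; a per-rule failure-count summary
#'   is attached as attribute `report`.
#' @export
variant_qc <- function(genotypes, maf_min = 0.02, hwe_min = 1e-6,
                       miss_max = 0.05) {
  stopifnot(is.matrix(genotypes))
  ids <- rownames(genotypes) %||% sprintf("snp%05d", seq_len(nrow(genotypes)))
  res <- t(vapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    miss <- mean(is.na(g))
    g <- g[!is.na(g)]
    if (!length(g)) return(c(NA_real_, NA_real_, 1))
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    if (af > 0.5) cnt <- rev(cnt)
    c(maf, hwe_exact_test(cnt[1], cnt[2], cnt[3]), miss)
  }, numeric(3)))
  out <- data.frame(snp_id = ids, maf = res[, 1], hwe_p = res[, 2],
                    missingness = res[, 3], stringsAsFactors = FALSE)
  out$pass_maf <- !is.na(out$maf) & out$maf >= maf_min
  out$pass_hwe <- !is.na(out$hwe_p) & out$hwe_p >= hwe_min
  out$pass_missingness <- out$missingness < miss_max
  out$pass <- out$pass_maf & out$pass_hwe & out$pass_missingness
  attr(out, "report") <- data.frame(
    rule = c(sprintf("MAF < %g", maf_min), sprintf("HWE p < %g", hwe_min),
             sprintf("missingness >= %g", miss_max)),
    n_failed = c(sum(!out$pass_maf), sum(!out$pass_hwe),
                 sum(!out$pass_missingness)))
  out
}

#' cis-meQTL scan around one CpG
#'
#' Tests every QC-passed variant within the cis window (closed interval,
#' default +-1 Mb of the CpG position) by regressing the CpG's beta-values on
#' the additive dosage. By default no covariates enter the scan (configurable);
#' samples with missing dosage are dropped per variant. Variants reaching
#' genome-wide significance (`p < sig`) are flagged, and the top variant
#' (lowest p; ties broken by smaller distance, then id) is marked.
#'
#' @param cpg_beta Per-sample beta-values of the CpG.
#' @param cpg_pos 1-based position of the CpG.
#' @param genotypes SNP x sample dosage matrix.
#' @param snp_annotation data.frame with `id`, `pos` (1-based), rows matching
#'   `genotypes`.
#' @param window cis-window half-width in bp (default 1e6).
#' @param sig Genome-wide significance threshold (default 5e-8).
#' @param covariates Optional covariates to adjust the scan.
#' @return data.frame of `MeqtlRecord` rows: `snp_id`, `pos`, `distance`,
#'   `effect`, `se`, `p`, `significant`, `is_top`; empty (0 rows) when no
#'   variant lies in the window.
#' @export
cis_meqtl_scan <- function(cpg_beta, cpg_pos, genotypes, snp_annotation,
                           window = 1e6, sig = 5e-8, covariates = NULL) {
  stopifnot(nrow(genotypes) == nrow(snp_annotation))
  dist <- snp_annotation$pos - cpg_pos
  in_win <- which(abs(dist) <= window)
  if (!length(in_win))
    return(data.frame(snp_id = character(0), pos = integer(0),
                      distance = integer(0), effect = numeric(0),
                      se = numeric(0), p = numeric(0),
                      significant = logical(0), is_top = logical(0)))
  cmat <- as_covariate_matrix(covariates, n = length(cpg_beta))
  rows <- lapply(in_win, function(i) {
    g <- genotypes[i, ]
    keep <- !is.na(g) & !is.na(cpg_beta) & complete.cases(cmat)
    fit <- tryCatch(
      fit_cpg_model(cpg_beta[keep], g[keep],
                    if (ncol(cmat)) cmat[keep, , drop = FALSE] else NULL),
      error = function(e) list(effect = NA_real_, se = NA_real_, p = NA_real_))
    data.frame(snp_id = snp_annotation$id[i], pos = snp_annotation$pos[i],
               distance = dist[i], effect = fit$effect, se = fit$se,
               p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < sig
  out$is_top <- FALSE
  top <- select_top_variant(out, sig = sig)
  if (nrow(top)) out$is_top[out$snp_id == top$snp_id] <- TRUE
  out
}

#' Top-associating variant among significant meQTL records
#'
#' Returns the significant record with the lowest p-value; exact ties are
#' broken by smaller absolute distance to the CpG, then lexicographic variant
#' id. With no significant record an empty data.frame is returned.
#'
#' @param records meQTL record data.frame from [cis_meqtl_scan()].
#' @param sig Significance threshold applied before selection.
#' @return One-row data.frame (the top variant) or an empty data.frame.
#' @export
select_top_variant <- function(records, sig = 5e-8) {
  cand <- records[!is.na(records$p) & records$p < sig, , drop = FALSE]
  if (!nrow(cand)) {
    message("no variant reaches p < ", format(sig), "; no top variant selected")
    return(cand)
  }
  ord <- order(cand$p, abs(cand$distance), cand$snp_id)
  cand[ord[1], , drop = FALSE]
}

#' Conditional liver-phenotype model with and without the top variant
#'
#' Fits the two nested linear models on the identical complete-case sample:
#' `outcome ~ CpG + covariates` and `outcome ~ CpG + variant + covariates`,
#' and reports the CpG effect in both together with the variant's effect in
#' the joint model. This asks whether the discovered meQTL explains the
#' CpG-phenotype association: if the phenotype loads on the non-genetic part
#' of methylation, the CpG coefficient is insensitive to conditioning and the
#' variant shows no independent association.
#'
#' @param outcome Per-sample liver phenotype (typically INT-transformed).
#' @param cpg_beta Per-sample CpG beta-values.
#' @param snp_dosage Per-sample additive dosage of the top variant.
#' @param covariates Covariate data.frame or matrix.
#' @return List (`ConditionalResult`): `n`, `cpg_effect`/`cpg_se`/`cpg_p`
#'   (without variant), `cpg_effect_adj`/`cpg_se_adj`/`cpg_p_adj` (with
#'   variant), `snp_effect`/`snp_se`/`snp_p`, `collinear` flag.
#' @export
conditional_association <- function(outcome, cpg_beta, snp_dosage,
                                    covariates = NULL) {
  cmat <- as_covariate_matrix(covariates, n = length(outcome))
  keep <- complete.cases(outcome, cpg_beta, snp_dosage, cmat)
  y <- outcome[keep]; m <- cpg_beta[keep]; g <- snp_dosage[keep]
  cmat <- cmat[keep, , drop = FALSE]
  collinear <- abs(cor(m, g)) > 0.999
  if (collinear)
    warning("CpG and variant are nearly collinear; both models still fitted")
  base <- fit_cpg_model(y, m, cmat)
  joint_cov <- cbind(snp = g, cmat)
  adj <- fit_cpg_model(y, m, joint_cov)
  snp_fit <- fit_cpg_model(y, g, cbind(cpg = m, cmat))
  list(n = length(y),
       cpg_effect = base$effect, cpg_se = base$se, cpg_p = base$p,
       cpg_effect_adj = adj$effect, cpg_se_adj = adj$se, cpg_p_adj = adj$p,
       snp_effect = snp_fit$effect, snp_se = snp_fit$se, snp_p = snp_fit$p,
       collinear = collinear)
}
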