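#' eQTM scan: nearby-transcript expression on CpG methylation
#'
#' For every transcript whose start lies within the window (closed interval,
#' default +-100 kb) of the CpG, fits
#' `expression ~ methylation + age + sex + BMI + smoking + alcohol` (the
#' supplied covariates) and reports the methylation slope with its nominal
#' p-value. Pairs with nominal p below `screen_alpha` are flagged as
#' mediation candidates.
#'
#' @param cpg_beta Per-sample beta-values of the CpG.
#' @param cpg_pos 1-based position of the CpG.
#' @param expression Gene x sample expression matrix.
#' @param gene_annotation data.frame with `id`, `start`, rows matching
#'   `expression`.
#' @param covariates Covariate data.frame or matrix.
#' @param window Window half-width in bp (default 1e5).
#' @param screen_alpha Nominal screen threshold for mediation candidacy.
#' @return data.frame (`EqtmResult` rows): `gene_id`, `distance`, `effect`,
#'   `se`, `p`, `candidate`; empty when no transcript lies in the window.
#' @export
eqtm_scan <- function(cpg_beta, cpg_pos, expression, gene_annotation,
                      covariates = NULL, window = 1e5, screen_alpha = 0.05) {
  stopifnot(nrow(expression) == nrow(gene_annotation))
  dist <- gene_annotation$start - cpg_pos
  in_win <- which(abs(dist) <= window)
  if (!length(in_win))
    return(data.frame(gene_id = character(0), distance = integer(0),
                      effect = numeric(0), se = numeric(0), p = numeric(0),
                      candidate = logical(0)))
  rows <- lapply(in_win, function(g) {
    fit <- fit_cpg_model(expression[g, ], cpg_beta, covariates)
    data.frame(gene_id = gene_annotation$id[g], distance = dist[g],
               effect = fit$effect, se = fit$se, p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$candidate <- out$p < screen_alpha
  out
}

#' Delta-method standard error of a product of coefficients
#'
#' First-order Delta-method SE of the indirect effect
#' \eqn{\beta_1 \gamma_2}, treating the two coefficients as independent
#' (they come from separate regressions):
#' \eqn{SE = \sqrt{\gamma_2^2 Var(\beta_1) + \beta_1^2 Var(\gamma_2)}},
#' with a 95% CI of estimate +- 1.96 SE.
#'
#' @param beta1 Exposure-to-mediator coefficient.
#' @param var_beta1 Its sampling variance (non-negative).
#' @param gamma2 Mediator-to-outcome coefficient.
#' @param var_gamma2 Its sampling variance (non-negative).
#' @return List: `estimate`, `se`, `ci` (length-2).
#' @export
indirect_effect_delta <- function(beta1, var_beta1, gamma2, var_gamma2) {
  if (var_beta1 < 0 || var_gamma2 < 0) stop("variances must be non-negative")
  est <- beta1 * gamma2
  se <- sqrt(gamma2^2 * var_beta1 + beta1^2 * var_gamma2)
  list(estimate = est, se = se, ci = est + c(-1, 1) * qnorm(0.975) * se)
}

#' Proportion mediated with Delta-method inference
#'
#' The proportion mediated is the indirect effect divided by the total
#' effect, reported as a fraction. Its Delta-method SE uses the ratio
#' gradient (1/total, -indirect/total^2) applied to the joint covariance
#' of (indirect, total); the cross term defaults to zero. When the total
#' effect is too close to zero the ratio is unstable and the proportion is
#' reported as undefined with a reason instead of a number.
#'
#' @param indirect Indirect-effect estimate.
#' @param total Total-effect estimate.
#' @param var_indirect,var_total Sampling variances.
#' @param cov_indirect_total Covariance between the two (default 0).
#' @param min_total Minimum |total| tolerated (default 1e-8).
#' @return List: `estimate`, `se`, `ci`, `defined`, `reason`,
#'   `percent` (formatted).
#' @export
proportion_mediated <- function(indirect, total, var_indirect, var_total,
                                cov_indirect_total = 0, min_total = 1e-8) {
  if (var_indirect < 0 || var_total < 0) stop("variances must be non-negative")
  if (!is.finite(total) || abs(total) < min_total)
    return(list(estimate = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                defined = FALSE,
                reason = "total effect too close to zero: ratio unstable",
                percent = NA_character_))
  est <- indirect / total
  grad <- c(1 / total, -indirect / total^2)
  covm <- matrix(c(var_indirect, cov_indirect_total,
                   cov_indirect_total, var_total), 2, 2)
  se <- sqrt(drop(t(grad) %*% covm %*% grad))
  list(estimate = est, se = se,
       ci = est + c(-1, 1) * qnorm(0.975) * se,
       defined = TRUE, reason = NA_character_,
       percent = sprintf("%.0f%%", 100 * est))
}

#' Product-of-coefficients mediation of a methylation-phenotype association
#'
#' Decomposes the association between DNA methylation (exposure) and a liver
#' phenotype (outcome, typically inverse-normal transformed FLI) into a
#' direct and an expression-mediated component by fitting three ordinary
#' least-squares models on the identical complete-case rows:
#' \enumerate{
#'   \item `outcome ~ exposure + C` (total effect \eqn{\eta_1}),
#'   \item `outcome ~ exposure + mediator + C` (direct effect \eqn{\gamma_1},
#'     mediator effect \eqn{\gamma_2}),
#'   \item `mediator ~ exposure + C` (exposure-mediator effect \eqn{\beta_1}).
#' }
#' The indirect effect is the product \eqn{\beta_1\gamma_2} with a
#' Delta-method SE; for nested OLS fits sharing rows and covariates the
#' in-sample identity \eqn{\eta_1 = \gamma_1 + \beta_1\gamma_2} holds exactly.
#' Mediation is inferred when the 95% CI of the indirect effect excludes
#' zero; an inconsistent-sign flag is raised when direct and indirect effects
#' have opposite signs. The valid causal reading of the decomposition rests
#' on the usual exchangeability (no-unmeasured-confounding) conditions, which
#' are assumptions, not tested properties.
#'
#' @param outcome Per-sample outcome vector.
#' @param exposure Per-sample exposure (CpG beta-values).
#' @param mediator Per-sample mediator (transcript expression).
#' @param covariates Covariate data.frame or matrix (default mediation set:
#'   age, sex, smoking, three-level alcohol category).
#' @param stratum Optional stratum label stored in the result.
#' @return A `mediation_result` object; see [print.mediation_result()].
#' @export
fit_mediation <- function(outcome, exposure, mediator, covariates = NULL,
                          stratum = NA_character_) {
  n_in <- length(outcome)
  if (length(exposure) != n_in || length(mediator) != n_in)
    stop("outcome, exposure and mediator must have identical length: ",
         "the in-sample effect decomposition breaks otherwise")
  cmat <- as_covariate_matrix(covariates, n = n_in)
  keep <- complete.cases(outcome, exposure, mediator, cmat)
  y <- outcome[keep]; x <- exposure[keep]; m <- mediator[keep]
  cmat <- cmat[keep, , drop = FALSE]

  total <- fit_cpg_model(y, x, cmat)                       # eta1
  joint <- fit_cpg_model(y, x, cbind(mediator = m, cmat))  # gamma1
  gamma2 <- fit_cpg_model(y, m, cbind(exposure = x, cmat)) # gamma2
  apath <- fit_cpg_model(m, x, cmat)                       # beta1

  ind <- indirect_effect_delta(apath$effect, apath$se^2,
                               gamma2$effect, gamma2$se^2)
  prop <- proportion_mediated(ind$estimate, total$effect,
                              ind$se^2, total$se^2)
  mediated <- ind$ci[1] > 0 || ind$ci[2] < 0
  out <- list(n = length(y), stratum = stratum,
              total = c(estimate = total$effect, se = total$se, p = total$p),
              direct = c(estimate = joint$effect, se = joint$se, p = joint$p),
              beta1 = c(estimate = apath$effect, se = apath$se, p = apath$p),
              gamma2 = c(estimate = gamma2$effect, se = gamma2$se,
                         p = gamma2$p),
              indirect = c(estimate = ind$estimate, se = ind$se),
              indirect_ci = ind$ci,
              proportion_mediated = prop,
              mediated = mediated,
              inconsistent_sign = mediated &&
                sign(ind$estimate) != sign(joint$effect) &&
                joint$effect != 0)
  class(out) <- "mediation_result"
  out
}

#' Mediation decision from the indirect-effect confidence interval
#'
#' Mediation is inferred when the 95% CI of the indirect effect does not
#' include zero. The inconsistent-sign flag marks decompositions where direct
#' and indirect effects point in opposite directions (suggesting a more
#' complex mechanism than expression regulation by methylation).
#'
#' @param result A `mediation_result` from [fit_mediation()].
#' @return List: `decision` (`"mediated"`/`"not_mediated"`),
#'   `inconsistent_sign`.
#' @export
infer_mediation <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  list(decision = if (result$mediated) "mediated" else "not_mediated",
       inconsistent_sign = isTRUE(result$inconsistent_sign))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation decomposition (product of coefficients, Delta-method SEs)\n")
  if (!is.na(x$stratum)) cat("  stratum:", x$stratum, "\n")
  cat(sprintf("  n = %d\n", x$n))
  cat(sprintf("  total    effect: %+.4f (SE %.4f, p = %.3g)\n",
              x$total["estimate"], x$total["se"], x$total["p"]))
  cat(sprintf("  direct   effect: %+.4f (SE %.4f, p = %.3g)\n",
              x$direct["estimate"], x$direct["se"], x$direct["p"]))
  cat(sprintf("  indirect effect: %+.4f (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$indirect["estimate"], x$indirect["se"],
              x$indirect_ci[1], x$indirect_ci[2]))
  pm <- x$proportion_mediated
  if (isTRUE(pm$defined))
    cat(sprintf("  proportion mediated: %.3f (%s; SE %.3f)\n",
                pm$estimate, pm$percent, pm$se))
  else cat("  proportion mediated: undefined (", pm$reason, ")\n", sep = "")
  cat("  decision:", if (x$mediated) "mediated" else "not mediated")
  if (isTRUE(x$inconsistent_sign)) cat(" [direct and indirect signs differ]")
  cat("\n")
  invisible(x)
}

#' @export
coef.mediation_result <- function(object, ...) {
  c(total = unname(object$total["estimate"]),
    direct = unname(object$direct["estimate"]),
    indirect = unname(object$indirect["estimate"]),
    beta1 = unname(object$beta1["estimate"]),
    gamma2 = unname(object$gamma2["estimate"]))
}

#' @export
confint.mediation_result <- function(object, parm = "indirect", level = 0.95,
                                     ...) {
  q <- qnorm(1 - (1 - level) / 2)
  rows <- list(
    total = object$total["estimate"] + c(-1, 1) * q * object$total["se"],
    direct = object$direct["estimate"] + c(-1, 1) * q * object$direct["se"],
    indirect = object$indirect["estimate"] +
      c(-1, 1) * q * object$indirect["se"])
  out <- do.call(rbind, rows[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  out
}

#' Bootstrap standard errors for the mediation decomposition
#'
#' Nonparametric bootstrap (resampling rows) of the indirect effect and the
#' proportion mediated, as an empirical cross-check of the Delta-method SEs.
#'
#' @param outcome,exposure,mediator,covariates As in [fit_mediation()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed.
#' @return List: `se_indirect`, `se_proportion`, `replicates` (matrix).
#' @export
bootstrap_mediation_se <- function(outcome, exposure, mediator,
                                   covariates = NULL, n_boot = 1000,
                                   seed = 1) {
  cmat <- as_covariate_matrix(covariates, n = length(outcome))
  keep <- complete.cases(outcome, exposure, mediator, cmat)
  y <- outcome[keep]; x <- exposure[keep]; m <- mediator[keep]
  cmat <- cmat[keep, , drop = FALSE]
  n <- length(y)
  reps <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- fit_mediation(y[idx], x[idx], m[idx], cmat[idx, , drop = FALSE])
      c(indirect = unname(f$indirect["estimate"]),
        proportion = if (isTRUE(f$proportion_mediated$defined))
          f$proportion_mediated$estimate else NA_real_)
    }, numeric(2)))
  })
  list(se_indirect = sd(reps[, "indirect"]),
       se_proportion = sd(reps[, "proportion"], na.rm = TRUE),
       replicates = reps)
}

#' BMI-stratified mediation analysis
#'
#' Runs the full mediation decomposition separately within each stratum
#' (normal-weight vs overweight/obese when stratifying by [bmi_strata()]).
#' Strata below the minimum size are skipped with a warning.
#'
#' @param outcome,exposure,mediator,covariates As in [fit_mediation()].
#' @param strata Factor defining the strata.
#' @param min_n Minimum stratum size (default 100).
#' @return Named list of `mediation_result` objects.
#' @export
stratified_mediation <- function(outcome, exposure, mediator,
                                 covariates = NULL, strata, min_n = 100) {
  strata <- as.factor(strata)
  out <- list()
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    if (length(idx) < min_n) {
      warning("stratum '", lev, "' has n = ", length(idx), " < ", min_n,
              "; skipped")
      next
    }
    cov_s <- if (is.null(covariates)) NULL else {
      cs <- covariates[idx, , drop = FALSE]
      if (is.data.frame(cs)) cs[] <- lapply(cs, function(v)
        if (is.factor(v)) droplevels(v) else v)
      cs
    }
    out[[lev]] <- fit_mediation(outcome[idx], exposure[idx], mediator[idx],
                                cov_s, stratum = lev)
  }
  out
}
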