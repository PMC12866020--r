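#' Per-CpG association model
#'
#' Fits the single-CpG association model: outcome regressed on the CpG's
#' beta-values plus covariates by ordinary least squares. For binary outcomes
#' the same linear contract is applied to the 0/1 indicator (linear
#' probability model; the coefficient is then a methylation-scale group
#' difference), with a logistic alternative available via `link`.
#'
#' @param outcome Numeric outcome vector (continuous, or 0/1 when
#'   `binary = TRUE`).
#' @param cpg Numeric vector of beta-values for one CpG.
#' @param covariates Covariate data.frame or numeric matrix (no intercept
#'   column; factors are expanded to dummies).
#' @param binary Is the outcome a 0/1 indicator?
#' @param link For binary outcomes: `"linear"` (default) or `"logistic"`.
#' @return List with `effect`, `se`, `statistic`, `p`, `z`, `n`, `df`.
#' @export
fit_cpg_model <- function(outcome, cpg, covariates = NULL, binary = FALSE,
                          link = c("linear", "logistic")) {
  link <- match.arg(link)
  cmat <- as_covariate_matrix(covariates, n = length(outcome))
  keep <- complete.cases(outcome, cpg, cmat)
  y <- outcome[keep]
  x <- cpg[keep]
  cmat <- cmat[keep, , drop = FALSE]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, cpg = x, cmat)
  if (n <= ncol(X) + 2)
    stop("too few complete observations (", n, ") for ", ncol(X), " predictors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  if (binary && link == "logistic") {
    fit <- glm.fit(X, y, family = binomial())
    co <- fit$coefficients["cpg"]
    # observed-information SE from the weighted cross-product
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    se <- sqrt(diag(solve(XtWX)))[["cpg"]]
    z <- co / se
    return(list(effect = unname(co), se = se, statistic = unname(z),
                p = z_to_p(z), z = unname(z), n = n, df = NA_integer_))
  }
  fit <- lm.fit(X, y)
  co <- fit$coefficients[["cpg"]]
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))
  se <- sqrt(sigma2 * XtXinv_diag[2])
  tstat <- co / se
  p <- 2 * pt(-abs(tstat), df)
  list(effect = co, se = se, statistic = tstat, p = p,
       z = t_to_z(tstat, df), n = n, df = df)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the squared test statistics divided by the median
#' of the null \eqn{\chi^2_1} distribution. Equals 1 in expectation under the
#' null; values above 1 indicate systematic inflation.
#'
#' @param z Vector of z-statistics (or provide `p`).
#' @param p Two-sided p-values (used when `z` is missing).
#' @param min_tests Minimum number of tests required.
#' @return The inflation factor (positive scalar).
#' @export
genomic_inflation_lambda <- function(z = NULL, p = NULL, min_tests = 100) {
  if (is.null(z)) {
    if (is.null(p)) stop("supply z or p")
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  } else {
    chisq <- z^2
  }
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) < min_tests)
    stop("genomic_inflation_lambda needs at least ", min_tests, " tests")
  median(chisq) / qchisq(0.5, df = 1)
}

#' Empirical-null correction of z-statistics (bias and inflation)
#'
#' Estimates the empirical null distribution of a vector of z-statistics by
#' fitting a three-component Gaussian mixture (a central null component plus
#' two tail components for true associations) with a deterministic constrained
#' EM algorithm. The null component's mean is the bias and its SD the
#' inflation; corrected statistics are \eqn{(z - bias)/inflation} with
#' two-sided normal p-values.
#'
#' Identifiability of the central component is enforced by constraining the
#' tail-component means to lie at least `separation` null-SDs away from the
#' null mean. EM starts from (mean 0, SD 1, weight 0.9) with tail components
#' at +-3; additional seeded random restarts are run and the best penalised
#' solution kept.
#'
#' @param z Numeric vector of z-statistics (at least `min_tests`).
#' @param min_tests Floor on the number of tests (default 1000; estimation is
#'   unstable below).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param separation Minimum distance of tail means from the null mean, in
#'   null-SD units.
#' @param restarts Number of seeded random restarts in addition to the
#'   deterministic start.
#' @return An `empirical_null` object: `bias`, `inflation`, component
#'   parameters, `z_corrected`, `p_corrected`, `lambda_before`,
#'   `lambda_after`, `converged`.
#' @export
empirical_null_correct <- function(z, min_tests = 1000, max_iter = 2000,
                                   tol = 1e-9, separation = 2.5,
                                   restarts = 3) {
  z <- z[is.finite(z)]
  if (length(z) < min_tests)
    stop("empirical_null_correct needs at least ", min_tests,
         " finite statistics")
  inits <- list(list(mu = c(0, -3, 3), sd = c(1, 2, 2), w = c(0.9, 0.05, 0.05)))
  if (restarts > 0) {
    rinits <- with_seed(20260926, lapply(seq_len(restarts), function(i)
      list(mu = c(rnorm(1, 0, 0.2), -runif(1, 2, 5), runif(1, 2, 5)),
           sd = c(runif(1, 0.8, 1.5), 2, 2),
           w = c(0.9, 0.05, 0.05))))
    inits <- c(inits, rinits)
  }
  fits <- lapply(inits, function(init)
    em_mixture3(z, init, max_iter = max_iter, tol = tol,
                separation = separation))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- fits[[which.max(ll)]]
  if (!best$converged) {
    warning("empirical-null EM did not converge; returning raw statistics")
    out <- list(bias = 0, inflation = 1, weights = c(1, 0, 0),
                mu = c(0, NA, NA), sd = c(1, NA, NA),
                z_corrected = z, p_corrected = z_to_p(z),
                lambda_before = genomic_inflation_lambda(z),
                lambda_after = genomic_inflation_lambda(z),
                converged = FALSE, loglik = best$loglik)
    class(out) <- "empirical_null"
    return(out)
  }
  bias <- best$mu[1]
  inflation <- best$sd[1]
  zc <- (z - bias) / inflation
  out <- list(bias = bias, inflation = inflation, weights = best$w,
              mu = best$mu, sd = best$sd,
              z_corrected = zc, p_corrected = z_to_p(zc),
              lambda_before = genomic_inflation_lambda(z),
              lambda_after = genomic_inflation_lambda(zc),
              converged = TRUE, loglik = best$loglik)
  class(out) <- "empirical_null"
  out
}

# Constrained EM for the 3-component normal mixture; component 1 is the null.
em_mixture3 <- function(z, init, max_iter = 2000, tol = 1e-9, separation = 2.5) {
  n <- length(z)
  mu <- init$mu; sd_ <- init$sd; w <- init$w
  ll_old <- -Inf; converged <- FALSE; ll <- -Inf
  zmat <- matrix(z, n, 3)
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(z, mu[k], sd_[k]), numeric(n))
    tot <- rowSums(dens) + 1e-300
    resp <- dens / tot
    nk <- colSums(resp) + 1e-12
    w <- nk / n
    mu <- colSums(resp * z) / nk
    mu[2] <- min(mu[2], mu[1] - separation * sd_[1])
    mu[3] <- max(mu[3], mu[1] + separation * sd_[1])
    sd_ <- sqrt(pmax(colSums(resp * sweep(zmat, 2, mu)^2) / nk, 1e-4))
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(mu = mu, sd = sd_, w = w, loglik = ll, converged = converged,
       iterations = it)
}

#' @export
print.empirical_null <- function(x, ...) {
  cat("Empirical-null correction (3-component Gaussian mixture, EM)\n")
  cat(sprintf("  bias      : %+.4f\n", x$bias))
  cat(sprintf("  inflation : %.4f\n", x$inflation))
  cat(sprintf("  null weight %.3f; lambda %.3f -> %.3f; converged: %s\n",
              x$weights[1], x$lambda_before, x$lambda_after, x$converged))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' Validates that p-values lie in (0, 1]; missing values propagate.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same length and NA pattern as `p`.
#' @export
benjamini_hochberg <- function(p) {
  check_numeric(p, "p", lower = 0, upper = 1, strict_lower = TRUE,
                allow_na = TRUE)
  p.adjust(p, method = "BH")
}

#' Epigenome-wide association study for one cohort and outcome
#'
#' Runs the per-CpG association model across a methylation matrix, computes
#' the genomic inflation factor of the resulting z-statistics, applies the
#' empirical-null bias/inflation correction when inflation exceeds the trigger
#' threshold, and adjusts the final p-values by Benjamini-Hochberg FDR. For
#' binary outcomes the crude group difference in mean beta-values
#' (`delta_beta` = mean cases - mean controls, covariate-free by definition)
#' is reported per CpG.
#'
#' CpGs with zero variance (or otherwise unfittable models) are reported with
#' missing statistics rather than dropped.
#'
#' @param methylation CpG x sample matrix of beta-values.
#' @param outcome Per-sample outcome vector (continuous, typically
#'   inverse-normal transformed, or 0/1).
#' @param covariates Per-sample covariate data.frame or matrix.
#' @param binary Is the outcome binary?
#' @param link Binary-outcome link, see [fit_cpg_model()].
#' @param lambda_trigger Inflation threshold above which the empirical-null
#'   correction is applied (set `Inf` to disable, `0` to force).
#' @param min_cpgs Minimum number of CpGs for inflation estimation.
#' @param outcome_name Label stored in the result.
#' @return An `ewas_result`: `table` (one row per CpG: `cpg_id`, `effect`,
#'   `se`, `z`, `p`, `z_corrected`, `p_corrected`, `q`, `delta_beta`, `n`),
#'   `lambda_raw`, `lambda_corrected`, `bias`, `inflation`, `corrected`.
#' @export
run_ewas <- function(methylation, outcome, covariates = NULL, binary = FALSE,
                     link = c("linear", "logistic"), lambda_trigger = 1.1,
                     min_cpgs = 100, outcome_name = "outcome") {
  link <- match.arg(link)
  stopifnot(is.matrix(methylation), ncol(methylation) == length(outcome))
  if (nrow(methylation) < min_cpgs)
    stop("run_ewas needs at least ", min_cpgs, " CpGs")
  cmat <- as_covariate_matrix(covariates, n = length(outcome))

  complete <- complete.cases(outcome, cmat)
  use_fast <- !binary && all(complete) && !anyNA(methylation)
  if (use_fast) {
    res <- ewas_fast_linear(methylation, outcome, cmat)
  } else {
    res <- t(vapply(seq_len(nrow(methylation)), function(j) {
      fit <- tryCatch(
        fit_cpg_model(outcome, methylation[j, ], cmat, binary = binary,
                      link = link),
        error = function(e) list(effect = NA_real_, se = NA_real_,
                                 statistic = NA_real_, p = NA_real_,
                                 z = NA_real_, n = NA_integer_))
      c(fit$effect, fit$se, fit$z, fit$p, fit$n)
    }, numeric(5)))
    colnames(res) <- c("effect", "se", "z", "p", "n")
  }
  tab <- data.frame(cpg_id = rownames(methylation) %||%
                      sprintf("cpg%05d", seq_len(nrow(methylation))),
                    effect = res[, "effect"], se = res[, "se"],
                    z = res[, "z"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  ok <- is.finite(tab$z)

  lambda_raw <- genomic_inflation_lambda(tab$z[ok], min_tests = min(min_cpgs, 100))
  bias <- 0; inflation <- 1; corrected <- FALSE; null_fit <- NULL
  tab$z_corrected <- tab$z
  tab$p_corrected <- tab$p
  if (lambda_raw > lambda_trigger) {
    null_fit <- empirical_null_correct(tab$z[ok], min_tests = min(sum(ok), 1000))
    if (null_fit$converged) {
      corrected <- TRUE
      bias <- null_fit$bias
      inflation <- null_fit$inflation
      tab$z_corrected[ok] <- (tab$z[ok] - bias) / inflation
      tab$p_corrected[ok] <- z_to_p(tab$z_corrected[ok])
    }
  }
  tab$q <- NA_real_
  # extreme statistics can underflow p to 0; floor at the smallest double
  tab$q[ok] <- benjamini_hochberg(pmax(tab$p_corrected[ok], 5e-324))
  if (binary) {
    cases <- outcome == 1
    tab$delta_beta <- rowMeans(methylation[, cases & !is.na(outcome),
                                           drop = FALSE], na.rm = TRUE) -
      rowMeans(methylation[, !cases & !is.na(outcome), drop = FALSE],
               na.rm = TRUE)
  } else {
    tab$delta_beta <- NA_real_
  }
  tab$n <- if (use_fast) length(outcome) else res[, "n"]

  out <- list(table = tab,
              lambda_raw = lambda_raw,
              lambda_corrected = genomic_inflation_lambda(
                tab$z_corrected[ok], min_tests = min(min_cpgs, 100)),
              bias = bias, inflation = inflation, corrected = corrected,
              null_fit = null_fit, outcome = outcome_name, binary = binary,
              n = length(outcome))
  class(out) <- "ewas_result"
  out
}

# Fast path: Frisch-Waugh-Lovell. Residualise outcome and every CpG on the
# covariates once, then the per-CpG OLS slope, SE and t are exact single
# regressions on the residuals with df = n - (p_covariates + 2).
ewas_fast_linear <- function(methylation, outcome, cmat) {
  n <- length(outcome)
  X <- cbind(1, cmat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient covariate matrix")
  ry <- qr.resid(qrX, outcome)
  rm_ <- methylation - t(qr.fitted(qrX, t(methylation)))
  sxx <- rowSums(rm_^2)
  sxy <- as.vector(rm_ %*% ry)
  df <- n - ncol(X) - 1
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- sum(ry^2) - ifelse(sxx > 0, sxy^2 / sxx, 0)
  se <- sqrt((rss / df) / sxx)
  se[sxx == 0] <- NA_real_
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  cbind(effect = beta, se = se, z = t_to_z(tstat, df), p = p, n = n)
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("EWAS of '", x$outcome, "' (", if (x$binary) "binary" else "continuous",
      "): ", nrow(x$table), " CpGs, n = ", x$n, "\n", sep = "")
  cat(sprintf("  lambda %.3f%s", x$lambda_raw,
              if (x$corrected)
                sprintf(" -> %.3f after empirical-null correction (bias %+.3f, inflation %.3f)",
                        x$lambda_corrected, x$bias, x$inflation)
              else " (no correction applied)"))
  cat("\n  FDR-significant CpGs (q < 0.05):", sum(x$table$q < 0.05, na.rm = TRUE),
      "\n")
  invisible(x)
}

#' @export
summary.ewas_result <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  hits <- tab[!is.na(tab$q) & tab$q < alpha, ]
  hits <- hits[order(hits$p_corrected), ]
  structure(list(outcome = object$outcome, n = object$n,
                 n_cpgs = nrow(tab), lambda_raw = object$lambda_raw,
                 lambda_corrected = object$lambda_corrected,
                 corrected = object$corrected, alpha = alpha, hits = hits),
            class = "summary.ewas_result")
}

#' @export
print.summary.ewas_result <- function(x, ...) {
  cat("EWAS summary: ", x$outcome, ", ", x$n_cpgs, " CpGs, n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  lambda raw %.3f, final %.3f (corrected: %s)\n",
              x$lambda_raw, x$lambda_corrected, x$corrected))
  cat("  ", nrow(x$hits), " CpGs at FDR < ", x$alpha, "\n", sep = "")
  if (nrow(x$hits)) print(head(x$hits[, c("cpg_id", "effect", "se",
                                          "p_corrected", "q")], 10))
  invisible(x)
}

#' Stratified EWAS
#'
#' Runs [run_ewas()] independently within each level of a stratifying factor
#' (e.g. alcohol consumption class). Strata below the minimum size are skipped
#' with a warning.
#'
#' @param methylation CpG x sample beta-value matrix.
#' @param outcome Per-sample outcome.
#' @param covariates Per-sample covariates.
#' @param strata Factor (or vector) defining the strata.
#' @param min_n Minimum stratum size.
#' @param ... Passed to [run_ewas()].
#' @return Named list of `ewas_result` objects, one per retained stratum, each
#'   carrying `stratum`, stratum `n` and (for binary outcomes) case counts.
#' @export
stratified_ewas <- function(methylation, outcome, covariates, strata,
                            min_n = 50, ...) {
  strata <- as.factor(strata)
  out <- list()
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    if (length(idx) < min_n) {
      warning("stratum '", lev, "' has n = ", length(idx),
              " < ", min_n, "; skipped")
      next
    }
    cov_s <- if (is.null(covariates)) NULL else
      covariates[idx, , drop = FALSE]
    r <- run_ewas(methylation[, idx, drop = FALSE], outcome[idx], cov_s, ...)
    r$stratum <- lev
    r$stratum_n <- length(idx)
    if (r$binary) r$stratum_cases <- sum(outcome[idx] == 1, na.rm = TRUE)
    out[[lev]] <- r
  }
  out
}
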