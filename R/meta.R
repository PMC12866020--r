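#' Inverse-variance-weighted fixed-effect pooling for one CpG
#'
#' Pools per-cohort effects with weights \eqn{w_i = 1/SE_i^2}: pooled effect
#' \eqn{\sum w_i \beta_i / \sum w_i}, pooled SE \eqn{(\sum w_i)^{-1/2}},
#' Z = effect/SE with a two-sided normal p-value. Cohorts with missing effect
#' or SE contribute a `?` to the direction string and no weight.
#'
#' @param effects Per-cohort effect estimates (fixed cohort order).
#' @param ses Per-cohort standard errors (positive).
#' @return List: `effect`, `se`, `z`, `p`, `direction`, `n_cohorts`,
#'   plus heterogeneity diagnostics `Q` (Cochran) and `I2`.
#' @examples
#' ivw_meta(c(-0.006, -0.008, -0.014), c(0.001, 0.001, 0.001))
#' @export
ivw_meta <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  ok <- is.finite(effects) & is.finite(ses)
  if (any(ses[ok] <= 0)) stop("standard errors must be positive")
  if (sum(ok) < 2) stop("ivw_meta needs at least 2 cohorts with finite results")
  w <- 1 / ses[ok]^2
  eff <- sum(w * effects[ok]) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- eff / se
  q <- sum(w * (effects[ok] - eff)^2)
  dfq <- sum(ok) - 1
  i2 <- max(0, (q - dfq) / q) * 100
  dir <- ifelse(!is.finite(effects), "?", ifelse(effects >= 0, "+", "-"))
  list(effect = eff, se = se, z = z, p = z_to_p(z),
       direction = paste(dir, collapse = ""), n_cohorts = sum(ok),
       Q = q, I2 = if (q > 0) i2 else 0)
}

#' Fixed-effect meta-analysis across cohort EWAS results
#'
#' Pools per-CpG effects across cohorts by inverse-variance weighting,
#' restricted to CpGs tested in at least `min_cohorts` cohorts; computes the
#' meta Z, p and Benjamini-Hochberg FDR over the pooled p-vector, the
#' direction string (one sign per cohort, fixed input order), the count of
#' cohorts in which the CpG is cohort-level FDR-significant, and the
#' replication flag (significant in at least `min_cohorts` cohorts).
#'
#' @param results Named list of `ewas_result` objects (or their `table`
#'   data.frames) in a fixed, documented cohort order.
#' @param min_cohorts Minimum cohorts per CpG (default 2); also the
#'   replication threshold.
#' @param alpha Cohort-level FDR significance threshold (default 0.05).
#' @param same_direction Require identical effect signs across significant
#'   cohorts for replication (default `FALSE`).
#' @return A `meta_result` data.frame: `cpg_id`, per-cohort columns, pooled
#'   `effect`, `se`, `z`, `p`, `q`, `direction`, `Q`, `I2`,
#'   `cohorts_significant`, `replicated`.
#' @export
meta_analysis <- function(results, min_cohorts = 2, alpha = 0.05,
                          same_direction = FALSE) {
  tabs <- lapply(results, function(r)
    if (inherits(r, "ewas_result")) r$table else r)
  labels <- names(tabs) %||% paste0("cohort", seq_along(tabs))
  cpgs <- sort(unique(unlist(lapply(tabs, `[[`, "cpg_id"))))
  k <- length(tabs)

  eff <- se <- qv <- matrix(NA_real_, length(cpgs), k,
                            dimnames = list(cpgs, labels))
  for (i in seq_len(k)) {
    m <- match(cpgs, tabs[[i]]$cpg_id)
    eff[, i] <- tabs[[i]]$effect[m]
    se[, i] <- tabs[[i]]$se[m]
    qv[, i] <- tabs[[i]]$q[m]
  }
  tested <- rowSums(is.finite(eff) & is.finite(se))
  keep <- tested >= min_cohorts
  if (!any(keep)) stop("no CpG present in at least ", min_cohorts, " cohorts")

  pooled <- lapply(which(keep), function(j) ivw_meta(eff[j, ], se[j, ]))
  sig <- rowSums(qv < alpha, na.rm = TRUE)
  out <- data.frame(cpg_id = cpgs[keep],
                    effect = vapply(pooled, `[[`, numeric(1), "effect"),
                    se = vapply(pooled, `[[`, numeric(1), "se"),
                    z = vapply(pooled, `[[`, numeric(1), "z"),
                    p = vapply(pooled, `[[`, numeric(1), "p"),
                    direction = vapply(pooled, `[[`, character(1), "direction"),
                    Q = vapply(pooled, `[[`, numeric(1), "Q"),
                    I2 = vapply(pooled, `[[`, numeric(1), "I2"),
                    cohorts_significant = sig[keep],
                    stringsAsFactors = FALSE)
  out$q <- benjamini_hochberg(out$p)
  repl <- out$cohorts_significant >= min_cohorts
  if (same_direction) {
    consistent <- vapply(which(keep), function(j) {
      s <- sign(eff[j, ])[qv[j, ] < alpha & !is.na(qv[j, ])]
      length(unique(s[!is.na(s)])) <= 1
    }, logical(1))
    repl <- repl & consistent
  }
  out$replicated <- repl
  attr(out, "cohorts") <- labels
  attr(out, "min_cohorts") <- min_cohorts
  class(out) <- c("meta_result", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Inverse-variance fixed-effect meta-analysis over cohorts: ",
      paste(attr(x, "cohorts"), collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x), " CpGs pooled; ", sum(x$replicated),
      " replicated (FDR-significant in >= ", attr(x, "min_cohorts"),
      " cohorts)\n", sep = "")
  top <- x[order(x$p), c("cpg_id", "effect", "se", "z", "p", "q",
                         "direction", "replicated")]
  print(head(as.data.frame(top), 10), row.names = FALSE)
  invisible(x)
}

#' Multi-cohort replication filter
#'
#' Selects CpGs that are cohort-level FDR-significant (q below `alpha`) in at
#' least `k` cohorts. A CpG absent from a cohort's results counts as
#' non-significant there. Direction consistency is optional and off by
#' default.
#'
#' @param results Named list of `ewas_result` objects or their tables.
#' @param k Minimum number of significant cohorts (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @param same_direction Require identical signs in the significant cohorts.
#' @return Character vector of passing CpG ids, with the per-cohort logical
#'   significance pattern attached as attribute `pattern`.
#' @export
replication_filter <- function(results, k = 2, alpha = 0.05,
                               same_direction = FALSE) {
  tabs <- lapply(results, function(r)
    if (inherits(r, "ewas_result")) r$table else r)
  labels <- names(tabs) %||% paste0("cohort", seq_along(tabs))
  cpgs <- sort(unique(unlist(lapply(tabs, `[[`, "cpg_id"))))
  sig <- eff <- matrix(NA, length(cpgs), length(tabs),
                       dimnames = list(cpgs, labels))
  for (i in seq_along(tabs)) {
    m <- match(cpgs, tabs[[i]]$cpg_id)
    sig[, i] <- tabs[[i]]$q[m] < alpha
    eff[, i] <- tabs[[i]]$effect[m]
  }
  sig[is.na(sig)] <- FALSE
  pass <- rowSums(sig) >= k
  if (same_direction) {
    consistent <- vapply(seq_len(nrow(sig)), function(j) {
      s <- sign(eff[j, sig[j, ]])
      length(unique(s[!is.na(s)])) <= 1
    }, logical(1))
    pass <- pass & consistent
  }
  structure(cpgs[pass], pattern = sig)
}

#' Cross-generation association summary
#'
#' Juxtaposes per-CpG effects across generational cohorts ordered young to
#' old, and flags CpGs whose absolute effect increases monotonically with
#' cohort age. CpGs absent from one generation's results are emitted with
#' missing cells (and no trend call) rather than dropped.
#'
#' @param results Named list of `ewas_result` objects (or tables), ordered
#'   young to old.
#' @param mean_ages Cohort mean ages in the same order.
#' @param cpg_ids CpGs to summarise (default: union over generations).
#' @return data.frame with one row per CpG x generation (`cpg_id`,
#'   `generation`, `mean_age`, `effect`, `se`, `p`) plus a per-CpG
#'   `trend` column (`"monotone_with_age"` / `"non_monotone"`).
#' @export
cross_generation_summary <- function(results, mean_ages, cpg_ids = NULL) {
  stopifnot(length(results) == length(mean_ages))
  tabs <- lapply(results, function(r)
    if (inherits(r, "ewas_result")) r$table else r)
  labels <- names(tabs) %||% paste0("G", rev(seq_along(tabs)) - 1)
  ord <- order(mean_ages)
  if (is.null(cpg_ids))
    cpg_ids <- sort(unique(unlist(lapply(tabs, `[[`, "cpg_id"))))
  rows <- list()
  for (cg in cpg_ids) {
    effs <- numeric(0)
    for (i in ord) {
      m <- match(cg, tabs[[i]]$cpg_id)
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = cg, generation = labels[i], mean_age = mean_ages[i],
        effect = if (is.na(m)) NA_real_ else tabs[[i]]$effect[m],
        se = if (is.na(m)) NA_real_ else tabs[[i]]$se[m],
        p = if (is.na(m)) NA_real_ else tabs[[i]]$p_corrected[m] %||%
          tabs[[i]]$p[m],
        stringsAsFactors = FALSE)
      effs <- c(effs, abs(rows[[length(rows)]]$effect))
    }
    trend <- if (anyNA(effs)) NA_character_
      else if (all(diff(effs) > 0)) "monotone_with_age" else "non_monotone"
    for (j in seq_along(ord))
      rows[[length(rows) - length(ord) + j]]$trend <- trend
  }
  do.call(rbind, rows)
}
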