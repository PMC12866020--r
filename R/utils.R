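# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Scalar/vector numeric validation with a readable caller-side message.
check_numeric <- function(x, name, lower = -Inf, upper = Inf,
                          allow_na = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  bad_na <- is.na(x)
  if (!allow_na && any(bad_na))
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  ok <- x[!bad_na]
  low_viol <- if (strict_lower) ok <= lower else ok < lower
  if (any(low_viol) || any(ok > upper))
    stop(sprintf("'%s' must lie in %s%g, %g]", name,
                 if (strict_lower) "(" else "[", lower, upper), call. = FALSE)
  invisible(x)
}

# Two-sided normal p-value from a z statistic.
z_to_p <- function(z) 2 * pnorm(-abs(z))

# Convert a t statistic with df degrees of freedom into an equivalent z-score
# (sign-preserving, matched two-sided tail area). Guards qnorm(0) at extreme t.
t_to_z <- function(t, df) {
  logp <- pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * (-qnorm(logp, log.p = TRUE))
}

# Rowwise means/sds for matrices without apply() overhead.
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2) / (n - 1), 0))
}

# Build a numeric model matrix from a data.frame / matrix of covariates,
# coercing factors/characters to dummies and checking full column rank.
as_covariate_matrix <- function(covariates, n = NULL) {
  if (is.null(covariates)) {
    if (is.null(n)) stop("covariates or n required")
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    return(covariates)
  }
  if (!is.data.frame(covariates)) stop("covariates must be a matrix or data.frame")
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}
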