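test_that("per-CpG OLS recovers a noiseless construction exactly", {
  set.seed(11)
  n <- 80
  covs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  cpg <- runif(n, 0.2, 0.8)
  y <- 2 * cpg + covs %*% c(0.5, -1, 0.25) + 3
  fit <- fit_cpg_model(drop(y), cpg, covs)
  expect_equal(fit$effect, 2, tolerance = 1e-10)
  expect_lt(fit$se, 1e-10)
})

test_that("per-CpG OLS equals the normal-equations oracle", {
  set.seed(12)
  for (i in 1:10) {
    n <- 20; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    cpg <- rnorm(n)
    y <- rnorm(n)
    fit <- fit_cpg_model(y, cpg, X)
    oracle <- ols_oracle(y, cbind(cpg, X))
    expect_equal(fit$effect, unname(oracle[2]), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail loudly, naming the offending column", {
  set.seed(13)
  n <- 50
  covs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "dup")))
  covs[, "dup"] <- covs[, "a"]
  expect_error(fit_cpg_model(rnorm(n), rnorm(n), covs), "dup")
})

test_that("p-values are uniform under a permuted outcome", {
  set.seed(14)
  n <- 500; ncpg <- 2000
  meth <- matrix(rbeta(ncpg * n, 2, 2), ncpg, n)
  covs <- data.frame(age = runif(n, 30, 60), sex = rbinom(n, 1, 0.5))
  y <- sample(0.5 * covs$age + rnorm(n))   # permutation breaks all structure
  res <- run_ewas(meth, y, covs, lambda_trigger = Inf)
  ks <- suppressWarnings(stats::ks.test(res$table$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fast matrix EWAS agrees with the single-CpG fits", {
  ch <- fixture_cohort
  covs <- ch$covariates[, c("age", "sex", "bmi", "smoking")]
  res <- run_ewas(ch$methylation, ch$phenotypes$ggt_int, covs,
                  lambda_trigger = Inf)
  for (j in c(1, 57, 300)) {
    f <- fit_cpg_model(ch$phenotypes$ggt_int, ch$methylation[j, ], covs)
    expect_equal(res$table$effect[j], f$effect, tolerance = 1e-10)
    expect_equal(res$table$se[j], f$se, tolerance = 1e-10)
    expect_equal(res$table$p[j], f$p, tolerance = 1e-10)
  }
})

test_that("genomic inflation factor behaves as a median-based variance ratio", {
  set.seed(15)
  expect_lt(abs(genomic_inflation_lambda(rnorm(1e5)) - 1), 0.03)
  lam <- genomic_inflation_lambda(rnorm(1e5, sd = 1.2))
  expect_gt(lam, 1.38); expect_lt(lam, 1.50)
  z0 <- rep(sqrt(qchisq(0.5, 1)), 200)
  expect_equal(genomic_inflation_lambda(z0), 1, tolerance = 1e-12)
  expect_equal(genomic_inflation_lambda(rep(0.6745, 200)), 1, tolerance = 1e-3)
  expect_error(genomic_inflation_lambda(rnorm(50)), "at least")
  # p-value interface agrees with the z interface
  z <- rnorm(5000)
  expect_equal(genomic_inflation_lambda(p = 2 * pnorm(-abs(z))),
               genomic_inflation_lambda(z), tolerance = 1e-9)
})

test_that("empirical-null fit is calibrated on already-null statistics", {
  set.seed(16)
  z <- rnorm(1e4)
  fit <- empirical_null_correct(z)
  expect_true(fit$converged)
  expect_lt(abs(fit$bias), 0.05)
  expect_gt(fit$inflation, 0.95); expect_lt(fit$inflation, 1.05)
  # applying the correction twice is a near no-op
  fit2 <- empirical_null_correct(fit$z_corrected)
  expect_lt(abs(fit2$bias), 0.05)
  expect_lt(abs(fit2$inflation - 1), 0.05)
})

test_that("empirical-null correction rescales a shifted, inflated null", {
  set.seed(17)
  z <- rnorm(5000, mean = 0.3, sd = 1.5)
  fit <- empirical_null_correct(z)
  expect_lt(abs(fit$bias - 0.3), 0.1)
  expect_lt(abs(fit$inflation - 1.5), 0.1)
  expect_lt(abs(fit$lambda_after - 1), 0.1)
  expect_equal(fit$z_corrected, (z - fit$bias) / fit$inflation)
})

test_that("BH adjustment matches hand computation and validates input", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 0)), "p")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "p")
  p <- c(0.9, NA, 0.001)
  expect_true(is.na(benjamini_hochberg(p)[2]))
  set.seed(18)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("run_ewas survives constant CpGs and reports delta-beta for binary outcomes", {
  ch <- fixture_cohort
  meth <- ch$methylation
  meth[5, ] <- 0.4                       # zero-variance probe
  y <- ch$phenotypes$steatosis
  covs <- ch$covariates[, c("age", "sex", "bmi")]
  res <- run_ewas(meth, y, covs, binary = TRUE, lambda_trigger = Inf)
  expect_true(is.na(res$table$effect[5]))
  expect_true(all(is.finite(res$table$q[-5])))
  # delta-beta is the crude case-control mean difference, covariate-free
  j <- 10
  db <- mean(meth[j, y == 1]) - mean(meth[j, y == 0])
  expect_equal(res$table$delta_beta[j], db)
  res_nocov <- run_ewas(meth, y, NULL, binary = TRUE, lambda_trigger = Inf)
  expect_equal(res$table$delta_beta, res_nocov$table$delta_beta)
  # the subtraction convention: case mean 0.50 vs control mean 0.511
  meth2 <- meth
  meth2[1, ] <- ifelse(y == 1, 0.5, 0.511)
  res2 <- run_ewas(meth2, y, NULL, binary = TRUE, lambda_trigger = Inf)
  expect_equal(res2$table$delta_beta[1], -0.011, tolerance = 1e-12)
})

test_that("logistic scoring is available for binary outcomes", {
  ch <- fixture_cohort
  y <- ch$phenotypes$steatosis
  f <- fit_cpg_model(y, ch$methylation[1, ],
                     ch$covariates[, c("age", "bmi")], binary = TRUE,
                     link = "logistic")
  g <- glm(y ~ ch$methylation[1, ] + ch$covariates$age + ch$covariates$bmi,
           family = binomial())
  expect_equal(f$effect, unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("stratified EWAS isolates stratum-specific signal", {
  set.seed(19)
  n <- 600; ncpg <- 150
  meth <- matrix(rbeta(ncpg * n, 5, 5), ncpg, n,
                 dimnames = list(sprintf("cg%03d", 1:ncpg), NULL))
  strata <- rep(c("none", "excess"), each = n / 2)
  y <- rnorm(n)
  y[strata == "excess"] <- y[strata == "excess"] +
    8 * (meth[1, strata == "excess"] - 0.5)
  covs <- data.frame(age = runif(n, 30, 60))

  # constant stratifier reproduces the unstratified analysis
  one <- stratified_ewas(meth, y, covs, rep("all", n), lambda_trigger = Inf)
  whole <- run_ewas(meth, y, covs, lambda_trigger = Inf)
  expect_equal(one$all$table$p, whole$table$p)

  res <- stratified_ewas(meth, y, covs, strata, lambda_trigger = Inf)
  expect_lt(res$excess$table$q[1], 0.05)
  expect_gt(res$none$table$q[1], 0.05)
  expect_equal(res$excess$stratum_n, n / 2)

  expect_warning(
    stratified_ewas(meth, y, covs, c(rep("big", n - 5), rep("tiny", 5)),
                    min_n = 50, lambda_trigger = Inf),
    "tiny")
})
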