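test_that("eQTM scan honours the 100 kb window and screens candidates", {
  set.seed(41)
  n <- 800
  meth <- rbeta(n, 5, 5)
  ann <- data.frame(id = c("g_in", "g_edge", "g_out", "g_linked"),
                    start = c(1e6 - 5e4, 1e6 + 1e5, 1e6 + 1e5 + 1, 1e6 + 2e4),
                    stringsAsFactors = FALSE)
  expr <- matrix(rnorm(4 * n), 4, n, dimnames = list(ann$id, NULL))
  expr["g_linked", ] <- expr["g_linked", ] - 5 * meth
  covs <- data.frame(age = runif(n, 30, 60), sex = rbinom(n, 1, 0.5))
  sc <- eqtm_scan(meth, 1e6, expr, ann, covs)
  expect_setequal(sc$gene_id, c("g_in", "g_edge", "g_linked"))  # 100,001 bp out
  expect_true(sc$candidate[sc$gene_id == "g_linked"])
  expect_lt(sc$p[sc$gene_id == "g_linked"], 0.05)
  expect_equal(sc$effect[sc$gene_id == "g_linked"], -5, tolerance = 0.3)
  expect_equal(nrow(eqtm_scan(meth, 1e7, expr, ann, covs)), 0)
})

test_that("null eQTM candidate rate sits near the nominal screen level", {
  set.seed(42)
  n <- 500
  meth <- sample(rbeta(n, 5, 5))   # permuted: unrelated to all expression
  ngene <- 400
  ann <- data.frame(id = sprintf("g%03d", 1:ngene),
                    start = 1e6 + seq(-5e4, 5e4, length.out = ngene))
  expr <- matrix(rnorm(ngene * n), ngene, n, dimnames = list(ann$id, NULL))
  sc <- eqtm_scan(meth, 1e6, expr, ann, covariates = NULL)
  expect_gt(mean(sc$candidate), 0.02)
  expect_lt(mean(sc$candidate), 0.09)
})

test_that("a noiseless linear chain decomposes exactly", {
  set.seed(43)
  n <- 200
  covs <- data.frame(age = runif(n, 30, 60), sex = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  # mediator variation orthogonalised in-sample so every fit is exact
  w <- residuals(lm(rnorm(n) ~ x + covs$age + covs$sex))
  m <- 0.5 * x + 0.02 * covs$age + w
  y <- 0.3 * x + 0.4 * m - 0.01 * covs$age + 0.2 * covs$sex
  f <- fit_mediation(y, x, m, covs)
  expect_equal(unname(f$total["estimate"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(f$direct["estimate"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(f$indirect["estimate"]), 0.2, tolerance = 1e-10)
})

test_that("total = direct + indirect holds exactly for nested OLS fits", {
  for (seed in 1:5) {
    dat <- simulate_mediation_data(n = 300, seed = seed)
    f <- fit_mediation(dat$y, dat$x, dat$m,
                       dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
    expect_equal(unname(f$total["estimate"]),
                 unname(f$direct["estimate"] + f$indirect["estimate"]),
                 tolerance = 1e-10)
  }
})

test_that("a broken first path yields no indirect effect", {
  dat <- simulate_mediation_data(n = 2000, a = 0, b = 0.4, c_direct = 0.3,
                                 seed = 44)
  f <- fit_mediation(dat$y, dat$x, dat$m,
                     dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
  expect_false(f$mediated)
  expect_lt(abs(f$indirect["estimate"]), 0.05)
  expect_lt(abs(f$total["estimate"] - f$direct["estimate"]), 0.05)
})

test_that("moderate-noise parameter recovery lands within sampling error", {
  dat <- simulate_mediation_data(n = 1500, a = 0.5, b = 0.4, c_direct = 0.3,
                                 seed = 45)
  f <- fit_mediation(dat$y, dat$x, dat$m,
                     dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
  expect_lt(abs(f$indirect["estimate"] - 0.2), 3 * f$indirect["se"])
  expect_true(f$mediated)
  expect_equal(unname(f$beta1["estimate"]), 0.5, tolerance = 0.1)
  expect_equal(unname(f$gamma2["estimate"]), 0.4, tolerance = 0.1)
})

test_that("Delta-method SE of the product reduces and composes correctly", {
  r <- indirect_effect_delta(0, 0.04, 3, 0)
  expect_equal(r$se, 3 * sqrt(0.04))
  expect_equal(r$estimate, 0)
  r2 <- indirect_effect_delta(0.5, 0.01, 0.4, 0.01)
  expect_equal(r2$se, 0.0640312423743285, tolerance = 1e-12)
  expect_equal(r2$ci, 0.2 + c(-1, 1) * qnorm(0.975) * r2$se)
  expect_error(indirect_effect_delta(0.5, -0.01, 0.4, 0.01), "non-negative")
})

test_that("proportion mediated is a guarded Delta-method ratio", {
  r <- proportion_mediated(0.1, 0.2, 0, 0)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0)
  expect_equal(r$percent, "50%")
  u <- proportion_mediated(0.1, 1e-12, 0.01, 0.01)
  expect_false(u$defined)
  expect_match(u$reason, "unstable")
  # gradient formula against a hand-computed case
  v <- proportion_mediated(0.2, 0.5, 0.01, 0.02)
  grad <- c(1 / 0.5, -0.2 / 0.25)
  expect_equal(v$se, sqrt(grad[1]^2 * 0.01 + grad[2]^2 * 0.02))
})

test_that("mediation is inferred from the indirect-effect CI, with sign flag", {
  dat <- simulate_mediation_data(n = 1500, a = 0.5, b = 0.4, c_direct = 0.3,
                                 seed = 46)
  f <- fit_mediation(dat$y, dat$x, dat$m,
                     dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
  d <- infer_mediation(f)
  expect_equal(d$decision, "mediated")
  expect_false(d$inconsistent_sign)

  # opposing direct and indirect paths raise the inconsistent-sign flag
  dat2 <- simulate_mediation_data(n = 3000, a = 0.5, b = 0.4, c_direct = -0.6,
                                  seed = 47)
  f2 <- fit_mediation(dat2$y, dat2$x, dat2$m,
                      dat2[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
  d2 <- infer_mediation(f2)
  expect_equal(d2$decision, "mediated")
  expect_true(d2$inconsistent_sign)
})

test_that("the mediation decision is invariant to standardised rescaling", {
  dat <- simulate_mediation_data(n = 1500, seed = 48)
  covs <- dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")]
  f1 <- fit_mediation(dat$y, scale(dat$x)[, 1], scale(dat$m)[, 1], covs)
  f2 <- fit_mediation(dat$y, scale(dat$x * 100)[, 1], scale(dat$m / 7)[, 1],
                      covs)
  expect_equal(f1$mediated, f2$mediated)
  expect_equal(unname(f1$indirect["estimate"]),
               unname(f2$indirect["estimate"]), tolerance = 1e-10)
})

test_that("stratified mediation isolates the stratum carrying the effect", {
  set.seed(49)
  over <- simulate_mediation_data(n = 686, a = 0.5, b = 0.4, c_direct = 0.3,
                                  seed = 50)
  normal <- simulate_mediation_data(n = 524, a = 0, b = 0, c_direct = 0.3,
                                    seed = 51)
  dat <- rbind(normal, over)
  strata <- factor(rep(c("normal_weight", "overweight_obese"),
                       c(nrow(normal), nrow(over))))
  res <- stratified_mediation(dat$y, dat$x, dat$m,
                              dat[, c("age", "sex", "smoking",
                                      "alcohol_drinks_cat")], strata)
  expect_named(res, c("normal_weight", "overweight_obese"))
  expect_false(res$normal_weight$mediated)
  expect_true(res$overweight_obese$mediated)
  expect_equal(res$overweight_obese$n, 686)
  expect_warning(
    stratified_mediation(dat$y, dat$x, dat$m, NULL,
                         factor(rep(c("a", "b"), c(nrow(dat) - 20, 20)))),
    "skipped")
})

test_that("row mismatches across the three models are a hard error", {
  dat <- simulate_mediation_data(n = 100, seed = 52)
  expect_error(fit_mediation(dat$y[-1], dat$x, dat$m), "identical length")
})
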