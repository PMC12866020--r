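test_that("inverse-variance pooling evaluates the closed-form formulas", {
  r <- ivw_meta(c(-0.006, -0.008, -0.014), c(0.001, 0.001, 0.001))
  expect_equal(r$effect, -0.00933333333333333, tolerance = 1e-12)
  expect_equal(r$se, 0.001 / sqrt(3), tolerance = 1e-15)
  expect_equal(r$direction, "---")
  # equal SEs reduce to the arithmetic mean, exactly
  expect_equal(ivw_meta(c(1, 2, 6), rep(0.3, 3))$effect, 3)
  # sign string follows cohort order
  expect_equal(ivw_meta(c(0.2, -0.1, -0.3), c(0.1, 0.1, 0.1))$direction, "+--")
  expect_equal(ivw_meta(c(0.2, NA, -0.3), c(0.1, 0.1, 0.1))$direction, "+?-")
  expect_error(ivw_meta(c(1, 2), c(0.1, -0.1)), "positive")
  expect_error(ivw_meta(c(1, NA), c(0.1, 0.1)), "at least 2")
})

test_that("pooled estimate matches a weighted-least-squares oracle", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    eff <- rnorm(k)
    se <- runif(k, 0.05, 0.5)
    r <- ivw_meta(eff, se)
    wls <- lm(eff ~ 1, weights = 1 / se^2)
    expect_equal(r$effect, unname(coef(wls)[1]), tolerance = 1e-12)
    # pooled SE below the best single cohort and decreasing as cohorts add
    expect_lte(r$se, min(se))
    if (k > 2) expect_lt(r$se, ivw_meta(eff[-1], se[-1])$se)
  }
})

make_tabs <- function(qmat, effmat = NULL) {
  ncpg <- nrow(qmat)
  lapply(seq_len(ncol(qmat)), function(i) {
    data.frame(cpg_id = sprintf("cg%02d", seq_len(ncpg)),
               effect = if (is.null(effmat)) rep(-0.01, ncpg) else effmat[, i],
               se = 0.002, p = qmat[, i], q = qmat[, i],
               stringsAsFactors = FALSE)
  })
}

test_that("replication filter counts FDR-significant cohorts", {
  q <- rbind(c(0.01, 0.04, 0.9),   # passes: 2 of 3
             c(0.01, 0.9, 0.9))    # fails
  got <- replication_filter(make_tabs(q))
  expect_equal(as.character(got), "cg01")

  # 10-CpG fixture with a planted pattern: exactly the 4 planted CpGs pass
  set.seed(22)
  qmat <- matrix(0.5, 10, 3)
  planted <- c(2, 3, 7, 10)
  for (j in planted) qmat[j, sample(3, 2)] <- 0.01
  qmat[5, 1] <- 0.01   # one cohort only: must not pass
  got <- replication_filter(make_tabs(qmat))
  expect_setequal(as.character(got), sprintf("cg%02d", planted))

  # invariant to cohort ordering
  tabs <- make_tabs(qmat)
  expect_setequal(as.character(replication_filter(tabs[c(3, 1, 2)])),
                  as.character(got))

  # optional same-direction requirement
  eff <- matrix(c(0.01, 0.01, -0.01), 1, 3)
  qd <- matrix(c(0.01, 0.01, 0.01), 1, 3)
  expect_length(replication_filter(make_tabs(qd, eff), same_direction = TRUE), 0)
  expect_length(replication_filter(make_tabs(qd, abs(eff)),
                                   same_direction = TRUE), 1)
})

test_that("meta-analysis table pools, adjusts and flags replication", {
  set.seed(23)
  ncpg <- 60
  qmat <- matrix(runif(ncpg * 3, 0.2, 1), ncpg, 3)
  qmat[1:4, 1:2] <- 0.001
  effmat <- matrix(rnorm(ncpg * 3, sd = 0.01), ncpg, 3)
  tabs <- make_tabs(qmat, effmat)
  names(tabs) <- c("A", "B", "C")
  m <- meta_analysis(tabs)
  expect_s3_class(m, "meta_result")
  expect_equal(nrow(m), ncpg)
  expect_true(all(m$replicated[1:4]))
  expect_false(any(m$replicated[-(1:4)]))
  expect_equal(nchar(m$direction[1]), 3)
  expect_equal(m$q, benjamini_hochberg(m$p))
  j <- 7
  expect_equal(m$effect[m$cpg_id == sprintf("cg%02d", j)],
               ivw_meta(effmat[j, ], rep(0.002, 3))$effect)
  # a CpG absent from one cohort still pools over the remaining two
  tabs2 <- tabs
  tabs2$C <- tabs2$C[-1, ]
  m2 <- meta_analysis(tabs2)
  expect_equal(m2$direction[m2$cpg_id == "cg01"],
               paste0(ifelse(effmat[1, 1] >= 0, "+", "-"),
                      ifelse(effmat[1, 2] >= 0, "+", "-"), "?"))
})

test_that("cross-generation summary flags age-monotone effects", {
  tabs <- list(
    G2 = data.frame(cpg_id = c("cgA", "cgB"), effect = c(0.01, 0.05),
                    se = 0.01, p = c(0.5, 0.01), stringsAsFactors = FALSE),
    G1 = data.frame(cpg_id = c("cgA", "cgB"), effect = c(-0.03, 0.02),
                    se = 0.01, p = c(0.01, 0.1), stringsAsFactors = FALSE),
    G0 = data.frame(cpg_id = c("cgA"), effect = c(-0.08),
                    se = 0.01, p = c(0.001), stringsAsFactors = FALSE))
  out <- cross_generation_summary(tabs, mean_ages = c(21, 50, 76))
  a <- out[out$cpg_id == "cgA", ]
  expect_equal(a$trend, rep("monotone_with_age", 3))
  expect_equal(a$generation, c("G2", "G1", "G0"))  # ordered young to old
  b <- out[out$cpg_id == "cgB", ]
  expect_equal(nrow(b), 3)                          # row emitted despite absence
  expect_true(is.na(b$effect[b$generation == "G0"]))
  expect_true(all(is.na(b$trend)))
})

test_that("planted age modulation produces monotone trends in generator truth", {
  gens <- simulate_three_generations(small_config(age_modulation = 1.5))
  tr <- gens$G1$truth$planted
  tabs <- lapply(gens, function(g)
    data.frame(cpg_id = g$truth$planted$cpg_id,
               effect = g$truth$planted$slope,
               se = 0.01, p = 0.5, stringsAsFactors = FALSE))
  out <- cross_generation_summary(tabs,
                                  mean_ages = vapply(gens, function(g)
                                    g$truth$cohort_mean_age, numeric(1)))
  expect_true(all(out$trend == "monotone_with_age"))
})
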