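test_that("HWE exact test agrees with exhaustive enumeration", {
  # small table checked against the direct combinatorial formula
  expect_equal(hwe_exact_test(5, 1, 5), hwe_oracle(5, 1, 5), tolerance = 1e-12)
  # the modal heterozygote configuration has p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  # monomorphic variants return 1 by convention
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 77), 1)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    nb <- sample(0:n, 1)
    nbb <- sample(0:floor(nb / 2), 1)
    nab <- nb - 2 * nbb
    naa <- n - nab - nbb
    expect_equal(hwe_exact_test(naa, nab, nbb), hwe_oracle(naa, nab, nbb),
                 tolerance = 1e-12)
  }
})

test_that("variant QC applies the printed thresholds with their boundary conventions", {
  set.seed(32)
  n <- 1000
  geno <- rbind(
    common  = rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3),
    rare    = c(rep(1, 38), rep(0, n - 38)),            # MAF 0.019 < 0.02
    missing = c(rep(NA, 50), rbinom(n - 50, 1, 0.25) +
                  rbinom(n - 50, 1, 0.25)),             # missingness exactly 0.05
    badhwe  = c(rep(0, 700), rep(2, 300)))              # no hets at all
  qc <- variant_qc(geno)
  row <- function(id) qc[qc$snp_id == id, ]
  expect_true(row("common")$pass)
  # the rare variant fails on MAF alone
  expect_false(row("rare")$pass_maf)
  expect_true(row("rare")$pass_missingness)
  expect_false(row("missing")$pass_missingness)   # "less than 5%" is strict
  expect_false(row("badhwe")$pass_hwe)
  expect_equal(attr(qc, "report")$n_failed[1], 1)

  # all-pass toy set
  toy <- t(vapply(1:5, function(i) rbinom(500, 1, 0.4) + rbinom(500, 1, 0.4),
                  integer(500)))
  qct <- variant_qc(toy)
  expect_true(all(qct$pass))
  expect_equal(sum(attr(qct, "report")$n_failed), 0)

  # raising the MAF threshold never enlarges the pass set
  loose <- variant_qc(geno, maf_min = 0.01)$pass
  tight <- variant_qc(geno, maf_min = 0.1)$pass
  expect_true(all(!tight | loose))
})

test_that("cis-meQTL scan honours the closed window and detects planted effects", {
  set.seed(33)
  n <- 1500
  ann <- data.frame(id = c("s_in", "s_edge", "s_out", "s_causal"),
                    pos = c(5e5, 2e6, 2e6 + 1, 1.2e6),  # CpG at 1e6
                    stringsAsFactors = FALSE)
  geno <- t(vapply(1:4, function(i) rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3),
                   integer(n)))
  rownames(geno) <- ann$id
  beta <- 0.5 + 0.05 * geno["s_causal", ] + rnorm(n, 0, 0.04)
  scan <- cis_meqtl_scan(beta, 1e6, geno, ann, window = 1e6)
  expect_setequal(scan$snp_id, c("s_in", "s_edge", "s_causal"))  # edge included
  expect_true(scan$significant[scan$snp_id == "s_causal"])
  expect_lt(scan$p[scan$snp_id == "s_causal"], 5e-8)
  expect_true(scan$is_top[scan$snp_id == "s_causal"])
  expect_lt(abs(scan$effect[scan$snp_id == "s_causal"] - 0.05), 0.01)

  # results invariant to variant input order
  ord <- c(3, 1, 4, 2)
  scan2 <- cis_meqtl_scan(beta, 1e6, geno[ord, ], ann[ord, ], window = 1e6)
  expect_equal(scan2[order(scan2$snp_id), c("effect", "p")],
               scan[order(scan$snp_id), c("effect", "p")],
               ignore_attr = TRUE)

  # empty window is an empty result, not an error
  empty <- cis_meqtl_scan(beta, 1e6, geno, ann, window = 10)
  expect_equal(nrow(empty), 0)
})

test_that("null variants do not reach genome-wide significance in excess", {
  set.seed(34)
  n <- 400
  geno <- t(vapply(1:1000, function(i) rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3),
                   integer(n)))
  rownames(geno) <- sprintf("s%04d", 1:1000)
  ann <- data.frame(id = rownames(geno), pos = seq_len(1000) * 100)
  beta <- rbeta(n, 5, 5)
  scan <- cis_meqtl_scan(beta, 5e4, geno, ann, window = 1e6)
  expect_equal(sum(scan$significant), 0)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("top-variant selection uses the documented tie-breaks", {
  rec <- data.frame(snp_id = c("b", "a", "c"), pos = 1:3,
                    distance = c(500, 50000, 100),
                    effect = 0.1, se = 0.01,
                    p = c(1e-9, 1e-12, 2e-8), stringsAsFactors = FALSE)
  expect_equal(select_top_variant(rec)$snp_id, "a")
  rec$p <- c(1e-10, 1e-10, 2e-8)
  expect_equal(select_top_variant(rec)$snp_id, "b")   # smaller |distance| wins
  rec$distance <- c(500, 500, 100)
  expect_equal(select_top_variant(rec)$snp_id, "a")   # then lexicographic id
  expect_message(out <- select_top_variant(rec[rec$p > 1e-5, ]), "no variant")
  expect_equal(nrow(out), 0)
  expect_equal(select_top_variant(rec[1, ])$snp_id, rec$snp_id[1])
})

test_that("conditional models distinguish meQTL-driven from confounded patterns", {
  set.seed(35)
  n <- 5000
  g <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  covs <- data.frame(age = runif(n, 30, 60))

  # phenotype driven by methylation itself (SNP acts only through the CpG):
  # CpG stays significant, the SNP shows no independent association
  m1 <- 0.5 + 0.05 * g + rnorm(n, 0, 0.05)
  y1 <- 3 * m1 + 0.01 * covs$age + rnorm(n)
  r1 <- conditional_association(y1, m1, g, covs)
  expect_lt(r1$cpg_p, 1e-10); expect_lt(r1$cpg_p_adj, 1e-10)
  expect_gt(r1$snp_p, 0.05)
  expect_lt(abs(r1$cpg_effect_adj - r1$cpg_effect) / abs(r1$cpg_effect), 0.1)

  # the SNP drives both methylation and phenotype directly:
  # conditioning attenuates the CpG effect towards zero
  m2 <- 0.5 + 0.05 * g + rnorm(n, 0, 0.05)
  y2 <- 0.5 * g + 0.01 * covs$age + rnorm(n)
  r2 <- conditional_association(y2, m2, g, covs)
  expect_lt(abs(r2$cpg_effect_adj), abs(r2$cpg_effect) * 0.5)

  # an irrelevant SNP leaves the CpG effect essentially unchanged
  g3 <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  r3 <- conditional_association(y1, m1, g3, covs)
  expect_lt(abs(r3$cpg_effect_adj - r3$cpg_effect), 0.05)
})
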