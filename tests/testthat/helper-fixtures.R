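# Shared fixtures: one small cohort configuration reused across test files.
# Sizes are kept small enough that the whole suite stays fast while the
# planted structure (effects, meQTLs, mediation triplets) remains detectable.

small_config <- function(seed = 7, ...) {
  cohort_config(n_samples_per_cohort = 400, n_cpgs = 300, n_true_cpgs = 8,
                n_snps = 40, n_genes = 20, n_mediation = 3, seed = seed, ...)
}

null_config <- function(seed = 1, n = 500, n_cpgs = 500) {
  cohort_config(n_samples_per_cohort = n, n_cpgs = n_cpgs, n_true_cpgs = 0,
                n_snps = 10, n_genes = 5, n_mediation = 0,
                effect_size_base = 0, mediation_a = 0, mediation_b = 0,
                mediation_c_direct = 0, seed = seed)
}

# one small cohort, built once per test run
fixture_cohort <- derive_phenotypes(simulate_cohort(small_config(), seed = 42,
                                                    label = "fix"))

# independent normal-equations solver used as the OLS oracle
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# independent brute-force Benjamini-Hochberg (step-up with cumulative min)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# independent exact Hardy-Weinberg enumeration via log-factorials
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- n_ab + 2 * n_bb
  na <- n_ab + 2 * n_aa
  if (nb == 0 || na == 0) return(1)
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
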