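# Fixture builders shared across tests. Everything is generated in code.

# A minimal valid variant record table.
make_variants <- function(n, ids = sprintf("rs%03d", seq_len(n)),
                          chrom = rep("1", n), pos = seq_len(n) * 2.1e7,
                          ea = rep("A", n), oa = rep("G", n),
                          eaf = rep(0.3, n), beta = rep(0.1, n),
                          se = rep(0.01, n), pval = rep(1e-10, n),
                          n_sample = rep(50000, n)) {
  tibble::tibble(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n_sample
  )
}

# A harmonized set built directly from effect arrays (bypasses allele
# bookkeeping for estimator tests).
make_harmonized <- function(bx, by, sey, sex = rep(0.01, length(bx)),
                            ids = sprintf("rs%03d", seq_along(bx))) {
  h <- tibble::tibble(
    variant_id = ids,
    effect_allele = "A", other_allele = "G",
    chrom = "1", pos = seq_along(bx) * 2.1e7,
    eaf_exposure = 0.3, beta_exposure = bx, se_exposure = sex,
    eaf_outcome = 0.3, beta_outcome = by, se_outcome = sey,
    action = "kept"
  )
  class(h) <- c("mr_harmonized", class(h))
  h
}

# Thresholds used when analysing simulated studies: the outcome-association
# screen is off because, with equal-powered simulated GWAS and a strong true
# total effect, it would remove the valid instruments themselves.
sim_thresholds <- function() instrument_thresholds(p_outcome = 0)

expect_rel_equal <- function(actual, expected, tol = 1e-10) {
  expect_lt(abs(actual - expected) / max(1e-12, abs(expected)), tol)
}
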