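# Reading, validation and allele harmonization.

test_that("TSV round trip preserves well-formed records and uppercases alleles", {
  x <- make_variants(3, ea = c("a", "C", "g"), oa = c("g", "T", "a"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  got <- read_summary_stats(path, dialect = mrpath_dialect())
  expect_equal(nrow(got), 3)
  expect_equal(nrow(attr(got, "rejects")), 0)
  expect_equal(got$effect_allele, c("A", "C", "G"))
  expect_equal(got$other_allele, c("G", "T", "A"))
  expect_equal(got$beta, x$beta)
})

test_that("invalid rows are rejected with per-row reasons", {
  x <- make_variants(6)
  x$se[2] <- 0
  x$eaf[3] <- 1.2
  x$pval[4] <- 0
  x$other_allele[5] <- "AT"   # indel-like: not a biallelic SNP
  x$variant_id[6] <- x$variant_id[1]
  got <- validate_variants(x)
  rejects <- attr(got, "rejects")
  expect_equal(nrow(got), 1)
  expect_setequal(rejects$reason,
                  c("nonpositive SE", "eaf outside [0,1]",
                    "pval outside (0,1]", "non-biallelic or invalid alleles",
                    "duplicate variant_id"))
})

test_that("missing required column and empty file raise typed errors", {
  x <- make_variants(2)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(x, -se), path)
  expect_error(read_summary_stats(path, dialect = mrpath_dialect()),
               class = "mrpath_error_config", regexp = "'se'")
  empty <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(x[0, ], empty)
  expect_error(read_summary_stats(empty, dialect = mrpath_dialect()),
               class = "mrpath_error_input")
})

one_rec <- function(id = "rs1", ea, oa, eaf = 0.3, beta = 0.2, se = 0.05) {
  make_variants(1, ids = id, ea = ea, oa = oa, eaf = eaf, beta = beta,
                se = se)
}

test_that("align_alleles covers kept/flipped/complement/palindromic/incompatible", {
  # Swapped alleles: flip the outcome.
  a <- align_alleles(one_rec(ea = "A", oa = "G"),
                     one_rec(ea = "G", oa = "A", eaf = 0.3, beta = 0.2))
  expect_equal(a$action, "flipped")
  expect_equal(a$beta_outcome, -0.2)
  expect_equal(a$eaf_outcome, 0.7)

  # Identical alleles: untouched.
  b <- align_alleles(one_rec(ea = "A", oa = "G"),
                     one_rec(ea = "A", oa = "G", beta = 0.2))
  expect_equal(b$action, "kept")
  expect_equal(b$beta_outcome, 0.2)

  # Strand complement, same orientation after complementing.
  cc <- align_alleles(one_rec(ea = "A", oa = "G"),
                      one_rec(ea = "T", oa = "C", beta = 0.2))
  expect_equal(cc$action, "strand_complemented")
  expect_equal(cc$beta_outcome, 0.2)
  # Complement plus flip.
  cf <- align_alleles(one_rec(ea = "A", oa = "G"),
                      one_rec(ea = "C", oa = "T", beta = 0.2))
  expect_equal(cf$action, "strand_complemented")
  expect_equal(cf$beta_outcome, -0.2)

  # Palindromic at intermediate frequency is dropped.
  p <- align_alleles(one_rec(ea = "A", oa = "T", eaf = 0.3),
                     one_rec(ea = "A", oa = "T", eaf = 0.50))
  expect_equal(p$action, "dropped_palindromic")
  expect_true(is.na(p$beta_outcome))

  # Palindromic away from 0.5: frequency sides resolve orientation.
  p2 <- align_alleles(one_rec(ea = "A", oa = "T", eaf = 0.2),
                      one_rec(ea = "A", oa = "T", eaf = 0.25, beta = 0.2))
  expect_equal(p2$action, "kept")
  p3 <- align_alleles(one_rec(ea = "A", oa = "T", eaf = 0.2),
                      one_rec(ea = "A", oa = "T", eaf = 0.8, beta = 0.2))
  expect_equal(p3$action, "flipped")
  expect_equal(p3$beta_outcome, -0.2)

  # Incompatible allele pair.
  inc <- align_alleles(one_rec(ea = "A", oa = "G"),
                       one_rec(ea = "A", oa = "C"))
  expect_equal(inc$action, "dropped_incompatible")

  # Mismatched ids are a usage error.
  expect_error(align_alleles(one_rec(id = "rs1", ea = "A", oa = "G"),
                             one_rec(id = "rs2", ea = "A", oa = "G")),
               class = "mrpath_error_usage")
})

test_that("harmonize_pair joins, drops, and logs every input variant", {
  # Disjoint sets error.
  expect_error(
    harmonize_pair(make_variants(2, ids = c("a", "b")),
                   make_variants(2, ids = c("c", "d"))),
    class = "mrpath_error_empty_set"
  )

  # Identical tables: everything kept unchanged.
  x <- make_variants(4, beta = c(0.1, 0.2, 0.3, 0.4))
  h <- harmonize_pair(x, x)
  expect_equal(h$action, rep("kept", 4))
  expect_equal(h$beta_outcome, x$beta)

  # 5 shared SNPs, one palindromic at eaf 0.5 -> 4 retained.
  exp5 <- make_variants(5, ea = c("A", "A", "A", "A", "A"),
                        oa = c("G", "G", "T", "G", "G"),
                        eaf = c(0.3, 0.3, 0.5, 0.3, 0.3))
  h5 <- harmonize_pair(exp5, exp5)
  expect_equal(nrow(h5), 4)
  actions <- attr(h5, "actions")
  expect_equal(sum(actions$action == "dropped_palindromic"), 1)

  # Exposure variants missing from the outcome are logged too.
  out_subset <- exp5[1:3, ]
  h3 <- harmonize_pair(exp5, out_subset)
  log <- attr(h3, "actions")
  expect_setequal(log$variant_id, exp5$variant_id)
  expect_equal(sum(log$action == "dropped_unmatched"), 2)
  expect_equal(anyDuplicated(log$variant_id), 0)
})

test_that("harmonization is idempotent and flipping is an involution", {
  exposure <- make_variants(6, ea = rep("A", 6), oa = rep("G", 6),
                            beta = seq(0.05, 0.3, by = 0.05))
  outcome <- make_variants(6, ea = c("G", "A", "T", "C", "A", "G"),
                           oa = c("A", "G", "C", "T", "G", "A"),
                           eaf = rep(0.4, 6), beta = rep(0.2, 6))
  h1 <- harmonize_pair(exposure, outcome)
  # Recast the harmonized output as an outcome table and harmonize again.
  out2 <- tibble::tibble(
    variant_id = h1$variant_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_outcome, beta = h1$beta_outcome, se = h1$se_outcome,
    pval = 0.5, n = 50000
  )
  h2 <- harmonize_pair(exposure[exposure$variant_id %in% h1$variant_id, ], out2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$action, rep("kept", nrow(h1)))

  # Applying the swap rule twice restores the original record.
  rec <- one_rec(ea = "A", oa = "G", beta = 0.2, eaf = 0.3)
  swapped <- one_rec(ea = "G", oa = "A", beta = 0.2, eaf = 0.3)
  once <- align_alleles(rec, swapped)
  back <- tibble::tibble(
    variant_id = "rs1", chrom = "1", pos = 2.1e7,
    effect_allele = "G", other_allele = "A",
    eaf = 1 - once$eaf_outcome, beta = -once$beta_outcome,
    se = once$se_outcome, pval = 0.5, n = 50000
  )
  twice <- align_alleles(swapped, back)
  expect_equal(twice$beta_outcome, swapped$beta)
  expect_equal(twice$eaf_outcome, swapped$eaf)
})

test_that("multi-exposure harmonization anchors every beta on one allele", {
  x1 <- make_variants(5, beta = c(0.1, 0.12, 0.08, 0.15, 0.2))
  # Second exposure recorded on the opposite allele for some SNPs.
  x2 <- make_variants(5, ea = c("G", "A", "G", "A", "A"),
                      oa = c("A", "G", "A", "G", "G"),
                      eaf = c(0.7, 0.3, 0.7, 0.3, 0.3),
                      beta = c(-0.05, 0.06, -0.04, 0.07, 0.05))
  y <- make_variants(5, beta = rep(0.02, 5))
  h <- harmonize_mvmr(list(e1 = x1, e2 = x2), y)
  expect_s3_class(h, "mr_harmonized_mv")
  expect_equal(nrow(h), 5)
  # Flipped-exposure betas come back on the anchor allele (sign restored).
  expect_equal(h$beta_e2, c(0.05, 0.06, 0.04, 0.07, 0.05))
  expect_equal(attr(h, "exposures"), c("e1", "e2"))
})
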