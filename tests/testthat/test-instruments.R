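# Instrument selection filters.

test_that("per-SNP variance explained and F statistic match direct evaluation", {
  expect_equal(per_snp_r2(0.5, 0), 0)
  expect_equal(per_snp_r2(0.5, 0.1), 0.005)
  expect_equal(per_snp_r2(0.1, 0.2), 0.0072)
  expect_error(per_snp_r2(0, 0.1), class = "mrpath_error_degenerate")

  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(0.01, 1000, 1), 0.01 * 998 / 0.99)
  expect_equal(f_statistic(0.5, 5, 1), 3)
  expect_error(f_statistic(0.5, 2, 1), class = "mrpath_error_degenerate")
})

test_that("clumping keeps independent variants and prunes LD partners", {
  x <- make_variants(3, pval = c(1e-10, 1e-9, 1e-8), pos = c(1e6, 2e6, 3e6))
  # No LD at all: everything survives.
  expect_setequal(clump(x, ld = tibble::tibble(id_a = character(),
                                               id_b = character(),
                                               r2 = numeric())),
                  x$variant_id)
  # r2(1,2) = 0.9 at the same locus: the weaker of the pair goes.
  ld <- tibble::tibble(id_a = "rs001", id_b = "rs002", r2 = 0.9)
  expect_setequal(clump(x, ld = ld), c("rs001", "rs003"))
  # Without LD information clumping degrades to a warning no-op.
  expect_warning(kept <- clump(x, ld = NULL), class = "mrpath_warning_no_ld")
  expect_setequal(kept, x$variant_id)
})

test_that("clumping follows the greedy loop on a two-block fixture", {
  # Two LD blocks of 4 + 2 singletons; hand-run of the greedy loop:
  # rs001 (best p) removes rs002-rs004; rs005 removes rs006-rs008;
  # singletons rs009, rs010 stay.
  x <- make_variants(
    10,
    pval = c(1e-20, 1e-12, 1e-11, 1e-10, 1e-18, 1e-13, 1e-9, 1e-8,
             1e-15, 1e-14),
    pos = c(1e6, 1.1e6, 1.2e6, 1.3e6, 5e7, 5.01e7, 5.02e7, 5.03e7,
            9e7, 1.3e8)
  )
  block <- function(ids) {
    combos <- utils::combn(ids, 2)
    tibble::tibble(id_a = combos[1, ], id_b = combos[2, ], r2 = 0.8)
  }
  ld <- dplyr::bind_rows(block(sprintf("rs%03d", 1:4)),
                         block(sprintf("rs%03d", 5:8)))
  expect_setequal(clump(x, ld = ld),
                  c("rs001", "rs005", "rs009", "rs010"))
  # Result is invariant to input row order.
  shuffled <- x[c(7, 2, 10, 4, 1, 9, 3, 8, 5, 6), ]
  expect_setequal(clump(shuffled, ld = ld), clump(x, ld = ld))
})

test_that("clumping respects the distance window", {
  # Correlated pair far outside the window is not pruned.
  x <- make_variants(2, pval = c(1e-10, 1e-9), pos = c(1e6, 1e6 + 2e7))
  ld <- tibble::tibble(id_a = "rs001", id_b = "rs002", r2 = 0.9)
  expect_setequal(clump(x, ld = ld, window_kb = 10000), x$variant_id)
  expect_equal(clump(x, ld = ld, window_kb = 30000), "rs001")
})

# 20-SNP fixture with known per-filter casualties:
# 3 non-significant, 2 low-MAF, 4 clumped away, 1 outcome-associated,
# 1 weak (F < 10), 9 survivors.
make_filter_fixture <- function() {
  x <- make_variants(20, eaf = rep(0.3, 20), beta = rep(0.15, 20),
                     n_sample = rep(50000, 20),
                     pos = seq_len(20) * 2.1e7)
  x$pval[1:3] <- 1e-5                    # fail significance
  x$eaf[4:5] <- 0.005                    # fail MAF
  # rs007-rs010 in LD with the lead rs006 (same window).
  x$pos[6:10] <- 1e6 + (0:4) * 1e4
  x$pval[6] <- 1e-30
  x$pval[7:10] <- 1e-12
  ld <- tibble::tibble(id_a = "rs006", id_b = sprintf("rs%03d", 7:10),
                       r2 = 0.95)
  # rs011 associated with the outcome.
  outcome <- x
  outcome$beta <- 0.001
  outcome$pval <- 0.5
  outcome$pval[11] <- 1e-4
  # rs012 weak: tiny effect -> F << 10 (its pval column stays significant).
  x$beta[12] <- 0.005
  list(exposure = x, outcome = outcome, ld = ld)
}

test_that("select_instruments applies the five filters in order with a count log", {
  fx <- make_filter_fixture()
  iv <- select_instruments(fx$exposure, fx$outcome, ld = fx$ld)
  expect_s3_class(iv, "mr_instruments")
  log <- attr(iv, "filter_log")
  expect_equal(unname(log),
               c(3L, 2L, 4L, 1L, 1L))
  expect_equal(names(log),
               c("significance", "maf", "clump", "outcome_association",
                 "weak_instrument"))
  expect_equal(nrow(iv), 9)
  expect_equal(sum(log) + nrow(iv), nrow(fx$exposure))
  expect_false("rs011" %in% iv$variant_id)   # outcome-associated
  expect_false("rs012" %in% iv$variant_id)   # weak
  expect_true(all(iv$f >= 10))
  expect_true(all(iv$pval < 5e-8))
  expect_gt(attr(iv, "aggregate_f"), 0)
})

test_that("when every variant passes, the retained set equals the clumped set", {
  x <- make_variants(6, pval = rep(1e-12, 6))
  outcome <- x
  outcome$pval <- 0.5
  ld <- tibble::tibble(id_a = character(), id_b = character(), r2 = numeric())
  iv <- select_instruments(x, outcome, ld = ld)
  expect_setequal(iv$variant_id, clump(x, ld = ld))
})

test_that("tightening any threshold never grows the retained set", {
  fx <- make_filter_fixture()
  base <- select_instruments(fx$exposure, fx$outcome, ld = fx$ld)
  tighter <- list(
    instrument_thresholds(p_exposure = 1e-13),
    instrument_thresholds(maf_min = 0.1),
    instrument_thresholds(r2_max = 0.0005),
    instrument_thresholds(p_outcome = 0.6),
    instrument_thresholds(f_min = 400)
  )
  for (thr in tighter) {
    got <- tryCatch(
      select_instruments(fx$exposure, fx$outcome, thresholds = thr,
                         ld = fx$ld),
      mrpath_error_empty_instruments = function(e) NULL
    )
    n_got <- if (is.null(got)) 0 else nrow(got)
    expect_lte(n_got, nrow(base))
    if (!is.null(got)) {
      expect_true(all(got$variant_id %in% base$variant_id) ||
                    thr$r2_max < 0.001)
    }
  }
})

test_that("zero survivors raise an empty-instrument error carrying the log", {
  x <- make_variants(3, pval = rep(1e-3, 3))
  err <- tryCatch(select_instruments(x, x, ld = NULL),
                  mrpath_error_empty_instruments = function(e) e)
  expect_s3_class(err, "mrpath_error_empty_instruments")
  expect_equal(sum(err$filter_log), 3)
})
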