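# Instrument selection: significance, MAF, LD clumping, outcome-association
# exclusion and instrument-strength (F) exclusion, applied in that order.

#' Per-SNP variance explained
#'
#' Approximates the fraction of trait variance explained by one SNP as
#' `2 * eaf * (1 - eaf) * beta^2`, which assumes a standardized (unit
#' variance) trait. Values are clipped just below 1.
#'
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param beta Additive per-allele effect.
#' @return Variance-explained fraction in \[0, 1).
#' @export
per_snp_r2 <- function(eaf, beta) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop_mrpath("per_snp_r2() requires 0 < eaf < 1.",
                "mrpath_error_degenerate")
  }
  pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12)
}

#' Instrument-strength F statistic
#'
#' `F = R^2 (n - k - 1) / (k (1 - R^2))` for `k` instruments jointly
#' explaining a fraction `R^2` of the exposure variance in a sample of `n`.
#' `F < 10` conventionally flags weak instruments.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Exposure GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments (default 1 for per-SNP F).
#' @return Nonnegative F value.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) {
    stop_mrpath("f_statistic() requires 0 <= r2 < 1.",
                "mrpath_error_degenerate")
  }
  if (any(n <= k + 1)) {
    stop_mrpath("f_statistic() requires n > k + 1.",
                "mrpath_error_degenerate")
  }
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Read a pairwise LD table
#'
#' Three tab-separated columns `id_a`, `id_b`, `r2`; the symmetric closure
#' is applied. Pairs absent from the table are treated as r2 = 0.
#'
#' @param path Path to the LD TSV.
#' @return A tibble with columns `id_a`, `id_b`, `r2` (both orientations).
#' @export
read_ld_table <- function(path) {
  ld <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("id_a", "id_b", "r2")) {
    if (!col %in% names(ld)) {
      stop_mrpath(paste0("LD table must contain column '", col, "'."),
                  "mrpath_error_config")
    }
  }
  symmetrize_ld(ld)
}

symmetrize_ld <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) {
    return(tibble(id_a = character(), id_b = character(), r2 = numeric()))
  }
  ld <- as_tibble(ld)[, c("id_a", "id_b", "r2")]
  dplyr::distinct(
    dplyr::bind_rows(ld, tibble(id_a = ld$id_b, id_b = ld$id_a, r2 = ld$r2)),
    .data$id_a, .data$id_b, .keep_all = TRUE
  )
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining variant with the smallest p-value (ties
#' broken by lexicographically smaller `variant_id`) and removes remaining
#' variants correlated with it above `r2_max` that lie within `window_kb` on
#' the same chromosome. Variants without chromosome/position information are
#' compared by LD alone. With `ld = NULL` clumping is a no-op and a warning
#' is emitted, since no correlation information is available.
#'
#' @param candidates Summary-statistics tibble.
#' @param ld Pairwise LD tibble (`id_a`, `id_b`, `r2`) or `NULL`.
#' @param r2_max LD threshold above which variants are clumped (default
#'   0.001).
#' @param window_kb Clumping distance in kilobases (default 10000).
#' @return Character vector of retained `variant_id`s, in retention order.
#' @export
clump <- function(candidates, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  if (nrow(candidates) == 0) return(character())
  if (is.null(ld)) {
    warn(paste(
      "clump(): no LD information supplied; clumping is a no-op.",
      "Supply a pairwise LD table to remove correlated instruments."
    ), class = "mrpath_warning_no_ld")
    ord <- order(candidates$pval, candidates$variant_id)
    return(candidates$variant_id[ord])
  }
  ld <- symmetrize_ld(ld)
  ld_pairs <- split(
    stats::setNames(ld$r2, ld$id_b),
    ld$id_a
  )
  ld_r2 <- function(a, b) {
    hits <- ld_pairs[[a]]
    if (is.null(hits)) return(rep(0, length(b)))
    v <- unname(hits[match(b, names(hits))])
    v[is.na(v)] <- 0
    v
  }
  pool <- candidates[order(candidates$pval, candidates$variant_id), ]
  kept <- character()
  while (nrow(pool) > 0) {
    lead <- pool[1, ]
    kept <- c(kept, lead$variant_id)
    pool <- pool[-1, ]
    if (nrow(pool) == 0) break
    r2 <- ld_r2(lead$variant_id, pool$variant_id)
    has_pos <- !is.na(lead$chrom) & !is.na(lead$pos) &
      !is.na(pool$chrom) & !is.na(pool$pos)
    in_window <- !has_pos |
      (pool$chrom == lead$chrom &
         abs(pool$pos - lead$pos) <= window_kb * 1000)
    in_window[is.na(in_window)] <- TRUE
    pool <- pool[!(r2 > r2_max & in_window), ]
  }
  kept
}

#' Instrument-selection thresholds
#'
#' Defaults are the conventional genome-wide pipeline: exposure p < 5e-8,
#' MAF > 0.01, LD clumping at r2 0.001 within 10,000 kb, exclusion of
#' variants associated with the outcome at p < 0.001, and exclusion of weak
#' instruments with per-SNP F < 10. The outcome-association cut-off of
#' 0.001 is far more permissive than genome-wide significance; it is the
#' convention this pipeline reproduces and is fully configurable.
#'
#' @param p_exposure Exposure significance threshold (keep p strictly below).
#' @param maf_min Minimum minor allele frequency (keep strictly above).
#' @param r2_max,window_kb LD clumping parameters.
#' @param p_outcome Outcome-association exclusion threshold (drop strictly
#'   below).
#' @param f_min Minimum per-SNP F statistic (drop strictly below).
#' @return A named list of thresholds.
#' @export
instrument_thresholds <- function(p_exposure = 5e-8, maf_min = 0.01,
                                  r2_max = 0.001, window_kb = 10000,
                                  p_outcome = 0.001, f_min = 10) {
  list(p_exposure = p_exposure, maf_min = maf_min, r2_max = r2_max,
       window_kb = window_kb, p_outcome = p_outcome, f_min = f_min)
}

#' Select instrumental variables for one exposure
#'
#' Applies, in order: (1) exposure significance; (2) minor-allele-frequency;
#' (3) greedy LD clumping; (4) outcome-association exclusion; (5) weak
#' instrument (per-SNP F) exclusion. Per-SNP variance explained and F are
#' computed with [per_snp_r2()] and [f_statistic()] (k = 1); an aggregate F
#' over the retained set (k = number retained, R2 summed) is stored as an
#' attribute.
#'
#' @param exposure Validated exposure summary-statistics tibble.
#' @param outcome Validated outcome summary-statistics tibble (used for the
#'   outcome-association exclusion; variants absent from it are not excluded
#'   by that filter).
#' @param thresholds List from [instrument_thresholds()].
#' @param ld Optional pairwise LD tibble for [clump()].
#'
#' @return A tibble of class `mr_instruments`: the surviving variant records
#'   plus `r2` and `f` columns. Attributes: `filter_log` (named integer
#'   vector of removals per filter), `aggregate_f`.
#' @export
select_instruments <- function(exposure, outcome,
                               thresholds = instrument_thresholds(),
                               ld = NULL) {
  x <- as_tibble(exposure)
  log_counts <- c(significance = 0L, maf = 0L, clump = 0L,
                  outcome_association = 0L, weak_instrument = 0L)

  keep <- x$pval < thresholds$p_exposure
  log_counts["significance"] <- sum(!keep)
  x <- x[keep, ]

  keep <- minor_allele_freq(x$eaf) > thresholds$maf_min
  log_counts["maf"] <- sum(!keep)
  x <- x[keep, ]

  if (nrow(x) > 0) {
    retained_ids <- clump(x, ld = ld, r2_max = thresholds$r2_max,
                          window_kb = thresholds$window_kb)
    log_counts["clump"] <- nrow(x) - length(retained_ids)
    x <- x[x$variant_id %in% retained_ids, ]
  }

  out_p <- outcome$pval[match(x$variant_id, outcome$variant_id)]
  keep <- is.na(out_p) | out_p >= thresholds$p_outcome
  log_counts["outcome_association"] <- sum(!keep)
  x <- x[keep, ]

  if (nrow(x) > 0) {
    x$r2 <- per_snp_r2(x$eaf, x$beta)
    x$f <- f_statistic(x$r2, x$n, k = 1)
    keep <- x$f >= thresholds$f_min
    log_counts["weak_instrument"] <- sum(!keep)
    x <- x[keep, ]
  } else {
    x$r2 <- numeric()
    x$f <- numeric()
  }

  if (nrow(x) == 0) {
    stop_mrpath(
      paste0("No instruments survive selection (removed: ",
             paste(names(log_counts), log_counts, sep = "=", collapse = ", "),
             ")."),
      "mrpath_error_empty_instruments",
      filter_log = log_counts
    )
  }
  aggregate_f <- f_statistic(min(sum(x$r2), 1 - 1e-12),
                             n = min(x$n), k = nrow(x))
  class(x) <- c("mr_instruments", class(x))
  attr(x, "filter_log") <- log_counts
  attr(x, "aggregate_f") <- aggregate_f
  x
}

#' Write an instrument set with per-SNP diagnostics as TSV
#' @param x An `mr_instruments` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
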