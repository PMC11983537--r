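# Multivariable MR: joint instrument selection across exposures and a
# weighted multiple-regression estimator of direct effects.

#' Select instruments jointly for several exposures
#'
#' Takes the union of variants genome-wide significant for any exposure,
#' requires each retained variant to have effects available in every
#' exposure table and the outcome table, and applies the same filter battery
#' as [select_instruments()] with the per-variant p-value taken as the
#' minimum across exposures (clumping is keyed on that minimum).
#'
#' @param exposure_tables Named list of two or more validated
#'   summary-statistics tibbles.
#' @param outcome Validated outcome tibble.
#' @param thresholds List from [instrument_thresholds()].
#' @param ld Optional pairwise LD tibble.
#' @return A tibble of class `mr_instruments` carrying the records of the
#'   min-p exposure per variant, with `filter_log` attribute.
#' @export
mvmr_select_instruments <- function(exposure_tables, outcome,
                                    thresholds = instrument_thresholds(),
                                    ld = NULL) {
  stopifnot(length(exposure_tables) >= 2)
  labels <- names(exposure_tables)
  # Union of genome-wide significant variants, then availability everywhere.
  sig_ids <- unique(unlist(lapply(exposure_tables, function(tab) {
    tab$variant_id[tab$pval < thresholds$p_exposure]
  })))
  everywhere <- Reduce(intersect, c(lapply(exposure_tables, `[[`, "variant_id"),
                                    list(outcome$variant_id)))
  ids <- intersect(sig_ids, everywhere)
  if (length(ids) == 0) {
    stop_mrpath("No variant is genome-wide significant for any exposure and present in all tables.",
                "mrpath_error_empty_instruments")
  }
  # Per variant: the exposure achieving the minimum p-value supplies the
  # record used for MAF, clumping, and instrument-strength filtering.
  pmat <- sapply(exposure_tables, function(tab) {
    tab$pval[match(ids, tab$variant_id)]
  })
  pmat <- matrix(pmat, nrow = length(ids),
                 dimnames = list(ids, labels))
  best <- labels[max.col(-pmat, ties.method = "first")]
  pooled <- purrr::map_dfr(seq_along(ids), function(i) {
    tab <- exposure_tables[[best[i]]]
    tab[match(ids[i], tab$variant_id), ]
  })
  pooled$pval <- apply(pmat, 1, min)
  # Significance was applied above over the union; run the shared battery
  # without re-applying it (min-p variants already pass).
  select_instruments(pooled, outcome, thresholds = thresholds, ld = ld)
}

#' Multivariable MR fit
#'
#' Weighted least squares, without intercept, of the outcome effects on the
#' exposure-effect columns of a multi-exposure harmonized set, with weights
#' `1 / se_outcome^2`. The coefficient covariance is the inverse weighted
#' normal matrix scaled by the multiplicative overdispersion factor
#' `max(1, RSS_w / (nsnp - K))`. With a single exposure this reduces exactly
#' to the fixed-effect IVW estimate.
#'
#' @param h An `mr_harmonized_mv` tibble (or any tibble with
#'   `beta_<label>` columns plus `beta_outcome`, `se_outcome`).
#' @param exposures Character vector of exposure labels; defaults to the
#'   `exposures` attribute of `h`.
#' @return Object of class `mvmr_fit`: `exposures`, `theta`, `theta_se`,
#'   `p`, `nsnp`, `rss_w`, `cond_note`.
#' @export
mvmr_fit <- function(h, exposures = attr(h, "exposures")) {
  if (is.null(exposures)) {
    stop_mrpath("mvmr_fit(): supply `exposures` labels.", "mrpath_error_usage")
  }
  cols <- paste0("beta_", exposures)
  missing <- setdiff(c(cols, "beta_outcome", "se_outcome"), names(h))
  if (length(missing) > 0) {
    stop_mrpath(paste0("mvmr_fit(): missing columns ",
                       paste(missing, collapse = ", ")),
                "mrpath_error_usage")
  }
  K <- length(exposures)
  n <- nrow(h)
  if (n <= K) {
    stop_mrpath(sprintf("mvmr_fit() requires more instruments (%d) than exposures (%d).",
                        n, K),
                "mrpath_error_insufficient_instruments")
  }
  X <- as.matrix(as_tibble(h)[, cols])
  y <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  xtwx <- crossprod(X, w * X)
  if (qr(xtwx)$rank < K) {
    stop_mrpath("mvmr_fit(): exposure-effect columns are collinear.",
                "mrpath_error_collinear")
  }
  xtwx_inv <- solve(xtwx)
  theta <- drop(xtwx_inv %*% crossprod(X, w * y))
  resid <- y - drop(X %*% theta)
  rss_w <- sum(w * resid^2)
  phi <- max(1, rss_w / (n - K))
  theta_se <- sqrt(diag(xtwx_inv) * phi)
  structure(
    list(
      exposures = exposures,
      theta = stats::setNames(theta, exposures),
      theta_se = stats::setNames(theta_se, exposures),
      p = stats::setNames(z_pvalue(theta, theta_se), exposures),
      nsnp = n,
      rss_w = rss_w,
      heterogeneity_p = pchisq(rss_w, df = n - K, lower.tail = FALSE),
      cond_note = "conditional weak-instrument F statistics not computed"
    ),
    class = "mvmr_fit"
  )
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR fit (%d SNPs, %d exposures)\n",
              x$nsnp, length(x$exposures)))
  for (e in x$exposures) {
    ors <- to_odds_ratio(x$theta[[e]], x$theta_se[[e]])
    cat(sprintf("  %s: b = %.4f (SE %.4f), OR = %.3f (%.3f-%.3f), p = %.3g\n",
                e, x$theta[[e]], x$theta_se[[e]],
                ors$or, ors$or_low, ors$or_high, x$p[[e]]))
  }
  invisible(x)
}
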