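# Univariable two-sample MR estimators and diagnostics.
#
# All estimators operate on an mr_harmonized tibble (beta_exposure,
# se_exposure, beta_outcome, se_outcome per variant) and return an
# mr_estimate object; tidy()/glance() give tibble views.

new_mr_estimate <- function(method, b, se, nsnp, q = NA_real_,
                            q_p = NA_real_, egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_, mode = NA_character_) {
  or <- to_odds_ratio(b, se)
  structure(
    list(
      method = method, b = b, se = se, p = z_pvalue(b, se),
      or = or$or, or_low = or$or_low, or_high = or$or_high,
      nsnp = nsnp, q = q, q_p = q_p,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_p = egger_intercept_p,
      mode = mode
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs)\n", x$method, x$nsnp))
  cat(sprintf("  b = %.4f (SE %.4f), p = %.3g\n", x$b, x$se, x$p))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f)\n", x$or, x$or_low, x$or_high))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f (p = %.3g)\n", x$q, x$q_p))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  }
  invisible(x)
}

check_harmonized <- function(h, min_snps, caller) {
  needed <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(h))
  if (length(missing) > 0) {
    stop_mrpath(paste0(caller, "() needs harmonized columns: ",
                       paste(missing, collapse = ", ")),
                "mrpath_error_usage")
  }
  if (nrow(h) == 0) {
    stop_mrpath(paste0(caller, "(): empty harmonized set."),
                "mrpath_error_empty_set")
  }
  if (nrow(h) < min_snps) {
    stop_mrpath(
      sprintf("%s() requires at least %d instruments (got %d).",
              caller, min_snps, nrow(h)),
      "mrpath_error_insufficient_instruments"
    )
  }
  invisible(h)
}

#' Per-variant Wald ratio estimates
#'
#' The ratio `beta_outcome / beta_exposure` per variant with the first-order
#' standard error `se_outcome / |beta_exposure|` (exposure uncertainty is
#' ignored, the usual no-measurement-error approximation).
#'
#' @param h An `mr_harmonized` tibble.
#' @return Tibble: `variant_id`, `ratio`, `ratio_se`, `weight`
#'   (inverse-variance weight `beta_exposure^2 / se_outcome^2`).
#' @export
ratio_estimates <- function(h) {
  check_harmonized(h, 1, "ratio_estimates")
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    stop_mrpath(
      paste0("Zero exposure effect for variant(s): ",
             paste(h$variant_id[zero], collapse = ", ")),
      "mrpath_error_degenerate"
    )
  }
  tibble(
    variant_id = h$variant_id,
    ratio = h$beta_outcome / h$beta_exposure,
    ratio_se = h$se_outcome / abs(h$beta_exposure),
    weight = h$beta_exposure^2 / h$se_outcome^2
  )
}

#' Inverse-variance-weighted estimator
#'
#' Weighted mean of the per-variant Wald ratios with weights
#' `beta_exposure^2 / se_outcome^2` (equivalently weighted through-origin
#' regression of outcome on exposure effects). The random-effects standard
#' error is the fixed-effect one inflated multiplicatively by
#' `max(1, sqrt(Q / (nsnp - 1)))`; `mode = "auto"` selects random effects
#' when Cochran's Q has p < 0.05.
#'
#' @param h An `mr_harmonized` tibble.
#' @param mode `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(h, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  check_harmonized(h, 1, "mr_ivw")
  r <- ratio_estimates(h)
  if (nrow(h) == 1) {
    warn("mr_ivw(): single instrument; returning the Wald ratio.",
         class = "mrpath_warning_single_snp")
    return(new_mr_estimate("IVW", r$ratio, r$ratio_se, 1, mode = "fixed"))
  }
  w <- r$weight
  b <- sum(w * r$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (r$ratio - b)^2)
  q_p <- pchisq(q, df = nrow(h) - 1, lower.tail = FALSE)
  inflation <- max(1, sqrt(q / (nrow(h) - 1)))
  use_random <- switch(mode,
    fixed = FALSE,
    random = TRUE,
    auto = q_p < 0.05
  )
  se <- if (use_random) se_fixed * inflation else se_fixed
  new_mr_estimate(if (use_random) "IVW-random" else "IVW",
                  b, se, nrow(h), q = q, q_p = q_p,
                  mode = if (use_random) "random" else "fixed")
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1 / se_outcome^2`, after orienting every variant so
#' its exposure effect is non-negative. A non-zero intercept indicates
#' directional horizontal pleiotropy. Slope and intercept standard errors
#' carry a multiplicative overdispersion factor
#' `max(1, sqrt(RSS_w / (nsnp - 2)))`.
#'
#' @param h An `mr_harmonized` tibble with at least 3 variants.
#' @return An `mr_estimate` with Egger intercept fields populated.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3, "mr_egger")
  sign_flip <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- h$beta_exposure * sign_flip
  by <- h$beta_outcome * sign_flip
  w <- 1 / h$se_outcome^2
  if (length(unique(bx)) < 2) {
    stop_mrpath("mr_egger(): exposure effects are constant after orientation.",
                "mrpath_error_collinear")
  }
  # Closed-form weighted simple regression.
  sw <- sum(w)
  mx <- sum(w * bx) / sw
  my <- sum(w * by) / sw
  sxx <- sum(w * (bx - mx)^2)
  sxy <- sum(w * (bx - mx) * (by - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- by - intercept - slope * bx
  rss_w <- sum(w * resid^2)
  phi <- max(1, rss_w / (nrow(h) - 2))
  se_slope <- sqrt(phi / sxx)
  se_intercept <- sqrt(phi * (1 / sw + mx^2 / sxx))
  new_mr_estimate(
    "Egger", slope, se_slope, nrow(h),
    q = rss_w, q_p = pchisq(rss_w, df = nrow(h) - 2, lower.tail = FALSE),
    egger_intercept = intercept,
    egger_intercept_se = se_intercept,
    egger_intercept_p = z_pvalue(intercept, se_intercept)
  )
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5)$y
}

#' Weighted-median estimator
#'
#' The causal estimate at the 50th percentile of the weight-ordered Wald
#' ratios (linear interpolation over cumulative weights), consistent when at
#' least half the weight comes from valid instruments. The standard error is
#' a seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on the observed values with their
#' standard errors and the estimate recomputed.
#'
#' @param h An `mr_harmonized` tibble with at least 3 variants.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  check_harmonized(h, 3, "mr_weighted_median")
  if (missing(seed)) {
    stop_mrpath("mr_weighted_median() requires an explicit `seed`.",
                "mrpath_error_config")
  }
  r <- ratio_estimates(h)
  w <- 1 / r$ratio_se^2
  b <- weighted_median_point(r$ratio, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(h), h$beta_exposure, h$se_exposure)
      by <- rnorm(nrow(h), h$beta_outcome, h$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      rr <- by / bx
      ww <- bx^2 / h$se_outcome^2
      weighted_median_point(rr, ww)
    }, numeric(1))
  })
  new_mr_estimate("WM", b, sd(boots), nrow(h))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - b_IVW)^2` against a chi-square reference with
#' `nsnp - 1` degrees of freedom.
#'
#' @param h An `mr_harmonized` tibble with at least 2 variants.
#' @return One-row tibble: `q`, `df`, `p`.
#' @export
cochran_q <- function(h) {
  check_harmonized(h, 2, "cochran_q")
  est <- mr_ivw(h, mode = "fixed")
  tibble(q = est$q, df = nrow(h) - 1, p = est$q_p)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each variant omitted in turn; the final
#' row (`variant_id = "(all)"`) is the full-set estimate.
#'
#' @param h An `mr_harmonized` tibble with at least 3 variants.
#' @param mode IVW mode passed through (default `"auto"`).
#' @return Tibble: `variant_id` (the omitted variant), `b`, `se`, `p`,
#'   `nsnp`.
#' @export
leave_one_out <- function(h, mode = "auto") {
  check_harmonized(h, 3, "leave_one_out")
  rows <- purrr::map_dfr(seq_len(nrow(h)), function(j) {
    est <- mr_ivw(h[-j, ], mode = mode)
    tibble(variant_id = h$variant_id[j], b = est$b, se = est$se,
           p = est$p, nsnp = est$nsnp)
  })
  full <- mr_ivw(h, mode = mode)
  dplyr::bind_rows(rows, tibble(variant_id = "(all)", b = full$b,
                                se = full$se, p = full$p, nsnp = full$nsnp))
}

#' Run the full univariable estimator battery
#'
#' IVW (auto fixed/random), MR-Egger and weighted median on one harmonized
#' set, as one tidy table mirroring a per-exposure results row block.
#'
#' @param h An `mr_harmonized` tibble.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Tibble with one row per method (columns as [tidy.mr_estimate()]).
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1L) {
  ests <- list(mr_ivw(h, mode = "auto"))
  if (nrow(h) >= 3) {
    ests <- c(ests, list(mr_egger(h),
                         mr_weighted_median(h, n_boot = n_boot, seed = seed)))
  }
  purrr::map_dfr(ests, function(e) dplyr::bind_cols(tidy(e), glance(e)))
}
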