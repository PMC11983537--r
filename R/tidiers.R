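# broom-style tidy()/glance() methods for fitted objects.

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `nsnp`, `estimate`, `std_error`,
#'   `p_value`, `or`, `or_low`, `or_high`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, nsnp = x$nsnp, estimate = x$b, std_error = x$se,
    p_value = x$p, or = x$or, or_low = x$or_low, or_high = x$or_high
  )
}

#' Diagnostics of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `q`, `q_p`, `egger_intercept`,
#'   `egger_intercept_p`, `mode`.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    q = x$q, q_p = x$q_p,
    egger_intercept = x$egger_intercept,
    egger_intercept_p = x$egger_intercept_p,
    mode = x$mode
  )
}

#' Tidy a multivariable MR fit
#'
#' @param x An `mvmr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per exposure: `exposure`, `nsnp`, `estimate`,
#'   `std_error`, `p_value`, `or`, `or_low`, `or_high`.
#' @export
tidy.mvmr_fit <- function(x, ...) {
  ors <- to_odds_ratio(unname(x$theta), unname(x$theta_se))
  tibble(
    exposure = x$exposures, nsnp = x$nsnp,
    estimate = unname(x$theta), std_error = unname(x$theta_se),
    p_value = unname(x$p),
    or = ors$or, or_low = ors$or_low, or_high = ors$or_high
  )
}

#' Fit-level summary of a multivariable MR fit
#' @param x An `mvmr_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nsnp`, `n_exposures`, `rss_w`,
#'   `heterogeneity_p`.
#' @export
glance.mvmr_fit <- function(x, ...) {
  tibble(nsnp = x$nsnp, n_exposures = length(x$exposures),
         rss_w = x$rss_w, heterogeneity_p = x$heterogeneity_p)
}

#' Tidy an MR-PRESSO result
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return Tibble with one row per variant: `variant_id`, `p_adjusted`,
#'   `outlier`.
#' @export
tidy.mr_presso <- function(x, ...) {
  tibble(
    variant_id = names(x$per_snp_p),
    p_adjusted = unname(x$per_snp_p),
    outlier = names(x$per_snp_p) %in% x$outliers
  )
}

#' Test-level summary of an MR-PRESSO result
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return One-row tibble: `rss_obs`, `global_p`, `n_outliers`, `b_raw`,
#'   `b_corrected`, `distortion`, `distortion_p`, `n_sim`.
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    rss_obs = x$rss_obs, global_p = x$global_p,
    n_outliers = length(x$outliers), b_raw = x$b_raw,
    b_corrected = x$b_corrected, distortion = x$distortion,
    distortion_p = x$distortion_p, n_sim = x$n_sim
  )
}

#' Tidy a mediation result
#'
#' One row shaped like a mediation report table: indirect effect with
#' delta-method CI and p, proportion mediated with bootstrap CI.
#'
#' @param x An `mr_mediation`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.mr_mediation <- function(x, ...) {
  tibble(
    mediator = x$mediator,
    indirect = x$indirect, indirect_se = x$indirect_se,
    ci_low = x$indirect_low, ci_high = x$indirect_high,
    p_value = x$indirect_p,
    proportion = x$proportion,
    proportion_low = x$proportion_low, proportion_high = x$proportion_high,
    admitted = x$admitted
  )
}

#' Path-coefficient summary of a mediation result
#' @param x An `mr_mediation`.
#' @param ... Unused.
#' @return One-row tibble: `alpha`, `se_alpha`, `beta1`, `se_beta1`,
#'   `beta_total`, `se_beta_total`, `direct`, `n_boot`, `seed`.
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble(
    alpha = x$alpha, se_alpha = x$se_alpha,
    beta1 = x$beta1, se_beta1 = x$se_beta1,
    beta_total = x$beta_total, se_beta_total = x$se_beta_total,
    direct = x$direct, n_boot = x$n_boot, seed = x$seed
  )
}
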