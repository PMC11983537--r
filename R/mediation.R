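# Two-step MR mediation: product of coefficients, delta-method SE,
# proportion mediated with bootstrap confidence interval.

#' Product-of-coefficients indirect effect
#'
#' The mediated (indirect) effect of exposure on outcome through one
#' mediator: `alpha * beta1`, where `alpha` is the exposure-to-mediator
#' effect and `beta1` the mediator-to-outcome direct effect adjusted for the
#' exposure.
#'
#' @param alpha Exposure-to-mediator effect (log scale).
#' @param beta1 Mediator-to-outcome direct effect (log odds).
#' @return `alpha * beta1`.
#' @export
mediation_effect <- function(alpha, beta1) alpha * beta1

#' Delta-method standard error of a product
#'
#' First-order approximation `sqrt(alpha^2 se_beta1^2 + beta1^2 se_alpha^2)`
#' (no cross term; the two estimates come from different GWAS and are
#' treated as independent).
#'
#' @param alpha,beta1 The two estimates.
#' @param se_alpha,se_beta1 Their standard errors (non-negative).
#' @return Standard error of `alpha * beta1`.
#' @export
delta_se <- function(alpha, se_alpha, beta1, se_beta1) {
  if (any(se_alpha < 0 | se_beta1 < 0)) {
    stop_mrpath("delta_se() requires non-negative standard errors.",
                "mrpath_error_input")
  }
  sqrt(alpha^2 * se_beta1^2 + beta1^2 * se_alpha^2)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * indirect / beta_total` (a percentage). A negative value signals
#' inconsistent mediation (indirect and total effects of opposite sign) and
#' triggers a warning.
#'
#' @param indirect Indirect effect `alpha * beta1`.
#' @param beta_total Total exposure-to-outcome effect from univariable MR.
#' @return Percentage mediated.
#' @export
proportion_mediated <- function(indirect, beta_total) {
  if (any(beta_total == 0)) {
    stop_mrpath("proportion_mediated() undefined for beta_total = 0.",
                "mrpath_error_degenerate")
  }
  prop <- 100 * indirect / beta_total
  if (any(prop < 0)) {
    warn("Inconsistent mediation: indirect and total effects have opposite signs.",
         class = "mrpath_warning_inconsistent_mediation")
  }
  prop
}

#' Bootstrap confidence interval for the proportion mediated
#'
#' Draws `alpha`, `beta1` and `beta_total` independently from normal
#' distributions centred on their estimates with their standard errors and
#' recomputes the proportion for each draw. The default interval is the
#' normal approximation `point +/- 1.96 * sd(bootstrap draws)`, which yields
#' an interval symmetric about the point estimate; `type = "percentile"`
#' returns the empirical 2.5/97.5 percentiles instead. Draws in which
#' `|beta_total|` falls below `guard` are rejected and redrawn (the ratio of
#' normals has no finite moments without such a guard).
#'
#' @param alpha,se_alpha,beta1,se_beta1,beta_total,se_beta_total Estimates
#'   and standard errors of the three path coefficients.
#' @param n_boot Bootstrap iterations, at least 100 (default 1000).
#' @param seed Integer seed.
#' @param type `"normal"` (default) or `"percentile"`.
#' @param guard Rejection threshold for `|beta_total|` draws (default 1e-6).
#' @return List: `low`, `high`, `boot_sd`, `n_rejected`.
#' @export
bootstrap_proportion_ci <- function(alpha, se_alpha, beta1, se_beta1,
                                    beta_total, se_beta_total,
                                    n_boot = 1000, seed,
                                    type = c("normal", "percentile"),
                                    guard = 1e-6) {
  type <- match.arg(type)
  if (n_boot < 100) {
    stop_mrpath("bootstrap_proportion_ci() requires n_boot >= 100.",
                "mrpath_error_config")
  }
  point <- 100 * alpha * beta1 / beta_total
  draws <- withr::with_seed(seed, {
    a <- rnorm(n_boot, alpha, se_alpha)
    b1 <- rnorm(n_boot, beta1, se_beta1)
    bt <- rnorm(n_boot, beta_total, se_beta_total)
    rejected <- 0L
    bad <- abs(bt) < guard
    while (any(bad)) {
      rejected <- rejected + sum(bad)
      if (rejected > n_boot / 2) {
        stop_mrpath("bootstrap_proportion_ci(): more than half of the total-effect draws fell below the guard; the proportion is unstable.",
                    "mrpath_error_instability")
      }
      bt[bad] <- rnorm(sum(bad), beta_total, se_beta_total)
      bad <- abs(bt) < guard
    }
    list(prop = 100 * a * b1 / bt, rejected = rejected)
  })
  boot_sd <- sd(draws$prop)
  if (draws$rejected > 0) {
    warn(sprintf("bootstrap_proportion_ci(): %d draw(s) redrawn under the |beta_total| guard.",
                 draws$rejected),
         class = "mrpath_warning_guard")
  }
  if (type == "normal") {
    list(low = point - 1.96 * boot_sd, high = point + 1.96 * boot_sd,
         boot_sd = boot_sd, n_rejected = draws$rejected)
  } else {
    q <- stats::quantile(draws$prop, c(0.025, 0.975), names = FALSE)
    list(low = q[1], high = q[2], boot_sd = boot_sd,
         n_rejected = draws$rejected)
  }
}

#' Assemble a mediation result from path-coefficient estimates
#'
#' The arithmetic core of two-step mediation, usable directly on published
#' summary estimates: indirect effect `alpha * beta1`, delta-method SE and
#' 95% CI, z-test p, proportion mediated with bootstrap CI.
#'
#' @param mediator Mediator label.
#' @param alpha,se_alpha Step-1 (exposure-to-mediator) estimate and SE.
#' @param beta1,se_beta1 Step-2 (mediator-to-outcome, exposure-adjusted)
#'   estimate and SE.
#' @param beta_total,se_beta_total Total exposure-to-outcome effect and SE.
#' @param alpha_p,beta1_p Optional p-values used for the admission check
#'   (both must be < 0.05); recomputed from the z statistic when omitted.
#' @param n_boot,seed,ci_type Passed to [bootstrap_proportion_ci()].
#' @return Object of class `mr_mediation` with fields `mediator`, `alpha`,
#'   `se_alpha`, `beta1`, `se_beta1`, `beta_total`, `se_beta_total`,
#'   `indirect`, `indirect_se`, `indirect_low`, `indirect_high`,
#'   `indirect_p`, `proportion`, `proportion_low`, `proportion_high`,
#'   `admitted`, `n_boot`, `seed`.
#' @export
mediate_from_estimates <- function(mediator, alpha, se_alpha, beta1, se_beta1,
                                   beta_total, se_beta_total,
                                   alpha_p = NULL, beta1_p = NULL,
                                   n_boot = 1000, seed = 1L,
                                   ci_type = "normal") {
  if (is.null(alpha_p)) alpha_p <- z_pvalue(alpha, se_alpha)
  if (is.null(beta1_p)) beta1_p <- z_pvalue(beta1, se_beta1)
  indirect <- mediation_effect(alpha, beta1)
  ind_se <- delta_se(alpha, se_alpha, beta1, se_beta1)
  prop <- proportion_mediated(indirect, beta_total)
  ci <- bootstrap_proportion_ci(alpha, se_alpha, beta1, se_beta1,
                                beta_total, se_beta_total,
                                n_boot = n_boot, seed = seed, type = ci_type)
  structure(
    list(
      mediator = mediator,
      alpha = alpha, se_alpha = se_alpha, alpha_p = alpha_p,
      beta1 = beta1, se_beta1 = se_beta1, beta1_p = beta1_p,
      beta_total = beta_total, se_beta_total = se_beta_total,
      indirect = indirect, indirect_se = ind_se,
      indirect_low = indirect - 1.96 * ind_se,
      indirect_high = indirect + 1.96 * ind_se,
      indirect_p = z_pvalue(indirect, ind_se),
      proportion = prop,
      proportion_low = ci$low, proportion_high = ci$high,
      direct = beta_total - indirect,
      admitted = alpha_p < 0.05 && beta1_p < 0.05,
      n_boot = n_boot, seed = seed
    ),
    class = "mr_mediation"
  )
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediation through %s%s\n", x$mediator,
              if (x$admitted) "" else " (not admitted)"))
  cat(sprintf("  alpha = %.3f, beta1 = %.3f, total = %.3f\n",
              x$alpha, x$beta1, x$beta_total))
  cat(sprintf("  indirect = %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$indirect, x$indirect_low, x$indirect_high, x$indirect_p))
  cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f%%, %.2f%%)\n",
              x$proportion, x$proportion_low, x$proportion_high))
  invisible(x)
}

#' Two-step MR mediation from raw summary statistics
#'
#' Step 1 estimates the exposure-to-mediator effect `alpha` by univariable
#' IVW on the exposure's instruments; step 2 estimates the mediator's direct
#' effect on the outcome `beta1` by multivariable MR adjusting for the
#' exposure. The total effect comes from univariable IVW of exposure on
#' outcome. The mediator is admitted only when both `alpha` and `beta1` are
#' significant at 0.05; a failed admission flags the result rather than
#' erroring.
#'
#' @param exposure,mediator,outcome Validated summary-statistics tibbles.
#' @param thresholds Instrument-selection thresholds
#'   ([instrument_thresholds()]).
#' @param ld Optional pairwise LD tibble.
#' @param n_boot,seed,ci_type Passed to the proportion bootstrap.
#' @param mediator_label Label for reporting (default `"mediator"`).
#' @param ivw_mode IVW mode for steps 1 and the total effect (default
#'   `"auto"`).
#' @return An `mr_mediation` object (see [mediate_from_estimates()]) with an
#'   additional `nsnp` field (step-1, step-2 and total-effect instrument
#'   counts).
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               thresholds = instrument_thresholds(),
                               ld = NULL, n_boot = 1000, seed = 1L,
                               ci_type = "normal",
                               mediator_label = "mediator",
                               ivw_mode = "auto") {
  # Step 1: exposure -> mediator, UVMR on the exposure's instruments.
  iv_xm <- select_instruments(exposure, mediator, thresholds = thresholds,
                              ld = ld)
  h_xm <- harmonize_pair(iv_xm, mediator)
  step1 <- mr_ivw(h_xm, mode = ivw_mode)

  # Total effect: exposure -> outcome, UVMR.
  iv_xy <- select_instruments(exposure, outcome, thresholds = thresholds,
                              ld = ld)
  h_xy <- harmonize_pair(iv_xy, outcome)
  total <- mr_ivw(h_xy, mode = ivw_mode)

  # Step 2: mediator -> outcome adjusted for exposure, MVMR.
  tables <- list(mediator = mediator, exposure = exposure)
  names(tables) <- c(mediator_label, "exposure")
  iv_mv <- mvmr_select_instruments(tables, outcome, thresholds = thresholds,
                                   ld = ld)
  h_mv <- harmonize_mvmr(lapply(tables, function(tab) {
    tab[tab$variant_id %in% iv_mv$variant_id, ]
  }), outcome)
  fit <- mvmr_fit(h_mv)
  beta1 <- fit$theta[[mediator_label]]
  se_beta1 <- fit$theta_se[[mediator_label]]

  res <- mediate_from_estimates(
    mediator = mediator_label,
    alpha = step1$b, se_alpha = step1$se,
    beta1 = beta1, se_beta1 = se_beta1,
    beta_total = total$b, se_beta_total = total$se,
    alpha_p = step1$p, beta1_p = fit$p[[mediator_label]],
    n_boot = n_boot, seed = seed, ci_type = ci_type
  )
  res$nsnp <- c(step1 = step1$nsnp, step2 = fit$nsnp, total = total$nsnp)
  res
}

#' Bundled worked example: published two-step MR summary estimates
#'
#' Path-coefficient estimates for the mediation of the educational
#' attainment (EA) to IgA nephropathy (IgAN) effect through insomnia, body
#' mass index and waist circumference, as published: `alpha` is the IVW
#' effect of EA on each mediator, `beta1` the EA-adjusted MVMR effect of the
#' mediator on IgAN. The total effect `beta_total = -0.788` is the value the
#' published proportions are arithmetically consistent with (the published
#' headline UVMR odds ratio 0.433 implies -0.837 instead; the difference
#' reflects the instrument set behind the mediation-stage total effect, and
#' this table does not attempt to reconcile it). `se_beta_total` is derived
#' from the headline odds-ratio confidence interval.
#'
#' @return Tibble with columns `mediator`, `alpha`, `se_alpha`, `beta1`,
#'   `se_beta1`, `beta_total`, `se_beta_total`.
#' @export
ea_igan_estimates <- function() {
  tibble(
    mediator = c("insomnia", "body mass index", "waist circumference"),
    alpha = c(-0.195, -0.686, -0.505),
    se_alpha = c(0.028, 0.065, 0.054),
    beta1 = c(0.506, 0.127, 0.155),
    se_beta1 = c(0.185, 0.041, 0.052),
    beta_total = -0.788,
    se_beta_total = 0.132
  )
}

#' Run the mediation arithmetic over a table of path coefficients
#'
#' @param estimates Tibble shaped like [ea_igan_estimates()].
#' @param n_boot,seed,ci_type Passed to [mediate_from_estimates()].
#' @return Tibble with one row per mediator: indirect effect, delta-method
#'   95% CI, p, proportion mediated (%) with bootstrap 95% CI.
#' @export
mediation_table <- function(estimates, n_boot = 1000, seed = 1L,
                            ci_type = "normal") {
  purrr::map_dfr(seq_len(nrow(estimates)), function(i) {
    row <- estimates[i, ]
    m <- mediate_from_estimates(
      row$mediator, row$alpha, row$se_alpha, row$beta1, row$se_beta1,
      row$beta_total, row$se_beta_total,
      n_boot = n_boot, seed = seed + i, ci_type = ci_type
    )
    tidy(m)
  })
}
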