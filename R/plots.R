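# ggplot2 views of harmonized sets and results. Each plot_* function also
# has a *_data companion returning the tidy table it draws, so downstream
# tooling can restyle figures from the data alone.

#' Scatter-plot data for a harmonized set
#'
#' @param h An `mr_harmonized` tibble.
#' @return Tibble: `variant_id`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @export
scatter_data <- function(h) {
  as_tibble(h)[, c("variant_id", "beta_exposure", "se_exposure",
                   "beta_outcome", "se_outcome")]
}

#' Exposure-outcome effect scatter with fitted MR lines
#'
#' @param h An `mr_harmonized` tibble.
#' @param estimates Optional list of `mr_estimate` objects whose fitted
#'   lines are overlaid (Egger lines use their intercept; others pass
#'   through the origin).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, estimates = list()) {
  d <- scatter_data(h)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exposure,
                                       y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
      ymax = .data$beta_outcome + 1.96 * .data$se_outcome
    ), width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome")
  if (length(estimates) > 0) {
    lines <- purrr::map_dfr(estimates, function(e) {
      tibble(method = e$method, slope = e$b,
             intercept = if (is.na(e$egger_intercept)) 0 else e$egger_intercept)
    })
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    ) + ggplot2::labs(colour = "Method")
  }
  p
}

#' Funnel-plot data: Wald ratios against their precision
#' @param h An `mr_harmonized` tibble.
#' @return Tibble: `variant_id`, `ratio`, `precision` (1 / ratio SE).
#' @export
funnel_data <- function(h) {
  r <- ratio_estimates(h)
  tibble(variant_id = r$variant_id, ratio = r$ratio,
         precision = 1 / r$ratio_se)
}

#' Funnel plot of per-variant ratio estimates
#' @param h An `mr_harmonized` tibble.
#' @param b Optional reference slope drawn as a vertical line (e.g. the IVW
#'   estimate).
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(h, b = NULL) {
  d <- funnel_data(h)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Wald ratio", y = "Precision (1/SE)")
  if (!is.null(b)) {
    p <- p + ggplot2::geom_vline(xintercept = b, linetype = "dashed")
  }
  p
}

#' Leave-one-out plot
#' @param loo Tibble from [leave_one_out()].
#' @return A ggplot object (estimate with 95% CI per omitted variant).
#' @export
plot_mr_loo <- function(loo) {
  loo$variant_id <- factor(loo$variant_id, levels = rev(loo$variant_id))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$b, y = .data$variant_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$b - 1.96 * .data$se, xmax = .data$b + 1.96 * .data$se
    ), height = 0) +
    ggplot2::geom_vline(xintercept = loo$b[loo$variant_id == "(all)"],
                        linetype = "dashed") +
    ggplot2::labs(x = "IVW estimate (variant omitted)", y = NULL)
}

#' Forest plot of method or exposure results
#'
#' @param results Tibble with columns `estimate`, `std_error` and a label
#'   column (`label_col`), e.g. rows bound from [tidy.mr_estimate()].
#' @param label_col Name of the labelling column (default `"method"`).
#' @param exponentiate Plot odds ratios on a log axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results, label_col = "method",
                           exponentiate = TRUE) {
  d <- as_tibble(results)
  d$label <- factor(d[[label_col]], levels = rev(unique(d[[label_col]])))
  d$mid <- d$estimate
  d$lo <- d$estimate - 1.96 * d$std_error
  d$hi <- d$estimate + 1.96 * d$std_error
  null_line <- 0
  if (exponentiate) {
    d$mid <- exp(d$mid); d$lo <- exp(d$lo); d$hi <- exp(d$hi)
    null_line <- 1
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dashed") +
    ggplot2::labs(x = if (exponentiate) "Odds ratio (95% CI)"
                      else "Estimate (95% CI)", y = NULL)
  if (exponentiate) p <- p + ggplot2::scale_x_log10()
  p
}

#' @rdname plot_mr_scatter
#' @param object An `mr_harmonized` tibble.
#' @param ... Passed to [plot_mr_scatter()].
#' @export
autoplot.mr_harmonized <- function(object, ...) plot_mr_scatter(object, ...)

#' Path-diagram data for a mediation result
#'
#' The three path coefficients and the implied direct effect
#' (`beta_total - alpha * beta1`) as a tidy edge table.
#'
#' @param x An `mr_mediation`.
#' @return Tibble: `from`, `to`, `coefficient`, `value`.
#' @export
mediation_path_data <- function(x) {
  tibble(
    from = c("exposure", x$mediator, "exposure"),
    to = c(x$mediator, "outcome", "outcome"),
    coefficient = c("alpha", "beta1", "direct"),
    value = c(x$alpha, x$beta1, x$direct)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
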