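# Internal helpers: error signalling and shared validation.

stop_mrpath <- function(message, class, ...) {
  abort(message, class = c(class, "mrpath_error"), ...)
}

# Two-sided normal p-value for an estimate/SE pair. Large-sample summary
# statistics justify the normal reference everywhere in this package.
z_pvalue <- function(b, se) {
  ifelse(se > 0, 2 * pnorm(-abs(b / se)), as.numeric(b == 0))
}

#' Convert a log odds ratio to an odds ratio with 95% confidence interval
#'
#' @param b Log-odds slope (numeric vector).
#' @param se Standard error of `b`; must be non-negative.
#'
#' @return A tibble with columns `or`, `or_low`, `or_high`. Values are
#'   exponentiated from unrounded inputs; round only when reporting
#'   (conventionally 3 decimals).
#' @examples
#' to_odds_ratio(0.127, 0.041)
#' @export
to_odds_ratio <- function(b, se) {
  if (any(se < 0)) stop_mrpath("`se` must be >= 0.", "mrpath_error_input")
  tibble(
    or = exp(b),
    or_low = exp(b - 1.96 * se),
    or_high = exp(b + 1.96 * se)
  )
}

minor_allele_freq <- function(eaf) pmin(eaf, 1 - eaf)

# Columns every validated summary-statistics table carries.
variant_columns <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)
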