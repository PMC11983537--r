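# MR-PRESSO: simulation-based residual-sum-of-squares global test,
# per-variant outlier test, and distortion test with outlier-corrected
# re-estimation.

# Leave-one-out IVW slopes for every variant at once, given vectors (or
# matrices with one column per replicate) of exposure/outcome effects.
loo_slopes <- function(bx, by, w) {
  swr <- colSums(as.matrix(w * (by / bx)))
  sw <- colSums(as.matrix(w))
  sweep_wr <- sweep(-as.matrix(w * (by / bx)), 2, swr, "+")
  sweep_w <- sweep(-as.matrix(w), 2, sw, "+")
  sweep_wr / sweep_w
}

presso_core <- function(h, n_sim, seed) {
  check_harmonized(h, 4, "mr_presso")
  if (n_sim < 1) {
    stop_mrpath("MR-PRESSO requires n_sim >= 1.", "mrpath_error_config")
  }
  bx <- h$beta_exposure
  by <- h$beta_outcome
  sex <- h$se_exposure
  sey <- h$se_outcome
  w <- bx^2 / sey^2
  nsnp <- length(bx)

  b_loo <- drop(loo_slopes(bx, by, w))
  d_obs <- (by - b_loo * bx)^2 / sey^2
  rss_obs <- sum(d_obs)

  perturb_exposure <- !any(is.na(sex))
  if (!perturb_exposure) {
    warn("mr_presso(): exposure SEs unavailable; perturbing outcome only.",
         class = "mrpath_warning_no_sex")
  }

  d_sim <- withr::with_seed(seed, {
    bx_star <- if (perturb_exposure) {
      matrix(rnorm(nsnp * n_sim, mean = bx, sd = sex), nrow = nsnp)
    } else {
      matrix(bx, nrow = nsnp, ncol = n_sim)
    }
    by_star <- matrix(rnorm(nsnp * n_sim, mean = b_loo * bx, sd = sey),
                      nrow = nsnp)
    w_star <- bx_star^2 / sey^2
    b_loo_star <- loo_slopes(bx_star, by_star, w_star)
    (by_star - b_loo_star * bx_star)^2 / sey^2
  })
  rss_sim <- colSums(d_sim)

  list(b_loo = b_loo, d_obs = d_obs, rss_obs = rss_obs,
       d_sim = d_sim, rss_sim = rss_sim, n_sim = n_sim, seed = seed)
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed residual sum of squares compares each variant's outcome
#' effect with the prediction from the leave-one-out IVW slope; its null
#' distribution is simulated by redrawing effects from their sampling
#' distributions under that predicted model. The empirical p-value carries
#' the +1 correction, so its floor is `1 / (n_sim + 1)`.
#'
#' @param h An `mr_harmonized` tibble with at least 4 variants.
#' @param n_sim Number of simulated replicates (default 1000).
#' @param seed Integer seed.
#' @return List: `rss_obs`, `global_p`, `n_sim`, `seed`.
#' @export
mr_presso_global <- function(h, n_sim = 1000, seed) {
  core <- presso_core(h, n_sim, seed)
  list(
    rss_obs = core$rss_obs,
    global_p = (1 + sum(core$rss_sim >= core$rss_obs)) / (n_sim + 1),
    n_sim = n_sim,
    seed = seed
  )
}

#' MR-PRESSO per-variant outlier test
#'
#' Each variant's observed residual contribution is compared with its own
#' simulated null distribution; the resulting per-variant p-values are
#' Bonferroni-multiplied by the number of instruments and variants with
#' adjusted p < `flag_threshold` are flagged.
#'
#' @inheritParams mr_presso_global
#' @param flag_threshold Adjusted-p threshold for flagging (default 0.05).
#' @return List: `per_snp_p` (named, Bonferroni-adjusted), `outliers`
#'   (character vector of flagged variant ids).
#' @export
mr_presso_outliers <- function(h, n_sim = 1000, seed, flag_threshold = 0.05) {
  core <- presso_core(h, n_sim, seed)
  p_raw <- rowMeans(core$d_sim >= core$d_obs)
  p_adj <- pmin(p_raw * nrow(h), 1)
  names(p_adj) <- h$variant_id
  list(per_snp_p = p_adj,
       outliers = h$variant_id[p_adj < flag_threshold])
}

#' MR-PRESSO distortion test
#'
#' Quantifies how much the flagged outliers distort the IVW estimate:
#' `100 * (b_raw - b_corrected) / |b_corrected|`, with an empirical null
#' built by treating random outlier-sized subsets as outliers.
#'
#' @param h An `mr_harmonized` tibble.
#' @param outliers Character vector of flagged variant ids (non-empty, not
#'   all variants).
#' @inheritParams mr_presso_global
#' @return List: `b_raw`, `b_corrected`, `distortion`, `distortion_p`.
#' @export
mr_presso_distortion <- function(h, outliers, n_sim = 1000, seed) {
  if (length(outliers) == 0) {
    stop_mrpath("Distortion test requires a non-empty outlier set.",
                "mrpath_error_usage")
  }
  if (all(h$variant_id %in% outliers)) {
    stop_mrpath("Distortion test undefined when every variant is an outlier.",
                "mrpath_error_degenerate")
  }
  b_raw <- mr_ivw(h, mode = "fixed")$b
  keep <- !(h$variant_id %in% outliers)
  b_corrected <- mr_ivw(h[keep, ], mode = "fixed")$b
  stat_obs <- 100 * (b_raw - b_corrected) / abs(b_corrected)
  k <- sum(!keep)
  stat_sim <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      drop_idx <- sample(nrow(h), k)
      b_c <- mr_ivw(h[-drop_idx, ], mode = "fixed")$b
      100 * (b_raw - b_c) / abs(b_c)
    }, numeric(1))
  })
  list(
    b_raw = b_raw,
    b_corrected = b_corrected,
    distortion = stat_obs,
    distortion_p = (1 + sum(abs(stat_sim) >= abs(stat_obs))) / (n_sim + 1)
  )
}

#' Full MR-PRESSO analysis
#'
#' Runs the global test, the per-variant outlier test, and — when outliers
#' are flagged — the distortion test with outlier-corrected IVW
#' re-estimation.
#'
#' @inheritParams mr_presso_outliers
#' @return An object of class `mr_presso`: `rss_obs`, `global_p`,
#'   `per_snp_p`, `outliers`, `b_raw`, `b_corrected`, `distortion`,
#'   `distortion_p`, `n_sim`, `seed`. Corrected-estimate fields are `NA`
#'   when no outlier is flagged.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, flag_threshold = 0.05) {
  core <- presso_core(h, n_sim, seed)
  global_p <- (1 + sum(core$rss_sim >= core$rss_obs)) / (n_sim + 1)
  p_raw <- rowMeans(core$d_sim >= core$d_obs)
  p_adj <- stats::setNames(pmin(p_raw * nrow(h), 1), h$variant_id)
  outliers <- h$variant_id[p_adj < flag_threshold]
  res <- list(
    rss_obs = core$rss_obs, global_p = global_p, per_snp_p = p_adj,
    outliers = outliers, b_raw = mr_ivw(h, mode = "fixed")$b,
    b_corrected = NA_real_, distortion = NA_real_, distortion_p = NA_real_,
    n_sim = n_sim, seed = seed
  )
  if (length(outliers) > 0 && length(outliers) < nrow(h)) {
    dist <- mr_presso_distortion(h, outliers, n_sim = n_sim, seed = seed)
    res$b_corrected <- dist$b_corrected
    res$distortion <- dist$distortion
    res$distortion_p <- dist$distortion_p
  }
  class(res) <- "mr_presso"
  res
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d)\n", x$n_sim))
  cat(sprintf("  RSS = %.4f, global p = %.4g\n", x$rss_obs, x$global_p))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers: %s\n", paste(x$outliers, collapse = ", ")))
    cat(sprintf("  b raw = %.4f, corrected = %.4f (distortion p = %.3g)\n",
                x$b_raw, x$b_corrected, x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Serialize an MR-PRESSO result to JSON
#' @param x An `mr_presso` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presso_report <- function(x, path) {
  jsonlite::write_json(
    list(rss_obs = x$rss_obs, global_p = x$global_p,
         per_snp_p = as.list(x$per_snp_p),
         outliers = x$outliers, b_raw = x$b_raw,
         b_corrected = x$b_corrected, distortion = x$distortion,
         distortion_p = x$distortion_p, n_sim = x$n_sim, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
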