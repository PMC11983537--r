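# Orchestration: full MR runs (forward, bidirectional, mediation screen)
# from a single run configuration, with TSV/JSON reporting.

#' Build or read a run configuration
#'
#' A run configuration names the study tables (paths to TSV files or
#' in-memory tibbles), the instrument-selection thresholds, analysis flags
#' and the seed. `read_run_config()` loads the same structure from a YAML
#' file (paths only).
#'
#' @param studies Named list of summary-statistics tables: each element a
#'   file path or a validated tibble.
#' @param thresholds List from [instrument_thresholds()].
#' @param ld Optional LD table (path or tibble).
#' @param presso Run MR-PRESSO in [run_pair()] (default `TRUE`).
#' @param n_boot Bootstrap iterations for weighted-median SEs and mediation
#'   proportion CIs.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Integer seed used for every stochastic component.
#' @param out Optional output directory; when set, report tables are
#'   written under it.
#' @return A `run_config` list with tables resolved to tibbles.
#' @export
run_config <- function(studies, thresholds = instrument_thresholds(),
                       ld = NULL, presso = TRUE, n_boot = 1000,
                       n_sim = 1000, seed = 1L, out = NULL) {
  stopifnot(is.list(studies), length(studies) >= 2)
  if (is.null(names(studies)) || any(names(studies) == "")) {
    stop_mrpath("`studies` must be a fully named list.", "mrpath_error_config")
  }
  resolve <- function(x, label) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop_mrpath(paste0("Study '", label, "': file not found: ", x),
                    "mrpath_error_config")
      }
      return(read_summary_stats(x, dialect = mrpath_dialect()))
    }
    validate_variants(x)
  }
  studies <- purrr::imap(studies, resolve)
  if (is.character(ld)) ld <- read_ld_table(ld)
  structure(
    list(studies = studies, thresholds = thresholds, ld = ld,
         presso = presso, n_boot = n_boot, n_sim = n_sim,
         seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file with keys `studies` (name: path mapping),
#'   optional `thresholds`, `ld`, `presso`, `n_boot`, `n_sim`, `seed`,
#'   `out`. Relative paths are resolved against the file's directory.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  thr <- do.call(instrument_thresholds,
                 if (is.null(raw$thresholds)) list() else raw$thresholds)
  run_config(
    studies = lapply(raw$studies, rel),
    thresholds = thr,
    ld = rel(raw$ld),
    presso = isTRUE(raw$presso) || is.null(raw$presso),
    n_boot = raw$n_boot %||% 1000,
    n_sim = raw$n_sim %||% 1000,
    seed = raw$seed %||% 1L,
    out = raw$out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(bundle, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$results, file.path(dir, paste0(stem, "_results.tsv")))
  readr::write_tsv(bundle$scatter, file.path(dir, paste0(stem, "_scatter.tsv")))
  readr::write_tsv(bundle$funnel, file.path(dir, paste0(stem, "_funnel.tsv")))
  readr::write_tsv(bundle$leave_one_out,
                   file.path(dir, paste0(stem, "_leave_one_out.tsv")))
  readr::write_tsv(attr(bundle$harmonized, "actions"),
                   file.path(dir, paste0(stem, "_harmonization.tsv")))
  jsonlite::write_json(bundle$log, file.path(dir, paste0(stem, "_log.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run one exposure-outcome MR analysis
#'
#' Instrument selection, harmonization, the estimator battery (IVW with
#' automatic fixed/random choice, MR-Egger, weighted median), Cochran's Q,
#' leave-one-out and (optionally) MR-PRESSO, plus plot-ready data tables.
#' When the configuration names an output directory, every table and a JSON
#' run log (thresholds, seed, instrument counts, filter log) are written
#' under it.
#'
#' @param cfg A [run_config()].
#' @param exposure_label,outcome_label Names of studies in `cfg$studies`.
#' @return A report bundle: list with `instruments`, `harmonized`,
#'   `results` (tidy per-method table), `heterogeneity`, `leave_one_out`,
#'   `presso` (or `NULL`), `scatter`, `funnel`, `log`.
#' @export
run_pair <- function(cfg, exposure_label, outcome_label) {
  stopifnot(inherits(cfg, "run_config"))
  exposure <- cfg$studies[[exposure_label]]
  outcome <- cfg$studies[[outcome_label]]
  if (is.null(exposure) || is.null(outcome)) {
    stop_mrpath("Unknown study label.", "mrpath_error_config")
  }
  iv <- select_instruments(exposure, outcome, thresholds = cfg$thresholds,
                           ld = cfg$ld)
  h <- harmonize_pair(iv, outcome)
  results <- mr_all_methods(h, n_boot = cfg$n_boot, seed = cfg$seed)
  results <- dplyr::bind_cols(
    tibble(exposure = exposure_label, outcome = outcome_label,
           .rows = nrow(results)),
    results
  )
  het <- if (nrow(h) >= 2) cochran_q(h) else NULL
  loo <- if (nrow(h) >= 3) leave_one_out(h) else NULL
  presso <- NULL
  if (isTRUE(cfg$presso) && nrow(h) >= 4) {
    presso <- mr_presso(h, n_sim = cfg$n_sim, seed = cfg$seed)
  }
  bundle <- list(
    instruments = iv,
    harmonized = h,
    results = results,
    heterogeneity = het,
    leave_one_out = loo,
    presso = presso,
    scatter = scatter_data(h),
    funnel = funnel_data(h),
    log = list(
      exposure = exposure_label, outcome = outcome_label,
      thresholds = cfg$thresholds, seed = cfg$seed,
      n_boot = cfg$n_boot, n_sim = cfg$n_sim,
      nsnp = nrow(h),
      filter_log = as.list(attr(iv, "filter_log")),
      aggregate_f = attr(iv, "aggregate_f"),
      presso_global_p = if (is.null(presso)) NULL else presso$global_p
    )
  )
  if (!is.null(cfg$out)) {
    write_report(bundle, cfg$out,
                 paste0(exposure_label, "_to_", outcome_label))
  }
  bundle
}

#' Run an MR analysis in both directions
#'
#' [run_pair()] with the exposure and outcome roles swapped in the second
#' run; a per-direction error (for example no instruments for the reverse
#' direction) is captured in that direction's slot rather than aborting the
#' other. The `summary` element flags whether each direction's IVW estimate
#' is significant at 0.05 — significance in both warns of reverse causation.
#'
#' @param cfg A [run_config()].
#' @param a_label,b_label Study labels.
#' @return List: `forward`, `reverse` (bundles or error conditions),
#'   `summary` tibble.
#' @export
run_bidirectional <- function(cfg, a_label, b_label) {
  run_safe <- function(x_lab, y_lab) {
    tryCatch(run_pair(cfg, x_lab, y_lab), mrpath_error = function(e) e)
  }
  forward <- run_safe(a_label, b_label)
  reverse <- run_safe(b_label, a_label)
  sig <- function(bundle) {
    if (inherits(bundle, "condition")) return(NA)
    ivw <- bundle$results[bundle$results$method %in% c("IVW", "IVW-random"), ]
    ivw$p_value[1] < 0.05
  }
  list(
    forward = forward, reverse = reverse,
    summary = tibble(
      direction = c(paste(a_label, "->", b_label),
                    paste(b_label, "->", a_label)),
      significant = c(sig(forward), sig(reverse))
    )
  )
}

#' Screen candidate mediators of an exposure-outcome effect
#'
#' Runs [two_step_mediation()] for each candidate mediator; a mediator is
#' admitted when its step-1 and exposure-adjusted step-2 effects are both
#' significant at 0.05. Per-mediator failures are recorded inline rather
#' than aborting the screen.
#'
#' @param cfg A [run_config()].
#' @param exposure_label,outcome_label Study labels.
#' @param mediator_labels Character vector of candidate mediator labels.
#' @return Tibble with one row per mediator (tidy mediation columns plus
#'   `error` for failed candidates), in the order given.
#' @export
run_mediation_screen <- function(cfg, exposure_label, mediator_labels,
                                 outcome_label) {
  rows <- purrr::map(mediator_labels, function(m_lab) {
    res <- tryCatch(
      two_step_mediation(
        cfg$studies[[exposure_label]], cfg$studies[[m_lab]],
        cfg$studies[[outcome_label]],
        thresholds = cfg$thresholds, ld = cfg$ld,
        n_boot = cfg$n_boot, seed = cfg$seed, mediator_label = m_lab
      ),
      mrpath_error = function(e) e
    )
    if (inherits(res, "condition")) {
      return(tibble(mediator = m_lab, admitted = FALSE,
                    error = conditionMessage(res)))
    }
    dplyr::mutate(tidy(res), error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out, file.path(cfg$out, paste0(
      exposure_label, "_to_", outcome_label, "_mediation.tsv")))
  }
  out
}
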