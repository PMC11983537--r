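# Summary-statistic-level simulator for a two-step MR study design:
# exposure -> mediator -> outcome with a direct exposure -> outcome path.
#
# The structural model has two instrument classes. Exposure instruments
# carry per-SNP effects gamma_j on the exposure; their marginal effects are
# gamma_j (exposure), alpha * gamma_j (mediator) and
# (tau + alpha * beta1) * gamma_j + pleiotropy (outcome). Mediator
# instruments carry delta_j on the mediator only: zero on the exposure,
# delta_j on the mediator, beta1 * delta_j + pleiotropy on the outcome.
# Mediator-specific instruments are what identify the multivariable-MR
# direct effect; without them the exposure- and mediator-effect columns are
# collinear in truth.

#' Configuration for a simulated two-step MR study
#'
#' Defaults are the package's reference study conditions: 100 exposure
#' instruments and 100 mediator instruments, GWAS sample sizes of 100,000,
#' structural effects `alpha = -0.2` (exposure on mediator),
#' `beta1 = 0.5` (mediator on outcome) and `tau = -0.7` (direct exposure on
#' outcome), giving a total effect of -0.8 and a true proportion mediated of
#' 12.5%.
#'
#' @param n_snps Number of exposure instruments (>= 4).
#' @param n_snps_mediator Number of mediator-specific instruments.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100).
#' @param alpha_true,beta1_true,tau_true Structural effects.
#' @param gamma_sd SD of per-SNP instrument effects (both classes).
#' @param pleiotropy List describing the horizontal-pleiotropy model:
#'   `list(type = "none")`; `list(type = "balanced", sd = )`;
#'   `list(type = "directional", mean = , sd = )`; or
#'   `list(type = "inside", cor = , sd = )` for pleiotropic effects
#'   correlated with instrument strength (an InSIDE violation).
#' @param maf_range Interval within (0, 0.5\] for uniform minor allele
#'   frequencies.
#' @param ld_blocks Optional `list(size = , r2 = , n_blocks = )` giving
#'   constant within-block LD among the first `size * n_blocks` exposure
#'   instruments (block members are placed within clumping distance).
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G allele
#'   pairs (default 0).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, n_snps_mediator = n_snps,
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 1e5,
                       alpha_true = -0.2, beta1_true = 0.5, tau_true = -0.7,
                       gamma_sd = 0.05,
                       pleiotropy = list(type = "none"),
                       maf_range = c(0.05, 0.5),
                       ld_blocks = NULL,
                       palindromic_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_snps = n_snps, n_snps_mediator = n_snps_mediator,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    alpha_true = alpha_true, beta1_true = beta1_true, tau_true = tau_true,
    gamma_sd = gamma_sd, pleiotropy = pleiotropy, maf_range = maf_range,
    ld_blocks = ld_blocks, palindromic_fraction = palindromic_fraction,
    seed = as.integer(seed)
  )
  problems <- character()
  if (n_snps < 4) problems <- c(problems, "n_snps must be >= 4")
  if (n_snps_mediator < 0) problems <- c(problems, "n_snps_mediator must be >= 0")
  if (min(n_exposure, n_mediator, n_outcome) < 100) {
    problems <- c(problems, "sample sizes must be >= 100")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    problems <- c(problems, "maf_range must lie within (0, 0.5]")
  }
  if (!is.list(pleiotropy) ||
      !pleiotropy$type %in% c("none", "balanced", "directional", "inside")) {
    problems <- c(problems, "pleiotropy$type must be one of none, balanced, directional, inside")
  }
  if (gamma_sd <= 0) problems <- c(problems, "gamma_sd must be > 0")
  if (palindromic_fraction < 0 || palindromic_fraction > 1) {
    problems <- c(problems, "palindromic_fraction must be in [0, 1]")
  }
  if (length(problems) > 0) {
    stop_mrpath(paste0("Invalid simulation configuration: ",
                       paste(problems, collapse = "; ")),
                "mrpath_error_config")
  }
  class(cfg) <- "sim_config"
  cfg
}

draw_pleiotropy <- function(cfg, instrument_effects) {
  n <- length(instrument_effects)
  p <- cfg$pleiotropy
  switch(p$type,
    none = rep(0, n),
    balanced = rnorm(n, 0, p$sd),
    # Directional pleiotropy acts along the trait-increasing allele of each
    # instrument, so it biases slope estimators rather than averaging out.
    directional = sign(instrument_effects) * rnorm(n, p$mean, p$sd),
    inside = {
      # Pleiotropic effects correlated with instrument strength.
      scale <- p$sd / cfg$gamma_sd
      p$cor * scale * instrument_effects +
        sqrt(1 - p$cor^2) * rnorm(n, 0, p$sd)
    }
  )
}

gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

non_palindromic_pairs <- cbind(
  ea = c("A", "A", "C", "C", "G", "G", "T", "T"),
  oa = c("C", "G", "A", "T", "A", "T", "C", "G")
)
palindromic_pairs <- cbind(ea = c("A", "T", "C", "G"),
                           oa = c("T", "A", "G", "C"))

observed_gwas <- function(ids, chrom, pos, alleles, maf, true_beta, n) {
  se <- gwas_se(n, maf)
  beta <- true_beta + rnorm(length(maf), 0, se)
  tibble(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = alleles[, "ea"], other_allele = alleles[, "oa"],
    eaf = maf, beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n
  )
}

#' Simulate a two-step MR study at the summary-statistic level
#'
#' Generates exposure, mediator and outcome GWAS summary-statistics tables
#' under the structural model described in [sim_config()], with observed
#' effects drawn around the true marginal effects using the standardized
#' GWAS standard error `1 / sqrt(2 n maf (1 - maf))` (binary-outcome effects
#' are treated directly on the log-odds scale with the same approximation).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome` (validated
#'   summary-statistics tibbles), `ld` (pairwise LD tibble, or `NULL`), and
#'   `truth` — a `sim_truth` list holding the generating parameters, per-SNP
#'   instrument effects (`gamma`, `delta`) and pleiotropy draws (`pi`), the
#'   implied `total_effect = tau + alpha * beta1`, and `proportion_true`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nx <- cfg$n_snps
  nm <- cfg$n_snps_mediator
  n_total <- nx + nm

  withr::with_seed(cfg$seed, {
    ids <- sprintf("rs%06d", seq_len(n_total))
    maf <- runif(n_total, cfg$maf_range[1], cfg$maf_range[2])

    n_pal <- round(cfg$palindromic_fraction * n_total)
    pal_rows <- sample(nrow(palindromic_pairs), n_pal, replace = TRUE)
    npal_rows <- sample(nrow(non_palindromic_pairs), n_total - n_pal,
                        replace = TRUE)
    alleles <- rbind(
      palindromic_pairs[pal_rows, , drop = FALSE],
      non_palindromic_pairs[npal_rows, , drop = FALSE]
    )[sample(n_total), , drop = FALSE]

    gamma <- rnorm(nx, 0, cfg$gamma_sd)
    delta <- if (nm > 0) rnorm(nm, 0, cfg$gamma_sd) else numeric()
    pi_all <- draw_pleiotropy(cfg, c(gamma, delta))

    true_x <- c(gamma, rep(0, nm))
    true_m <- c(cfg$alpha_true * gamma, delta)
    true_y <- c((cfg$tau_true + cfg$alpha_true * cfg$beta1_true) * gamma,
                cfg$beta1_true * delta) + pi_all

    # Positions: one clumping window per variant unless LD blocks group them.
    chrom <- as.character(rep_len(1:22, n_total))
    slot <- stats::ave(seq_len(n_total), chrom, FUN = seq_along)
    pos <- slot * 2.1e7
    ld <- NULL
    if (!is.null(cfg$ld_blocks)) {
      size <- cfg$ld_blocks$size
      n_blocks <- cfg$ld_blocks$n_blocks
      r2 <- cfg$ld_blocks$r2
      stopifnot(size >= 2, n_blocks >= 1, size * n_blocks <= n_total)
      pairs <- list()
      for (b in seq_len(n_blocks)) {
        members <- ((b - 1) * size + 1):(b * size)
        chrom[members] <- chrom[members[1]]
        pos[members] <- pos[members[1]] + (seq_len(size) - 1) * 1e4
        combos <- utils::combn(members, 2)
        pairs[[b]] <- tibble(id_a = ids[combos[1, ]],
                             id_b = ids[combos[2, ]], r2 = r2)
      }
      ld <- symmetrize_ld(dplyr::bind_rows(pairs))
    }

    exposure <- observed_gwas(ids, chrom, pos, alleles, maf, true_x,
                              cfg$n_exposure)
    mediator <- observed_gwas(ids, chrom, pos, alleles, maf, true_m,
                              cfg$n_mediator)
    outcome <- observed_gwas(ids, chrom, pos, alleles, maf, true_y,
                             cfg$n_outcome)

    total_effect <- cfg$tau_true + cfg$alpha_true * cfg$beta1_true
    truth <- structure(
      list(
        config = cfg,
        gamma = stats::setNames(gamma, ids[seq_len(nx)]),
        delta = stats::setNames(delta, ids[nx + seq_len(nm)]),
        pi = stats::setNames(pi_all, ids),
        total_effect = total_effect,
        proportion_true = 100 * cfg$alpha_true * cfg$beta1_true / total_effect
      ),
      class = "sim_truth"
    )
    list(
      exposure = validate_variants(exposure),
      mediator = validate_variants(mediator),
      outcome = validate_variants(outcome),
      ld = ld,
      truth = truth
    )
  })
}

#' Write a simulated study to disk
#'
#' Emits the three summary-statistics tables (TSV, the dialect
#' [read_summary_stats()] reads with [mrpath_dialect()]), the LD table when
#' present, and the generating truth as JSON.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(study$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(study$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(study$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(study$ld)) {
    readr::write_tsv(study$ld, file.path(dir, "ld.tsv"))
  }
  truth <- study$truth
  jsonlite::write_json(
    list(
      config = truth$config[setdiff(names(truth$config), "ld_blocks")],
      gamma = as.list(truth$gamma), delta = as.list(truth$delta),
      pi = as.list(truth$pi),
      total_effect = truth$total_effect,
      proportion_true = truth$proportion_true
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(dir)
}
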