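# Reading, validating and harmonizing GWAS summary-statistics tables.
#
# A summary-statistics table is a tibble with one row per biallelic SNP:
# variant_id, chrom, pos (optional), effect_allele, other_allele, eaf,
# beta, se, pval, n. Effect sizes for binary traits are log odds ratios.

#' Column dialect for summary-statistics files
#'
#' Maps the package's logical column names onto the header names used in a
#' particular export format. The default matches IEU-OpenGWAS-style flat
#' exports; any name can be overridden.
#'
#' @param variant_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n
#'   Column names in the file for each logical field. `chrom` and `pos` are
#'   optional in the file and may be set to `NA` to skip them.
#'
#' @return A named character vector suitable for the `dialect` argument of
#'   [read_summary_stats()].
#' @export
gwas_dialect <- function(variant_id = "SNP", chrom = "chr", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele", eaf = "eaf",
                         beta = "beta", se = "se", pval = "pval",
                         n = "samplesize") {
  c(variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-separated file with a header row, renames columns according
#' to `dialect`, uppercases alleles, and drops rows that violate the
#' per-variant invariants (positive SE, frequency in \[0, 1\], p-value in
#' (0, 1\], single-base distinct alleles, unique variant id). Rejected rows
#' are retained, with a reason each, in the `rejects` attribute.
#'
#' @param path Path to a tab-separated summary-statistics file.
#' @param dialect Named character vector from [gwas_dialect()] mapping
#'   logical names to file column names.
#'
#' @return A validated tibble of variant records with attribute `rejects`,
#'   a tibble of `(variant_id, reason)` for every dropped row.
#' @export
read_summary_stats <- function(path, dialect = gwas_dialect()) {
  if (!file.exists(path)) {
    stop_mrpath(paste0("Summary-statistics file not found: ", path),
                "mrpath_error_input")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    stop_mrpath(paste0("Summary-statistics file is empty: ", path),
                "mrpath_error_input")
  }
  required <- setdiff(names(dialect), c("chrom", "pos"))
  for (logical_name in required) {
    if (!dialect[[logical_name]] %in% names(raw)) {
      stop_mrpath(
        paste0("Required column '", dialect[[logical_name]],
               "' (", logical_name, ") is missing from ", path),
        "mrpath_error_config"
      )
    }
  }
  out <- tibble(
    variant_id = as.character(raw[[dialect[["variant_id"]]]]),
    chrom = if (!is.na(dialect[["chrom"]]) && dialect[["chrom"]] %in% names(raw)) {
      as.character(raw[[dialect[["chrom"]]]])
    } else NA_character_,
    pos = if (!is.na(dialect[["pos"]]) && dialect[["pos"]] %in% names(raw)) {
      as.numeric(raw[[dialect[["pos"]]]])
    } else NA_real_,
    effect_allele = toupper(as.character(raw[[dialect[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[dialect[["other_allele"]]]])),
    eaf = as.numeric(raw[[dialect[["eaf"]]]]),
    beta = as.numeric(raw[[dialect[["beta"]]]]),
    se = as.numeric(raw[[dialect[["se"]]]]),
    pval = as.numeric(raw[[dialect[["pval"]]]]),
    n = as.numeric(raw[[dialect[["n"]]]])
  )
  validate_variants(out)
}

#' Validate a table of variant records
#'
#' Applies the same row-level checks as [read_summary_stats()] to an
#' in-memory data frame (for example one produced by [simulate_study()]).
#'
#' @param x Data frame with the logical summary-statistics columns.
#' @return Validated tibble with a `rejects` attribute.
#' @export
validate_variants <- function(x) {
  x <- as_tibble(x)
  if (!"chrom" %in% names(x)) x$chrom <- NA_character_
  if (!"pos" %in% names(x)) x$pos <- NA_real_
  x <- x[, variant_columns]
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(!(x$effect_allele %in% bases & x$other_allele %in% bases),
                 "non-biallelic or invalid alleles")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(!(x$se > 0), "nonpositive SE")
  reason <- flag(!(x$eaf >= 0 & x$eaf <= 1), "eaf outside [0,1]")
  reason <- flag(!(x$pval > 0 & x$pval <= 1), "pval outside (0,1]")
  reason <- flag(!(x$n > 0), "nonpositive sample size")
  reason <- flag(is.na(x$variant_id) | x$variant_id == "", "missing variant id")
  reason <- flag(duplicated(x$variant_id), "duplicate variant_id")

  rejects <- tibble(variant_id = x$variant_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  kept <- x[is.na(reason), ]
  attr(kept, "rejects") <- rejects
  kept
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) oa == complement_allele(ea)

#' Align one outcome record to an exposure record's effect allele
#'
#' Implements the harmonization rules for a single shared variant: identical
#' allele pairs are kept; swapped pairs are flipped (outcome beta negated,
#' eaf reflected); strand-complement pairs are complemented and then matched;
#' palindromic (A/T or C/G) variants are dropped when either study's effect
#' allele frequency is within `palindrome_band` of 0.5, and otherwise
#' oriented by whether the two frequencies fall on the same side of 0.5;
#' anything else is dropped as incompatible.
#'
#' @param exposure,outcome One-row data frames (variant records) sharing a
#'   `variant_id`.
#' @param palindrome_band Half-width of the intermediate-frequency band
#'   around 0.5 within which palindromic variants are unresolvable. The
#'   default 0.08 drops palindromic variants with minor allele frequency
#'   above 0.42 in either study.
#'
#' @return One-row tibble: `variant_id`, `action`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome` (post-transformation; effect columns are
#'   `NA` for dropped variants), and `reason`.
#' @export
align_alleles <- function(exposure, outcome, palindrome_band = 0.08) {
  if (exposure$variant_id != outcome$variant_id) {
    stop_mrpath("align_alleles() requires records for the same variant_id.",
                "mrpath_error_usage")
  }
  ea_x <- exposure$effect_allele
  oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele
  oa_y <- outcome$other_allele

  result <- function(action, flip = FALSE, reason = NA_character_) {
    dropped <- startsWith(action, "dropped")
    tibble(
      variant_id = exposure$variant_id,
      action = action,
      beta_outcome = if (dropped) NA_real_ else if (flip) -outcome$beta else outcome$beta,
      se_outcome = if (dropped) NA_real_ else outcome$se,
      eaf_outcome = if (dropped) NA_real_ else if (flip) 1 - outcome$eaf else outcome$eaf,
      reason = reason
    )
  }

  same_set <- setequal(c(ea_x, oa_x), c(ea_y, oa_y))
  comp_set <- setequal(c(ea_x, oa_x),
                       complement_allele(c(ea_y, oa_y)))
  if (!same_set && !comp_set) {
    return(result("dropped_incompatible", reason = "allele pair mismatch"))
  }

  if (is_palindromic(ea_x, oa_x)) {
    # Strand is unresolvable from alleles; use allele frequencies.
    intermediate <- abs(exposure$eaf - 0.5) < palindrome_band |
      abs(outcome$eaf - 0.5) < palindrome_band
    if (intermediate) {
      return(result("dropped_palindromic",
                    reason = "palindromic with intermediate allele frequency"))
    }
    same_side <- (exposure$eaf - 0.5) * (outcome$eaf - 0.5) > 0
    if (same_side) {
      return(result("kept", reason = "palindromic, frequencies concordant"))
    }
    return(result("flipped", flip = TRUE,
                  reason = "palindromic, frequencies discordant"))
  }

  if (same_set) {
    if (ea_x == ea_y) return(result("kept"))
    return(result("flipped", flip = TRUE))
  }
  # Strand complement: complement the outcome alleles, then match.
  if (ea_x == complement_allele(ea_y)) {
    return(result("strand_complemented"))
  }
  result("strand_complemented", flip = TRUE)
}

#' Harmonize an exposure instrument table with an outcome table
#'
#' Inner-joins the two tables on `variant_id` (in exposure input order) and
#' applies [align_alleles()] per variant. Dropped variants are excluded from
#' the harmonized effect arrays but recorded, along with exposure variants
#' absent from the outcome table, in the `actions` attribute.
#'
#' @param exposure,outcome Validated summary-statistics tibbles.
#' @param palindrome_band Passed to [align_alleles()].
#'
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `chrom`, `pos`, `eaf_exposure`,
#'   `beta_exposure`, `se_exposure`, `eaf_outcome`, `beta_outcome`,
#'   `se_outcome`, `action`; attribute `actions` is the full audit tibble
#'   `(variant_id, action, reason)`.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_band = 0.08) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop_mrpath(
      "No shared variants between the exposure and outcome tables.",
      "mrpath_error_empty_set"
    )
  }
  exp_shared <- exposure[exposure$variant_id %in% shared, ]
  out_idx <- match(exp_shared$variant_id, outcome$variant_id)

  aligned <- purrr::map_dfr(seq_len(nrow(exp_shared)), function(i) {
    align_alleles(exp_shared[i, ], outcome[out_idx[i], ],
                  palindrome_band = palindrome_band)
  })

  h <- tibble(
    variant_id = exp_shared$variant_id,
    effect_allele = exp_shared$effect_allele,
    other_allele = exp_shared$other_allele,
    chrom = exp_shared$chrom,
    pos = exp_shared$pos,
    eaf_exposure = exp_shared$eaf,
    beta_exposure = exp_shared$beta,
    se_exposure = exp_shared$se,
    eaf_outcome = aligned$eaf_outcome,
    beta_outcome = aligned$beta_outcome,
    se_outcome = aligned$se_outcome,
    action = aligned$action
  )
  unmatched <- setdiff(exposure$variant_id, shared)
  actions <- dplyr::bind_rows(
    tibble(variant_id = aligned$variant_id, action = aligned$action,
           reason = aligned$reason),
    tibble(variant_id = unmatched,
           action = rep("dropped_unmatched", length(unmatched)),
           reason = rep("absent from outcome table", length(unmatched)))
  )
  h <- h[!startsWith(h$action, "dropped"), ]
  class(h) <- c("mr_harmonized", class(h))
  attr(h, "actions") <- actions
  h
}

#' Harmonize several exposures and one outcome to a common effect allele
#'
#' Orientation is anchored on the first exposure: the outcome and every
#' additional exposure are aligned to its effect alleles, and only variants
#' retained in every pairwise harmonization are kept.
#'
#' @param exposures Named list of validated summary-statistics tibbles
#'   (two or more).
#' @param outcome Validated outcome summary-statistics tibble.
#' @param palindrome_band Passed to [align_alleles()].
#'
#' @return A tibble of class `mr_harmonized_mv`: `variant_id`, allele and
#'   position columns, one `beta_<label>`/`se_<label>` pair per exposure,
#'   and `beta_outcome`/`se_outcome`. Attribute `exposures` holds the labels.
#' @export
harmonize_mvmr <- function(exposures, outcome, palindrome_band = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 2)
  labels <- names(exposures)
  if (is.null(labels) || any(labels == "")) {
    stop_mrpath("`exposures` must be a fully named list.", "mrpath_error_usage")
  }
  anchor <- harmonize_pair(exposures[[1]], outcome,
                           palindrome_band = palindrome_band)
  out <- tibble(
    variant_id = anchor$variant_id,
    effect_allele = anchor$effect_allele,
    other_allele = anchor$other_allele,
    chrom = anchor$chrom,
    pos = anchor$pos,
    beta_outcome = anchor$beta_outcome,
    se_outcome = anchor$se_outcome
  )
  out[[paste0("beta_", labels[1])]] <- anchor$beta_exposure
  out[[paste0("se_", labels[1])]] <- anchor$se_exposure

  # Re-use the pairwise aligner with the anchor playing the exposure role,
  # so each extra exposure's betas land on the anchor's effect allele.
  anchor_as_table <- tibble(
    variant_id = anchor$variant_id, chrom = anchor$chrom, pos = anchor$pos,
    effect_allele = anchor$effect_allele, other_allele = anchor$other_allele,
    eaf = anchor$eaf_exposure, beta = anchor$beta_exposure,
    se = anchor$se_exposure, pval = 1, n = 1
  )
  for (k in seq_along(labels)[-1]) {
    hk <- harmonize_pair(anchor_as_table, exposures[[k]],
                         palindrome_band = palindrome_band)
    idx <- match(out$variant_id, hk$variant_id)
    out[[paste0("beta_", labels[k])]] <- hk$beta_outcome[idx]
    out[[paste0("se_", labels[k])]] <- hk$se_outcome[idx]
  }
  keep <- stats::complete.cases(
    out[, c(paste0("beta_", labels), "beta_outcome")]
  )
  out <- out[keep, ]
  class(out) <- c("mr_harmonized_mv", class(out))
  attr(out, "exposures") <- labels
  out
}

#' Write the harmonization audit trail as TSV
#'
#' @param h An `mr_harmonized` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(h, path) {
  readr::write_tsv(attr(h, "actions"), path)
  invisible(path)
}

#' Write a summary-statistics table as TSV
#'
#' Writes the package's logical column layout; round-trips through
#' [read_summary_stats()] with the identity dialect below.
#'
#' @param x Summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  readr::write_tsv(as_tibble(x)[, intersect(variant_columns, names(x))], path)
  invisible(path)
}

#' Identity dialect matching [write_summary_stats()] output
#' @return A named character vector for [read_summary_stats()].
#' @export
mrpath_dialect <- function() {
  gwas_dialect(variant_id = "variant_id", chrom = "chrom", pos = "pos",
               eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}
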