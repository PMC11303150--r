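#' Canonical column set for GWAS summary statistics
#'
#' Every stage of the package consumes per-variant association records with
#' these columns: `snp_id`, `chrom`, `pos` (1-based bp), `effect_allele`,
#' `other_allele` (single bases A/C/G/T), `eaf` (effect-allele frequency),
#' `beta`, `se`, `pvalue`, `n` (sample size).
#'
#' @keywords internal
#' @name summary-stats-columns
NULL

SUMMARY_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

BASES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics tibble
#'
#' Coerces a data frame of per-variant GWAS associations to the package's
#' canonical layout, dropping rows that violate the record invariants
#' (`se > 0`, `eaf` in \[0, 1\], `pvalue` in (0, 1\], `n > 0`, single-base
#' alleles with `effect_allele != other_allele`). Duplicate `snp_id`s are
#' resolved first-occurrence-wins. The number of dropped rows is recorded in
#' the `n_dropped` attribute and reported via a message.
#'
#' @param data Data frame with the columns listed in
#'   [summary-stats-columns].
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"case-control"`.
#' @param quiet Suppress the dropped-row message.
#'
#' @return A tibble of class `summary_stats` with attributes `trait_id`,
#'   `trait_type` and `n_dropped`.
#' @export
#' @examples
#' ss <- summary_stats(tibble::tibble(
#'   snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'   effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'   eaf = c(0.3, 0.4), beta = c(0.1, -0.05), se = c(0.01, 0.02),
#'   pvalue = c(1e-10, 1e-8), n = 10000
#' ), trait_id = "LDL", trait_type = "quantitative")
summary_stats <- function(data, trait_id = "trait",
                          trait_type = c("quantitative", "case-control"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMMARY_COLS, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "targetmr_config_error"
    )
  }
  out <- as_tibble(data[SUMMARY_COLS])
  out$snp_id <- as.character(out$snp_id)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    out[[col]] <- as.numeric(out[[col]])
  }

  ok <- !is.na(out$snp_id) & !is.na(out$beta) &
    !is.na(out$se) & out$se > 0 &
    !is.na(out$eaf) & out$eaf >= 0 & out$eaf <= 1 &
    !is.na(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    !is.na(out$n) & out$n > 0 &
    out$effect_allele %in% BASES & out$other_allele %in% BASES &
    out$effect_allele != out$other_allele
  dup <- duplicated(out$snp_id)
  keep <- ok & !dup
  n_dropped <- sum(!keep)
  out <- out[keep, ]
  if (n_dropped > 0 && !quiet) {
    inform(paste0(
      "summary_stats [", trait_id, "]: dropped ", n_dropped,
      " row(s) failing record invariants or duplicating snp_id"
    ))
  }
  if (nrow(out) == 0) {
    abort("no valid summary-statistic rows remain", class = "targetmr_empty_error")
  }
  structure(out,
    class = c("summary_stats", class(out)),
    trait_id = trait_id, trait_type = trait_type, n_dropped = n_dropped
  )
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a TSV or CSV file (delimiter auto-detected from the header line),
#' renames columns via `column_map`, and validates the result with
#' [summary_stats()].
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(snp_id = "SNP", beta = "b")`. Canonical
#'   names already present in the file need no entry.
#' @inheritParams summary_stats
#'
#' @return A `summary_stats` tibble.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = "trait",
                               trait_type = c("quantitative", "case-control"),
                               quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "targetmr_config_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad) > 0) {
      abort(
        paste0("column_map refers to absent column(s): ",
               paste(bad, collapse = ", ")),
        class = "targetmr_config_error"
      )
    }
    names(raw)[match(unname(column_map), names(raw))] <- names(column_map)
  }
  summary_stats(raw, trait_id = trait_id, trait_type = trait_type, quiet = quiet)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Intersects the two traits on `snp_id` and aligns the outcome records to the
#' exposure's effect allele. When the outcome's alleles are swapped relative to
#' the exposure, the outcome beta is negated and its effect-allele frequency
#' complemented. Strand-ambiguous (palindromic, A/T or C/G) variants are
#' removed under `palindrome_policy = "drop"` (the default); under `"infer"`
#' they are aligned by allele frequency and removed only when the minor-allele
#' frequency exceeds `maf_infer_threshold` for either trait (too close to 0.5
#' to orient). Variants whose alleles match neither directly nor swapped are
#' dropped as unmatched.
#'
#' @param exposure,outcome `summary_stats` tibbles (or data frames with the
#'   canonical columns).
#' @param palindrome_policy `"drop"` or `"infer"`.
#' @param maf_infer_threshold Frequency above which a palindromic variant is
#'   considered unresolvable under `"infer"`.
#'
#' @return A tibble of class `harmonized_set` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `n_exposure`, `n_outcome`, `chrom`, `pos`, `palindromic`, and attributes
#'   `flipped`, `dropped_palindromic`, `dropped_unmatched`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer"),
                      maf_infer_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("exposure and outcome must be non-empty", class = "targetmr_empty_error")
  }

  ex <- as_tibble(exposure)
  ou <- as_tibble(outcome)
  m <- dplyr::inner_join(
    ex %>% select("snp_id", "chrom", "pos",
                  ea_x = "effect_allele", oa_x = "other_allele",
                  eaf_x = "eaf", beta_x = "beta", se_x = "se", n_x = "n"),
    ou %>% select("snp_id", ea_y = "effect_allele", oa_y = "other_allele",
                  eaf_y = "eaf", beta_y = "beta", se_y = "se", n_y = "n"),
    by = "snp_id"
  )
  if (nrow(m) == 0) {
    abort("no shared snp_id between exposure and outcome",
          class = "targetmr_empty_error")
  }
  n_intersect <- nrow(m)

  same <- m$ea_y == m$ea_x & m$oa_y == m$oa_x
  swapped <- m$ea_y == m$oa_x & m$oa_y == m$ea_x
  matched <- same | swapped
  dropped_unmatched <- sum(!matched)
  m <- m[matched, ]
  swapped <- swapped[matched]

  # align outcome to the exposure effect allele
  m$beta_y[swapped] <- -m$beta_y[swapped]
  m$eaf_y[swapped] <- 1 - m$eaf_y[swapped]

  pal <- is_palindromic(m$ea_x, m$oa_x)
  dropped_palindromic <- 0L
  if (palindrome_policy == "drop") {
    dropped_palindromic <- sum(pal)
    m <- m[!pal, ]
    swapped <- swapped[!pal]
    pal <- pal[!pal]
  } else {
    # infer orientation from allele frequency: if the two traits sit on
    # opposite sides of 0.5 the outcome is presumed strand-flipped
    too_common <- pal &
      (pmin(m$eaf_x, 1 - m$eaf_x) > maf_infer_threshold |
         pmin(m$eaf_y, 1 - m$eaf_y) > maf_infer_threshold)
    disagree <- pal & !too_common & ((m$eaf_x - 0.5) * (m$eaf_y - 0.5) < 0)
    m$beta_y[disagree] <- -m$beta_y[disagree]
    m$eaf_y[disagree] <- 1 - m$eaf_y[disagree]
    swapped <- xor(swapped, disagree)   # net orientation changes
    dropped_palindromic <- sum(too_common)
    keep <- !too_common
    m <- m[keep, ]
    swapped <- swapped[keep]
    pal <- pal[keep]
  }
  flipped <- sum(swapped)               # flips among retained variants

  out <- tibble(
    snp_id = m$snp_id,
    effect_allele = m$ea_x, other_allele = m$oa_x,
    beta_exposure = m$beta_x, se_exposure = m$se_x, eaf_exposure = m$eaf_x,
    beta_outcome = m$beta_y, se_outcome = m$se_y, eaf_outcome = m$eaf_y,
    n_exposure = m$n_x, n_outcome = m$n_y,
    chrom = m$chrom, pos = m$pos, palindromic = pal
  )
  structure(out,
    class = c("harmonized_set", class(out)),
    flipped = flipped,
    dropped_palindromic = as.integer(dropped_palindromic),
    dropped_unmatched = as.integer(dropped_unmatched),
    exposure_id = attr(exposure, "trait_id") %||% "exposure",
    outcome_id = attr(outcome, "trait_id") %||% "outcome",
    outcome_type = attr(outcome, "trait_type") %||% "quantitative"
  )
}

#' Write a harmonized set as TSV with a fixed column order
#'
#' @param h A `harmonized_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  cols <- c("snp_id", "effect_allele", "other_allele",
            "beta_exposure", "se_exposure", "eaf_exposure",
            "beta_outcome", "se_outcome", "n_exposure", "n_outcome")
  readr::write_tsv(as_tibble(h)[cols], path, progress = FALSE)
  invisible(path)
}

#' Harmonization bookkeeping counts
#'
#' @param h A `harmonized_set` tibble.
#' @return A one-row tibble with `n_snp`, `flipped`, `dropped_palindromic`,
#'   `dropped_unmatched`.
#' @export
harmonization_counts <- function(h) {
  tibble(
    n_snp = nrow(h),
    flipped = attr(h, "flipped"),
    dropped_palindromic = attr(h, "dropped_palindromic"),
    dropped_unmatched = attr(h, "dropped_unmatched")
  )
}
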