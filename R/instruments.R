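#' Read a square LD matrix from TSV
#'
#' The file must be a square table of squared correlations with snp_ids as
#' both the header row and the first column.
#'
#' @param path Path to the TSV.
#' @return A symmetric numeric matrix with unit diagonal, snp_ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("LD matrix needs snp_id dimnames", class = "targetmr_config_error")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
      any(abs(diag(m) - 1) > 1e-8) || any(m < -1e-12 | m > 1 + 1e-12)) {
    abort("LD matrix must be symmetric with unit diagonal and entries in [0,1]",
          class = "targetmr_config_error")
  }
  m
}

#' Filter to genome-wide-significant, common variants
#'
#' Retains records with `pvalue < p_threshold` (strict) and minor-allele
#' frequency `min(eaf, 1 - eaf) > maf_min` (strict).
#'
#' @param stats A `summary_stats` tibble.
#' @param p_threshold Significance threshold; default the genome-wide
#'   5e-8.
#' @param maf_min Minimum minor-allele frequency; default 0.01.
#' @return The filtered tibble (possibly empty), attributes preserved.
#' @export
filter_significant <- function(stats, p_threshold = 5e-8, maf_min = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1, maf_min >= 0, maf_min < 0.5)
  keep <- stats$pvalue < p_threshold & pmin(stats$eaf, 1 - stats$eaf) > maf_min
  restore_stats_attrs(stats[keep, ], stats)
}

restore_stats_attrs <- function(new, old) {
  structure(new,
    class = class(old),
    trait_id = attr(old, "trait_id"), trait_type = attr(old, "trait_type"),
    n_dropped = attr(old, "n_dropped")
  )
}

ld_r2_lookup <- function(ld, id_a, id_b) {
  # variants absent from the supplied matrix are treated as uncorrelated
  if (is.null(ld)) return(0)
  if (!(id_a %in% rownames(ld)) || !(id_b %in% rownames(ld))) return(0)
  ld[id_a, id_b]
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' removes every other variant on the same chromosome within `window_kb`
#' of it whose squared correlation with it is at least `r2_threshold`.
#' Ties on p-value are broken by position, then lexicographic `snp_id`, so
#' the result does not depend on input row order. Variants missing from
#' `ld` are treated as uncorrelated (with a warning).
#'
#' @param stats A `summary_stats` tibble.
#' @param ld Symmetric squared-correlation matrix with snp_id dimnames, or
#'   `NULL` for fully independent variants.
#' @param r2_threshold Squared-correlation threshold; default 0.001 (the
#'   stringent trait-level setting).
#' @param window_kb Window in kilobases; default 10000.
#' @return The kept subset, ordered by chromosome and position.
#' @export
clump <- function(stats, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(stats) <= 1) return(stats)
  if (!is.null(ld)) {
    missing_ld <- setdiff(stats$snp_id, rownames(ld))
    if (length(missing_ld) > 0) {
      warn(paste0(length(missing_ld),
                  " variant(s) absent from LD matrix; treated as uncorrelated"))
    }
  }
  window_bp <- window_kb * 1000
  ord <- order(stats$pvalue, stats$pos, stats$snp_id)
  pending <- stats[ord, ]
  kept <- character(0)
  while (nrow(pending) > 0) {
    top <- pending[1, ]
    kept <- c(kept, top$snp_id)
    in_window <- pending$chrom == top$chrom &
      abs(pending$pos - top$pos) <= window_bp &
      pending$snp_id != top$snp_id
    r2 <- vapply(pending$snp_id, ld_r2_lookup, numeric(1),
                 ld = ld, id_b = top$snp_id, USE.NAMES = FALSE)
    drop <- in_window & r2 >= r2_threshold
    pending <- pending[!drop & pending$snp_id != top$snp_id, ]
  }
  out <- stats[stats$snp_id %in% kept, ]
  out <- out[order(out$chrom, out$pos, out$snp_id), ]
  restore_stats_attrs(out, stats)
}

#' Variance in the exposure explained by one variant
#'
#' Computes
#' \deqn{R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
#'   {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
#'    2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,\mathrm{SE}(\beta)^2},}
#' which simplifies to \eqn{\beta^2 / (\beta^2 + N\,\mathrm{SE}^2)}; the full
#' form is evaluated as written.
#'
#' @param beta Per-allele effect estimate.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param se Standard error of `beta`.
#' @param n Sample size.
#' @return Proportion of variance explained, vectorized.
#' @export
snp_r2 <- function(beta, eaf, se, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    abort("eaf must lie strictly inside (0, 1)", class = "targetmr_degenerate_error")
  }
  stopifnot(all(se > 0), all(n > 1))
  het <- 2 * eaf * (1 - eaf)
  (het * beta^2) / (het * beta^2 + het * n * se^2)
}

#' Instrument-strength F statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}. Instruments with \eqn{F \le 10} are
#' conventionally flagged weak.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size (> 2).
#' @return F statistic, vectorized.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 >= 1)) {
    abort("r2 must be < 1", class = "targetmr_degenerate_error")
  }
  stopifnot(all(r2 >= 0), all(n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Restrict summary statistics to a gene window
#'
#' Keeps variants on `region$chrom` with position in the closed interval
#' `[start - window_kb * 1000, end + window_kb * 1000]`.
#'
#' @param stats A `summary_stats` tibble.
#' @param region A list or one-row data frame with `gene`, `chrom`, `start`,
#'   `end` (1-based, closed).
#' @param window_kb Flanking window in kilobases.
#' @return The restricted tibble.
#' @export
restrict_to_region <- function(stats, region, window_kb = 250) {
  stopifnot(region$start <= region$end)
  lo <- region$start - window_kb * 1000
  hi <- region$end + window_kb * 1000
  keep <- stats$chrom == as.character(region$chrom) &
    stats$pos >= lo & stats$pos <= hi
  restore_stats_attrs(stats[keep, ], stats)
}

#' Read gene regions from a BED-like TSV
#'
#' Expects columns `chrom`, `start`, `end`, `gene` (1-based closed
#' coordinates).
#'
#' @param path Path to the TSV.
#' @return A tibble of gene regions.
#' @export
read_gene_regions <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("chrom", "start", "end", "gene"), names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("gene-region file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "targetmr_config_error")
  }
  if (any(out$start > out$end)) {
    abort("gene region with start > end", class = "targetmr_config_error")
  }
  out$chrom <- as.character(out$chrom)
  as_tibble(out)
}

finalize_instrument_set <- function(stats, selection_params, f_min = 10) {
  if (nrow(stats) == 0) {
    out <- as_tibble(stats)
    out$r2_explained <- numeric(0)
    out$f_stat <- numeric(0)
  } else {
    out <- as_tibble(stats)
    out$r2_explained <- snp_r2(out$beta, out$eaf, out$se, out$n)
    out$f_stat <- f_statistic(out$r2_explained, out$n)
    out <- out[out$f_stat > f_min, ]
  }
  structure(out,
    class = c("instrument_set", class(out)),
    trait_id = attr(stats, "trait_id"), trait_type = attr(stats, "trait_type"),
    selection_params = selection_params,
    mean_f = if (nrow(out) > 0) mean(out$f_stat) else NA_real_,
    uninstrumentable = nrow(out) == 0
  )
}

#' Select genome-wide instruments for a lipid trait
#'
#' Applies the standard trait-level instrument pipeline: genome-wide
#' significance and minor-allele-frequency filters, stringent LD clumping
#' (defaults r-squared < 0.001 within 10,000 kb), per-variant variance
#' explained and F statistic, and removal of weak instruments (F <= `f_min`).
#'
#' @inheritParams filter_significant
#' @inheritParams clump
#' @param f_min Weak-instrument cutoff (strict: instruments must exceed it).
#' @return An `instrument_set` tibble with `r2_explained` and `f_stat`
#'   columns; attribute `uninstrumentable` is `TRUE` when empty.
#' @export
select_trait_instruments <- function(stats, ld = NULL, p_threshold = 5e-8,
                                     maf_min = 0.01, r2_threshold = 0.001,
                                     window_kb = 10000, f_min = 10) {
  sig <- filter_significant(stats, p_threshold, maf_min)
  kept <- clump(sig, ld, r2_threshold, window_kb)
  finalize_instrument_set(kept, selection_params = list(
    p_threshold = p_threshold, maf_min = maf_min,
    r2_threshold = r2_threshold, window_kb = window_kb, f_min = f_min
  ), f_min = f_min)
}

#' Select cis instruments for a drug-target gene region
#'
#' Restricts to the gene's flanking window (default 250 kb each side, closed
#' interval), then applies the significance/MAF filters and relaxed clumping
#' appropriate for a single cis region (defaults r-squared < 0.2 within
#' 250 kb), and finally the instrument-strength cut. An empty result is not
#' an error: the returned set carries `uninstrumentable = TRUE`.
#'
#' @inheritParams select_trait_instruments
#' @param region Gene region (list or one-row data frame with `gene`,
#'   `chrom`, `start`, `end`).
#' @param window_kb Flanking window in kilobases (default 250).
#' @return An `instrument_set` tibble.
#' @export
select_drug_target_instruments <- function(stats, region, ld = NULL,
                                           window_kb = 250, p_threshold = 5e-8,
                                           maf_min = 0.01, r2_threshold = 0.2,
                                           f_min = 10) {
  local_stats <- restrict_to_region(stats, region, window_kb)
  sig <- filter_significant(local_stats, p_threshold, maf_min)
  kept <- clump(sig, ld, r2_threshold, window_kb)
  out <- finalize_instrument_set(kept, selection_params = list(
    gene = region$gene, window_kb = window_kb, p_threshold = p_threshold,
    maf_min = maf_min, r2_threshold = r2_threshold, f_min = f_min
  ), f_min = f_min)
  if (attr(out, "uninstrumentable")) {
    inform(paste0("target ", region$gene, ": no instrument passes selection"))
  }
  out
}

#' Select cis-eQTL instruments for gene expression
#'
#' Same machinery as [select_drug_target_instruments()] with the stricter
#' cis-eQTL clumping threshold (r-squared < 0.1) at genome-wide significance.
#'
#' @inheritParams select_drug_target_instruments
#' @return An `instrument_set` tibble.
#' @export
select_cis_eqtl_instruments <- function(stats, region, ld = NULL,
                                        window_kb = 250, p_threshold = 5e-8,
                                        maf_min = 0.01, r2_threshold = 0.1,
                                        f_min = 10) {
  select_drug_target_instruments(stats, region, ld,
    window_kb = window_kb, p_threshold = p_threshold, maf_min = maf_min,
    r2_threshold = r2_threshold, f_min = f_min
  )
}
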