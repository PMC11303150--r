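#' Tidy an MR estimate into a one-row tibble
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with `method`, `n_snp`, `beta`, `se`, `pvalue`, and —
#'   when present — odds-ratio, heterogeneity and Egger-intercept columns.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(
    method = x$method, n_snp = x$n_snp,
    beta = x$beta, se = x$se, pvalue = x$pvalue
  )
  for (fld in c("or_point", "or_low", "or_high", "q_stat", "q_df", "q_pvalue",
                "intercept", "intercept_se", "intercept_pvalue")) {
    if (!is.null(x[[fld]])) out[[fld]] <- x[[fld]]
  }
  out
}

#' One-line model summary for an MR estimate
#'
#' @inheritParams tidy.mr_estimate
#' @return A one-row tibble with `method`, `n_snp`, `beta`, `pvalue`, and
#'   `heterogeneity_p` (when computed).
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, n_snp = x$n_snp, beta = x$beta, pvalue = x$pvalue,
    heterogeneity_p = x$q_pvalue %||% NA_real_
  )
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return A one-row tibble with `h0`..`h4`, `pp_conditional`, `n_snps`.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(
    h0 = x$h0, h1 = x$h1, h2 = x$h2, h3 = x$h3, h4 = x$h4,
    pp_conditional = x$pp_conditional, n_snps = x$n_snps
  )
}

#' @rdname tidy.coloc_result
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) tidy(x, ...)

#' Tidy an MR-PRESSO result (per-variant rows)
#'
#' @param x A `presso_result`.
#' @param ... Unused.
#' @return The per-variant tibble with residuals and outlier p-values.
#' @method tidy presso_result
#' @export
tidy.presso_result <- function(x, ...) x$per_snp

#' One-line summary of an MR-PRESSO result
#'
#' @inheritParams tidy.presso_result
#' @return A one-row tibble with the global and distortion tests and the
#'   before/after estimates.
#' @method glance presso_result
#' @export
glance.presso_result <- function(x, ...) {
  tibble(
    global_rss_obs = x$global_rss_obs, global_pvalue = x$global_pvalue,
    n_outliers = length(x$outlier_ids),
    distortion_pvalue = x$distortion_pvalue,
    beta_before = x$estimate_before$beta, beta_after = x$estimate_after$beta,
    n_sim = x$n_sim
  )
}

#' Tidy a mediation decomposition
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return A one-row tibble (see [mediation_report()]).
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) mediation_report(list(x))

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(target = x$target, total_effect = x$total_effect,
         proportion = x$proportion, se_indirect = x$se_indirect)
}
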