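#' Two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation on the coefficient (log-odds / SD)
#' scale: the indirect (mediated) effect is `beta1 * beta2`, the direct
#' effect is `total - indirect`, and the proportion mediated is
#' `indirect / total`. The standard error of the indirect effect uses the
#' product delta method `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (the two steps
#' come from non-overlapping samples, so their covariance is taken as zero).
#'
#' All three inputs must be consistently oriented; an indirect effect whose
#' sign opposes the total effect is flagged (`sign_discordant`), not
#' suppressed.
#'
#' @param total `mr_estimate` (or list with `beta`, `se`) for the
#'   exposure -> outcome total effect.
#' @param step1 Estimate for the exposure -> mediator effect (beta1).
#' @param step2 Estimate for the mediator -> outcome effect (beta2).
#' @param target Label carried into reports.
#' @return A `mediation_result` list: `target`, `total_effect`, `beta1`,
#'   `beta2`, `indirect`, `direct`, `proportion`, `se_indirect`,
#'   `ci_indirect` (95%), `sign_discordant`, `proportion_defined`.
#' @export
two_step_mediation <- function(total, step1, step2, target = "target") {
  indirect <- step1$beta * step2$beta
  direct <- total$beta - indirect
  proportion_defined <- total$beta != 0
  proportion <- if (proportion_defined) indirect / total$beta else NA_real_
  se_ind <- sqrt(step1$beta^2 * step2$se^2 + step2$beta^2 * step1$se^2)
  sign_discordant <- indirect != 0 && total$beta != 0 &&
    sign(indirect) != sign(total$beta)
  if (sign_discordant) {
    warn(paste0("mediated effect for ", target,
                " has opposite sign to the total effect"))
  }
  structure(list(
    target = target,
    total_effect = total$beta,
    beta1 = step1$beta, beta2 = step2$beta,
    indirect = indirect, direct = direct, proportion = proportion,
    se_indirect = se_ind,
    ci_indirect = c(indirect - 1.96 * se_ind, indirect + 1.96 * se_ind),
    sign_discordant = sign_discordant,
    proportion_defined = proportion_defined
  ), class = "mediation_result")
}

#' Tabulate mediation decompositions
#'
#' One row per target with the proportion mediated expressed in percent; a
#' proportion outside \[0, 1\] (possible with noisy ratio-of-estimates
#' arithmetic) is flagged in `out_of_range`.
#'
#' @param results List of `mediation_result` objects (or a single one).
#' @return A tibble with columns `target`, `total_effect`, `indirect_effect`,
#'   `direct_effect`, `proportion_pct`, `se_indirect`, `ci_low`, `ci_high`,
#'   `out_of_range`, `sign_discordant`.
#' @export
mediation_report <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  if (length(results) == 0) {
    return(tibble(
      target = character(), total_effect = numeric(),
      indirect_effect = numeric(), direct_effect = numeric(),
      proportion_pct = numeric(), se_indirect = numeric(),
      ci_low = numeric(), ci_high = numeric(),
      out_of_range = logical(), sign_discordant = logical()
    ))
  }
  purrr::map_dfr(results, function(r) {
    tibble(
      target = r$target,
      total_effect = r$total_effect,
      indirect_effect = r$indirect,
      direct_effect = r$direct,
      proportion_pct = 100 * r$proportion,
      se_indirect = r$se_indirect,
      ci_low = r$ci_indirect[1], ci_high = r$ci_indirect[2],
      out_of_range = !is.na(r$proportion) && (r$proportion < 0 || r$proportion > 1),
      sign_discordant = r$sign_discordant
    )
  })
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>", x$target, "\n")
  cat(sprintf("  total %.4g = direct %.4g + indirect %.4g (beta1 %.4g * beta2 %.4g)\n",
              x$total_effect, x$direct, x$indirect, x$beta1, x$beta2))
  cat(sprintf("  proportion mediated %.3g%%, indirect 95%% CI (%.4g, %.4g)\n",
              100 * x$proportion, x$ci_indirect[1], x$ci_indirect[2]))
  invisible(x)
}
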