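#' Scatter plot of instrument effects with estimator fit lines
#'
#' Outcome effects against exposure effects (instruments oriented to
#' positive exposure effect), with the IVW line through the origin and,
#' when enough instruments are available, the MR-Egger line with its free
#' intercept.
#'
#' @param h A `harmonized_set` tibble.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h) {
  flip <- sign(h$beta_exposure)
  df <- tibble(
    bx = h$beta_exposure * flip, by = h$beta_outcome * flip,
    se_by = h$se_outcome
  )
  lines <- tibble(
    method = "IVW", intercept = 0, slope = mr_ivw(h)$beta
  )
  if (nrow(h) >= 3) {
    eg <- mr_egger(h)
    lines <- bind_rows(lines, tibble(
      method = "MR-Egger", intercept = eg$intercept, slope = eg$beta
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - 1.96 * .data$se_by,
                   ymax = .data$by + 1.96 * .data$se_by),
      width = 0, colour = "grey70"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "effect on exposure", y = "effect on outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of estimates across methods or units
#'
#' @param results A tidy estimate table (e.g. from [mr_all_methods()] or a
#'   results-bundle table) with `beta`, `se`, and a labelling column.
#' @param label Column to label rows by (default `method`).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results, label = "method") {
  df <- as_tibble(results)
  df$label <- interaction(df[[label]],
                          if ("unit" %in% names(df)) df$unit else "",
                          drop = TRUE, sep = " ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out sensitivity plot
#'
#' @param loo Output of [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$snp_id,
                                    colour = .data$influential)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "IVW estimate omitting the variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tibble(
    hypothesis = factor(c("H0", "H1", "H2", "H3", "H4")),
    posterior = c(object$h0, object$h1, object$h2, object$h3, object$h4)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' @method autoplot presso_result
#' @export
autoplot.presso_result <- function(object, ...) {
  df <- object$per_snp
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_id, y = .data$residual,
                                   fill = .data$is_outlier)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(y = "leave-one-out residual", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
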