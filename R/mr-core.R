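new_mr_estimate <- function(method, beta, se, pvalue, n_snp, ...) {
  structure(
    c(list(method = method, beta = beta, se = se,
           pvalue = pvalue, n_snp = n_snp), list(...)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate> method:", x$method, "\n")
  cat(sprintf("  beta = %.4g (se %.4g), p = %.3g, n_snp = %d\n",
              x$beta, x$se, x$pvalue, x$n_snp))
  if (!is.null(x$or_point)) {
    cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f)\n",
                x$or_point, x$or_low, x$or_high))
  }
  invisible(x)
}

check_min_snps <- function(h, k_min, what) {
  if (nrow(h) < k_min) {
    abort(paste0(what, " requires at least ", k_min, " instruments (got ",
                 nrow(h), ")"),
          class = "targetmr_insufficient_error")
  }
}

#' Per-variant Wald ratio estimates
#'
#' For each instrument, the causal-effect ratio `beta_outcome /
#' beta_exposure` with first-order delta-method standard error
#' `se_outcome / |beta_exposure|` and inverse-variance weight.
#'
#' @param h A `harmonized_set` tibble.
#' @return A tibble with `snp_id`, `ratio`, `se_ratio`, `weight`.
#' @export
ratio_estimates <- function(h) {
  if (any(h$beta_exposure == 0)) {
    abort("beta_exposure = 0 makes the Wald ratio undefined",
          class = "targetmr_degenerate_error")
  }
  tibble(
    snp_id = h$snp_id,
    ratio = h$beta_outcome / h$beta_exposure,
    se_ratio = h$se_outcome / abs(h$beta_exposure),
    weight = (h$beta_exposure / h$se_outcome)^2
  )
}

#' Wald ratio for a single instrument
#'
#' @param h A `harmonized_set` tibble with exactly one row.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(h) {
  stopifnot(nrow(h) == 1)
  r <- ratio_estimates(h)
  new_mr_estimate("wald", beta = r$ratio, se = r$se_ratio,
                  pvalue = two_sided_p(r$ratio / r$se_ratio), n_snp = 1L)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' Pools per-variant Wald ratios by inverse-variance weighting. The
#' fixed-effect standard error `1/sqrt(sum(w))` is inflated by
#' `max(1, sqrt(Q / (k - 1)))` under the multiplicative random-effects
#' model, where Q is Cochran's heterogeneity statistic. The p-value uses
#' the normal reference; Q is referred to chi-square with k - 1 df.
#'
#' @param h A `harmonized_set` tibble with >= 2 instruments.
#' @param random_effects Apply the multiplicative SE inflation (default).
#' @return An `mr_estimate` with method `"ivw_re"` (or `"ivw_fe"`) carrying
#'   `q_stat`, `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(h, random_effects = TRUE) {
  check_min_snps(h, 2, "IVW")
  r <- ratio_estimates(h)
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (r$ratio - beta)^2)
  k <- nrow(r)
  scale <- if (random_effects) max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scale
  new_mr_estimate(
    if (random_effects) "ivw_re" else "ivw_fe",
    beta = beta, se = se, pvalue = two_sided_p(beta / se), n_snp = k,
    q_stat = q, q_df = k - 1L,
    q_pvalue = pchisq(q, df = k - 1, lower.tail = FALSE)
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept, weights `1/se_outcome^2`, after orienting every instrument to
#' a positive exposure effect. The slope estimates the causal effect; the
#' intercept estimates average directional pleiotropy, and its test is the
#' Egger intercept test. Standard errors use multiplicative overdispersion
#' (residual standard deviation floored at 1); both coefficients are referred
#' to a t distribution with k - 2 df. Cochran's Q about the Egger fit is
#' reported with k - 2 df.
#'
#' @param h A `harmonized_set` tibble with >= 3 instruments.
#' @return An `mr_estimate` with method `"egger"` carrying `intercept`,
#'   `intercept_se`, `intercept_pvalue`, `q_stat`, `q_df`, `q_pvalue`.
#' @export
mr_egger <- function(h) {
  check_min_snps(h, 3, "MR-Egger")
  flip <- sign(h$beta_exposure)
  if (any(flip == 0)) {
    abort("beta_exposure = 0 cannot be oriented", class = "targetmr_degenerate_error")
  }
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  k <- nrow(h)
  if (diff(range(bx)) < .Machine$double.eps^0.5 * max(abs(bx))) {
    abort("MR-Egger needs variation in the exposure effects",
          class = "targetmr_degenerate_error")
  }
  X <- cbind(intercept = 1, slope = bx)
  xtwx_inv <- solve(crossprod(X, w * X))
  est <- drop(xtwx_inv %*% crossprod(X, w * by))
  resid <- by - drop(X %*% est)
  q <- sum(w * resid^2)
  sigma <- sqrt(q / (k - 2))
  scale <- max(1, sigma)                      # overdispersion floored at 1
  se <- sqrt(diag(xtwx_inv)) * scale
  pval <- 2 * pt(-abs(est / se), df = k - 2)
  new_mr_estimate(
    "egger",
    beta = unname(est["slope"]), se = unname(se["slope"]),
    pvalue = unname(pval["slope"]), n_snp = k,
    intercept = unname(est["intercept"]),
    intercept_se = unname(se["intercept"]),
    intercept_pvalue = unname(pval["intercept"]),
    q_stat = q, q_df = k - 2L,
    q_pvalue = pchisq(q, df = k - 2, lower.tail = FALSE)
  )
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  p <- weight[ord] / sum(weight)
  cum <- cumsum(p) - p / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  below <- max(which(cum <= 0.5))
  if (cum[below] == 0.5) return(r[below])
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median estimator
#'
#' The inverse-variance-weighted median of the per-variant ratio estimates:
#' consistent when instruments carrying at least half of the total weight are
#' valid. The point estimate interpolates the ratio at cumulative weight 0.5;
#' the standard error comes from a parametric bootstrap that redraws each
#' ratio from `Normal(ratio_i, se_ratio_i)`.
#'
#' @param h A `harmonized_set` tibble with >= 3 instruments.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  check_min_snps(h, 3, "weighted median")
  r <- ratio_estimates(h)
  beta <- weighted_median_point(r$ratio, r$weight)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(rnorm(nrow(r), r$ratio, r$se_ratio), r$weight)
    }, numeric(1))
  })
  se <- sd(boot)
  new_mr_estimate("weighted_median", beta = beta, se = se,
                  pvalue = two_sided_p(beta / se), n_snp = nrow(r))
}

mode_bandwidth <- function(ratio, bandwidth_factor) {
  k <- length(ratio)
  s <- min(sd(ratio), mad(ratio))   # mad() uses the 1.4826 consistency constant
  bandwidth_factor * 0.9 * s * k^(-1 / 5)
}

mode_point <- function(ratio, prob, bandwidth, n_grid = 512) {
  if (bandwidth <= 0 || diff(range(ratio)) == 0) return(ratio[1])
  grid <- seq(min(ratio) - 3 * bandwidth, max(ratio) + 3 * bandwidth,
              length.out = n_grid)
  dens <- drop(prob %*% dnorm(outer(ratio, grid, "-") / bandwidth)) / bandwidth
  grid[which.max(dens)]
}

#' Mode-based estimator (simple or weighted)
#'
#' The mode of the per-variant ratio estimates under a Gaussian kernel
#' density: consistent when the largest homogeneous cluster of instruments is
#' valid (zero modal pleiotropy assumption). Weights are uniform for the
#' simple mode and inverse-variance for the weighted mode. Bandwidth follows
#' a Silverman-type rule, `bandwidth_factor * 0.9 * min(sd, mad) * k^(-1/5)`
#' over the ratios; the estimate is the density argmax on a dense grid
#' spanning the ratio range. Standard error by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights in the kernel density.
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth.
#' @return An `mr_estimate` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1L) {
  check_min_snps(h, 3, "mode estimator")
  r <- ratio_estimates(h)
  prob <- if (weighted) r$weight / sum(r$weight) else rep(1 / nrow(r), nrow(r))
  bw <- mode_bandwidth(r$ratio, bandwidth_factor)
  beta <- mode_point(r$ratio, prob, bw)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      rr <- rnorm(nrow(r), r$ratio, r$se_ratio)
      mode_point(rr, prob, mode_bandwidth(rr, bandwidth_factor))
    }, numeric(1))
  })
  se <- sd(boot)
  if (se == 0) se <- .Machine$double.eps
  new_mr_estimate(
    if (weighted) "weighted_mode" else "simple_mode",
    beta = beta, se = se, pvalue = two_sided_p(beta / se), n_snp = nrow(r)
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the random-effects IVW estimator omitting each instrument in turn.
#' An instrument is flagged influential when omitting it changes the
#' estimate's significance at 0.05 or moves the point estimate by more than
#' the full-set (fixed-effect) standard error.
#'
#' @param h A `harmonized_set` tibble with >= 3 instruments.
#' @return A tibble with one row per omitted variant: `snp_id`, `beta`,
#'   `se`, `pvalue`, `influential`.
#' @export
mr_leave_one_out <- function(h) {
  check_min_snps(h, 3, "leave-one-out")
  full <- mr_ivw(h)
  r <- ratio_estimates(h)
  se_fixed <- sqrt(1 / sum(r$weight))
  purrr::map_dfr(seq_len(nrow(h)), function(i) {
    fit <- mr_ivw(h[-i, ])
    tibble(
      snp_id = h$snp_id[i], beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
      influential = ((fit$pvalue < 0.05) != (full$pvalue < 0.05)) |
        (abs(fit$beta - full$beta) > se_fixed)
    )
  })
}

#' Multivariable IVW regression
#'
#' Regresses outcome effects on the matrix of exposure effects with no
#' intercept and weights `1/se_outcome^2`, giving one conditional (direct)
#' estimate per exposure. Standard errors use multiplicative overdispersion
#' floored at 1.
#'
#' @param exposure_betas Data frame or matrix of per-variant exposure effects
#'   (one column per exposure), aligned to a common effect allele per SNP.
#' @param beta_outcome,se_outcome Outcome effects and standard errors on the
#'   same variants and allele coding.
#' @return A tibble with one row per exposure: `exposure`, `beta`, `se`,
#'   `pvalue`, `n_snp` (method `"mvmr_ivw"`).
#' @export
mr_multivariable_ivw <- function(exposure_betas, beta_outcome, se_outcome) {
  X <- as.matrix(exposure_betas)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X)
  if (k < ncol(X) + 1) {
    abort("multivariable IVW needs more instruments than exposures",
          class = "targetmr_insufficient_error")
  }
  # an exposure with no instrument effects at all contributes nothing: report
  # it as NA rather than treating it as a rank deficiency
  zero_col <- apply(X == 0, 2, all)
  if (any(zero_col)) {
    warn(paste0("exposure(s) with all-zero effects excluded from the fit: ",
                paste(colnames(X)[zero_col], collapse = ", ")))
    sub <- mr_multivariable_ivw(X[, !zero_col, drop = FALSE],
                                beta_outcome, se_outcome)
    out <- bind_rows(sub, tibble(
      exposure = colnames(X)[zero_col], method = "mvmr_ivw",
      beta = NA_real_, se = NA_real_, pvalue = NA_real_, n_snp = k
    ))
    return(out[match(colnames(X), out$exposure), ])
  }
  if (qr(X)$rank < ncol(X)) {
    # name the exposures involved in the dependency
    drop_test <- vapply(seq_len(ncol(X)), function(j) {
      qr(X[, -j, drop = FALSE])$rank == qr(X)$rank
    }, logical(1))
    abort(paste0("collinear exposure effects: ",
                 paste(colnames(X)[drop_test], collapse = ", ")),
          class = "targetmr_collinear_error")
  }
  w <- 1 / se_outcome^2
  xtwx_inv <- solve(crossprod(X, w * X))
  est <- drop(xtwx_inv %*% crossprod(X, w * beta_outcome))
  resid <- beta_outcome - drop(X %*% est)
  df <- k - ncol(X)
  scale <- max(1, sqrt(sum(w * resid^2) / df))
  se <- sqrt(diag(xtwx_inv)) * scale
  tibble(
    exposure = colnames(X),
    method = "mvmr_ivw",
    beta = unname(est), se = unname(se),
    pvalue = 2 * pt(-abs(est / se), df = df),
    n_snp = k
  )
}

#' Express an estimate as an odds ratio (optionally flipping exposure sign)
#'
#' For a binary outcome, exponentiates the log-odds causal estimate into an
#' odds ratio with a 95% Wald interval. `scale_flip` negates the estimate
#' first, re-expressing the exposure as the pharmacologically relevant
#' direction (e.g. a 1-SD *decrease* in LDL-C for an LDL-lowering target).
#'
#' @param est An `mr_estimate`.
#' @param scale_flip Negate the log-odds estimate before exponentiating.
#' @return The `mr_estimate` with `or_point`, `or_low`, `or_high` added.
#' @export
to_odds_ratio <- function(est, scale_flip = FALSE) {
  beta <- if (scale_flip) -est$beta else est$beta
  est$beta <- beta
  est$or_point <- exp(beta)
  est$or_low <- exp(beta - 1.96 * est$se)
  est$or_high <- exp(beta + 1.96 * est$se)
  est
}

#' Run the full univariable estimator stack
#'
#' Applies every estimator the instrument count supports: Wald ratio for a
#' single instrument; IVW for two; IVW, MR-Egger, weighted median and both
#' modes for three or more.
#'
#' @inheritParams mr_weighted_median
#' @return A tibble with one row per method (the [tidy()] of each estimate).
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1L) {
  k <- nrow(h)
  fits <- if (k == 1) {
    list(wald_ratio(h))
  } else if (k == 2) {
    list(mr_ivw(h))
  } else {
    list(
      mr_ivw(h), mr_egger(h),
      mr_weighted_median(h, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed)
    )
  }
  purrr::map_dfr(fits, tidy)
}
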