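#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the scale of the study's real inputs: a lipid-trait
#' exposure GWAS of ~187,000 samples and a disease outcome GWAS of ~120,000
#' samples, with common variants (effect-allele frequency in 0.05-0.95) and
#' per-variant exposure effects strong enough to pass genome-wide
#' significance.
#'
#' @param n_snp Number of instruments.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param true_beta Causal effect of the exposure on the outcome.
#' @param pleiotropy List with `fraction` of instruments carrying a direct
#'   (horizontal) outcome effect, and the `mean` and `sd` of that effect.
#'   `mean != 0` gives directional pleiotropy; `mean = 0, sd > 0` balanced.
#' @param eaf_range Interval the effect-allele frequencies are drawn from.
#' @param beta_gx_sd Standard deviation of the latent per-variant exposure
#'   effects (rejection-sampled to genome-wide significance).
#' @param seed Integer seed; every generator is a pure function of its
#'   config including the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_snp = 30, n_exposure = 187167,
                              n_outcome = 120568, true_beta = 0,
                              pleiotropy = list(fraction = 0, mean = 0, sd = 0.05),
                              eaf_range = c(0.05, 0.95),
                              beta_gx_sd = 0.02, seed = 1L) {
  stopifnot(
    n_snp >= 1, n_exposure > 2, n_outcome > 2,
    pleiotropy$fraction >= 0, pleiotropy$fraction <= 1,
    eaf_range[1] > 0, eaf_range[2] < 1, eaf_range[1] <= eaf_range[2],
    beta_gx_sd > 0
  )
  structure(list(
    n_snp = n_snp, n_exposure = n_exposure, n_outcome = n_outcome,
    true_beta = true_beta, pleiotropy = pleiotropy, eaf_range = eaf_range,
    beta_gx_sd = beta_gx_sd, seed = as.integer(seed)
  ), class = "simulation_config")
}

# GWAS standard error for a standardized trait: 1 / sqrt(2 eaf (1-eaf) n)
gwas_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# p-values clamped away from exact zero so they satisfy the (0, 1] invariant
safe_p <- function(z) pmax(two_sided_p(z), 1e-300)

# draw latent exposure effects conditioned to pass significance (rejection
# sampling on the latent effect itself: winner's-curse free)
draw_significant_beta <- function(n, sd, se, z_crit) {
  beta <- rnorm(n, 0, sd)
  repeat {
    fail <- abs(beta / se) <= z_crit
    if (!any(fail)) break
    beta[fail] <- rnorm(sum(fail), 0, sd)
  }
  beta
}

make_summary_stats <- function(snp_id, pos, eaf, beta, se, n, trait_id,
                               trait_type = "quantitative",
                               effect_allele = NULL, other_allele = NULL,
                               chrom = "1") {
  k <- length(snp_id)
  # cycle through non-palindromic pairs so harmonization keeps everything
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  idx <- ((seq_len(k) - 1) %% 4) + 1
  summary_stats(tibble(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele %||% vapply(idx, function(i) pairs[[i]][1], ""),
    other_allele = other_allele %||% vapply(idx, function(i) pairs[[i]][2], ""),
    eaf = eaf, beta = beta, se = se,
    pvalue = safe_p(beta / se), n = n
  ), trait_id = trait_id, trait_type = trait_type, quiet = TRUE)
}

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Per variant: the effect-allele frequency is uniform on `eaf_range`; the
#' latent exposure effect is Normal(0, `beta_gx_sd`) rejection-sampled to
#' genome-wide significance in the exposure sample; standard errors follow
#' `1/sqrt(2 eaf (1-eaf) n)` for a standardized trait. The reported outcome
#' effect is `true_beta * beta_gx` plus a horizontal-pleiotropy effect for
#' the configured fraction of variants plus sampling noise at the outcome
#' standard error. The exposure effects are reported without sampling noise,
#' so instrument strength is exact and the first-order ratio standard error
#' is well calibrated.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `exposure` and `outcome` (`summary_stats` tibbles) and
#'   `truth` (tibble of latent values per variant plus the config).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    k <- cfg$n_snp
    snp_id <- sprintf("snp%04d", seq_len(k))
    pos <- seq_len(k) * 1000000L
    eaf <- runif(k, cfg$eaf_range[1], cfg$eaf_range[2])
    se_x <- gwas_se(eaf, cfg$n_exposure)
    se_y <- gwas_se(eaf, cfg$n_outcome)
    z_crit <- qnorm(1 - 5e-8 / 2)
    beta_gx <- draw_significant_beta(k, cfg$beta_gx_sd, se_x, z_crit)

    n_pleio <- round(cfg$pleiotropy$fraction * k)
    pleio_idx <- if (n_pleio > 0) sample.int(k, n_pleio) else integer(0)
    alpha <- rep(0, k)
    if (n_pleio > 0) {
      alpha[pleio_idx] <- rnorm(n_pleio, cfg$pleiotropy$mean, cfg$pleiotropy$sd)
    }
    beta_gy <- cfg$true_beta * beta_gx + alpha + rnorm(k, 0, se_y)

    list(
      exposure = make_summary_stats(snp_id, pos, eaf, beta_gx, se_x,
                                    cfg$n_exposure, "sim_exposure"),
      outcome = make_summary_stats(snp_id, pos, eaf, beta_gy, se_y,
                                   cfg$n_outcome, "sim_outcome"),
      truth = list(
        per_snp = tibble(snp_id = snp_id, beta_gx = beta_gx, alpha = alpha,
                         pleiotropic = seq_len(k) %in% pleio_idx),
        true_beta = cfg$true_beta, config = cfg
      )
    )
  })
}

#' Simulate an exposure -> mediator -> outcome chain
#'
#' Generates `n_snp` exposure instruments (latent effect `gamma` on the
#' exposure, `beta1 * gamma` on the mediator, `(direct + beta1*beta2) * gamma`
#' on the outcome) plus `n_snp` mediator-specific instruments with no
#' exposure effect (latent effect `delta` on the mediator, `beta2 * delta` on
#' the outcome), so that both mediation steps are estimable by two-sample MR:
#' beta1 from the exposure instruments against the mediator, beta2 from the
#' mediator instruments against the outcome, and the total effect from the
#' exposure instruments against the outcome.
#'
#' @param beta1 Exposure -> mediator effect.
#' @param beta2 Mediator -> outcome effect.
#' @param direct Direct exposure -> outcome effect (not through the mediator).
#' @param base_cfg A [simulation_config()]; `n_snp` counts each instrument
#'   set, `n_exposure` is also used for the mediator GWAS.
#' @return A list with `exposure`, `mediator`, `outcome` (`summary_stats`)
#'   and `truth` (instrument roles, `total = direct + beta1*beta2`,
#'   `proportion = beta1*beta2/total`).
#' @export
simulate_mediation_chain <- function(beta1, beta2, direct, base_cfg) {
  stopifnot(inherits(base_cfg, "simulation_config"))
  cfg <- base_cfg
  withr::with_seed(cfg$seed, {
    k <- cfg$n_snp
    total <- direct + beta1 * beta2
    snp_x <- sprintf("snpx%04d", seq_len(k))
    snp_m <- sprintf("snpm%04d", seq_len(k))
    pos <- seq_len(2 * k) * 1000000L
    eaf <- runif(2 * k, cfg$eaf_range[1], cfg$eaf_range[2])
    n_med <- cfg$n_exposure
    se_x <- gwas_se(eaf, cfg$n_exposure)
    se_m <- gwas_se(eaf, n_med)
    se_y <- gwas_se(eaf, cfg$n_outcome)
    z_crit <- qnorm(1 - 5e-8 / 2)

    gamma <- draw_significant_beta(k, cfg$beta_gx_sd, se_x[seq_len(k)], z_crit)
    delta <- draw_significant_beta(k, cfg$beta_gx_sd, se_m[k + seq_len(k)], z_crit)

    beta_on_x <- c(gamma, rnorm(k, 0, se_x[k + seq_len(k)]))
    beta_on_m <- c(beta1 * gamma + rnorm(k, 0, se_m[seq_len(k)]), delta)
    beta_on_y <- c(total * gamma, beta2 * delta) + rnorm(2 * k, 0, se_y)

    ids <- c(snp_x, snp_m)
    list(
      exposure = make_summary_stats(ids, pos, eaf, beta_on_x, se_x,
                                    cfg$n_exposure, "sim_exposure"),
      mediator = make_summary_stats(ids, pos, eaf, beta_on_m, se_m,
                                    n_med, "sim_mediator"),
      outcome = make_summary_stats(ids, pos, eaf, beta_on_y, se_y,
                                   cfg$n_outcome, "sim_outcome"),
      truth = list(
        exposure_instruments = snp_x, mediator_instruments = snp_m,
        beta1 = beta1, beta2 = beta2, direct = direct, total = total,
        proportion = beta1 * beta2 / total, config = cfg
      )
    )
  })
}

#' Configuration for the colocalization-region generator
#'
#' @param n_snp Variants in the region.
#' @param hypothesis Generating hypothesis, one of `"H0"`..`"H4"`.
#' @param ld_rho AR(1) correlation between adjacent variants, in \[0, 1).
#' @param z_causal Expected z-score at the causal variant.
#' @param n1,n2 Trait sample sizes.
#' @param seed Integer seed.
#' @return A `region_sim_config` list.
#' @export
region_sim_config <- function(n_snp = 50, hypothesis = "H4", ld_rho = 0,
                              z_causal = 8, n1 = 100000, n2 = 100000,
                              seed = 1L) {
  stopifnot(hypothesis %in% c("H0", "H1", "H2", "H3", "H4"),
            ld_rho >= 0, ld_rho < 1, n_snp >= 1)
  structure(list(
    n_snp = n_snp, hypothesis = hypothesis, ld_rho = ld_rho,
    z_causal = z_causal, n1 = n1, n2 = n2, seed = as.integer(seed)
  ), class = "region_sim_config")
}

ld_smear <- function(n_snp, causal_idx, z_causal, ld_rho) {
  if (length(causal_idx) == 0) return(rep(0, n_snp))
  ld_rho^abs(seq_len(n_snp) - causal_idx) * z_causal
}

#' Simulate a colocalization region under a chosen hypothesis
#'
#' Draws latent causal variants per hypothesis (none; trait 1 only; trait 2
#' only; two distinct; one shared), builds each trait's expected z-scores as
#' the causal signal smeared over neighbours by AR(1) LD, adds standard
#' normal noise, and back-computes betas and standard errors at the given
#' sample sizes (`se = 1/sqrt(n)`, `beta = z * se`).
#'
#' @param cfg A [region_sim_config()].
#' @return A list with `trait1`, `trait2` (tibbles of `snp_id`, `beta`, `se`
#'   with `trait_type` attribute) and `truth` (hypothesis and causal indices).
#' @export
simulate_coloc_region <- function(cfg) {
  stopifnot(inherits(cfg, "region_sim_config"))
  withr::with_seed(cfg$seed, {
    k <- cfg$n_snp
    snp_id <- sprintf("rsnp%04d", seq_len(k))
    causal1 <- causal2 <- integer(0)
    if (cfg$hypothesis %in% c("H1", "H3")) causal1 <- sample.int(k, 1)
    if (cfg$hypothesis == "H2") causal2 <- sample.int(k, 1)
    if (cfg$hypothesis == "H3") {
      causal2 <- sample(setdiff(seq_len(k), causal1), 1)
    }
    if (cfg$hypothesis == "H4") causal1 <- causal2 <- sample.int(k, 1)

    z1 <- ld_smear(k, causal1, cfg$z_causal, cfg$ld_rho) + rnorm(k)
    z2 <- ld_smear(k, causal2, cfg$z_causal, cfg$ld_rho) + rnorm(k)
    se1 <- rep(1 / sqrt(cfg$n1), k)
    se2 <- rep(1 / sqrt(cfg$n2), k)
    mk <- function(z, se) {
      structure(tibble(snp_id = snp_id, beta = z * se, se = se),
                trait_type = "quantitative")
    }
    list(
      trait1 = mk(z1, se1), trait2 = mk(z2, se2),
      truth = list(hypothesis = cfg$hypothesis,
                   causal1 = causal1, causal2 = causal2, config = cfg)
    )
  })
}

#' Write a summary-statistics tibble in the TSV dialect the reader consumes
#'
#' @param stats A `summary_stats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(as_tibble(stats)[SUMMARY_COLS], path, progress = FALSE)
  invisible(path)
}
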