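#' Simulate a complete drug-target study configuration
#'
#' Builds a self-contained synthetic study mirroring the structure of the
#' real analysis: three lipid-trait exposures (null causal effect on the
#' outcome), four drug-target gene regions whose regional variants carry the
#' target-specific causal effects on the binary outcome (one protective
#' target, three risk targets), a vitamin-D-like mediator with its own
#' genome-wide instruments, cis-eQTL tables per target, covariate GWAS for
#' the multivariable analysis, and per-region AR(1)-style LD matrices.
#' Target total effects and first-step mediator effects default to the
#' magnitudes of the motivating analysis (totals 0.66, 0.62, 0.25, -0.97
#' log-odds for LDLR, LPL, CETP, HMGCR; first-step effects -0.091, -0.031,
#' -0.076, 0; mediator -> outcome effect ln(0.68)).
#'
#' @param seed Integer seed.
#' @param snps_per_region Significant regional variants per target gene.
#' @param snps_per_trait Genome-wide instruments per lipid trait.
#' @param n_mediator_snps Dedicated mediator instruments.
#' @param thresholds Threshold overrides passed to [study_config()] (e.g. a
#'   smaller bootstrap count for quick runs).
#' @return A [study_config()] ready for [run_study()]; the latent truth is
#'   attached as attribute `truth`.
#' @export
simulate_study <- function(seed = 1L, snps_per_region = 8,
                           snps_per_trait = 20, n_mediator_snps = 15,
                           thresholds = list()) {
  n_exp <- 187167
  n_out <- 120568
  n_med <- 120000
  beta2 <- log(0.68)
  targets <- tibble(
    gene = c("LDLR", "LPL", "CETP", "HMGCR"),
    chrom = c("19", "8", "16", "5"),
    start = c(1000000, 1000000, 1000000, 1000000),
    end = c(1050000, 1050000, 1050000, 1050000),
    trait = c("LDL", "TG", "HDL", "LDL"),
    direction = c("activator", "activator", "inhibitor", "inhibitor"),
    flip = FALSE,
    total = c(0.66, 0.62, 0.25, -0.97),
    beta1 = c(-0.091, -0.031, -0.076, 0)
  )
  traits <- c(LDL = "2", HDL = "3", TG = "4")   # chromosome per trait

  withr::with_seed(seed, {
    z_crit <- qnorm(1 - 5e-8 / 2)
    panel <- list()
    add_snps <- function(prefix, chrom, pos0, k, spacing) {
      tibble(
        snp_id = sprintf("%s%03d", prefix, seq_len(k)),
        chrom = chrom, pos = as.integer(pos0 + (seq_len(k) - 1) * spacing),
        eaf = runif(k, 0.1, 0.9)
      )
    }
    for (i in seq_len(nrow(targets))) {
      panel[[targets$gene[i]]] <- add_snps(
        paste0(tolower(targets$gene[i]), "_"),
        targets$chrom[i], 1005000, snps_per_region, 5000
      )
    }
    for (tr in names(traits)) {
      panel[[paste0("trait_", tr)]] <- add_snps(
        paste0(tolower(tr), "_"), traits[[tr]], 1000000, snps_per_trait, 1000000
      )
    }
    panel$mediator <- add_snps("vitd_", "12", 1000000, n_mediator_snps, 1000000)
    panel <- bind_rows(panel, .id = "block")

    k_all <- nrow(panel)
    se_exp <- gwas_se(panel$eaf, n_exp)
    se_med <- gwas_se(panel$eaf, n_med)
    se_out <- gwas_se(panel$eaf, n_out)

    # latent per-variant effects on the trait each block instruments
    latent <- draw_significant_beta(k_all, 0.02, se_exp, z_crit)

    # exposure GWAS per lipid trait: own instruments plus the target-region
    # variants of targets assigned to the trait; everything else null + noise
    expo <- list()
    for (tr in names(traits)) {
      own <- panel$block %in% c(paste0("trait_", tr),
                                targets$gene[targets$trait == tr])
      beta <- ifelse(own, latent, 0) + ifelse(own, 0, rnorm(k_all, 0, se_exp))
      expo[[tr]] <- make_summary_stats(panel$snp_id, panel$pos, panel$eaf,
                                       beta, se_exp, n_exp, tr,
                                       chrom = panel$chrom)
    }

    # outcome: regional variants act through their target's total effect;
    # mediator instruments act through the mediator
    theta <- setNames(targets$total, targets$gene)
    eff_out <- rep(0, k_all)
    for (g in targets$gene) {
      idx <- panel$block == g
      eff_out[idx] <- theta[[g]] * latent[idx]
    }
    med_idx <- panel$block == "mediator"
    eff_out[med_idx] <- beta2 * latent[med_idx]
    beta_out <- eff_out + rnorm(k_all, 0, se_out)
    outcome <- make_summary_stats(panel$snp_id, panel$pos, panel$eaf,
                                  beta_out, se_out, n_out, "MIF",
                                  trait_type = "case-control",
                                  chrom = panel$chrom)

    # mediator GWAS: own instruments exact; target regions via beta1
    b1 <- setNames(targets$beta1, targets$gene)
    eff_med <- rep(0, k_all)
    for (g in targets$gene) {
      idx <- panel$block == g
      eff_med[idx] <- b1[[g]] * latent[idx]
    }
    beta_med <- eff_med + rnorm(k_all, 0, se_med)
    beta_med[med_idx] <- latent[med_idx]
    mediator <- make_summary_stats(panel$snp_id, panel$pos, panel$eaf,
                                   beta_med, se_med, n_med, "vitamin_D",
                                   chrom = panel$chrom)

    # covariates for the multivariable analysis: independent small effects
    covariates <- purrr::map(
      setNames(c("BMI", "CHD"), c("BMI", "CHD")),
      function(cv) {
        b <- rnorm(k_all, 0, 0.005) + rnorm(k_all, 0, se_exp)
        make_summary_stats(panel$snp_id, panel$pos, panel$eaf,
                           b, se_exp, n_exp, cv, chrom = panel$chrom)
      }
    )

    # cis-eQTL tables: expression effects proportional to the lipid effects
    eqtl <- purrr::map(setNames(targets$gene, targets$gene), function(g) {
      idx <- panel$block == g
      b <- ifelse(idx, 2 * latent, 0) + rnorm(k_all, 0, se_exp)
      make_summary_stats(panel$snp_id[idx], panel$pos[idx],
                         panel$eaf[idx], b[idx], se_exp[idx],
                         n_exp, paste0(g, "_expression"),
                         chrom = panel$chrom[idx])
    })

    # modest LD between neighbouring regional variants
    ld <- purrr::map(setNames(targets$gene, targets$gene), function(g) {
      ids <- panel$snp_id[panel$block == g]
      k <- length(ids)
      m <- 0.5^abs(outer(seq_len(k), seq_len(k), "-"))
      dimnames(m) <- list(ids, ids)
      m
    })

    cfg <- study_config(
      exposures = expo, outcome = outcome,
      targets = targets[c("gene", "chrom", "start", "end",
                          "trait", "direction", "flip")],
      covariates = covariates, mediator = mediator, eqtl = eqtl,
      ld = ld, thresholds = thresholds, seed = seed
    )
    attr(cfg, "truth") <- list(
      targets = targets, beta2 = beta2,
      trait_effects = setNames(rep(0, length(traits)), names(traits))
    )
    cfg
  })
}
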