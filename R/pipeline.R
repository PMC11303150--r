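#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up q-values: sort the p-values ascending, take
#' `q_(i) = min over j >= i of p_(j) * m / j`, and map back to input order.
#' Delegates to [stats::p.adjust()]. `NA` entries stay `NA` and do not count
#' toward the family size `m`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in (0, 1]", class = "targetmr_config_error")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Assemble a study configuration
#'
#' Bundles every input and threshold of the full drug-target MR study. All
#' summary-statistics entries are `summary_stats` tibbles (file paths can be
#' resolved beforehand with [read_summary_stats()]).
#'
#' @param exposures Named list of lipid-trait `summary_stats`.
#' @param outcome Outcome `summary_stats` (typically case-control).
#' @param targets Tibble with one row per drug target: `gene`, `chrom`,
#'   `start`, `end`, `trait` (name of the exposure whose GWAS instruments
#'   the target region), `direction` (free-text label, e.g. "activator"),
#'   `flip` (logical: re-sign the estimate so drug action is the exposure
#'   unit).
#' @param covariates Named list of covariate `summary_stats` for the
#'   multivariable analysis (optional).
#' @param mediator Mediator `summary_stats` (optional; enables two-step
#'   mediation for FDR-significant targets).
#' @param eqtl Named list (by gene) of cis-eQTL `summary_stats` (optional).
#' @param ld Named list (by gene) of LD r-squared matrices; `ld_traits` a
#'   matrix for the trait-level clumping (either may be `NULL` for
#'   independent variants).
#' @param thresholds Selection and testing thresholds; see defaults.
#' @param coloc_priors Priors for [coloc_abf()].
#' @param seed Integer seed for every stochastic step.
#' @return A `study_config` list.
#' @export
study_config <- function(exposures, outcome, targets,
                         covariates = NULL, mediator = NULL, eqtl = NULL,
                         ld = NULL, ld_traits = NULL,
                         thresholds = list(), coloc_priors = list(),
                         seed = 1L) {
  thr <- utils::modifyList(list(
    p_gwas = 5e-8, maf = 0.01,
    clump_trait = list(r2 = 0.001, kb = 10000),
    clump_target = list(r2 = 0.2, kb = 250),
    clump_eqtl = list(r2 = 0.1, kb = 250),
    f_min = 10, alpha = 0.05,
    n_boot = 1000, presso_n_sim = 1000
  ), thresholds)
  pri <- utils::modifyList(list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5), coloc_priors)
  stopifnot(
    thr$p_gwas > 0, thr$p_gwas < 1, thr$maf >= 0, thr$maf < 0.5,
    thr$alpha > 0, thr$alpha < 1,
    all(c("gene", "chrom", "start", "end", "trait", "flip") %in% names(targets))
  )
  structure(list(
    exposures = exposures, outcome = outcome, targets = as_tibble(targets),
    covariates = covariates, mediator = mediator, eqtl = eqtl,
    ld = ld, ld_traits = ld_traits, thresholds = thr, coloc_priors = pri,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors [study_config()]: summary-statistics entries are paths
#' (with optional `column_map` and `trait_type`), `targets` a list of target
#' records, thresholds and priors scalar maps.
#'
#' @param path Path to the YAML file.
#' @param base_dir Directory data paths are resolved against (defaults to
#'   the YAML's directory).
#' @return A `study_config`.
#' @export
read_study_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  load_stats <- function(entry, id) {
    read_summary_stats(
      file.path(base_dir, entry$path),
      column_map = unlist(entry$column_map),
      trait_id = id,
      trait_type = entry$trait_type %||% "quantitative"
    )
  }
  exposures <- purrr::imap(y$exposures, load_stats)
  outcome <- load_stats(y$outcome, y$outcome$id %||% "outcome")
  targets <- purrr::map_dfr(y$targets, as_tibble)
  covariates <- if (!is.null(y$covariates)) purrr::imap(y$covariates, load_stats)
  mediator <- if (!is.null(y$mediator)) load_stats(y$mediator, "mediator")
  eqtl <- if (!is.null(y$eqtl)) purrr::imap(y$eqtl, load_stats)
  ld <- if (!is.null(y$ld)) {
    purrr::map(y$ld, ~ read_ld_matrix(file.path(base_dir, .x)))
  }
  study_config(
    exposures = exposures, outcome = outcome, targets = targets,
    covariates = covariates, mediator = mediator, eqtl = eqtl, ld = ld,
    thresholds = y$thresholds %||% list(),
    coloc_priors = y$coloc_priors %||% list(),
    seed = y$seed %||% 1L
  )
}

# run one estimator stack on a harmonized set, downgrading thin instrument
# sets to what they support
estimate_unit <- function(h, n_boot, seed, flip, binary_outcome) {
  res <- mr_all_methods(h, n_boot = n_boot, seed = seed)
  if (flip) {
    res$beta <- -res$beta
  }
  if (binary_outcome) {
    res$or_point <- exp(res$beta)
    res$or_low <- exp(res$beta - 1.96 * res$se)
    res$or_high <- exp(res$beta + 1.96 * res$se)
  }
  res
}

sensitivity_unit <- function(h, unit, n_sim, seed) {
  row <- tibble(
    unit = unit, n_snp = nrow(h),
    q_stat = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
    n_influential_loo = NA_integer_,
    presso_global_p = NA_real_, presso_n_outliers = NA_integer_,
    presso_distortion_p = NA_real_
  )
  if (nrow(h) >= 2) {
    ivw <- mr_ivw(h)
    row$q_stat <- ivw$q_stat
    row$q_df <- ivw$q_df
    row$q_pvalue <- ivw$q_pvalue
  }
  if (nrow(h) >= 3) {
    eg <- mr_egger(h)
    row$egger_intercept <- eg$intercept
    row$egger_intercept_p <- eg$intercept_pvalue
    row$n_influential_loo <- sum(mr_leave_one_out(h)$influential)
  }
  if (nrow(h) >= 4) {
    pr <- mr_presso(h, n_sim = n_sim, seed = seed)
    row$presso_global_p <- pr$global_pvalue
    row$presso_n_outliers <- length(pr$outlier_ids)
    row$presso_distortion_p <- pr$distortion_pvalue
  }
  row
}

flagged_row <- function(unit, method, note) {
  tibble(unit = unit, method = method, n_snp = 0L,
         beta = NA_real_, se = NA_real_, pvalue = NA_real_,
         flag = note)
}

#' Run the full drug-target MR study
#'
#' Executes, in order: trait-level instrument selection, harmonization and
#' the univariable estimator stack plus sensitivity analyses for every
#' exposure; multivariable IVW adjusting for the configured covariates;
#' drug-target MR for every target gene region with per-target direction
#' flips and Benjamini-Hochberg FDR across the targets' IVW p-values;
#' cis-eQTL MR where expression data are supplied; colocalization of the
#' target's lipid and outcome signals for FDR-significant targets; and
#' two-step mediation through the configured mediator for FDR-significant
#' targets. A stage with no usable instruments yields a flagged row, never
#' an abort.
#'
#' @param cfg A [study_config()].
#' @return A `results_bundle`: list of tibbles `trait_mr`, `trait_mvmr`,
#'   `target_mr`, `eqtl_mr`, `coloc`, `mediation`, `sensitivity`, plus a
#'   character `log`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  thr <- cfg$thresholds
  outcome <- cfg$outcome
  binary <- identical(attr(outcome, "trait_type"), "case-control")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # ---- trait-level univariable MR -------------------------------------
  trait_rows <- list()
  sens_rows <- list()
  trait_h <- list()
  for (nm in names(cfg$exposures)) {
    sel <- select_trait_instruments(
      cfg$exposures[[nm]], ld = cfg$ld_traits,
      p_threshold = thr$p_gwas, maf_min = thr$maf,
      r2_threshold = thr$clump_trait$r2, window_kb = thr$clump_trait$kb,
      f_min = thr$f_min
    )
    if (nrow(sel) == 0) {
      trait_rows[[nm]] <- flagged_row(nm, "none", "no_instruments")
      note("trait ", nm, ": no instruments")
      next
    }
    h <- harmonize(sel, outcome)
    trait_h[[nm]] <- h
    cnt <- harmonization_counts(h)
    note("trait ", nm, ": ", cnt$n_snp, " instruments (", cnt$flipped,
         " flipped, ", cnt$dropped_palindromic, " palindromic dropped, ",
         cnt$dropped_unmatched, " unmatched)")
    res <- estimate_unit(h, thr$n_boot, cfg$seed, flip = FALSE,
                         binary_outcome = binary)
    res$unit <- nm
    res$flag <- NA_character_
    trait_rows[[nm]] <- res
    sens_rows[[paste0("trait_", nm)]] <-
      sensitivity_unit(h, nm, thr$presso_n_sim, cfg$seed)
  }
  trait_mr <- bind_rows(trait_rows)

  # ---- multivariable MR ------------------------------------------------
  trait_mvmr <- NULL
  if (!is.null(cfg$covariates) && length(cfg$covariates) > 0) {
    mv_rows <- list()
    for (nm in names(trait_h)) {
      h <- trait_h[[nm]]
      X <- tibble(!!nm := h$beta_exposure)
      ok <- rep(TRUE, nrow(h))
      for (cv in names(cfg$covariates)) {
        cvh <- harmonize(cfg$covariates[[cv]], outcome)
        idx <- match(h$snp_id, cvh$snp_id)
        aligned <- ifelse(cvh$effect_allele[idx] == h$effect_allele, 1,
                          ifelse(cvh$effect_allele[idx] == h$other_allele, -1, NA))
        X[[cv]] <- cvh$beta_exposure[idx] * aligned
        ok <- ok & !is.na(X[[cv]])
      }
      if (sum(ok) >= ncol(X) + 1) {
        mv <- mr_multivariable_ivw(X[ok, ], h$beta_outcome[ok], h$se_outcome[ok])
        mv$unit <- nm
        mv_rows[[nm]] <- mv[mv$exposure == nm, ]
      } else {
        note("mvmr ", nm, ": too few shared variants")
      }
    }
    trait_mvmr <- bind_rows(mv_rows)
  }

  # ---- drug-target MR with FDR ----------------------------------------
  target_rows <- list()
  target_h <- list()
  for (i in seq_len(nrow(cfg$targets))) {
    tg <- cfg$targets[i, ]
    expo <- cfg$exposures[[tg$trait]]
    sel <- select_drug_target_instruments(
      expo, region = tg, ld = cfg$ld[[tg$gene]],
      window_kb = thr$clump_target$kb, p_threshold = thr$p_gwas,
      maf_min = thr$maf, r2_threshold = thr$clump_target$r2,
      f_min = thr$f_min
    )
    if (nrow(sel) == 0) {
      target_rows[[tg$gene]] <- flagged_row(tg$gene, "none", "uninstrumentable")
      note("target ", tg$gene, ": uninstrumentable")
      next
    }
    h <- harmonize(sel, outcome)
    target_h[[tg$gene]] <- h
    res <- estimate_unit(h, thr$n_boot, cfg$seed, flip = tg$flip,
                         binary_outcome = binary)
    res$unit <- tg$gene
    res$flag <- NA_character_
    target_rows[[tg$gene]] <- res
    sens_rows[[paste0("target_", tg$gene)]] <-
      sensitivity_unit(h, tg$gene, thr$presso_n_sim, cfg$seed)
    if (tg$flip) note("target ", tg$gene, ": estimate re-signed (", tg$direction, ")")
  }
  target_mr <- bind_rows(target_rows)
  primary <- target_mr %>%
    filter(.data$method %in% c("ivw_re", "wald", "none")) %>%
    group_by(.data$unit) %>% slice(1) %>% ungroup()
  primary$q_fdr <- bh_fdr(primary$pvalue)
  target_mr <- left_join(target_mr,
                         primary %>% select("unit", "q_fdr"), by = "unit")
  significant <- primary$unit[!is.na(primary$q_fdr) &
                                primary$q_fdr < thr$alpha]
  note("FDR-significant targets: ",
       if (length(significant)) paste(significant, collapse = ", ") else "none")

  # ---- cis-eQTL MR ------------------------------------------------------
  eqtl_rows <- list()
  if (!is.null(cfg$eqtl)) {
    for (gene in names(cfg$eqtl)) {
      tg <- cfg$targets[cfg$targets$gene == gene, ]
      if (nrow(tg) == 0) next
      sel <- select_cis_eqtl_instruments(
        cfg$eqtl[[gene]], region = tg, ld = cfg$ld[[gene]],
        window_kb = thr$clump_eqtl$kb %||% thr$clump_target$kb,
        p_threshold = thr$p_gwas, maf_min = thr$maf,
        r2_threshold = thr$clump_eqtl$r2, f_min = thr$f_min
      )
      if (nrow(sel) == 0) {
        eqtl_rows[[gene]] <- flagged_row(gene, "none", "uninstrumentable")
        next
      }
      h <- harmonize(sel, outcome)
      res <- estimate_unit(h, thr$n_boot, cfg$seed, flip = FALSE,
                           binary_outcome = binary)
      res$unit <- gene
      res$flag <- NA_character_
      eqtl_rows[[gene]] <- res
    }
  }
  eqtl_mr <- bind_rows(eqtl_rows)

  # ---- colocalization for associated targets ---------------------------
  coloc_rows <- list()
  for (gene in significant) {
    tg <- cfg$targets[cfg$targets$gene == gene, ]
    expo_reg <- restrict_to_region(cfg$exposures[[tg$trait]], tg,
                                   thr$clump_target$kb)
    out_reg <- restrict_to_region(outcome, tg, thr$clump_target$kb)
    if (nrow(expo_reg) == 0 || nrow(out_reg) == 0) {
      note("coloc ", gene, ": no regional variants")
      next
    }
    cl <- coloc_abf(
      structure(as_tibble(expo_reg)[c("snp_id", "beta", "se")],
                trait_type = attr(cfg$exposures[[tg$trait]], "trait_type")),
      structure(as_tibble(out_reg)[c("snp_id", "beta", "se")],
                trait_type = attr(outcome, "trait_type")),
      p1 = cfg$coloc_priors$p1, p2 = cfg$coloc_priors$p2,
      p12 = cfg$coloc_priors$p12
    )
    coloc_rows[[gene]] <- tidy(cl) %>% mutate(target = gene, .before = 1)
  }
  coloc_tbl <- bind_rows(coloc_rows)

  # ---- two-step mediation for associated targets ------------------------
  mediation_tbl <- NULL
  if (!is.null(cfg$mediator) && length(significant) > 0) {
    med_sel <- select_trait_instruments(
      cfg$mediator, ld = cfg$ld_traits,
      p_threshold = thr$p_gwas, maf_min = thr$maf,
      r2_threshold = thr$clump_trait$r2, window_kb = thr$clump_trait$kb,
      f_min = thr$f_min
    )
    step2 <- NULL
    if (nrow(med_sel) >= 1) {
      h2 <- harmonize(med_sel, outcome)
      step2 <- if (nrow(h2) >= 2) mr_ivw(h2) else wald_ratio(h2)
      note("mediator: ", nrow(h2), " instruments for the second step")
    } else {
      note("mediator: no instruments; mediation skipped")
    }
    if (!is.null(step2)) {
      med_results <- list()
      for (gene in significant) {
        tg <- cfg$targets[cfg$targets$gene == gene, ]
        h <- target_h[[gene]]
        if (is.null(h)) next
        sel <- select_drug_target_instruments(
          cfg$exposures[[tg$trait]], region = tg, ld = cfg$ld[[tg$gene]],
          window_kb = thr$clump_target$kb, p_threshold = thr$p_gwas,
          maf_min = thr$maf, r2_threshold = thr$clump_target$r2,
          f_min = thr$f_min
        )
        h1 <- tryCatch(harmonize(sel, cfg$mediator),
                       targetmr_empty_error = function(e) NULL)
        if (is.null(h1)) {
          note("mediation ", gene, ": no shared variants with mediator")
          next
        }
        step1 <- if (nrow(h1) >= 2) mr_ivw(h1) else wald_ratio(h1)
        total <- if (nrow(h) >= 2) mr_ivw(h) else wald_ratio(h)
        if (tg$flip) {
          total$beta <- -total$beta
          step1$beta <- -step1$beta
        }
        med_results[[gene]] <- two_step_mediation(total, step1, step2,
                                                  target = gene)
      }
      mediation_tbl <- mediation_report(med_results)
    }
  }

  structure(list(
    trait_mr = trait_mr,
    trait_mvmr = trait_mvmr %||% tibble(),
    target_mr = target_mr,
    eqtl_mr = eqtl_mr,
    coloc = coloc_tbl,
    mediation = mediation_tbl %||% mediation_report(list()),
    sensitivity = bind_rows(sens_rows),
    log = log_lines
  ), class = "results_bundle")
}

#' Write every table of a results bundle as TSV
#'
#' File contents are a pure function of the bundle (no timestamps), so
#' re-running a study with the same configuration and seed reproduces every
#' file byte-for-byte.
#'
#' @param bundle A `results_bundle` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("trait_mr", "trait_mvmr", "target_mr", "eqtl_mr",
              "coloc", "mediation", "sensitivity")
  for (tb in tables) {
    readr::write_tsv(as_tibble(bundle[[tb]]), file.path(dir, paste0(tb, ".tsv")),
                     progress = FALSE)
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  for (tb in c("trait_mr", "trait_mvmr", "target_mr", "eqtl_mr",
               "coloc", "mediation", "sensitivity")) {
    cat(sprintf("  %-12s %d row(s)\n", tb, nrow(as_tibble(x[[tb]]))))
  }
  invisible(x)
}
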