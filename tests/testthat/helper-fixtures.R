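# shared fixture builders and independent oracles

# build a harmonized_set directly from effect vectors
make_h <- function(beta_exposure, beta_outcome, se_outcome,
                   se_exposure = rep(0.01, length(beta_exposure)),
                   snp_id = sprintf("rs%03d", seq_along(beta_exposure))) {
  k <- length(beta_exposure)
  out <- tibble::tibble(
    snp_id = snp_id,
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    eaf_exposure = 0.3,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = 0.3,
    n_exposure = 1e5, n_outcome = 1e5,
    chrom = "1", pos = seq_len(k) * 1000L, palindromic = FALSE
  )
  structure(out, class = c("harmonized_set", class(out)),
            flipped = 0L, dropped_palindromic = 0L, dropped_unmatched = 0L,
            outcome_type = "quantitative")
}

# minimal well-formed summary-statistics data frame
make_stats_df <- function(n = 3, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 100000L,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = runif(n, 0.1, 0.9),
    beta = rnorm(n, 0, 0.05), se = runif(n, 0.005, 0.02),
    pvalue = runif(n, 1e-12, 0.9), n = 50000
  ))
}

# exhaustive configuration-enumeration colocalization oracle (linear space,
# unsimplified Wakefield formula, explicit double loop for H3)
oracle_coloc <- function(b1, s1, b2, s2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd1 = 0.15, sd2 = 0.15) {
  abf <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    sqrt(1 - r) * exp((b / s)^2 * r / 2)
  }
  a1 <- abf(b1, s1, sd1)
  a2 <- abf(b2, s2, sd2)
  k <- length(a1)
  l0 <- 1
  l1 <- p1 * sum(a1)
  l2 <- p2 * sum(a2)
  l3 <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) l3 <- l3 + p1 * p2 * a1[i] * a2[j]
    }
  }
  l4 <- p12 * sum(a1 * a2)
  post <- c(l0, l1, l2, l3, l4)
  stats::setNames(post / sum(post), c("h0", "h1", "h2", "h3", "h4"))
}
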