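test_that("significance and MAF filters use strict inequalities", {
  df <- make_stats_df(4)
  df$pvalue <- c(4e-8, 5e-8, 1e-9, 1e-9)
  df$eaf <- c(0.30, 0.30, 0.995, 0.5)
  ss <- summary_stats(df, quiet = TRUE)
  kept <- filter_significant(ss, p_threshold = 5e-8, maf_min = 0.01)
  # p = 5e-8 exactly is removed; eaf 0.995 has MAF 0.005 < 0.01
  expect_setequal(kept$snp_id, c("rs001", "rs004"))
})

test_that("clumping keeps the best variant per correlated window", {
  df <- make_stats_df(2)
  df$pos <- c(100000L, 105000L)   # 5 kb apart
  df$pvalue <- c(1e-10, 1e-9)
  ss <- summary_stats(df, quiet = TRUE)
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
               dimnames = list(ss$snp_id, ss$snp_id))
  kept <- clump(ss, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(kept$snp_id, "rs001")

  # single variant is its own clump
  expect_equal(clump(ss[1, ], ld)$snp_id, "rs001")

  # different chromosomes never clump regardless of the r2 entry
  df2 <- df
  df2$chrom <- c("1", "2")
  kept2 <- clump(summary_stats(df2, quiet = TRUE), ld,
                 r2_threshold = 0.001, window_kb = 10000)
  expect_equal(nrow(kept2), 2)
})

test_that("clumping is order-stable and respects threshold limits", {
  withr::local_seed(42)
  df <- make_stats_df(12)
  df$pos <- sort(sample.int(5000000L, 12))
  df$pvalue <- runif(12, 1e-12, 1e-8)
  ss <- summary_stats(df, quiet = TRUE)
  ids <- ss$snp_id
  ld <- matrix(runif(144, 0, 0.8), 12, 12, dimnames = list(ids, ids))
  ld <- (ld + t(ld)) / 2
  diag(ld) <- 1

  a <- clump(ss, ld, r2_threshold = 0.1, window_kb = 10000)
  shuffle <- ss[sample.int(12), ]
  b <- clump(shuffle, ld, r2_threshold = 0.1, window_kb = 10000)
  expect_equal(a$snp_id, b$snp_id)

  # threshold above 1 removes nothing
  expect_equal(nrow(clump(ss, ld, r2_threshold = 1.01, window_kb = 1e6)), 12)
  # threshold 0 with an enormous window keeps one variant per chromosome
  expect_equal(nrow(clump(ss, ld, r2_threshold = 0, window_kb = 1e9)), 1)

  # variants absent from the LD matrix are uncorrelated, with a warning
  expect_warning(clump(ss, ld[1:6, 1:6], r2_threshold = 0.1), "absent")
})

test_that("variance explained follows the EAF-weighted formula", {
  # hand arithmetic: numerator 0.005; denominator 0.005 + 0.5*100*0.0001
  expect_equal(snp_r2(beta = 0.1, eaf = 0.5, se = 0.01, n = 100), 0.5)
  expect_equal(snp_r2(beta = 0, eaf = 0.3, se = 0.01, n = 1000), 0)
  # symmetric in eaf <-> 1 - eaf
  expect_equal(snp_r2(0.07, 0.2, 0.01, 5e4), snp_r2(0.07, 0.8, 0.01, 5e4))
  expect_error(snp_r2(0.1, 1, 0.01, 100), class = "targetmr_degenerate_error")

  # algebraic simplification beta^2 / (beta^2 + n se^2) is the oracle
  withr::local_seed(7)
  for (i in 1:50) {
    beta <- rnorm(1, 0, 0.1); eaf <- runif(1, 0.01, 0.99)
    se <- runif(1, 0.001, 0.05); n <- sample(1000:500000, 1)
    expect_equal(snp_r2(beta, eaf, se, n), beta^2 / (beta^2 + n * se^2),
                 tolerance = 1e-12)
  }
})

test_that("F statistic matches its formula and flags weak instruments", {
  expect_equal(f_statistic(0, 100), 0)
  expect_equal(f_statistic(0.01, 1000), 0.01 * 998 / 0.99)
  expect_gt(f_statistic(0.01, 2000), f_statistic(0.01, 1000))
  expect_error(f_statistic(1, 100), class = "targetmr_degenerate_error")
})

test_that("drug-target selection restricts to a closed gene window", {
  region <- list(gene = "GENE1", chrom = "1", start = 1000000, end = 1050000)
  df <- make_stats_df(4)
  df$pos <- c(
    1000000L - 250000L,      # exactly at the window edge: kept
    1000000L - 300000L,      # 300 kb upstream: excluded
    1020000L,                # inside the gene
    1050000L + 250000L       # downstream edge: kept
  )
  df$pvalue <- rep(1e-12, 4)
  df$beta <- rep(0.05, 4)    # strong instruments (F >> 10)
  df$eaf <- rep(0.3, 4)
  df$se <- rep(0.004, 4)
  ss <- summary_stats(df, quiet = TRUE)

  sel <- select_drug_target_instruments(ss, region, ld = NULL,
                                        window_kb = 250)
  expect_setequal(sel$snp_id, c("rs001", "rs003", "rs004"))
  expect_true(all(sel$f_stat > 10))
  expect_false(attr(sel, "uninstrumentable"))
  expect_true(is.finite(attr(sel, "mean_f")))

  # three significant in-window variants with pairwise r2 = 0.05 all survive
  ld <- matrix(0.05, 3, 3,
               dimnames = list(sel$snp_id, sel$snp_id))
  diag(ld) <- 1
  sel2 <- select_drug_target_instruments(ss, region, ld = ld, window_kb = 250)
  expect_equal(nrow(sel2), 3)
})

test_that("cis-eQTL selection clumps at r2 < 0.1 and flags empty sets", {
  region <- list(gene = "GENE1", chrom = "1", start = 1000000, end = 1050000)
  df <- make_stats_df(2)
  df$pos <- c(1010000L, 1020000L)
  df$pvalue <- c(1e-12, 1e-9)
  df$beta <- c(0.06, 0.05); df$se <- 0.004; df$eaf <- 0.3
  ss <- summary_stats(df, quiet = TRUE)
  ld <- matrix(c(1, 0.15, 0.15, 1), 2, 2,
               dimnames = list(ss$snp_id, ss$snp_id))

  sel <- select_cis_eqtl_instruments(ss, region, ld = ld)
  expect_equal(sel$snp_id, "rs001")   # r2 0.15 >= 0.1: weaker p removed

  # nothing genome-wide significant: flagged, not an error
  weak <- df
  weak$pvalue <- c(1e-6, 1e-7)
  expect_message(
    sel2 <- select_cis_eqtl_instruments(summary_stats(weak, quiet = TRUE),
                                        region, ld = ld),
    "no instrument"
  )
  expect_equal(nrow(sel2), 0)
  expect_true(attr(sel2, "uninstrumentable"))

  # a single isolated significant eQTL gives a one-variant set
  sel3 <- select_cis_eqtl_instruments(
    summary_stats(df[1, ], quiet = TRUE), region, ld = NULL)
  expect_equal(nrow(sel3), 1)
})

test_that("LD matrices and gene regions read from TSV validate", {
  ids <- c("rs1", "rs2")
  m <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(ids, ids))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(m) |> dplyr::mutate(snp_id = ids, .before = 1),
                   path)
  back <- read_ld_matrix(path)
  expect_equal(back, m)

  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgene", "19\t1000000\t1050000\tLDLR"), bed)
  reg <- read_gene_regions(bed)
  expect_equal(reg$gene, "LDLR")
  expect_error(read_gene_regions(path), class = "targetmr_config_error")
})
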