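test_that("well-formed tables parse and invalid rows are dropped with counts", {
  df <- make_stats_df(3)
  ss <- summary_stats(df, trait_id = "LDL", quiet = TRUE)
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3)
  expect_equal(attr(ss, "n_dropped"), 0L)

  bad <- df
  bad$se[2] <- 0
  expect_message(ss2 <- summary_stats(bad, trait_id = "LDL"), "dropped 1")
  expect_equal(nrow(ss2), 2)
  expect_equal(attr(ss2, "n_dropped"), 1L)
  expect_false("rs002" %in% ss2$snp_id)

  # duplicate snp_id: first occurrence wins
  dup <- dplyr::bind_rows(df, df[1, ] |> dplyr::mutate(beta = 99))
  ss3 <- summary_stats(dup, quiet = TRUE)
  expect_equal(nrow(ss3), 3)
  expect_equal(ss3$beta[ss3$snp_id == "rs001"], df$beta[1])

  expect_error(summary_stats(df[, -4], quiet = TRUE),
               class = "targetmr_config_error")
  allbad <- df |> dplyr::mutate(pvalue = 0)
  expect_error(summary_stats(allbad, quiet = TRUE),
               class = "targetmr_empty_error")
})

test_that("reader auto-detects delimiter and honours the column map", {
  df <- make_stats_df(4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, tsv)
  ss_tsv <- read_summary_stats(tsv, trait_id = "t", quiet = TRUE)
  expect_equal(nrow(ss_tsv), 4)

  # shuffled, renamed columns with a column map give the identical object
  shuffled <- df[, c(5, 1, 3, 2, 8, 4, 10, 6, 9, 7)]
  names(shuffled)[names(shuffled) == "snp_id"] <- "SNP"
  names(shuffled)[names(shuffled) == "beta"] <- "b"
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, csv)
  ss_csv <- read_summary_stats(csv, column_map = c(snp_id = "SNP", beta = "b"),
                               trait_id = "t", quiet = TRUE)
  expect_equal(as.data.frame(ss_csv), as.data.frame(ss_tsv))

  expect_error(
    read_summary_stats(csv, column_map = c(snp_id = "nope"), quiet = TRUE),
    class = "targetmr_config_error"
  )
  expect_error(read_summary_stats("/no/such/file.tsv", quiet = TRUE),
               class = "targetmr_config_error")
})

make_pair <- function() {
  ex <- summary_stats(tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("A", "C", "A", "G"),
    other_allele  = c("G", "T", "T", "C"),
    eaf = c(0.3, 0.4, 0.2, 0.25), beta = c(0.10, 0.08, 0.05, 0.04),
    se = 0.01, pvalue = 1e-10, n = 50000
  ), trait_id = "exposure", quiet = TRUE)
  ou <- summary_stats(tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs9"),
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 900L),
    effect_allele = c("G", "C", "A", "C", "A"),   # rs1 swapped, rs4 palindromic C/G
    other_allele  = c("A", "T", "T", "G", "G"),
    eaf = c(0.7, 0.4, 0.2, 0.75, 0.5),
    beta = c(-0.05, 0.03, 0.02, 0.01, 0), se = 0.01,
    pvalue = c(1e-6, 1e-3, 0.02, 0.5, 0.9), n = 40000
  ), trait_id = "outcome", quiet = TRUE)
  list(ex = ex, ou = ou)
}

test_that("harmonization flips swapped alleles and drops palindromes", {
  p <- make_pair()
  h <- harmonize(p$ex, p$ou, palindrome_policy = "drop")
  cnt <- harmonization_counts(h)

  # rs1: outcome coded G/A with beta -0.05 -> flipped to +0.05 on A/G
  expect_equal(h$beta_outcome[h$snp_id == "rs1"], 0.05)
  expect_equal(h$eaf_outcome[h$snp_id == "rs1"], 0.3)
  expect_equal(cnt$flipped, 1L)   # flips counted among retained variants

  # rs3 is A/T palindromic, rs4 is C/G palindromic -> both dropped
  expect_false(any(c("rs3", "rs4") %in% h$snp_id))
  expect_equal(cnt$dropped_palindromic, 2L)

  # identical coding passes through untouched
  expect_equal(h$beta_outcome[h$snp_id == "rs2"], 0.03)

  # bookkeeping closes over the snp_id intersection (rs9 never intersects)
  expect_equal(cnt$n_snp + cnt$dropped_palindromic + cnt$dropped_unmatched, 4L)

  expect_error(harmonize(p$ex, p$ex[0, ]), class = "targetmr_empty_error")
})

test_that("palindrome infer policy aligns by frequency and drops common ones", {
  p <- make_pair()
  h <- harmonize(p$ex, p$ou, palindrome_policy = "infer",
                 maf_infer_threshold = 0.42)
  # rs3 (A/T): eaf 0.2 both traits, same side of 0.5 -> kept unflipped
  expect_equal(h$beta_outcome[h$snp_id == "rs3"], 0.02)
  # rs4 (C/G swapped to exposure coding gives eaf 0.25 vs 0.25) kept
  expect_true("rs4" %in% h$snp_id)

  # an A/T variant with opposite frequency sides gets sign-corrected
  ex2 <- p$ex
  ou2 <- p$ou
  ou2$eaf[ou2$snp_id == "rs3"] <- 0.8
  h2 <- harmonize(ex2, ou2, palindrome_policy = "infer")
  expect_equal(h2$beta_outcome[h2$snp_id == "rs3"], -0.02)
})

test_that("harmonization is idempotent and sign-consistent", {
  p <- make_pair()
  h <- harmonize(p$ex, p$ou)

  # rebuild the two traits from the harmonized set and harmonize again
  rebuild <- function(h, side) {
    summary_stats(tibble::tibble(
      snp_id = h$snp_id, chrom = h$chrom, pos = h$pos,
      effect_allele = h$effect_allele, other_allele = h$other_allele,
      eaf = h[[paste0("eaf_", side)]], beta = h[[paste0("beta_", side)]],
      se = h[[paste0("se_", side)]], pvalue = 0.5, n = h[[paste0("n_", side)]]
    ), quiet = TRUE)
  }
  h2 <- harmonize(rebuild(h, "exposure"), rebuild(h, "outcome"))
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(attr(h2, "flipped"), 0L)
  expect_equal(attr(h2, "dropped_palindromic"), 0L)

  # flipping every outcome record's allele coding changes nothing
  ou_flipped <- p$ou
  tmp <- ou_flipped$effect_allele
  ou_flipped$effect_allele <- ou_flipped$other_allele
  ou_flipped$other_allele <- tmp
  ou_flipped$beta <- -ou_flipped$beta
  ou_flipped$eaf <- 1 - ou_flipped$eaf
  h3 <- harmonize(p$ex, ou_flipped)
  expect_equal(h3$beta_outcome, h$beta_outcome)
  expect_equal(h3$snp_id, h$snp_id)
})

test_that("harmonized sets round-trip through the fixed-column TSV writer", {
  p <- make_pair()
  h <- harmonize(p$ex, p$ou)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back)[1:3], c("snp_id", "effect_allele", "other_allele"))
  expect_equal(back$beta_outcome, h$beta_outcome)
})
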