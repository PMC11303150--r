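test_that("Wald ratio follows its definition and sign convention", {
  h <- make_h(0.2, 0.1, se_outcome = 0.05)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.25)

  expect_equal(wald_ratio(make_h(0.2, 0, se_outcome = 0.05))$beta, 0)

  # negating the exposure coding flips the ratio's sign, not its magnitude
  h2 <- make_h(-0.2, 0.1, se_outcome = 0.05)
  expect_equal(wald_ratio(h2)$beta, -0.5)
  expect_equal(wald_ratio(h2)$se, 0.25)

  expect_error(wald_ratio(make_h(0, 0.1, se_outcome = 0.05)),
               class = "targetmr_degenerate_error")
})

test_that("IVW pools ratios by inverse variance with floored Q inflation", {
  # ratios 0.5 (se 0.1) and 0.7 (se 0.2): weights 100, 25 -> beta 0.54
  h <- make_h(c(1, 1), c(0.5, 0.7), se_outcome = c(0.1, 0.2))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.54)
  expect_equal(est$q_df, 1L)

  # identical ratios: Q = 0, random-effects se equals fixed se
  h0 <- make_h(c(1, 1, 1), c(0.4, 0.4, 0.4), se_outcome = c(0.1, 0.1, 0.1))
  est0 <- mr_ivw(h0)
  expect_equal(est0$q_stat, 0)
  expect_equal(est0$se, sqrt(1 / (3 / 0.1^2)))

  # the max(1, .) contract: under-dispersion never shrinks the SE
  estf <- mr_ivw(h0, random_effects = FALSE)
  expect_equal(est0$se, estf$se)

  expect_error(mr_ivw(make_h(1, 0.5, se_outcome = 0.1)),
               class = "targetmr_insufficient_error")
})

test_that("IVW equals the no-intercept WLS slope (algebraic identity)", {
  withr::local_seed(11)
  for (rep in 1:20) {
    k <- sample(3:40, 1)
    h <- make_h(rnorm(k, 0.05, 0.02), rnorm(k, 0.01, 0.02),
                se_outcome = runif(k, 0.005, 0.05))
    wls <- lm(beta_outcome ~ beta_exposure - 1, data = h,
              weights = 1 / h$se_outcome^2)
    expect_equal(mr_ivw(h)$beta, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("Egger regression recovers slope and intercept", {
  # exact line through the origin: slope recovered, intercept 0
  bx <- c(0.05, 0.10, 0.15, 0.20)
  h <- make_h(bx, 0.4 * bx, se_outcome = rep(0.01, 4))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)

  # adding a constant offset with equal weights shifts only the intercept
  h2 <- make_h(bx, 0.4 * bx + 0.03, se_outcome = rep(0.01, 4))
  est2 <- mr_egger(h2)
  expect_equal(est2$beta, 0.4, tolerance = 1e-12)
  expect_equal(est2$intercept, 0.03, tolerance = 1e-12)

  # matches closed-form WLS with intercept on a noisy fixture
  withr::local_seed(5)
  k <- 8
  h3 <- make_h(runif(k, 0.02, 0.2), rnorm(k, 0.02, 0.01),
               se_outcome = runif(k, 0.005, 0.02))
  ref <- lm(beta_outcome ~ beta_exposure, data = h3,
            weights = 1 / h3$se_outcome^2)   # bx already all positive
  est3 <- mr_egger(h3)
  expect_equal(est3$beta, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(est3$intercept, unname(coef(ref)[1]), tolerance = 1e-10)

  # orientation: flipping an instrument's coding leaves the fit unchanged
  h4 <- h3
  h4$beta_exposure[1] <- -h4$beta_exposure[1]
  h4$beta_outcome[1] <- -h4$beta_outcome[1]
  expect_equal(mr_egger(h4)$beta, est3$beta)

  expect_error(mr_egger(make_h(c(1, 1), c(0.1, 0.2), se_outcome = c(0.1, 0.1))),
               class = "targetmr_insufficient_error")
})

test_that("weighted median interpolates at cumulative weight one half", {
  # equal weights, odd count: the ordinary median
  h <- make_h(c(1, 1, 1), c(0.1, 0.5, 0.9), se_outcome = c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.5)

  # a dominant instrument (> 50% of weight) pins the estimate to its ratio
  hd <- make_h(c(1, 2, 1), c(0.2, 2 * 0.7, 0.9),
               se_outcome = c(0.2, 0.2, 0.2))
  # weights prop to (bx/se)^2: 25, 100, 25 -> middle holds 2/3 of the weight
  expect_equal(mr_weighted_median(hd, n_boot = 50, seed = 1)$beta, 0.7)

  # equal weights equals the ordinary median for even counts too
  he <- make_h(rep(1, 4), c(0.1, 0.3, 0.5, 0.9), se_outcome = rep(0.1, 4))
  expect_equal(mr_weighted_median(he, n_boot = 50, seed = 1)$beta,
               median(c(0.1, 0.3, 0.5, 0.9)))

  # robustness: 7 valid instruments at 0.3, 3 outliers at 2.0 with small weight
  bx <- c(rep(1, 7), rep(0.3, 3))
  by <- c(rep(0.3, 7) + c(-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03),
          rep(2.0 * 0.3, 3))
  ho <- make_h(bx, by, se_outcome = rep(0.1, 10))
  est <- mr_weighted_median(ho, n_boot = 200, seed = 2)
  expect_lt(abs(est$beta - 0.3), 0.05)
})

test_that("mode estimators find the dominant ratio cluster", {
  # degenerate: all ratios equal
  h0 <- make_h(rep(1, 3), rep(0.7, 3), se_outcome = rep(0.1, 3))
  expect_equal(mr_mode(h0, n_boot = 50, seed = 1)$beta, 0.7)

  # 8 ratios near 0.3, 2 near 1.5: mode lands on the big cluster
  withr::local_seed(3)
  ratios <- c(rnorm(8, 0.3, 0.02), rnorm(2, 1.5, 0.02))
  h <- make_h(rep(1, 10), ratios, se_outcome = rep(0.05, 10))
  est <- mr_mode(h, weighted = FALSE, n_boot = 100, seed = 4)
  bw <- targetmr:::mode_bandwidth(ratios, 1)
  expect_lt(abs(est$beta - 0.3), bw + 0.05)

  # weighted and simple modes disagree when the minority cluster carries
  # the majority of the weight
  bx <- c(rep(0.2, 6), rep(2, 3))
  by <- c(0.2 * c(0.28, 0.29, 0.30, 0.31, 0.32, 0.30), 2 * c(1.49, 1.5, 1.51))
  hw <- make_h(bx, by, se_outcome = rep(0.05, 9))
  simple <- mr_mode(hw, weighted = FALSE, n_boot = 50, seed = 5)$beta
  weighted <- mr_mode(hw, weighted = TRUE, n_boot = 50, seed = 5)$beta
  expect_lt(abs(simple - 0.3), 0.1)
  expect_lt(abs(weighted - 1.5), 0.1)
})

test_that("leave-one-out flags gross outliers and only them", {
  withr::local_seed(9)
  k <- 10
  bx <- runif(k, 0.05, 0.2)
  # perfectly homogeneous instruments: omission moves nothing
  h <- make_h(bx, 0.3 * bx, se_outcome = rep(0.002, k))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), k)
  expect_false(any(loo$influential))
  h$beta_outcome <- 0.3 * h$beta_exposure + rnorm(k, 0, 0.002)

  # one gross outlier (ratio ~10x the rest) is flagged when left out
  h$beta_outcome[1] <- 3 * h$beta_exposure[1]
  loo2 <- mr_leave_one_out(h)
  expect_true(loo2$influential[loo2$snp_id == h$snp_id[1]])
})

test_that("multivariable IVW gives conditional estimates per exposure", {
  withr::local_seed(21)
  k <- 6
  x1 <- runif(k, 0.05, 0.2)

  # an all-zero nuisance column leaves the first estimate at univariable IVW
  h <- make_h(x1, 0.5 * x1 + rnorm(k, 0, 0.01), se_outcome = rep(0.01, k))
  X <- data.frame(main = x1, nuisance = rep(0, k))
  expect_warning(mv <- mr_multivariable_ivw(X, h$beta_outcome, h$se_outcome),
                 "all-zero")
  expect_equal(mv$beta[mv$exposure == "main"], mr_ivw(h)$beta,
               tolerance = 1e-10)
  expect_true(is.na(mv$beta[mv$exposure == "nuisance"]))

  # genuine collinearity is an error naming the offending exposures
  expect_error(
    mr_multivariable_ivw(data.frame(a = x1, b = 2 * x1),
                         h$beta_outcome, h$se_outcome),
    class = "targetmr_collinear_error"
  )

  # orthogonal exposures with equal weights: each slope equals its own
  # separate no-intercept regression
  x2 <- c(1, -1, 1, -1, 1, -1) * 0.1
  x1o <- rep(0.1, 6)                     # sum(x1o * x2) = 0
  y <- 0.3 * x1o - 0.2 * x2 + rnorm(6, 0, 0.001)
  mv2 <- mr_multivariable_ivw(data.frame(a = x1o, b = x2), y, rep(0.01, 6))
  sep_a <- sum(x1o * y) / sum(x1o^2)
  sep_b <- sum(x2 * y) / sum(x2^2)
  expect_equal(mv2$beta[mv2$exposure == "a"], sep_a, tolerance = 1e-10)
  expect_equal(mv2$beta[mv2$exposure == "b"], sep_b, tolerance = 1e-10)

  expect_error(
    mr_multivariable_ivw(data.frame(a = c(1, 2), b = c(2, 4), c = c(0, 1)),
                         c(0.1, 0.2), c(0.1, 0.1)),
    class = "targetmr_insufficient_error"
  )
})

test_that("multivariable IVW recovers direct effects on synthetic data", {
  withr::local_seed(33)
  k <- 40
  x1 <- rnorm(k, 0, 0.05)
  x2 <- rnorm(k, 0, 0.05)
  se_y <- rep(0.01, k)
  y <- 0.3 * x1 - 0.2 * x2 + rnorm(k, 0, se_y)
  mv <- mr_multivariable_ivw(data.frame(e1 = x1, e2 = x2), y, se_y)
  expect_lt(abs(mv$beta[1] - 0.3), 2 * mv$se[1])
  expect_lt(abs(mv$beta[2] + 0.2), 2 * mv$se[2])
})

test_that("odds-ratio conversion exponentiates and the flip is an involution", {
  est <- wald_ratio(make_h(1, 0, se_outcome = 0.1))
  est$se <- 0.1
  or0 <- to_odds_ratio(est)
  expect_equal(or0$or_point, 1)
  expect_equal(round(or0$or_low, 2), 0.82)
  expect_equal(round(or0$or_high, 2), 1.22)

  est2 <- wald_ratio(make_h(1, log(1.94), se_outcome = 0.1))
  expect_equal(to_odds_ratio(est2)$or_point, 1.94)

  flipped_twice <- to_odds_ratio(to_odds_ratio(est2, scale_flip = TRUE),
                                 scale_flip = TRUE)
  expect_equal(flipped_twice$beta, est2$beta)
  expect_equal(flipped_twice$or_point, to_odds_ratio(est2)$or_point)
})

test_that("the estimator stack degrades gracefully with instrument count", {
  h1 <- make_h(0.2, 0.1, se_outcome = 0.05)
  expect_equal(mr_all_methods(h1)$method, "wald")
  h2 <- make_h(c(1, 1), c(0.5, 0.7), se_outcome = c(0.1, 0.2))
  expect_equal(mr_all_methods(h2)$method, "ivw_re")
  h5 <- make_h(c(0.8, 0.9, 1, 1.1, 1.2),
               c(0.8, 0.9, 1, 1.1, 1.2) * c(0.28, 0.3, 0.3, 0.31, 0.33),
               se_outcome = rep(0.05, 5))
  out <- mr_all_methods(h5, n_boot = 50, seed = 1)
  expect_setequal(out$method, c("ivw_re", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
})
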