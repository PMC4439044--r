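test_that("natural escapement arithmetic follows the retained-fraction products", {
  # no strays, single age: the full return-year escapement
  expect_equal(natural_escapement(c(`2003` = 5000), c(`3` = 1), 0, 0, 2000),
               5000)
  # both stray removals at 50%: a quarter of the total is retained
  expect_equal(natural_escapement(c(`2003` = 5000), c(`3` = 1), 0.5, 0.5, 2000),
               1250)
  # three return ages weighted by the age distribution
  esc <- c(`2002` = 1000, `2003` = 4000, `2004` = 2000)
  ages <- c(`2` = 0.07, `3` = 0.87, `4` = 0.06)
  expect_equal(
    natural_escapement(esc, ages, 0.1, 0.2, 2000),
    (1000 * 0.07 + 4000 * 0.87 + 2000 * 0.06) * 0.9 * 0.8)
  # per-year adclip rates
  expect_equal(
    natural_escapement(esc, ages, c(`2002` = 0, `2003` = 0.5, `2004` = 1), 0, 2000),
    1000 * 0.07 + 4000 * 0.5 * 0.87)
  expect_error(natural_escapement(c(`2003` = 5000), c(`3` = 1), 0, 0, 2002),
               "2005")
})

test_that("spawners by phenotype partition the natural escapement exactly", {
  beta <- c(fry = 0.23, parr = 0.64, smolt = 0.13)
  E <- spawners_by_phenotype(7800, beta)
  expect_equal(sum(E), 7800)
  expect_equal(unname(E / 7800), unname(beta))
  expect_equal(unname(spawners_by_phenotype(100, c(1, 0, 0))), c(100, 0, 0))
  expect_equal(unname(spawners_by_phenotype(0, beta)), c(0, 0, 0))
})

test_that("survival ratios and intervals follow the log-scale delta method", {
  s <- survival_estimate(E = 3781, J = 212042, se_J = 40000, se_beta = 0.05,
                         beta = 0.64)
  expect_equal(s$S, 3781 / 212042)
  expect_equal(s$se_logS, sqrt((40000 / 212042)^2 + (0.05 / 0.64)^2))
  # endpoints symmetric in log space
  expect_equal(log(s$hi95) - log(s$S), log(s$S) - log(s$lo95))
  # zero SEs collapse the interval onto the estimate
  s0 <- survival_estimate(E = 100, J = 10000, se_J = 0, se_beta = 0, beta = 0.5)
  expect_equal(s0$lo95, s0$S)
  expect_equal(s0$hi95, s0$S)
  expect_error(survival_estimate(E = 10, J = 0, beta = 0.5), "J > 0")
})

test_that("delta interval matches a parametric bootstrap of the ratio at small CVs", {
  E_n <- 5894; beta <- 0.64; J <- 212042
  for (cv in c(0.05, 0.1)) {
    s <- survival_estimate(E = E_n * beta, J = J, se_J = cv * J,
                           se_beta = cv * beta, beta = beta)
    bs <- survival_ci_bootstrap(E_n, beta, cv * beta, J, cv * J,
                                n_boot = 2e5, seed = 31)
    expect_equal(s$lo95, unname(bs["lo95"]), tolerance = 0.02)
    expect_equal(s$hi95, unname(bs["hi95"]), tolerance = 0.02)
  }
})

test_that("interval-width SE mapping inverts the log-scale CI construction", {
  # a log-normal interval maps back to its generating SE
  S <- 0.02; se_log <- 0.12
  lo <- exp(log(S) - 1.96 * se_log); hi <- exp(log(S) + 1.96 * se_log)
  expect_equal(se_from_interval(S, lo, hi) / S, se_log)
  # sd method uses the draws directly
  set.seed(32)
  d <- rnorm(1000, 10, 2)
  expect_equal(se_from_interval(10, 8, 12, draws = d, method = "sd"), sd(d))
})

test_that("half-up rounding reports percentages at two decimals", {
  expect_equal(round_half_up(0.185, 2), 0.19)
  expect_equal(round_half_up(1.204, 2), 1.20)
  expect_equal(round_half_up(c(0.0726, 1.7831) , 2), c(0.07, 1.78))
})
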