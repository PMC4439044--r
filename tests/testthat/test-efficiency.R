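test_that("intercept-only fit recovers the recapture fraction in closed form", {
  trials <- data.frame(date = as.Date("2000-02-01") + 0:9,
                       released = 100L, recaptured = 50L,
                       phenotype = rep(phenotype_levels(), length.out = 10),
                       flow = runif(10, 5, 50))
  fit <- fit_efficiency(trials, formula = ~1)
  expect_equal(unname(plogis(fit$coefficients)), 0.5, tolerance = 1e-8)
})

test_that("pure binomial trials give dispersion near 1 and coefficient recovery", {
  set.seed(11)
  beta <- c(`(Intercept)` = -1.5, `log(flow)` = -0.3,
            phenotypeparr = -0.2, phenotypesmolt = -0.4)
  phis <- replicate(20, {
    flow <- runif(60, 5, 80)
    ph <- factor(rep(phenotype_levels(), 20), levels = phenotype_levels())
    X <- model.matrix(~ log(flow) + phenotype, data.frame(flow = flow, phenotype = ph))
    p <- plogis(drop(X %*% beta))
    trials <- data.frame(date = as.Date("2000-01-10"), released = 200L,
                         recaptured = rbinom(60, 200L, p),
                         phenotype = ph, flow = flow)
    fit_efficiency(trials)$dispersion
  })
  expect_equal(mean(phis), 1, tolerance = 0.1)

  # large single fit: every coefficient within 2 SE of truth
  set.seed(12)
  flow <- runif(600, 5, 80)
  ph <- factor(rep(phenotype_levels(), 200), levels = phenotype_levels())
  X <- model.matrix(~ log(flow) + phenotype, data.frame(flow = flow, phenotype = ph))
  p <- plogis(drop(X %*% beta))
  trials <- data.frame(date = as.Date("2000-01-10"), released = 500L,
                       recaptured = rbinom(600, 500L, p),
                       phenotype = ph, flow = flow)
  fit <- fit_efficiency(trials)
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$coefficients - beta) <= 2 * se))
})

test_that("overdispersed trials yield phi approximating the generating value", {
  set.seed(13)
  phis <- replicate(20, {
    flow <- runif(80, 5, 80)
    ph <- factor(rep(phenotype_levels(), length.out = 80),
                 levels = phenotype_levels())
    p <- plogis(-1.5 - 0.3 * log(flow))
    trials <- data.frame(date = as.Date("2000-01-10"), released = 200L,
                         recaptured = rbetabinom(80, 200L, p, phi = 3),
                         phenotype = ph, flow = flow)
    fit_efficiency(trials)$dispersion
  })
  expect_equal(mean(phis), 3, tolerance = 0.25)
})

test_that("missing phenotypes and degenerate designs are reported", {
  trials <- data.frame(date = as.Date("2000-02-01"), released = 100L,
                       recaptured = 10L, phenotype = "fry", flow = 20)
  expect_error(fit_efficiency(trials), "parr, smolt")
})

test_that("beta-binomial draws match binomial moments at phi = 1 and inflate at phi > 1", {
  set.seed(21)
  x1 <- rbetabinom(20000, 50, 0.2, phi = 1)
  expect_equal(mean(x1), 10, tolerance = 0.02)
  expect_equal(var(x1), 50 * 0.2 * 0.8, tolerance = 0.05)
  x3 <- rbetabinom(20000, 50, 0.2, phi = 3)
  expect_equal(mean(x3), 10, tolerance = 0.05)
  expect_equal(var(x3), 3 * 50 * 0.2 * 0.8, tolerance = 0.1)
  # degenerate edges
  expect_true(all(rbetabinom(100, 10, 1, phi = 2) == 10))
  expect_true(all(rbetabinom(100, 10, 0, phi = 2) == 0))
  expect_true(all(rbetabinom(100, 0, 0.5, phi = 2) == 0))
})

test_that("phenology metrics are ordered and match cumulative quartiles", {
  d <- as.Date("2000-01-01") + 0:99
  # single-day passage: all five metrics coincide
  one <- phenology(d, c(rep(0, 40), 100, rep(0, 59)))
  expect_true(all(unlist(one) == as.numeric(d[41])))
  # uniform passage: quartile crossings at days 25/50/75
  u <- phenology(d, rep(1, 100))
  expect_equal(u$first_date, d[1])
  expect_equal(u$iqr_start, d[25])
  expect_equal(u$median_date, d[50])
  expect_equal(u$iqr_end, d[75])
  expect_equal(u$last_date, d[100])
  # symmetric bimodal passage peaks around the centre date
  s <- phenology(d[1:5], c(3, 1, 2, 1, 3))
  expect_equal(s$median_date, d[3])
  expect_true(s$first_date <= s$iqr_start & s$iqr_start <= s$median_date)
  expect_true(s$median_date <= s$iqr_end & s$iqr_end <= s$last_date)
  expect_error(phenology(d, rep(0, 100)), "undefined")
})
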