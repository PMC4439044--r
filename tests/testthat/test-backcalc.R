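test_that("noise-free calibration recovers the line exactly and flags degeneracy", {
  or <- seq(250, 650, length.out = 30)
  fl <- 0.171 * or - 12.76
  m <- fit_or_fl(or, fl)
  expect_equal(m$slope, 0.171, tolerance = 1e-10)
  expect_equal(m$intercept, -12.76, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_error(fit_or_fl(rep(400, 10), rnorm(10, 55, 3)), "zero spread")
  expect_error(fit_or_fl(c(400, 410), c(55, 57)), "at least 3")
})

test_that("back-calculation evaluates the reported line", {
  m <- fit_or_fl(seq(250, 650, length.out = 10),
                 0.171 * seq(250, 650, length.out = 10) - 12.76)
  expect_equal(backcalculate_fl(400, m), 55.64, tolerance = 1e-8)
  expect_equal(backcalculate_fl(600, m), 89.84, tolerance = 1e-8)
  root <- 12.76 / 0.171
  expect_equal(backcalculate_fl(root, m), 0, tolerance = 1e-8)
  expect_warning(backcalculate_fl(10, m), "<= 0")
})

test_that("slope is recovered within 2 SE under Gaussian calibration noise", {
  set.seed(20)
  hits <- replicate(30, {
    or <- runif(200, 250, 650)
    fl <- 0.171 * or - 12.76 + rnorm(200, 0, 5)
    m <- fit_or_fl(or, fl)
    abs(m$slope - 0.171) <= 2 * m$slope_se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("proportion point estimates and resamples always sum to one", {
  set.seed(21)
  or <- runif(100, 250, 650)
  m <- fit_or_fl(or, 0.171 * or - 12.76 + rnorm(100, 0, 5))
  radii <- runif(57, 260, 640)
  pr <- proportions_with_ci(radii, m, n_resample = 300, seed = 5)
  expect_equal(sum(pr$beta), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(pr$replicates) - 1) < 1e-12))
  expect_true(all(pr$lo95 <= pr$hi95))
})

test_that("interval collapses to a point mass as residual spread vanishes", {
  or <- seq(250, 650, length.out = 50)
  m0 <- fit_or_fl(or, 0.171 * or - 12.76)          # all residuals ~ 0
  radii <- c(rep(420, 5), rep(460, 10), rep(500, 5))  # all parr, interior
  pr <- proportions_with_ci(radii, m0, n_resample = 200, seed = 6)
  expect_equal(unname(pr$beta), c(0, 1, 0))
  expect_equal(pr$lo95, pr$beta, tolerance = 1e-12)
  expect_equal(pr$hi95, pr$beta, tolerance = 1e-12)
})

test_that("a fish at the fry/parr boundary splits evenly under symmetric residuals", {
  # calibration with symmetric +/-4 mm residuals, fish predicted at 55.0 mm
  or <- rep(seq(300, 600, length.out = 12), each = 2)
  fl <- 0.171 * or - 12.76 + rep(c(-4, 4), 12)
  m <- fit_or_fl(or, fl)
  expect_equal(m$slope, 0.171, tolerance = 1e-10)  # balanced noise cancels
  radius_at_55 <- (55 + 12.76) / 0.171
  pr <- proportions_with_ci(radius_at_55, m, n_resample = 10000, seed = 7)
  # Monte-Carlo se of the fry share is 0.5/sqrt(10000) = 0.005
  expect_lt(abs(mean(pr$replicates[, "fry"]) - 0.5), 0.025)
})

test_that("resampled intervals are reproducible under a fixed seed", {
  set.seed(22)
  or <- runif(80, 250, 650)
  m <- fit_or_fl(or, 0.171 * or - 12.76 + rnorm(80, 0, 5))
  radii <- runif(40, 280, 620)
  a <- proportions_with_ci(radii, m, n_resample = 500, seed = 9)
  b <- proportions_with_ci(radii, m, n_resample = 500, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$lo95, b$lo95)
})
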