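test_that("posteriors are normalised, symmetric at midpoints, and decisive at site means", {
  refs <- two_site_references(n = 200, seed = 5)
  cls <- train_isoscape(refs)
  x <- seq(0.7060, 0.7075, length.out = 31)
  post <- site_posterior(cls, x)
  expect_equal(rowSums(post), rep(1, 31))
  mid <- mean(cls$means)
  expect_equal(unname(site_posterior(cls, mid)[1, ]), c(0.5, 0.5),
               tolerance = 1e-10)
  expect_gt(site_posterior(cls, cls$means[cls$sites == "STA"])[, "STA"], 0.99)
})

test_that("1-D discriminant assignment equals the nearest-mean oracle", {
  set.seed(6)
  iso <- isoscape_truth()
  refs <- do.call(rbind, lapply(seq_len(nrow(iso)), function(k) {
    data.frame(site = iso$site[k], ratio = rnorm(40, iso$mean_ratio[k], 1e-4))
  }))
  cls <- train_isoscape(refs)
  x <- runif(1000, 0.7035, 0.7095)
  post <- site_posterior(cls, x)
  lda_pred <- cls$sites[max.col(post)]
  oracle <- cls$sites[apply(abs(outer(x, cls$means, "-")), 1, which.min)]
  expect_identical(lda_pred, oracle)
})

test_that("posterior probabilities agree with MASS::lda as an independent check", {
  refs <- two_site_references(n = 100, seed = 8)
  cls <- train_isoscape(refs)
  fit <- MASS::lda(site ~ ratio, data = refs, prior = c(0.5, 0.5))
  x <- data.frame(ratio = seq(0.7063, 0.7074, length.out = 25))
  ours <- site_posterior(cls, x$ratio)
  theirs <- predict(fit, x)$posterior
  expect_equal(ours[, "SJR"], unname(theirs[, "SJR"]), tolerance = 1e-6)
  expect_equal(ours[, "STA"], unname(theirs[, "STA"]), tolerance = 1e-6)
})

test_that("jackknife scores: perfect separation gives 100%, identical sites ~50%", {
  far <- data.frame(site = rep(c("A", "B"), each = 20),
                    ratio = c(rnorm(20, 0.704, 1e-5), rnorm(20, 0.709, 1e-5)))
  js <- jackknife_scores(far)
  expect_equal(unname(js$correct), c(1, 1))
  set.seed(9)
  same <- data.frame(site = rep(c("A", "B"), each = 150),
                     ratio = rnorm(300, 0.706, 1e-4))
  expect_equal(jackknife_scores(same)$overall, 0.5, tolerance = 0.12)
  one <- rbind(far, data.frame(site = "C", ratio = 0.7055))
  expect_warning(jackknife_scores(one), "single reference")
})

test_that("natal assignment uses post-core spots and flags strays", {
  refs <- two_site_references(n = 100, seed = 10)
  cls <- train_isoscape(refs)
  prof <- data.frame(distance_um = c(70, 105, 160, 190, 220, 260, 300),
                     ratio = c(0.7080, 0.7080, rep(0.70660, 3), 0.70716, 0.70716),
                     se = 6e-5)
  a <- assign_natal(prof, cls, "STA")
  expect_false(a$is_stray)
  expect_equal(a$natal_ratio, 0.70660)   # core spots excluded from the window
  expect_equal(sum(a$posterior), 1)
  b <- assign_natal(transform(prof, ratio = 0.70716), cls, "STA")
  expect_true(b$is_stray)
  expect_identical(b$predicted_site, "SJR")
})

test_that("stray fraction is recovered from a mixed adult sample", {
  set.seed(15)
  p <- tiny_params(stray_fraction = 0.5)
  iso <- isoscape_truth()
  cohort <- generate_cohort(p, seed = 31)
  surv <- simulate_survivors(cohort, seed = 32)
  esc <- generate_escapement(surv, p, iso, seed = 33)
  spots <- generate_profiles(esc$adults, p, iso, seed = 34)
  refs <- do.call(rbind, lapply(seq_len(nrow(iso)), function(k) {
    data.frame(site = iso$site[k], ratio = rnorm(50, iso$mean_ratio[k],
                                                 iso$sd_ratio[k]))
  }))
  cls <- train_isoscape(refs)
  by_fish <- split(spots, spots$fish_id)
  stray <- vapply(by_fish, function(pr) assign_natal(pr, cls, "STA")$is_stray,
                  logical(1))
  f_true <- mean(esc$adults$natal_site != "STA")
  expect_equal(mean(stray), f_true, tolerance = 0.02)
})

test_that("exit detection finds the last natal spot on a two-plateau profile", {
  refs <- two_site_references(n = 100, seed = 12)
  cls <- train_isoscape(refs)
  prof <- data.frame(distance_um = seq(150, 500, by = 50),
                     ratio = c(rep(0.70660, 4), rep(0.70716, 4)))
  e <- detect_exit(prof, cls, "STA", "SJR")
  expect_true(e$defined)
  expect_equal(e$exit_index, 4L)
  expect_equal(e$exit_radius_um, 300)
  # re-running on the same profile is idempotent
  expect_identical(e, detect_exit(prof, cls, "STA", "SJR"))
  # a profile that never leaves the natal signature is flagged
  flat <- data.frame(distance_um = seq(150, 500, by = 50), ratio = 0.70660)
  expect_false(detect_exit(flat, cls, "STA", "SJR")$defined)
})

test_that("detected exit radius lies within one spot spacing of the true transition", {
  refs <- two_site_references(n = 200, seed = 13)
  cls <- train_isoscape(refs)
  set.seed(14)
  for (ramp_w in c(5, 15, 30)) {
    for (rep in 1:10) {
      true_exit <- runif(1, 300, 450)
      spacing <- 30
      pos <- seq(150, 650, by = spacing)
      ratio <- ifelse(pos <= true_exit, 0.70660,
                      0.70716 - 0.00056 * exp(-((pos - true_exit) / ramp_w)^2)) +
        rnorm(length(pos), 0, 4e-5)
      e <- detect_exit(data.frame(distance_um = pos, ratio = ratio),
                       cls, "STA", "SJR")
      expect_true(e$defined)
      expect_lte(abs(e$exit_radius_um - true_exit), spacing)
    }
  }
})
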