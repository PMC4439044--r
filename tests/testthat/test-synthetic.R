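test_that("cohort generation conserves requested totals exactly", {
  p <- tiny_params()
  cohort <- generate_cohort(p, seed = 41)
  requested <- sum(p$pulses$magnitude) + p$baseline_daily * nrow(cohort$daily)
  expect_equal(sum(cohort$totals), requested)
  expect_true(all(cohort$daily[, phenotype_levels()] >= 0))
  expect_equal(range(cohort$daily$date), p$season)
})

test_that("cohort generation is deterministic and handles degenerate inputs", {
  p <- tiny_params()
  a <- generate_cohort(p, seed = 42)
  b <- generate_cohort(p, seed = 42)
  expect_identical(a$daily, b$daily)
  # zero pulses, zero baseline: an empty river
  p0 <- tiny_params(baseline_daily = 0L)
  p0$pulses$magnitude <- 0L
  z <- generate_cohort(p0, seed = 1)
  expect_true(all(z$totals == 0))
  # a single one-day pulse lands entirely on its date and is conserved
  p1 <- tiny_params(baseline_daily = 0L,
                    pulses = data.frame(date = as.Date("2000-02-01"),
                                        magnitude = 10000L, sd_days = 0,
                                        flow_peak = 30))
  one <- generate_cohort(p1, seed = 2)
  expect_equal(sum(one$totals), 10000)
  day <- one$daily[one$daily$date == as.Date("2000-02-01"), ]
  expect_equal(sum(day[, phenotype_levels()]), 10000)
  expect_error(world_params(season = as.Date(c("2000-06-30", "2000-01-01"))),
               "empty season")
})

test_that("fry dominate early passage and smolts late passage", {
  cohort <- generate_cohort(tiny_params(), seed = 43)
  d <- cohort$daily
  early <- d$date <= as.Date("2000-02-28")
  late <- d$date >= as.Date("2000-05-01")
  expect_gt(sum(d$fry[early]), sum(d$smolt[early]))
  expect_gt(sum(d$smolt[late]), sum(d$fry[late]))
})

test_that("a perfect trap catches the whole cohort and omits missing days", {
  skip_days <- as.Date(c("2000-02-10", "2000-02-11"))
  p <- noisefree_params(missing_days = skip_days)
  cohort <- generate_cohort(p, seed = 44)
  trap <- simulate_trap(cohort, seed = 45)
  expect_false(any(trap$catch$date %in% skip_days))
  kept <- !cohort$daily$date %in% skip_days
  expect_equal(trap$catch$raw_count,
               unname(rowSums(cohort$daily[kept, phenotype_levels()])))
})

test_that("binomial trap catch has binomial variance at phi = 1", {
  p <- tiny_params(phi = 1,
                   eff_coefficients = c(`(Intercept)` = qlogis(0.2),
                                        `log(flow)` = 0, phenotypeparr = 0,
                                        phenotypesmolt = 0),
                   baseline_daily = 0L)
  p$pulses$magnitude <- c(0L, 20000L, 0L, 0L, 0L)  # one fry pulse
  cohort <- generate_cohort(p, seed = 46)
  set.seed(47)
  catches <- replicate(300, sum(simulate_trap(cohort, seed = NULL)$catch$raw_count))
  n <- sum(cohort$totals)
  expect_equal(mean(catches), n * 0.2, tolerance = 0.01)
  expect_equal(var(catches), n * 0.2 * 0.8, tolerance = 0.15)
})

test_that("daily measurements respect the 50-fish cap", {
  cohort <- generate_cohort(tiny_params(), seed = 48)
  trap <- simulate_trap(cohort, seed = 49)
  per_day <- table(trap$measured$date)
  expect_lte(max(per_day), 50)
  merged <- merge(trap$catch, as.data.frame(per_day, stringsAsFactors = FALSE),
                  by.x = "date", by.y = "Var1", all.x = TRUE)
  expect_true(all(merged$raw_count >= ifelse(is.na(merged$Freq), 0, merged$Freq)))
})

test_that("noise-free profiles sit on the natal plateau up to the exit spot", {
  p <- noisefree_params()
  iso <- isoscape_truth()
  adults <- data.frame(fish_id = "F1", natal_site = "STA",
                       exit_radius_um = 430)
  prof <- generate_profiles(adults, p, iso, seed = 50)
  natal_side <- prof$distance_um <= 430 & prof$distance_um > p$core_radius_um
  expect_true(all(prof$ratio[natal_side] == 0.70660))
  expect_true(any(prof$distance_um == 430))   # a spot lies exactly at exit
  beyond <- prof$ratio[prof$distance_um > 430]
  expect_true(all(beyond > 0.70660))
  expect_true(max(prof$ratio) > 0.708)        # reaches toward the ocean value
})

test_that("noise-free calibration pairs refit the generating line exactly", {
  p <- noisefree_params()
  calib <- generate_calibration(p, seed = 51)
  m <- fit_or_fl(calib$or_um, calib$fl_mm)
  expect_equal(m$slope, p$backcalc_slope, tolerance = 1e-10)
  expect_equal(m$intercept, p$backcalc_intercept, tolerance = 1e-8)
})

test_that("escapement mixes strays at the requested fraction with consistent totals", {
  p <- tiny_params(stray_fraction = 0.5)
  cohort <- generate_cohort(p, seed = 52)
  surv <- simulate_survivors(cohort, seed = 53)
  esc <- generate_escapement(surv, p, isoscape_truth(), seed = 54)
  f <- mean(esc$adults$natal_site != "STA")
  expect_equal(f, 0.5, tolerance = 0.02)
  expect_true(all(esc$adults$natal_site != "SJR"))   # mainstem is not a natal source
  # steady-state arithmetic: natural_escapement recovers the natal count
  En <- natural_escapement(esc$config$escapement_by_year,
                           esc$config$age_distribution,
                           esc$config$adclip_stray_rate, f,
                           esc$config$cohort_year)
  expect_equal(En, nrow(surv), tolerance = 1e-8)
  # zero straying leaves the sample purely natal
  p0 <- tiny_params(stray_fraction = 0)
  esc0 <- generate_escapement(surv, p0, isoscape_truth(), seed = 55)
  expect_true(all(esc0$adults$natal_site == "STA"))
})

test_that("whole worlds are reproducible from one seed", {
  p <- tiny_params()
  a <- simulate_world(p, seed = 56)
  b <- simulate_world(p, seed = 56)
  expect_identical(a$inputs, b$inputs)
  expect_identical(a$truth, b$truth)
})
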