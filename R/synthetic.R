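#' Default isoscape ground truth for the synthetic world
#'
#' Site-level 87Sr/86Sr means and SDs emulating the Central Valley
#' baseline: a natal focal site (STA, Stanislaus-like, 0.70660 +/-
#' 0.00008), the mainstem immediately downstream (SJR, San
#' Joaquin-like, 0.70716 +/- 0.00013) and several hatchery sources that
#' supply strays.  All means lie inside the geologically plausible
#' (0.703, 0.7095) band.
#'
#' @param n_reference Reference samples per site used when simulating
#'   the training baseline.
#' @return Data frame with columns `site`, `mean_ratio`, `sd_ratio`,
#'   `n_reference`.
#' @export
isoscape_truth <- function(n_reference = 50L) {
  out <- data.frame(
    site = c("STA", "SJR", "MOK", "MER", "FEA", "NIM"),
    mean_ratio = c(0.70660, 0.70716, 0.70577, 0.70750, 0.70423, 0.70860),
    sd_ratio = c(0.00008, 0.00013, 0.00010, 0.00012, 0.00010, 0.00010),
    n_reference = as.integer(n_reference)
  )
  stopifnot(all(out$mean_ratio > 0.703 & out$mean_ratio < 0.7095),
            all(out$sd_ratio > 0))
  out
}

#' Parameters of the synthetic outmigration world
#'
#' Defaults describe a wet-year Stanislaus-like season: roughly 2.1
#' million outmigrants released in flow-linked pulses between January
#' and June, fry-dominated early and smolt-dominated late via a fork
#' length distribution whose mean drifts upward through the season,
#' trap efficiency of a few percent falling with flow, overdispersed
#' recaptures (phi = 2), and outmigrant-to-spawner survival of 0.07%
#' (fry), 1.78% (parr) and 0.77% (smolt).
#'
#' @param season Two dates bounding the outmigration period
#'   (inclusive).
#' @param pulses Data frame with columns `date`, `magnitude` (total
#'   fish in the pulse), `sd_days` (spread) and `flow_peak` (added flow
#'   at the crest, m3/s).
#' @param baseline_daily Baseline passage on every day (fish).
#' @param fl_mean_start,fl_mean_end Seasonal drift of the daily mean
#'   fork length (mm); the drift is logistic in season fraction with
#'   midpoint `fl_mid` and rate `fl_rate`, keeping early pulses
#'   fry-sized and late pulses smolt-sized.
#' @param fl_mid,fl_rate Midpoint and rate of the logistic size drift
#'   (season fractions).
#' @param fl_sd Daily fork-length SD (mm); the distribution is
#'   truncated at `fl_floor`.
#' @param fl_floor Smallest biologically plausible fork length (mm).
#' @param flow_baseline Base river flow (m3/s).
#' @param true_survival Named per-phenotype outmigrant-to-spawner
#'   survival probabilities.
#' @param eff_coefficients Named logit-scale truth for trap efficiency
#'   (names must match the model design: `(Intercept)`, `log(flow)`,
#'   `phenotypeparr`, `phenotypesmolt`).
#' @param phi Trap overdispersion (quasibinomial phi >= 1).
#' @param trial_release,trial_interval_days Mark-release trial size and
#'   cadence.
#' @param measure_cap Maximum fish measured per day (50, the field
#'   protocol).
#' @param backcalc_slope,backcalc_intercept,backcalc_resid_sd True
#'   OR-FL line (mm per um, mm) and residual SD used for calibration
#'   pairs.
#' @param n_calibration Number of OR-FL calibration pairs.
#' @param spot_spacing_um,ramp_width_um,profile_noise_sd,spot_se
#'   Otolith transect geometry and noise.
#' @param core_radius_um Yolk-sac core region excluded from natal
#'   assignment.
#' @param downstream_length_um Otolith distance spent in the mainstem
#'   before ocean entry.
#' @param ocean_ratio Global marine 87Sr/86Sr.
#' @param focal_site,downstream_site Site labels in the isoscape.
#' @param stray_fraction Fraction of unmarked adults that are strays
#'   from other sources.
#' @param adclip_stray_rate Fraction of the total escapement that is
#'   adclipped hatchery strays.
#' @param age_split Named age fractions of returning adults.
#' @param missing_days Dates on which the trap did not fish.
#' @return List of class `world_params`.
#' @export
world_params <- function(
    season = as.Date(c("2000-01-01", "2000-06-30")),
    pulses = data.frame(
      date = as.Date(c("2000-01-25", "2000-02-14", "2000-03-20",
                       "2000-04-20", "2000-05-08")),
      magnitude = c(350000L, 1400000L, 180000L, 120000L, 60000L),
      sd_days = c(4, 5, 6, 6, 5),
      flow_peak = c(45, 70, 35, 25, 20)),
    baseline_daily = 300L,
    fl_mean_start = 36, fl_mean_end = 92, fl_mid = 0.45, fl_rate = 0.12,
    fl_sd = 6, fl_floor = 25,
    flow_baseline = 10,
    true_survival = c(fry = 0.0007, parr = 0.0178, smolt = 0.0077),
    eff_coefficients = c(`(Intercept)` = -1.8, `log(flow)` = -0.35,
                         phenotypeparr = -0.25, phenotypesmolt = -0.5),
    phi = 2,
    trial_release = 100L, trial_interval_days = 7L,
    measure_cap = 50L,
    backcalc_slope = 0.171, backcalc_intercept = -12.76,
    backcalc_resid_sd = 5.5, n_calibration = 224L,
    spot_spacing_um = 30, ramp_width_um = 15,
    profile_noise_sd = 0.00006, spot_se = 0.00006,
    core_radius_um = 140, downstream_length_um = 150,
    ocean_ratio = 0.70918,
    focal_site = "STA", downstream_site = "SJR",
    stray_fraction = 0.18,
    adclip_stray_rate = 0.1,
    age_split = c(`2` = 0.07, `3` = 0.87, `4` = 0.06),
    missing_days = as.Date(character(0))) {
  season <- as.Date(season)
  if (season[2] < season[1]) stop("empty season")
  stopifnot(all(as.Date(pulses$date) >= season[1]),
            all(as.Date(pulses$date) <= season[2]),
            all(pulses$magnitude >= 0), phi >= 1,
            all(true_survival > 0 & true_survival < 1),
            abs(sum(age_split) - 1) < 1e-8,
            stray_fraction >= 0, stray_fraction < 1,
            adclip_stray_rate >= 0, adclip_stray_rate < 1)
  structure(as.list(environment()), class = "world_params")
}

# Truncated-normal bin probabilities over (floor, b1], (b1, b2], (b2, Inf).
phenotype_bin_probs <- function(mean, sd, floor = 25, breaks = c(55, 75)) {
  lo <- stats::pnorm(floor, mean, sd)
  cuts <- stats::pnorm(c(breaks, Inf), mean, sd)
  p <- diff(c(lo, cuts)) / (1 - lo)
  pmax(p, 0) / sum(pmax(p, 0))
}

# Draw truncated normal restricted to (lo, hi] by inverse CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + stats::runif(n) * pmax(b - a, 1e-12), mean, sd)
}

#' Generate the true outmigration cohort
#'
#' Builds the ground-truth daily passage, fork-length mixture and
#' environmental series for one season.  Pulse totals are apportioned
#' over days with a Gaussian kernel by largest-remainder rounding, so
#' requested totals are conserved exactly; each day's count is split
#' into fry/parr/smolt by a multinomial draw from the day's truncated
#' fork-length distribution.  Flow carries a peak at each pulse crest,
#' temperature ramps seasonally and turbidity tracks flow.
#'
#' @param params A [world_params()] list.
#' @param seed RNG seed (required for reproducibility).
#' @return Object of class `cohort_truth`: list with `daily` (date,
#'   flow, temp_c, turbidity_ntu, fl_mean, fl_sd, fry, parr, smolt),
#'   `totals` (per-phenotype true seasonal passage), and the
#'   generating `params`.
#' @export
generate_cohort <- function(params = world_params(), seed) {
  stopifnot(inherits(params, "world_params"))
  maybe_seed(seed)
  days <- seq(params$season[1], params$season[2], by = "day")
  nd <- length(days)
  t_frac <- if (nd > 1) (seq_len(nd) - 1) / (nd - 1) else 0

  total_by_day <- rep(as.integer(params$baseline_daily), nd)
  flow <- rep(params$flow_baseline, nd)
  for (k in seq_len(nrow(params$pulses))) {
    centre <- as.numeric(as.Date(params$pulses$date[k]) - days[1]) + 1
    sdk <- params$pulses$sd_days[k]
    w <- if (sdk > 0) stats::dnorm(seq_len(nd), centre, sdk)
         else as.numeric(seq_len(nd) == centre)
    total_by_day <- total_by_day +
      apportion_integer(params$pulses$magnitude[k], w)
    kern <- if (sdk > 0) exp(-0.5 * ((seq_len(nd) - centre) / sdk)^2)
            else as.numeric(seq_len(nd) == centre)
    flow <- flow + params$pulses$flow_peak[k] * kern
  }

  fl_mean <- params$fl_mean_start +
    (params$fl_mean_end - params$fl_mean_start) *
      stats::plogis((t_frac - params$fl_mid) / params$fl_rate)
  counts <- matrix(0L, nrow = nd, ncol = 3L,
                   dimnames = list(NULL, phenotype_levels()))
  for (d in seq_len(nd)) {
    if (total_by_day[d] == 0L) next
    pr <- phenotype_bin_probs(fl_mean[d], params$fl_sd, params$fl_floor)
    counts[d, ] <- stats::rmultinom(1L, total_by_day[d], pr)[, 1L]
  }

  temp <- 8 + 14 * t_frac + stats::rnorm(nd, 0, 0.5)
  turb <- pmax(1 + 0.25 * flow + stats::rnorm(nd, 0, 1), 0.5)
  daily <- data.frame(date = days, flow = flow, temp_c = temp,
                      turbidity_ntu = turb, fl_mean = fl_mean,
                      fl_sd = params$fl_sd, counts)
  structure(list(daily = daily,
                 totals = colSums(counts),
                 params = params),
            class = "cohort_truth")
}

#' Simulate rotary-screw-trap sampling of a cohort
#'
#' Forward model of the trap: daily per-phenotype catch is
#' beta-binomial around the true passage with logistic efficiency in
#' log flow and phenotype and overdispersion `phi`; up to
#' `measure_cap` caught fish per day are measured for fork length
#' (drawn from the day's truncated size mixture conditional on
#' phenotype); periodic mark-release trials record released/recaptured
#' counts at the ambient flow.  Records for `missing_days` are
#' omitted entirely.
#'
#' @param cohort A `cohort_truth`.
#' @param seed RNG seed.
#' @param eff_coefficients,phi,missing_days Override the values stored
#'   in the cohort's params.
#' @return List with data frames `catch` (date, raw_count,
#'   operational), `measured` (date, fl_mm), `trials` (date, released,
#'   recaptured, phenotype, flow) and the per-day true efficiency
#'   matrix `efficiency`.
#' @export
simulate_trap <- function(cohort, seed, eff_coefficients = NULL,
                          phi = NULL, missing_days = NULL) {
  stopifnot(inherits(cohort, "cohort_truth"))
  p <- cohort$params
  if (is.null(eff_coefficients)) eff_coefficients <- p$eff_coefficients
  if (is.null(phi)) phi <- p$phi
  if (is.null(missing_days)) missing_days <- p$missing_days
  stopifnot(phi >= 1)
  maybe_seed(seed)
  lev <- phenotype_levels()
  daily <- cohort$daily
  nd <- nrow(daily)

  model0 <- efficiency_model(eff_coefficients, diag(0, length(eff_coefficients)),
                             max(phi, 1))
  grid <- data.frame(flow = rep(daily$flow, times = 3L),
                     phenotype = factor(rep(lev, each = nd), levels = lev))
  eff <- matrix(stats::plogis(drop(efficiency_design(model0, grid) %*%
                                     eff_coefficients)),
                nrow = nd, dimnames = list(NULL, lev))
  if (any(eff <= 0) || any(eff > 1)) stop("efficiency outside (0, 1]")

  passage <- as.matrix(daily[, lev])
  catch_m <- matrix(rbetabinom(length(passage), as.vector(passage),
                               as.vector(eff), phi = phi),
                    nrow = nd, dimnames = list(NULL, lev))

  missing <- daily$date %in% as.Date(missing_days)
  catch_rows <- list(); meas_rows <- list()
  for (d in which(!missing)) {
    raw <- sum(catch_m[d, ])
    catch_rows[[length(catch_rows) + 1L]] <-
      data.frame(date = daily$date[d], raw_count = raw, operational = TRUE)
    if (raw == 0L) next
    n_meas <- min(p$measure_cap, raw)
    meas_counts <- if (raw <= p$measure_cap) catch_m[d, ]
                   else stats::rmultinom(1L, n_meas, catch_m[d, ] / raw)[, 1L]
    bounds <- rbind(c(p$fl_floor, 55), c(55, 75), c(75, Inf))
    fl <- unlist(lapply(seq_len(3L), function(j) {
      if (meas_counts[j] == 0L) return(numeric(0))
      rtruncnorm(meas_counts[j], daily$fl_mean[d], daily$fl_sd[d],
                 bounds[j, 1L], bounds[j, 2L])
    }))
    if (length(fl) > 0L) {
      meas_rows[[length(meas_rows) + 1L]] <-
        data.frame(date = daily$date[d], fl_mm = fl)
    }
  }

  trial_days <- seq(4L, nd, by = p$trial_interval_days)
  trials <- do.call(rbind, lapply(trial_days, function(d) {
    data.frame(date = daily$date[d], released = p$trial_release,
               recaptured = rbetabinom(3L, p$trial_release, eff[d, ], phi = phi),
               phenotype = lev, flow = daily$flow[d])
  }))
  list(catch = do.call(rbind, catch_rows),
       measured = if (length(meas_rows)) do.call(rbind, meas_rows)
                  else data.frame(date = as.Date(character(0)), fl_mm = numeric(0)),
       trials = trials,
       efficiency = eff)
}

#' Draw the surviving adults of a cohort
#'
#' Binomial survival per phenotype at the true rates; each survivor is
#' given an outmigration day (proportional to its phenotype's daily
#' passage) and a fork length from that day's size mixture conditional
#' on the phenotype bin, from which its true otolith exit radius
#' follows by inverting the OR-FL line.
#'
#' @param cohort A `cohort_truth`.
#' @param seed RNG seed.
#' @return Data frame with `fish_id`, `phenotype`, `fl_mm`,
#'   `exit_radius_um`, `natal_site`.
#' @export
simulate_survivors <- function(cohort, seed) {
  stopifnot(inherits(cohort, "cohort_truth"))
  p <- cohort$params
  maybe_seed(seed)
  lev <- phenotype_levels()
  daily <- cohort$daily
  bounds <- rbind(c(p$fl_floor, 55), c(55, 75), c(75, Inf))
  out <- list()
  for (j in seq_len(3L)) {
    J <- sum(daily[[lev[j]]])
    n <- if (J > 0) stats::rbinom(1L, J, p$true_survival[[lev[j]]]) else 0L
    if (n == 0L) next
    day <- sample.int(nrow(daily), n, replace = TRUE, prob = daily[[lev[j]]])
    fl <- rtruncnorm(n, daily$fl_mean[day], daily$fl_sd[day],
                     bounds[j, 1L], bounds[j, 2L])
    out[[j]] <- data.frame(phenotype = lev[j], fl_mm = fl)
  }
  adults <- do.call(rbind, out)
  if (is.null(adults)) {
    return(data.frame(fish_id = character(0), phenotype = character(0),
                      fl_mm = numeric(0), exit_radius_um = numeric(0),
                      natal_site = character(0)))
  }
  adults$exit_radius_um <- (adults$fl_mm - p$backcalc_intercept) / p$backcalc_slope
  adults$natal_site <- p$focal_site
  adults$fish_id <- sprintf("AD%04d", seq_len(nrow(adults)))
  adults[, c("fish_id", "phenotype", "fl_mm", "exit_radius_um", "natal_site")]
}

#' Build the escapement configuration and unmarked adult sample
#'
#' Mixes the natal survivors with strays from other isoscape sources at
#' the requested fraction, assigns return ages, and constructs a
#' steady-state escapement table (equal totals across return years)
#' whose arithmetic is exactly consistent with
#' [natural_escapement()]: removing the adclip rate and the realised
#' unmarked-stray fraction recovers the natal survivor count.
#'
#' @param survivors Data frame from [simulate_survivors()].
#' @param params A [world_params()] list.
#' @param isoscape Data frame from [isoscape_truth()].
#' @param seed RNG seed.
#' @return List with `adults` (fish_id, natal_site, phenotype, fl_mm,
#'   exit_radius_um, age; strays included) and `config` (list:
#'   escapement_by_year, age_distribution, adclip_stray_rate,
#'   cohort_year).
#' @export
generate_escapement <- function(survivors, params, isoscape = isoscape_truth(),
                                seed) {
  stopifnot(inherits(params, "world_params"))
  maybe_seed(seed)
  n_nat <- nrow(survivors)
  f <- params$stray_fraction
  n_stray <- round(n_nat * f / (1 - f))
  adults <- survivors
  if (n_stray > 0) {
    other <- setdiff(isoscape$site, c(params$focal_site, params$downstream_site))
    src <- sample(other, n_stray, replace = TRUE)
    fl <- stats::runif(n_stray, 60, 90)   # hatchery strays left large
    strays <- data.frame(
      fish_id = sprintf("ST%04d", seq_len(n_stray)),
      phenotype = as.character(assign_phenotype(fl)),
      fl_mm = fl,
      exit_radius_um = (fl - params$backcalc_intercept) / params$backcalc_slope,
      natal_site = src)
    adults <- rbind(adults, strays)
  }
  ages <- as.integer(names(params$age_split))
  adults$age <- sample(ages, nrow(adults), replace = TRUE,
                       prob = params$age_split)
  cohort_year <- as.integer(format(params$season[1], "%Y"))
  unmarked_total <- nrow(adults)
  total_escapement <- unmarked_total / (1 - params$adclip_stray_rate)
  years <- as.character(cohort_year + ages)
  config <- list(
    escapement_by_year = stats::setNames(rep(total_escapement, length(years)),
                                         years),
    age_distribution = params$age_split,
    adclip_stray_rate = params$adclip_stray_rate,
    cohort_year = cohort_year)
  list(adults = adults, config = config)
}

#' Generate otolith 87Sr/86Sr spot profiles for adults
#'
#' Three-plateau profile per fish: core (yolk-sac) spots pulled toward
#' the maternal marine value, a natal plateau at the fish's source mean
#' out to its exit radius (a spot is placed exactly at the exit,
#' emulating the targeted re-spots analysts place around the transition
#' zone), then a ramped rise to the downstream mainstem plateau and
#' finally the ocean value.  Ramps are Gaussian-kernel relaxations of
#' width `ramp_width_um`, mimicking the ~12 days of growth each laser
#' spot integrates; spot noise is additive Gaussian.
#'
#' @param adults Data frame with `fish_id`, `natal_site`,
#'   `exit_radius_um`.
#' @param params A [world_params()] list.
#' @param isoscape Data frame from [isoscape_truth()].
#' @param seed RNG seed.
#' @param noise_sd Override the spot noise SD in `params`.
#' @return Data frame of spots: `fish_id`, `index`, `distance_um`,
#'   `ratio`, `se`.
#' @export
generate_profiles <- function(adults, params, isoscape = isoscape_truth(),
                              seed, noise_sd = NULL) {
  stopifnot(inherits(params, "world_params"))
  if (is.null(noise_sd)) noise_sd <- params$profile_noise_sd
  maybe_seed(seed)
  mu <- stats::setNames(isoscape$mean_ratio, isoscape$site)
  down <- mu[[params$downstream_site]]
  ocean <- params$ocean_ratio
  s <- params$spot_spacing_um
  w <- params$ramp_width_um
  out <- vector("list", nrow(adults))
  for (i in seq_len(nrow(adults))) {
    natal <- mu[[adults$natal_site[i]]]
    exit <- adults$exit_radius_um[i]
    if (exit <= params$core_radius_um + 5) {
      stop("exit radius inside the core region; profile span too short")
    }
    # Densify spacing for small fish so the natal region always holds
    # enough spots (the analyst's targeted re-spots near the core).
    s_i <- min(s, (exit - params$core_radius_um - 1) / 4)
    natal_pos <- rev(seq(exit, params$core_radius_um + 1, by = -s_i))
    post_pos <- seq(exit + s, exit + params$downstream_length_um + 4 * s, by = s)
    core_pos <- c(70, 105)
    pos <- c(core_pos, natal_pos, post_pos)
    r_ocean <- exit + params$downstream_length_um
    value <- function(r) {
      if (r <= exit) return(natal)
      if (r <= r_ocean) {
        return(down + (natal - down) * exp(-((r - exit) / w)^2))
      }
      ocean + (down - ocean) * exp(-((r - r_ocean) / w)^2)
    }
    ratio <- vapply(pos, value, numeric(1))
    ratio[seq_along(core_pos)] <- natal + 0.35 * (ocean - natal)
    ratio <- ratio + stats::rnorm(length(pos), 0, noise_sd)
    out[[i]] <- data.frame(fish_id = adults$fish_id[i],
                           index = seq_along(pos),
                           distance_um = pos, ratio = ratio,
                           se = params$spot_se)
  }
  do.call(rbind, out)
}

#' Generate OR-FL calibration pairs
#'
#' Known-origin juveniles with otolith radius drawn uniformly over the
#' calibrated range and fork length on the true line plus Gaussian
#' residuals.
#'
#' @param params A [world_params()] list.
#' @param seed RNG seed.
#' @param resid_sd Override the residual SD in `params` (0 gives an
#'   exact line).
#' @return Data frame with `or_um` and `fl_mm`.
#' @export
generate_calibration <- function(params = world_params(), seed,
                                 resid_sd = NULL) {
  stopifnot(inherits(params, "world_params"))
  if (is.null(resid_sd)) resid_sd <- params$backcalc_resid_sd
  maybe_seed(seed)
  or <- stats::runif(params$n_calibration, 250, 650)
  fl <- params$backcalc_slope * or + params$backcalc_intercept +
    stats::rnorm(params$n_calibration, 0, resid_sd)
  data.frame(or_um = or, fl_mm = fl)
}

#' Simulate a complete synthetic world
#'
#' Runs every generator with seeds derived from one base seed and
#' returns all pipeline inputs together with the ground truth needed to
#' score recovery: true and realised passage, realised phenotype
#' proportions of the escapement, and realised survival.
#'
#' @param params A [world_params()] list.
#' @param seed Base RNG seed; stage seeds are derived from it.
#' @return List with `inputs` (catch, measured, trials, environment,
#'   spots, calibration, isoscape_ref, escapement config) and `truth`.
#' @export
simulate_world <- function(params = world_params(), seed = 1L) {
  seed <- as.integer(seed)
  cohort <- generate_cohort(params, seed = seed)
  trap <- simulate_trap(cohort, seed = seed + 1L)
  survivors <- simulate_survivors(cohort, seed = seed + 2L)
  iso <- isoscape_truth()
  esc <- generate_escapement(survivors, params, iso, seed = seed + 3L)
  spots <- generate_profiles(esc$adults, params, iso, seed = seed + 4L)
  calib <- generate_calibration(params, seed = seed + 5L)
  maybe_seed(seed + 6L)
  iso_ref <- do.call(rbind, lapply(seq_len(nrow(iso)), function(k) {
    data.frame(site = iso$site[k],
               ratio = stats::rnorm(iso$n_reference[k], iso$mean_ratio[k],
                                    iso$sd_ratio[k]))
  }))
  surv_counts <- stats::setNames(
    as.integer(table(factor(survivors$phenotype, levels = phenotype_levels()))),
    phenotype_levels())
  truth <- list(
    totals = cohort$totals,
    daily = cohort$daily,
    survivors = surv_counts,
    realised_beta = as.numeric(surv_counts / sum(surv_counts)),
    realised_survival = as.numeric(surv_counts / cohort$totals),
    true_survival = params$true_survival,
    n_natal_adults = nrow(survivors),
    stray_fraction = params$stray_fraction)
  list(inputs = list(catch = trap$catch, measured = trap$measured,
                     trials = trap$trials,
                     environment = cohort$daily[, c("date", "flow", "temp_c",
                                                    "turbidity_ntu")],
                     spots = spots, calibration = calib,
                     isoscape_ref = iso_ref, escapement = esc$config),
       truth = truth,
       params = params)
}
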