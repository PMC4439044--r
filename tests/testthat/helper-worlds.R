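# Small worlds used across the unit tests: same structure as the
# default study conditions, scaled to run in seconds.

tiny_params <- function(...) {
  defaults <- list(
    pulses = data.frame(
      date = as.Date(c("2000-01-25", "2000-02-14", "2000-03-20",
                       "2000-04-20", "2000-05-08")),
      magnitude = c(3500L, 14000L, 1800L, 1200L, 600L),
      sd_days = c(4, 5, 6, 6, 5),
      flow_peak = c(45, 70, 35, 25, 20)),
    baseline_daily = 10L,
    true_survival = c(fry = 0.02, parr = 0.1, smolt = 0.05))
  args <- defaults
  extra <- list(...)
  args[names(extra)] <- extra   # replace data frames whole, no recursion
  do.call(world_params, args)
}

# Every stochastic stage switched off: perfect trap efficiency, pure
# binomial catch, exact otolith profiles and calibration, no strays.
noisefree_params <- function(...) {
  tiny_params(
    eff_coefficients = c(`(Intercept)` = 50, `log(flow)` = 0,
                         phenotypeparr = 0, phenotypesmolt = 0),
    phi = 1,
    profile_noise_sd = 0,
    backcalc_resid_sd = 0,
    stray_fraction = 0,
    adclip_stray_rate = 0,
    measure_cap = Inf,
    ...)
}

# Degenerate efficiency model: capture probability exactly p for every
# phenotype and flow, no coefficient uncertainty.
constant_efficiency_model <- function(p, phi = 1) {
  efficiency_model(c(`(Intercept)` = stats::qlogis(p)),
                   matrix(0, 1, 1), phi, formula = ~1)
}

perfect_efficiency_model <- function() {
  efficiency_model(c(`(Intercept)` = 50, `log(flow)` = 0,
                     phenotypeparr = 0, phenotypesmolt = 0),
                   diag(0, 4), 1)
}

# Reference baseline simulated at the Stanislaus-like and San
# Joaquin-like means/SDs.
two_site_references <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(
    site = rep(c("STA", "SJR"), each = n),
    ratio = c(rnorm(n, 0.70660, 0.00008), rnorm(n, 0.70716, 0.00013)))
}
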