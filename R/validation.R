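# Simulation studies validating the estimator chain against known
# ground truth.  Shared between the test suite, the analysis scripts
# and the acceptance script so the experiments are defined in exactly
# one place.

#' Scaled-down world parameters for replicated simulation studies
#'
#' A smaller season (about a tenth of the default passage) with higher
#' survival, sized so that replicated end-to-end studies run in
#' minutes while keeping survivor counts large enough that adult
#' binomial noise stays well below the propagated uncertainty.  All
#' noise settings (overdispersion, profile noise, calibration
#' residuals, stray and adclip rates) keep their defaults.
#'
#' @param ... Overrides forwarded to [world_params()].
#' @return A `world_params` list.
#' @export
study_world_params <- function(...) {
  defaults <- list(
    pulses = data.frame(
      date = as.Date(c("2000-01-25", "2000-02-14", "2000-03-20",
                       "2000-04-20", "2000-05-08")),
      magnitude = c(35000L, 140000L, 18000L, 12000L, 6000L),
      sd_days = c(4, 5, 6, 6, 5),
      flow_peak = c(45, 70, 35, 25, 20)),
    baseline_daily = 30L,
    true_survival = c(fry = 0.004, parr = 0.02, smolt = 0.01))
  args <- defaults
  extra <- list(...)
  args[names(extra)] <- extra   # no recursive merge: data frames replaced whole
  do.call(world_params, args)
}

#' Coverage of the Monte-Carlo passage interval
#'
#' Replicates whole seasons: a cohort is generated, trapped, the
#' efficiency model refitted from that season's trials, the catch
#' expanded, and the 95% interval of the seasonal total compared with
#' the true total passage.  Nominal coverage is 95%.
#'
#' @param n_seasons Number of replicate seasons.
#' @param seed Base seed; season `k` uses `seed + k`.
#' @param params World parameters (default [study_world_params()]).
#' @param n_draws Monte-Carlo draws per season.
#' @return List with `coverage` (fraction of seasons whose interval
#'   covers the true total), `covered` (logical vector) and
#'   `rel_error` (per-season relative error of the point estimate).
#' @export
expansion_coverage_study <- function(n_seasons = 200, seed = 1L,
                                     params = study_world_params(),
                                     n_draws = 1000) {
  covered <- logical(n_seasons)
  rel_err <- numeric(n_seasons)
  for (k in seq_len(n_seasons)) {
    cohort <- generate_cohort(params, seed = seed + 7L * k)
    trap <- simulate_trap(cohort, seed = seed + 7L * k + 1L)
    daily <- daily_phenotype_catch(trap$catch, trap$measured,
                                   season = params$season)
    eff <- fit_efficiency(trap$trials)
    est <- simulate_passage(daily, eff, cohort$daily[, c("date", "flow")],
                            n_draws = n_draws, seed = seed + 7L * k + 2L)
    row <- est$estimates[est$estimates$phenotype == "total", ]
    truth <- sum(cohort$totals)
    covered[k] <- row$lo95 <= truth && truth <= row$hi95
    rel_err[k] <- row$point / truth - 1
  }
  list(coverage = mean(covered), covered = covered, rel_error = rel_err)
}

#' End-to-end parameter recovery across replicate worlds
#'
#' For each world the full chain runs from raw synthetic inputs to
#' survival estimates; coverage of the delta-method 95% CI against the
#' known true survival probabilities and the relative bias of the
#' point estimates are accumulated per phenotype.
#'
#' @param n_worlds Number of replicate worlds.
#' @param seed Base seed; world `k` derives its seeds from
#'   `seed + 1000 * k`.
#' @param params World parameters (default [study_world_params()]).
#' @param config Pipeline configuration; defaults to 1000 expansion
#'   draws and 1000 residual resamples for runtime.
#' @return List with `coverage` (named per-phenotype coverage
#'   fraction), `bias` (named mean relative bias of the survival
#'   estimate), `estimates` (n_worlds x 3 matrix of survival
#'   estimates) and `truth` (true survival).
#' @export
recovery_study <- function(n_worlds = 100, seed = 1L,
                           params = study_world_params(),
                           config = NULL) {
  lev <- phenotype_levels()
  truth <- params$true_survival[lev]
  est <- lo <- hi <- matrix(NA_real_, n_worlds, 3L,
                            dimnames = list(NULL, lev))
  for (k in seq_len(n_worlds)) {
    wseed <- seed + 1000L * k
    world <- simulate_world(params, seed = wseed)
    cfg <- if (is.null(config)) {
      pipeline_config(season = params$season, n_draws = 1000,
                      n_resample = 1000, seed = wseed,
                      focal_site = params$focal_site,
                      downstream_site = params$downstream_site)
    } else config
    run <- run_pipeline(world$inputs, cfg)
    s <- run$survival
    idx <- match(s$phenotype, lev)
    est[k, idx] <- s$S
    lo[k, idx] <- s$lo95
    hi[k, idx] <- s$hi95
  }
  covered <- sweep(lo, 2L, truth, "<=") & sweep(hi, 2L, truth, ">=")
  list(coverage = colMeans(covered, na.rm = TRUE),
       bias = colMeans(sweep(est, 2L, truth, "/") - 1, na.rm = TRUE),
       estimates = est, truth = truth)
}
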