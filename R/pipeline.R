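#' Configuration for a pipeline run
#'
#' Collects every tunable of the inference chain with defaults matching
#' the study settings: a January 1 to June 30 season, 2000 Monte-Carlo
#' expansion draws, 5000 residual resamples, phenotype bins at 55 and
#' 75 mm, and the Stanislaus-like focal site with the mainstem San
#' Joaquin-like source immediately downstream.
#'
#' @param season Two dates bounding the outmigration season.
#' @param n_draws Monte-Carlo draws for the passage expansion.
#' @param n_resample Residual resamples for the proportion CIs.
#' @param seed Base seed; stage seeds are derived deterministically.
#' @param focal_site,downstream_site Isoscape site labels.
#' @param breaks Phenotype fork-length bin edges (mm).
#' @param window Triangular interpolation half-width (days).
#' @param natal_window Spots averaged for natal assignment.
#' @param core_radius_um Core (yolk-sac) exclusion radius.
#' @param clamp Efficiency clamp used during expansion.
#' @param se_method How SEs are derived from quantile intervals
#'   (`"log_ci"` or `"sd"`), see [se_from_interval()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(season = as.Date(c("2000-01-01", "2000-06-30")),
                            n_draws = 2000, n_resample = 5000, seed = 1L,
                            focal_site = "STA", downstream_site = "SJR",
                            breaks = c(55, 75), window = 3L,
                            natal_window = 3L, core_radius_um = 140,
                            clamp = c(1e-4, 1), se_method = "log_ci") {
  stopifnot(breaks[1] < breaks[2], n_draws >= 2, n_resample >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full inference chain
#'
#' Orchestrates: phenotype apportionment and interpolation of the raw
#' catch; quasibinomial efficiency fit; Monte-Carlo passage expansion
#' and phenology; isoscape training, natal assignment and stray
#' removal; natal-exit detection; OR-FL calibration and fork-length
#' back-calculation; phenotype proportions with resampling CIs; natural
#' escapement and delta-method survival.  Deterministic for a fixed
#' config.
#'
#' @param inputs List with data frames `catch`, `measured`, `trials`,
#'   `environment`, `spots`, `calibration`, `isoscape_ref` and the
#'   `escapement` config list (see [simulate_world()] for the schemas).
#' @param config A [pipeline_config()].
#' @param efficiency_fit Optional pre-built [efficiency_model()]
#'   replacing the GLM fit (used for calibration studies with known
#'   coefficients).
#' @return List of class `phenosurv_run` with components `passage`,
#'   `phenology`, `efficiency`, `assignments`, `stray_fraction`,
#'   `exits`, `backcalc`, `proportions`, `E_n` and `survival`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         efficiency_fit = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in c("catch", "measured", "trials", "environment", "spots",
               "calibration", "isoscape_ref")) {
    if (is.null(inputs[[nm]])) stop(sprintf("inputs$%s is missing", nm))
  }
  require_columns(inputs$environment, c("date", "flow"), "environment")
  require_columns(inputs$spots, c("fish_id", "distance_um", "ratio"), "spots")
  require_columns(inputs$calibration, c("or_um", "fl_mm"), "calibration")
  lev <- phenotype_levels()

  # -- juvenile side: catch -> passage ---------------------------------
  daily <- daily_phenotype_catch(inputs$catch, inputs$measured,
                                 season = config$season,
                                 window = config$window,
                                 breaks = config$breaks)
  eff <- if (is.null(efficiency_fit)) fit_efficiency(inputs$trials)
         else efficiency_fit
  passage <- simulate_passage(daily, eff, inputs$environment,
                              n_draws = config$n_draws,
                              seed = config$seed + 101L,
                              clamp = config$clamp)
  phen <- do.call(rbind, lapply(lev, function(p) {
    med <- passage$daily[[p]]
    if (sum(med) <= 0) return(NULL)
    cbind(phenotype = p, phenology(passage$daily$date, med))
  }))

  # -- adult side: otoliths -> proportions -----------------------------
  classifier <- train_isoscape(inputs$isoscape_ref)
  by_fish <- split(inputs$spots, inputs$spots$fish_id)
  assignments <- do.call(rbind, lapply(names(by_fish), function(id) {
    a <- assign_natal(by_fish[[id]], classifier, config$focal_site,
                      natal_window = config$natal_window,
                      core_radius_um = config$core_radius_um)
    data.frame(fish_id = id, natal_ratio = a$natal_ratio,
               predicted_site = a$predicted_site, is_stray = a$is_stray)
  }))
  stray_fraction <- mean(assignments$is_stray)
  natal_ids <- assignments$fish_id[!assignments$is_stray]

  exits <- do.call(rbind, lapply(natal_ids, function(id) {
    e <- detect_exit(by_fish[[id]], classifier, config$focal_site,
                     config$downstream_site)
    data.frame(fish_id = id, exit_index = e$exit_index,
               exit_radius_um = e$exit_radius_um, defined = e$defined)
  }))
  n_undefined <- sum(!exits$defined)
  if (n_undefined > 0L) {
    warning(sprintf("%d profile(s) never left the natal signature; excluded",
                    n_undefined))
  }
  exits_ok <- exits[exits$defined, , drop = FALSE]

  bc <- fit_or_fl(inputs$calibration$or_um, inputs$calibration$fl_mm)
  props <- proportions_with_ci(exits_ok$exit_radius_um, bc,
                               n_resample = config$n_resample,
                               seed = config$seed + 202L,
                               breaks = config$breaks)

  # -- survival --------------------------------------------------------
  survival <- NULL; E_n <- NA_real_
  if (!is.null(inputs$escapement)) {
    ec <- inputs$escapement
    E_n <- natural_escapement(ec$escapement_by_year, ec$age_distribution,
                              ec$adclip_stray_rate, stray_fraction,
                              ec$cohort_year)
    E_i <- spawners_by_phenotype(E_n, props$beta)
    est <- passage$estimates[match(lev, passage$estimates$phenotype), ]
    keep <- props$beta > 0 & est$point > 0
    se_J <- vapply(seq_len(3L), function(j) {
      if (!keep[j]) return(NA_real_)
      se_from_interval(est$point[j], est$lo95[j], est$hi95[j],
                       draws = passage$draws[, lev[j]],
                       method = config$se_method)
    }, numeric(1))
    se_b <- vapply(seq_len(3L), function(j) {
      if (!keep[j]) return(NA_real_)
      se_from_interval(props$beta[j], props$lo95[j], props$hi95[j],
                       draws = props$replicates[, lev[j]],
                       method = config$se_method)
    }, numeric(1))
    survival <- survival_estimate(E_i[keep], est$point[keep], se_J[keep],
                                  se_b[keep], props$beta[keep],
                                  phenotype = lev[keep])
  }

  structure(list(daily_catch = daily, efficiency = eff, passage = passage,
                 phenology = phen, classifier = classifier,
                 assignments = assignments, stray_fraction = stray_fraction,
                 exits = exits, backcalc = bc, proportions = props,
                 E_n = E_n, survival = survival, config = config),
            class = "phenosurv_run")
}

#' @export
print.phenosurv_run <- function(x, ...) {
  cat("phenosurv pipeline run\n----------------------\n")
  print(x$passage)
  cat(sprintf("\nUnmarked stray fraction: %.3f  (natural escapement E_n = %.0f)\n",
              x$stray_fraction, x$E_n))
  print(x$proportions)
  if (!is.null(x$survival)) {
    cat("\nOutmigrant-to-spawner survival:\n")
    s <- x$survival
    s$S <- signif(s$S, 3); s$se_logS <- signif(s$se_logS, 3)
    s$lo95 <- signif(s$lo95, 3); s$hi95 <- signif(s$hi95, 3)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline tables to disk
#'
#' Persists the seasonal passage, phenology, natal assignments, exit
#' points, proportions and survival tables as CSV under `dir`.
#'
#' @param run A `phenosurv_run`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "phenosurv_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(passage = "passage_estimates.csv",
             phenology = "phenology.csv",
             assignments = "natal_assignments.csv",
             exits = "exit_points.csv",
             survival = "survival.csv")
  utils::write.csv(run$passage$estimates, file.path(dir, files["passage"]),
                   row.names = FALSE)
  if (!is.null(run$phenology)) {
    utils::write.csv(run$phenology, file.path(dir, files["phenology"]),
                     row.names = FALSE)
  }
  utils::write.csv(run$assignments, file.path(dir, files["assignments"]),
                   row.names = FALSE)
  utils::write.csv(run$exits, file.path(dir, files["exits"]),
                   row.names = FALSE)
  props <- data.frame(phenotype = names(run$proportions$beta),
                      beta = run$proportions$beta,
                      lo95 = run$proportions$lo95,
                      hi95 = run$proportions$hi95, row.names = NULL)
  utils::write.csv(props, file.path(dir, "phenotype_proportions.csv"),
                   row.names = FALSE)
  if (!is.null(run$survival)) {
    utils::write.csv(run$survival, file.path(dir, files["survival"]),
                     row.names = FALSE)
  }
  invisible(file.path(dir, c(files, "phenotype_proportions.csv")))
}
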