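#' Calibrate the otolith-radius to fork-length model
#'
#' Ordinary least-squares line FL = a * OR + b fitted to known-origin
#' juveniles measured for both otolith radius (along the same transect
#' used for isotope spots) and fork length.  Residuals are retained for
#' the proportion-CI resampling.
#'
#' @param or_um Otolith radii (micrometres).
#' @param fl_mm Fork lengths (mm), same length as `or_um`.
#' @return Object of class `backcalc_model` with `slope`, `intercept`,
#'   their SEs, `residuals`, `r2` and `n`.
#' @export
fit_or_fl <- function(or_um, fl_mm) {
  stopifnot(is.numeric(or_um), is.numeric(fl_mm),
            length(or_um) == length(fl_mm))
  if (length(or_um) < 3L) stop("at least 3 calibration pairs are required")
  if (stats::sd(or_um) == 0) stop("otolith radii have zero spread; line is degenerate")
  fit <- stats::lm(fl_mm ~ or_um)
  # noise-free calibrations are legitimate here (validation worlds)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = sm$coefficients[2L, 2L],
                 intercept_se = sm$coefficients[1L, 2L],
                 residuals = unname(stats::residuals(fit)),
                 r2 = sm$r.squared,
                 n = length(or_um)),
            class = "backcalc_model")
}

#' @export
print.backcalc_model <- function(x, ...) {
  cat(sprintf("FL = %.4f (+/-%.4f SE) x OR %+.3f (+/-%.3f SE)  (r^2 = %.3f, n = %d)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se, x$r2, x$n))
  invisible(x)
}

#' Back-calculate fork length at natal exit
#'
#' Evaluates the calibration line at the otolith radius of the last
#' natal spot, giving the fork length at which the fish left the natal
#' river.
#'
#' @param exit_radius_um Otolith radius at natal exit (micrometres),
#'   strictly positive.
#' @param model A `backcalc_model`.
#' @return Numeric vector of fork lengths (mm).  Non-positive
#'   predictions are flagged with a warning (outside the calibrated
#'   range) and returned as is.
#' @export
backcalculate_fl <- function(exit_radius_um, model) {
  stopifnot(inherits(model, "backcalc_model"), all(exit_radius_um > 0))
  fl <- model$slope * exit_radius_um + model$intercept
  if (any(fl <= 0)) {
    warning(sprintf("%d back-calculated fork length(s) <= 0 mm; outside calibration range",
                    sum(fl <= 0)))
  }
  fl
}

#' Phenotype proportions of the escapement with resampling CIs
#'
#' Each fish's back-calculated fork length is classified into fry, parr
#' or smolt; the point proportions \eqn{\beta_i} use the unperturbed
#' predictions.  Uncertainty from the calibration line is propagated by
#' adding a calibration residual, resampled with replacement, to every
#' fish's predicted fork length and reclassifying, repeated
#' `n_resample` times; the 2.5%/97.5% quantiles of the resampled
#' proportions give the 95% CI.
#'
#' @param exit_radius_um Per-fish otolith radius at natal exit.
#' @param model A `backcalc_model` (its residuals drive the
#'   resampling).
#' @param n_resample Number of resampling replicates (default 5000).
#' @param seed Optional RNG seed.
#' @param breaks Phenotype bin edges, see [assign_phenotype()].
#' @return Object of class `phenotype_proportions`: list with `beta`
#'   (named proportions summing to 1), `lo95`, `hi95`, `replicates`
#'   (n_resample x 3 matrix) and `n_fish`.
#' @export
proportions_with_ci <- function(exit_radius_um, model, n_resample = 5000,
                                seed = NULL, breaks = c(55, 75)) {
  stopifnot(inherits(model, "backcalc_model"))
  if (length(exit_radius_um) == 0L) stop("no fish to classify")
  maybe_seed(seed)
  lev <- phenotype_levels()
  fl0 <- backcalculate_fl(exit_radius_um, model)
  share <- function(fl) {
    counts <- table(factor(as.character(assign_phenotype(fl, breaks)), levels = lev))
    as.numeric(counts) / length(fl)
  }
  beta <- stats::setNames(share(fl0), lev)
  nf <- length(fl0)
  res <- model$residuals
  reps <- matrix(NA_real_, nrow = n_resample, ncol = 3L,
                 dimnames = list(NULL, lev))
  for (r in seq_len(n_resample)) {
    reps[r, ] <- share(fl0 + sample(res, nf, replace = TRUE))
  }
  qs <- apply(reps, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(beta = beta,
                 lo95 = stats::setNames(qs[1L, ], lev),
                 hi95 = stats::setNames(qs[2L, ], lev),
                 replicates = reps, n_fish = nf,
                 n_resample = n_resample),
            class = "phenotype_proportions")
}

#' @export
print.phenotype_proportions <- function(x, ...) {
  cat(sprintf("Escapement phenotype proportions (n = %d fish, %d resamples)\n",
              x$n_fish, x$n_resample))
  print(data.frame(phenotype = names(x$beta), beta = round(x$beta, 3),
                   lo95 = round(x$lo95, 3), hi95 = round(x$hi95, 3),
                   row.names = NULL))
  invisible(x)
}
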