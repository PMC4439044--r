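#' Construct a trap-efficiency model object
#'
#' Holds the logit-scale coefficients of the capture-probability model,
#' their covariance, and the quasibinomial dispersion.  Usually created
#' by [fit_efficiency()]; the constructor is exported so that degenerate
#' models (e.g. perfect efficiency with zero coefficient uncertainty)
#' can be built directly for calibration checks.
#'
#' @param coefficients Named numeric vector on the logit scale.
#' @param covariance Covariance matrix of the coefficients (symmetric,
#'   positive semi-definite), already scaled by the dispersion.
#' @param dispersion Quasibinomial dispersion \eqn{\phi > 0} (Pearson
#'   chi-square / residual df).
#' @param formula One-sided formula for the linear predictor; the
#'   default uses log flow and the phenotype factor.
#' @param xlevels Factor levels used when building design matrices.
#' @return Object of class `efficiency_model`.
#' @export
efficiency_model <- function(coefficients, covariance, dispersion,
                             formula = ~ log(flow) + phenotype,
                             xlevels = list(phenotype = phenotype_levels())) {
  covariance <- as.matrix(covariance)
  stopifnot(length(coefficients) == nrow(covariance),
            nrow(covariance) == ncol(covariance),
            isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)),
            dispersion > 0)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("coefficient covariance must be positive semi-definite")
  }
  structure(list(coefficients = coefficients, covariance = covariance,
                 dispersion = dispersion, formula = formula,
                 xlevels = xlevels, fit = NULL),
            class = "efficiency_model")
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat("Trap-efficiency model (logit link)\n")
  print(x$coefficients)
  cat(sprintf("dispersion phi = %.3f\n", x$dispersion))
  invisible(x)
}

#' Fit the trap-efficiency model to mark-recapture trials
#'
#' Capture probability is modelled on the logit scale as a function of
#' log river flow and migratory phenotype, fitted as a quasibinomial GLM
#' because recapture counts are overdispersed relative to the binomial.
#' The dispersion \eqn{\phi} is the Pearson chi-square divided by the
#' residual degrees of freedom, and the coefficient covariance is scaled
#' by it.
#'
#' @param trials Data frame of mark-release trials with columns `date`,
#'   `released`, `recaptured`, `phenotype` and `flow` (m3/s).
#' @param formula Model formula for the recapture probability; the
#'   response is built internally from `recaptured` and `released`.
#' @return An `efficiency_model` with the fitted GLM attached.
#' @export
fit_efficiency <- function(trials, formula = ~ log(flow) + phenotype) {
  require_columns(trials, c("released", "recaptured"), "trials")
  vars <- all.vars(formula)
  require_columns(trials, vars, "trials")
  stopifnot(all(trials$released > 0),
            all(trials$recaptured >= 0),
            all(trials$recaptured <= trials$released))
  if ("phenotype" %in% vars) {
    trials$phenotype <- factor(trials$phenotype, levels = phenotype_levels())
    present <- table(trials$phenotype)
    if (any(present == 0L)) {
      stop(sprintf("no efficiency trials for phenotype(s): %s",
                   paste(names(present)[present == 0L], collapse = ", ")))
    }
  }
  full <- stats::update(formula, cbind(recaptured, released - recaptured) ~ .)
  fit <- stats::glm(full, family = stats::quasibinomial(), data = trials)
  if (any(is.na(stats::coef(fit)))) {
    stop("efficiency model design matrix is rank deficient")
  }
  mu <- stats::fitted(fit)
  if (all(mu > 1 - 1e-8) || all(mu < 1e-8)) {
    warning("fitted efficiencies are all at a boundary; possible separation")
  }
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  if (!is.finite(phi) || phi <= 0) phi <- 1
  out <- efficiency_model(stats::coef(fit), stats::vcov(fit), phi,
                          formula = formula, xlevels = fit$xlevels)
  out$fit <- fit
  out
}

#' Predict trap efficiency
#'
#' Inverse-logit of the linear predictor for given flow/phenotype
#' covariates, optionally under an alternative coefficient vector (a
#' Monte-Carlo draw), clamped away from 0 and 1 so that expansion by
#' division stays bounded.
#'
#' @param model An `efficiency_model`.
#' @param newdata Data frame holding the covariates named in the model
#'   formula (typically `flow` and `phenotype`).
#' @param coefficients Optional replacement coefficient vector.
#' @param clamp Two probabilities to which predictions are clipped.
#'   The lower bound keeps the expansion (division by efficiency)
#'   bounded; the upper bound defaults to 1 so that a perfect trap is
#'   representable exactly.
#' @return Numeric vector of capture probabilities.
#' @export
predict_efficiency <- function(model, newdata, coefficients = NULL,
                               clamp = c(1e-4, 1)) {
  stopifnot(inherits(model, "efficiency_model"))
  X <- efficiency_design(model, newdata)
  beta <- if (is.null(coefficients)) model$coefficients else coefficients
  p <- stats::plogis(drop(X %*% beta))
  pmin(pmax(p, clamp[1]), clamp[2])
}

# Design matrix for an efficiency model on new covariates.
efficiency_design <- function(model, newdata) {
  if ("phenotype" %in% names(newdata)) {
    newdata$phenotype <- factor(newdata$phenotype,
                                levels = model$xlevels$phenotype %||% phenotype_levels())
  }
  mt <- stats::terms(model$formula)
  xlev <- model$xlevels[intersect(names(model$xlevels), all.vars(model$formula))]
  X <- stats::model.matrix(mt, data = newdata, xlev = xlev)
  if (!identical(colnames(X), names(model$coefficients))) {
    stop("covariates do not match the efficiency model coefficients")
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta-binomial random deviates
#'
#' Draws from a beta-binomial with mean `size * prob` and quasibinomial
#' dispersion `phi`, parameterised through the intraclass correlation
#' \eqn{\rho = (\phi - 1)/(n - 1)} for trial size \eqn{n}, which maps
#' the GLM dispersion onto a proper generating distribution.  With
#' \eqn{\phi \le 1} (or \eqn{n \le 1}) the draw is plain binomial.
#'
#' @param n Number of deviates.
#' @param size Integer trial sizes (vectorised).
#' @param prob Success probabilities (vectorised).
#' @param phi Dispersion \eqn{\phi \ge 1}.
#' @return Integer vector of counts in `[0, size]`.
#' @export
rbetabinom <- function(n, size, prob, phi = 1) {
  stopifnot(phi > 0, all(size >= 0), all(prob >= 0 & prob <= 1))
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  out <- integer(n)
  over <- phi > 1 & size > 1
  if (any(!over)) {
    out[!over] <- stats::rbinom(sum(!over), size[!over], prob[!over])
  }
  if (any(over)) {
    rho <- pmin((phi - 1) / (size[over] - 1), 1 - 1e-9)
    nu <- 1 / rho - 1  # total concentration of the mixing beta
    p2 <- stats::rbeta(sum(over), pmax(prob[over] * nu, 1e-12),
                       pmax((1 - prob[over]) * nu, 1e-12))
    out[over] <- stats::rbinom(sum(over), size[over], p2)
  }
  out
}

#' Expand daily catch into passage estimates by Monte-Carlo simulation
#'
#' Propagates both estimation error (efficiency-model coefficients) and
#' sampling error (catch) into seasonal passage totals.  For each of
#' `n_draws` replicates: (1) a coefficient vector is drawn from the
#' multivariate normal defined by the fitted model; (2) daily
#' efficiencies follow from flow and phenotype; (3) a provisional daily
#' passage is the catch divided by efficiency (rounded to an integer no
#' smaller than the catch); (4) a simulated catch is drawn from a
#' beta-binomial with that trial size, the daily efficiency and the
#' model dispersion; (5) the final daily passage is the simulated catch
#' divided by efficiency.  Seasonal totals sum the daily passages; the
#' point estimate is the median of the draws and the interval the
#' 2.5%/97.5% quantiles.
#'
#' @param daily_catch Data frame from [daily_phenotype_catch()]:
#'   columns `date`, `fry`, `parr`, `smolt`.
#' @param model An `efficiency_model`.
#' @param flow Data frame with columns `date` and `flow` covering every
#'   catch day.
#' @param n_draws Number of Monte-Carlo replicates (default 2000).
#' @param seed Optional RNG seed for reproducibility.
#' @param clamp Efficiency clamp passed to [predict_efficiency()].
#' @return Object of class `passage_estimate`: a list with `estimates`
#'   (data frame of point/lo95/hi95 per phenotype and the seasonal
#'   total), `draws` (n_draws x 4 matrix of seasonal totals), `daily`
#'   (per-day median passage by phenotype) and `n_draws`.
#' @export
simulate_passage <- function(daily_catch, model, flow, n_draws = 2000,
                             seed = NULL, clamp = c(1e-4, 1)) {
  stopifnot(inherits(model, "efficiency_model"))
  lev <- phenotype_levels()
  require_columns(daily_catch, c("date", lev), "daily_catch")
  require_columns(flow, c("date", "flow"), "flow")
  maybe_seed(seed)
  daily_catch$date <- as.Date(daily_catch$date)
  flow$date <- as.Date(flow$date)
  fl <- flow$flow[match(daily_catch$date, flow$date)]
  if (any(is.na(fl))) stop("flow series does not cover every catch day")

  nd <- nrow(daily_catch)
  cells <- data.frame(
    date = rep(daily_catch$date, times = 3L),
    flow = rep(fl, times = 3L),
    phenotype = factor(rep(lev, each = nd), levels = lev)
  )
  catch <- c(daily_catch$fry, daily_catch$parr, daily_catch$smolt)
  catch <- round(pmax(catch, 0))
  X <- efficiency_design(model, cells)
  draws_beta <- MASS::mvrnorm(n_draws, mu = model$coefficients,
                              Sigma = model$covariance)
  if (is.null(dim(draws_beta))) draws_beta <- matrix(draws_beta, nrow = n_draws)

  eta <- X %*% t(draws_beta)                      # cells x n_draws
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, clamp[1]), clamp[2])
  catch_m <- matrix(catch, nrow = length(catch), ncol = n_draws)
  n_prov <- pmax(round(catch_m / p), catch_m)
  sim_catch <- matrix(
    rbetabinom(length(n_prov), as.vector(n_prov), as.vector(p),
               phi = model$dispersion),
    nrow = nrow(n_prov))
  passage <- sim_catch / p
  passage[catch_m == 0] <- 0                      # no catch, no expansion

  pheno_idx <- rep(seq_len(3L), each = nd)
  totals <- rowsum(passage, group = pheno_idx)    # 3 x n_draws
  totals <- t(totals)
  colnames(totals) <- lev
  totals <- cbind(totals, total = rowSums(totals))

  qs <- apply(totals, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  estimates <- data.frame(
    phenotype = colnames(totals),
    point = qs[1L, ], lo95 = qs[2L, ], hi95 = qs[3L, ],
    row.names = NULL
  )
  daily_med <- apply(passage, 1L, stats::median)
  daily <- data.frame(date = daily_catch$date,
                      matrix(daily_med, nrow = nd, dimnames = list(NULL, lev)))
  structure(list(estimates = estimates, draws = totals, daily = daily,
                 n_draws = n_draws),
            class = "passage_estimate")
}

#' @export
print.passage_estimate <- function(x, ...) {
  cat(sprintf("Seasonal passage estimates (%d Monte-Carlo draws)\n", x$n_draws))
  est <- x$estimates
  est[, -1] <- round(est[, -1])
  print(est, row.names = FALSE)
  invisible(x)
}

#' Migration phenology summary
#'
#' Summarises the date of passage past the trap with three metrics: the
#' range (first and last days with passage), the interquartile range,
#' and the median ("peak") date, all read off the cumulative daily
#' passage curve (first date at which the cumulative fraction reaches
#' 25%, 50%, 75%).
#'
#' @param date Vector of dates.
#' @param passage Non-negative daily passage aligned with `date`.
#' @return Data frame with columns `first_date`, `iqr_start`,
#'   `median_date`, `iqr_end`, `last_date`.
#' @export
phenology <- function(date, passage) {
  stopifnot(length(date) == length(passage), all(passage >= 0))
  if (sum(passage) <= 0) stop("phenology is undefined for zero total passage")
  date <- as.Date(date)
  ord <- order(date)
  date <- date[ord]; passage <- passage[ord]
  nz <- which(passage > 0)
  cum <- cumsum(passage) / sum(passage)
  crossing <- function(q) date[which(cum >= q)[1L]]
  data.frame(first_date = date[nz[1L]],
             iqr_start = crossing(0.25),
             median_date = crossing(0.5),
             iqr_end = crossing(0.75),
             last_date = date[nz[length(nz)]])
}
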