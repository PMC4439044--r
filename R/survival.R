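#' Natural escapement for an outmigration cohort
#'
#' Adults from one outmigration cohort return over several years.  For
#' each return age, the total escapement of the corresponding return
#' year is reduced by the adclipped (hatchery-marked) stray rate and
#' weighted by the age fraction; the summed cohort escapement is then
#' reduced by the unmarked stray fraction estimated from the otolith
#' natal assignments.
#'
#' @param escapement_by_year Named numeric vector, total escapement per
#'   return year (names are years).
#' @param age_distribution Named numeric vector of age fractions (names
#'   are ages in years) summing to 1.
#' @param adclip_stray_rate Fraction of the escapement that is
#'   adclipped hatchery strays; a scalar or a vector named by return
#'   year.
#' @param unmarked_stray_fraction Fraction of unmarked adults assigned
#'   to non-natal sources.
#' @param cohort_year Outmigration year of the cohort.
#' @return Natural escapement \eqn{E_n} (fish).
#' @export
natural_escapement <- function(escapement_by_year, age_distribution,
                               adclip_stray_rate, unmarked_stray_fraction,
                               cohort_year) {
  stopifnot(abs(sum(age_distribution) - 1) < 1e-8,
            all(age_distribution >= 0),
            all(adclip_stray_rate >= 0 & adclip_stray_rate <= 1),
            unmarked_stray_fraction >= 0, unmarked_stray_fraction <= 1)
  ages <- as.integer(names(age_distribution))
  if (anyNA(ages)) stop("age_distribution must be named by integer ages")
  total <- 0
  for (k in seq_along(ages)) {
    yr <- as.character(cohort_year + ages[k])
    if (!yr %in% names(escapement_by_year)) {
      stop(sprintf("escapement_by_year has no entry for return year %s", yr))
    }
    clip <- if (length(adclip_stray_rate) == 1L) adclip_stray_rate
            else {
              if (!yr %in% names(adclip_stray_rate)) {
                stop(sprintf("adclip_stray_rate has no entry for return year %s", yr))
              }
              adclip_stray_rate[[yr]]
            }
    total <- total + escapement_by_year[[yr]] * (1 - clip) * age_distribution[[k]]
  }
  total * (1 - unmarked_stray_fraction)
}

#' Spawners by migratory phenotype
#'
#' \eqn{E_i = E_n \beta_i}: the natural escapement apportioned by the
#' otolith-derived phenotype proportions.
#'
#' @param E_n Natural escapement (fish).
#' @param beta Named proportions over phenotypes summing to 1.
#' @return Named numeric vector of phenotype spawner counts summing to
#'   `E_n`.
#' @export
spawners_by_phenotype <- function(E_n, beta) {
  stopifnot(E_n >= 0, abs(sum(beta) - 1) < 1e-8, all(beta >= 0))
  E_n * beta
}

#' Outmigrant-to-spawner survival with delta-method CIs
#'
#' Survival of phenotype \eqn{i} is the ratio \eqn{S_i = E_i / J_i} of
#' spawners produced to juvenile outmigrants.  Treating \eqn{\beta_i}
#' and \eqn{J_i} as independent, the delta method gives
#' \deqn{SE(\log S_i) = \sqrt{(SE(J_i)/J_i)^2 + (SE(\beta_i)/\beta_i)^2}}
#' and the 95% CI is \eqn{\exp(\log S_i \pm 1.96\, SE(\log S_i))},
#' symmetric on the log scale.  Escapement uncertainty is not
#' propagated.
#'
#' @param E Spawners of each phenotype (\eqn{E_i}).
#' @param J Outmigrant passage estimates (\eqn{J_i}), strictly
#'   positive.
#' @param se_J Standard errors of `J` (natural scale).
#' @param se_beta Standard errors of the phenotype proportions
#'   (natural scale).
#' @param beta Phenotype proportions, strictly positive.
#' @param phenotype Optional labels for the output rows.
#' @return Data frame with columns `phenotype`, `E`, `J`, `S`
#'   (fraction), `se_logS`, `lo95`, `hi95` and `S_pct` (percent,
#'   half-up rounded to 2 decimals).
#' @export
survival_estimate <- function(E, J, se_J = 0, se_beta = 0, beta = NULL,
                              phenotype = NULL) {
  if (is.null(beta)) beta <- E / sum(E)
  k <- length(E)
  se_J <- rep_len(se_J, k); se_beta <- rep_len(se_beta, k)
  J <- rep_len(J, k); beta <- rep_len(beta, k)
  stopifnot(all(J > 0), all(beta > 0), all(E >= 0),
            all(se_J >= 0), all(se_beta >= 0))
  if (is.null(phenotype)) {
    phenotype <- if (!is.null(names(E))) names(E) else paste0("class", seq_len(k))
  }
  S <- E / J
  se_logS <- sqrt((se_J / J)^2 + (se_beta / beta)^2)
  lo <- exp(log(S) - 1.96 * se_logS)
  hi <- exp(log(S) + 1.96 * se_logS)
  data.frame(phenotype = phenotype, E = E, J = J, S = S,
             se_logS = se_logS, lo95 = lo, hi95 = hi,
             S_pct = round_half_up(100 * S, 2), row.names = NULL)
}

#' Standard error from a 95% quantile interval
#'
#' The Monte-Carlo expansion and the proportion resampling report
#' 2.5%/97.5% quantiles; the delta-method survival formula needs
#' standard errors.  The default maps the interval width on the log
#' scale, \eqn{SE(x)/x = (\log hi - \log lo)/(2 \times 1.96)},
#' matching the log-scale CI construction; `method = "sd"` instead
#' takes the standard deviation of the draws directly.
#'
#' @param point Point estimate.
#' @param lo95,hi95 Interval endpoints.
#' @param draws Optional vector of simulation draws (required for
#'   `method = "sd"`, and used as fallback when an endpoint is
#'   non-positive).
#' @param method `"log_ci"` (default) or `"sd"`.
#' @return Standard error on the natural scale.
#' @export
se_from_interval <- function(point, lo95, hi95, draws = NULL,
                             method = c("log_ci", "sd")) {
  method <- match.arg(method)
  if (method == "sd") {
    if (is.null(draws)) stop("method = 'sd' requires draws")
    return(stats::sd(draws))
  }
  if (lo95 <= 0 || hi95 <= 0 || point <= 0) {
    if (!is.null(draws)) return(stats::sd(draws))
    stop("log-scale interval mapping needs positive endpoints (supply draws as fallback)")
  }
  point * (log(hi95) - log(lo95)) / (2 * 1.96)
}

#' Bootstrap check of the delta-method survival interval
#'
#' Independent parametric bootstrap of the survival ratio: normal draws
#' of \eqn{J} and \eqn{\beta} around their estimates, survival
#' recomputed per draw, interval read off the 2.5%/97.5% quantiles.
#' Used to validate the closed-form delta CI at moderate CVs.
#'
#' @param E_n Natural escapement.
#' @param beta,se_beta Proportion and its SE.
#' @param J,se_J Passage and its SE.
#' @param n_boot Number of bootstrap draws.
#' @param seed Optional RNG seed.
#' @return Named vector with `lo95` and `hi95`.
#' @export
survival_ci_bootstrap <- function(E_n, beta, se_beta, J, se_J,
                                  n_boot = 1e6, seed = NULL) {
  maybe_seed(seed)
  b <- stats::rnorm(n_boot, beta, se_beta)
  j <- stats::rnorm(n_boot, J, se_J)
  keep <- b > 0 & j > 0
  s <- E_n * b[keep] / j[keep]
  stats::setNames(stats::quantile(s, c(0.025, 0.975), names = FALSE),
                  c("lo95", "hi95"))
}
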