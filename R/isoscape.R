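#' Train the one-dimensional isoscape discriminant
#'
#' Linear discriminant function analysis on a single analyte
#' (87Sr/86Sr) reduces to a Gaussian classifier with per-site means, a
#' pooled within-site variance and equal prior probabilities for all
#' sites; with those assumptions the decision boundaries are the
#' midpoints between adjacent site means.
#'
#' @param references Data frame of known-origin reference values with
#'   columns `site` and `ratio` (87Sr/86Sr); otolith and water samples
#'   are pooled with equal weight.
#' @return Object of class `isoscape_lda` with per-site `means`, `sd`
#'   (per-site), `pooled_sd`, sample sizes `n` and equal `priors`.
#' @export
train_isoscape <- function(references) {
  require_columns(references, c("site", "ratio"), "references")
  references$site <- as.character(references$site)
  n <- tapply(references$ratio, references$site, length)
  if (length(n) < 2L) stop("at least two sites are required")
  if (any(n < 2L)) {
    stop(sprintf("site(s) with fewer than 2 reference samples: %s",
                 paste(names(n)[n < 2L], collapse = ", ")))
  }
  means <- tapply(references$ratio, references$site, mean)
  vars <- tapply(references$ratio, references$site, stats::var)
  pooled <- sum((n - 1) * vars) / sum(n - 1)
  if (!is.finite(pooled) || pooled <= 0) {
    stop("pooled within-site variance is singular; reference ratios carry no spread")
  }
  structure(list(sites = names(means),
                 means = as.numeric(means),
                 sd = sqrt(as.numeric(vars)),
                 n = as.integer(n),
                 pooled_sd = sqrt(pooled),
                 priors = rep(1 / length(means), length(means))),
            class = "isoscape_lda")
}

#' @export
print.isoscape_lda <- function(x, ...) {
  cat("1-D isoscape discriminant (pooled variance, equal priors)\n")
  print(data.frame(site = x$sites, mean = x$means, sd = x$sd, n = x$n))
  cat(sprintf("pooled SD = %.6f\n", x$pooled_sd))
  invisible(x)
}

#' Posterior site-membership probabilities
#'
#' Normalised Gaussian likelihoods under the pooled-variance
#' discriminant, optionally restricted to a subset of sites (the exit
#' detector uses the two-site restriction natal vs immediate
#' downstream).
#'
#' @param classifier An `isoscape_lda`.
#' @param ratio Numeric vector of 87Sr/86Sr values.
#' @param sites Optional character subset of sites to condition on.
#' @return Matrix (length(ratio) x sites) of posteriors; rows sum to 1.
#' @export
site_posterior <- function(classifier, ratio, sites = NULL) {
  stopifnot(inherits(classifier, "isoscape_lda"))
  keep <- if (is.null(sites)) seq_along(classifier$sites)
          else match(sites, classifier$sites)
  if (anyNA(keep)) stop("unknown site in 'sites'")
  mu <- classifier$means[keep]
  sigma <- classifier$pooled_sd
  ll <- -outer(ratio, mu, "-")^2 / (2 * sigma^2)   # equal priors cancel
  ll <- ll - apply(ll, 1L, max)
  post <- exp(ll)
  post <- post / rowSums(post)
  colnames(post) <- classifier$sites[keep]
  post
}

#' Leave-one-out (jackknife) classification scores
#'
#' Each reference sample is withheld, the discriminant retrained on the
#' remainder, and the withheld sample classified; the per-site fraction
#' on the confusion-matrix diagonal measures isoscape performance.
#'
#' @param references As for [train_isoscape()].  Sites with a single
#'   sample are excluded with a warning.
#' @return List with `confusion` (actual rows x predicted columns),
#'   `correct` (named per-site correct fraction) and `overall`.
#' @export
jackknife_scores <- function(references) {
  require_columns(references, c("site", "ratio"), "references")
  references$site <- as.character(references$site)
  n <- table(references$site)
  if (any(n < 2L)) {
    drop <- names(n)[n < 2L]
    warning(sprintf("excluding site(s) with a single reference sample: %s",
                    paste(drop, collapse = ", ")))
    references <- references[!references$site %in% drop, , drop = FALSE]
  }
  sites <- sort(unique(references$site))
  pred <- character(nrow(references))
  for (i in seq_len(nrow(references))) {
    cls <- train_isoscape(references[-i, , drop = FALSE])
    post <- site_posterior(cls, references$ratio[i])
    pred[i] <- cls$sites[which.max(post)]
  }
  confusion <- table(actual = factor(references$site, levels = sites),
                     predicted = factor(pred, levels = sites))
  correct <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion, correct = correct,
       overall = sum(diag(confusion)) / sum(confusion))
}

#' Assign an adult otolith profile to its natal source
#'
#' The natal 87Sr/86Sr value of a fish is the precision-weighted mean
#' (weights 1/SE^2 where spot SEs are available, equal weights
#' otherwise) of the first `natal_window` spots beyond the core
#' (yolk-sac) region, whose maternally influenced chemistry does not
#' reflect ambient water.  The value is classified by the isoscape
#' discriminant; a fish whose predicted site differs from the focal
#' site is flagged a stray.  Posterior ties are broken toward the focal
#' site (conservative stray-calling).
#'
#' @param profile Data frame for one fish with columns `distance_um`
#'   and `ratio` ordered along the transect; an optional `se` column
#'   holds per-spot 2SE.
#' @param classifier An `isoscape_lda`.
#' @param focal_site Site label against which straying is judged.
#' @param natal_window Number of spots averaged (default 3).
#' @param core_radius_um Spots at or inside this distance are skipped.
#' @return List with `natal_ratio`, `predicted_site`, `posterior`
#'   (named vector) and `is_stray`.
#' @export
assign_natal <- function(profile, classifier, focal_site,
                         natal_window = 3L, core_radius_um = 140) {
  require_columns(profile, c("distance_um", "ratio"), "profile")
  stopifnot(inherits(classifier, "isoscape_lda"),
            focal_site %in% classifier$sites)
  profile <- profile[order(profile$distance_um), , drop = FALSE]
  use <- which(profile$distance_um > core_radius_um)
  if (length(use) < natal_window) {
    stop("profile has fewer spots beyond the core region than 'natal_window'")
  }
  use <- use[seq_len(natal_window)]
  se <- if ("se" %in% names(profile)) profile$se[use] else rep(NA_real_, length(use))
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, NA_real_)
  if (anyNA(w)) w <- rep(1, length(use))
  natal_ratio <- sum(w * profile$ratio[use]) / sum(w)
  post <- drop(site_posterior(classifier, natal_ratio))
  best <- max(post)
  winners <- names(post)[post >= best - 1e-12]
  predicted <- if (focal_site %in% winners) focal_site else names(post)[which.max(post)]
  list(natal_ratio = natal_ratio, predicted_site = predicted,
       posterior = post, is_stray = !identical(predicted, focal_site))
}

#' Locate the natal-exit point along an otolith profile
#'
#' Spots are scanned outward from the core, computing at each the
#' posterior probability of focal-site membership under the classifier
#' restricted to the focal site and its immediate downstream source
#' (natal exit is a two-source transition).  Exit is declared at the
#' first spot whose posterior both dropped by more than `drop` relative
#' to the previous spot and lies below `threshold`; the exit point is
#' the last spot before it ("the last natal spot").  If no spot
#' satisfies the rule but the profile does leave the natal signature,
#' the fallback is the last spot within 2 SD of the focal-site mean.  A
#' profile that never leaves the natal signature (incomplete transect
#' or death in the river) is flagged undefined.
#'
#' @param profile Data frame with `distance_um` and `ratio`, ordered by
#'   distance.
#' @param classifier An `isoscape_lda`.
#' @param focal_site Natal site label.
#' @param downstream_site Label of the source immediately downstream.
#' @param drop Minimum posterior decrease between consecutive spots.
#' @param threshold Posterior below which a spot is non-natal.
#' @return List with `exit_index`, `exit_radius_um`, `posterior`
#'   (per-spot focal posterior) and `defined` (FALSE when flagged).
#' @export
detect_exit <- function(profile, classifier, focal_site, downstream_site,
                        drop = 0.3, threshold = 0.5) {
  require_columns(profile, c("distance_um", "ratio"), "profile")
  stopifnot(inherits(classifier, "isoscape_lda"),
            all(c(focal_site, downstream_site) %in% classifier$sites),
            focal_site != downstream_site)
  profile <- profile[order(profile$distance_um), , drop = FALSE]
  post <- site_posterior(classifier, profile$ratio,
                         sites = c(focal_site, downstream_site))[, focal_site]
  n <- length(post)
  exit_index <- NA_integer_
  if (n >= 2L) {
    hit <- which(post[-1L] < threshold & (post[-n] - post[-1L]) > drop)
    if (length(hit) > 0L) exit_index <- hit[1L]   # spot before the drop
  }
  if (is.na(exit_index)) {
    mu <- classifier$means[match(focal_site, classifier$sites)]
    sdv <- classifier$sd[match(focal_site, classifier$sites)]
    natal_like <- abs(profile$ratio - mu) <= 2 * sdv
    if (all(natal_like)) {
      return(list(exit_index = NA_integer_, exit_radius_um = NA_real_,
                  posterior = post, defined = FALSE))
    }
    if (!any(natal_like)) {
      return(list(exit_index = NA_integer_, exit_radius_um = NA_real_,
                  posterior = post, defined = FALSE))
    }
    exit_index <- max(which(natal_like))
  }
  list(exit_index = exit_index,
       exit_radius_um = profile$distance_um[exit_index],
       posterior = post, defined = TRUE)
}
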