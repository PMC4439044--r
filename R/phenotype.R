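#' Migratory phenotype labels
#'
#' The three juvenile migratory phenotypes, ordered by increasing size at
#' outmigration.  Used as factor levels throughout the package.
#'
#' @return Character vector `c("fry", "parr", "smolt")`.
#' @export
phenotype_levels <- function() c("fry", "parr", "smolt")

#' Classify fork length into migratory phenotype
#'
#' Juvenile salmon are binned into migratory phenotypes purely by fork
#' length (FL): fry are \eqn{\le 55} mm, parr \eqn{> 55} to \eqn{\le 75}
#' mm, and smolts \eqn{> 75} mm.  Size bins replace subjective visual
#' staging criteria.
#'
#' @param fl Numeric vector of fork lengths in mm; all entries must be
#'   strictly positive.
#' @param breaks Two strictly increasing bin edges in mm (fry/parr and
#'   parr/smolt boundaries).  Both edges belong to the smaller class.
#' @return Factor with levels [phenotype_levels()].
#' @examples
#' assign_phenotype(c(55, 55.1, 75, 75.01))
#' @export
assign_phenotype <- function(fl, breaks = c(55, 75)) {
  stopifnot(is.numeric(fl), length(breaks) == 2L, breaks[1] < breaks[2])
  if (any(!is.finite(fl)) || any(fl <= 0)) {
    stop("fork lengths must be positive and finite")
  }
  lev <- phenotype_levels()
  out <- ifelse(fl <= breaks[1], lev[1], ifelse(fl <= breaks[2], lev[2], lev[3]))
  factor(out, levels = lev)
}

#' Apportion unmeasured fish to phenotypes
#'
#' On high-catch days only a subsample of fish (up to 50) is measured.
#' Unmeasured fish are assigned to phenotype using the observed
#' proportions among the measured fish of the same date, so the
#' per-phenotype counts always sum to the raw count exactly.
#'
#' @param raw_count Total number of fish caught that day (>= number
#'   measured).
#' @param measured_fl Numeric vector of measured fork lengths (mm); may
#'   be empty only if `fallback_shares` is supplied.
#' @param fallback_shares Optional probability vector over phenotypes
#'   used when no fish were measured that day (e.g. borrowed from the
#'   nearest measured day).
#' @param breaks Passed to [assign_phenotype()].
#' @return Named numeric vector of per-phenotype counts (possibly
#'   fractional) summing to `raw_count`.
#' @export
apportion_unmeasured <- function(raw_count, measured_fl,
                                 fallback_shares = NULL, breaks = c(55, 75)) {
  stopifnot(length(raw_count) == 1L, is.finite(raw_count), raw_count >= 0)
  lev <- phenotype_levels()
  if (raw_count == 0) {
    return(stats::setNames(numeric(3L), lev))
  }
  if (length(measured_fl) > 0) {
    if (raw_count < length(measured_fl)) {
      stop("raw_count is smaller than the number of measured fish")
    }
    shares <- prop.table(table(assign_phenotype(measured_fl, breaks)))
    shares <- as.numeric(shares[lev])
  } else if (!is.null(fallback_shares)) {
    stopifnot(length(fallback_shares) == 3L, all(fallback_shares >= 0),
              sum(fallback_shares) > 0)
    shares <- fallback_shares / sum(fallback_shares)
  } else {
    stop("no measured fish and no fallback shares for a day with catch")
  }
  stats::setNames(raw_count * shares, lev)
}

#' Interpolate missing daily catch with a triangular weighted mean
#'
#' Days on which the trap did not fish are filled with a weighted mean
#' of the observed values in a symmetric window, the weights decaying
#' linearly with distance in days (a triangular kernel).  Observed days
#' are never altered, and filled values use only originally observed
#' neighbours.
#'
#' @param x Numeric vector of daily values with `NA` marking missing
#'   days.
#' @param window Half-width of the window in days; a neighbour at
#'   offset \eqn{k} receives weight \eqn{1 - |k|/(window+1)}.
#' @return `x` with missing entries filled.  A missing day with no
#'   observed neighbour inside the window is set to 0 with a warning.
#' @export
interpolate_missing <- function(x, window = 3L) {
  stopifnot(is.numeric(x), window >= 1L)
  miss <- which(is.na(x))
  if (length(miss) == 0L) return(x)
  obs <- !is.na(x)
  out <- x
  empty <- 0L
  for (i in miss) {
    off <- setdiff(seq.int(-window, window), 0L)
    j <- i + off
    keep <- j >= 1L & j <= length(x)
    j <- j[keep]
    off <- off[keep]
    usable <- obs[j]
    if (!any(usable)) {
      out[i] <- 0
      empty <- empty + 1L
      next
    }
    w <- (1 - abs(off[usable]) / (window + 1))
    out[i] <- sum(w * x[j[usable]]) / sum(w)
  }
  if (empty > 0L) {
    warning(sprintf("%d missing day(s) had no observed neighbour within +/-%d days; filled with 0",
                    empty, window))
  }
  out
}

#' Build per-phenotype daily catch from raw records
#'
#' Applies [assign_phenotype()] to the measured fish of each day,
#' apportions unmeasured fish by the same-day measured proportions
#' (borrowing the nearest measured day when a day has catch but no
#' measurements), and fills non-operational days by
#' [interpolate_missing()].
#'
#' @param catch Data frame with columns `date` (Date), `raw_count`
#'   (integer) and `operational` (logical).
#' @param measured Data frame with columns `date` and `fl_mm`, one row
#'   per measured fish.
#' @param season Length-2 Date vector bounding the outmigration season
#'   (inclusive); defaults to the span of `catch$date`.
#' @param window Interpolation window, see [interpolate_missing()].
#' @param breaks Phenotype bin edges, see [assign_phenotype()].
#' @return Data frame with one row per season day and columns `date`,
#'   `fry`, `parr`, `smolt` (daily counts, interpolated where missing).
#' @export
daily_phenotype_catch <- function(catch, measured, season = NULL,
                                  window = 3L, breaks = c(55, 75)) {
  require_columns(catch, c("date", "raw_count", "operational"), "catch")
  require_columns(measured, c("date", "fl_mm"), "measured")
  catch$date <- as.Date(catch$date)
  measured$date <- as.Date(measured$date)
  if (is.null(season)) season <- range(catch$date)
  days <- seq(as.Date(season[1]), as.Date(season[2]), by = "day")
  lev <- phenotype_levels()
  mat <- matrix(NA_real_, nrow = length(days), ncol = 3L,
                dimnames = list(NULL, lev))
  measured_days <- sort(unique(measured$date))
  for (k in seq_along(days)) {
    d <- days[k]
    row <- catch[catch$date == d & catch$operational, , drop = FALSE]
    if (nrow(row) == 0L) next  # not fishing: leave NA for interpolation
    n <- sum(row$raw_count)
    fl <- measured$fl_mm[measured$date == d]
    if (n > 0 && length(fl) == 0L) {
      if (length(measured_days) == 0L) {
        stop("catch recorded but no fish measured on any day")
      }
      near <- measured_days[which.min(abs(as.numeric(measured_days - d)))]
      shares <- prop.table(table(assign_phenotype(
        measured$fl_mm[measured$date == near], breaks)))
      mat[k, ] <- apportion_unmeasured(n, numeric(0),
                                       fallback_shares = as.numeric(shares[lev]),
                                       breaks = breaks)
    } else {
      mat[k, ] <- apportion_unmeasured(n, fl, breaks = breaks)
    }
  }
  for (p in lev) mat[, p] <- interpolate_missing(mat[, p], window = window)
  data.frame(date = days, mat, row.names = NULL)
}
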