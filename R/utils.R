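# Internal helpers shared across modules.

# Abort with the offending data-frame name and missing column named.
require_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(sprintf("'%s' must be a data frame", what))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals, as used when
#' reporting survival percentages (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Seed the RNG only when a seed is supplied; keeps functions usable both
# standalone and inside an outer seeded simulation.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Largest-remainder apportionment of `total` (a non-negative integer)
# over non-negative weights; returns integers summing to `total` exactly.
apportion_integer <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
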