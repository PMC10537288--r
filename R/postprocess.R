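#' Sliding-window smoothing of a per-pulse ratio series
#'
#' For each pulse with a full trailing window of `window` pulses (the last
#' 100 pulses by default, about one minute of monitoring), the displayed
#' value is the mean of the window's non-missing ratios after excluding
#' values outside the `ci_level` normal confidence band `m +/- z s` (sample
#' mean and n-1 standard deviation of the raw non-missing values, one
#' exclusion pass). Windows with fewer than `min_valid` non-missing values -
#' counted before outlier exclusion - are reported missing, as are the first
#' `window - 1` pulses. The window is trailing (causal), which introduces
#' the display delay inherent to retrospective smoothing.
#'
#' @param values Numeric vector of per-pulse P2/P1 ratios, `NA` for pulses
#'   that did not pass selection.
#' @param window Window length in pulses.
#' @param min_valid Minimum number of non-missing values required.
#' @param ci_level Two-sided normal confidence level for outlier exclusion.
#' @return Numeric vector of the same length (the smoothed display series).
#' @export
smooth_ratio <- function(values, window = 100L, min_valid = 50L,
                         ci_level = 0.95) {
  stopifnot(length(values) > 0, min_valid >= 1, min_valid <= window,
            ci_level > 0, ci_level < 1)
  n <- length(values)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  for (t in window:n) {
    w <- values[(t - window + 1L):t]
    v <- w[!is.na(w)]
    if (length(v) < min_valid) next
    if (length(v) >= 2L) {
      m <- mean(v); s <- stats::sd(v)
      keep <- abs(v - m) <= z * s
      v <- v[keep]
    }
    out[t] <- mean(v)
  }
  out
}

#' Fraction of displayed (non-missing) values in a smoothed series
#'
#' @param values Smoothed ratio series from [smooth_ratio()].
#' @return Fraction in \[0, 1\].
#' @export
displayed_fraction <- function(values) {
  if (length(values) == 0)
    icpr_stop("icpr_empty_series", "cannot compute the displayed fraction of an empty series")
  mean(!is.na(values))
}
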