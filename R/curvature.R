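#' Discrete curvature of a sampled series
#'
#' Computes `kappa(x) = x'' / (1 + x'^2)^(3/2)` with first and second
#' derivatives estimated by central finite differences on the unit-spaced
#' sample grid (one-sided at the two endpoints). The abscissa unit is one
#' sample of the 180-point frame.
#'
#' @param x Numeric series, length >= 5.
#' @return Numeric vector of the same length.
#' @export
pulse_curvature <- function(x) {
  n <- length(x)
  stopifnot(n >= 5L)
  d1 <- numeric(n); d2 <- numeric(n)
  i <- 2:(n - 1)
  d1[i] <- (x[i + 1] - x[i - 1]) / 2
  d1[1] <- x[2] - x[1]
  d1[n] <- x[n] - x[n - 1]
  d2[i] <- x[i + 1] - 2 * x[i] + x[i - 1]
  d2[1] <- x[3] - 2 * x[2] + x[1]
  d2[n] <- x[n] - 2 * x[n - 1] + x[n - 2]
  d2 / (1 + d1^2)^1.5
}

# Centered moving average of width w with linear-extrapolation padding, so a
# locally linear signal stays linear at the edges (partial windows would bend
# it and fabricate curvature there).
moving_average <- function(x, w = 5L) {
  n <- length(x)
  h <- w %/% 2L
  left <- x[1] + (x[2] - x[1]) * (-h):(-1)
  right <- x[n] + (x[n] - x[n - 1]) * 1:h
  xp <- c(left, x, right)
  cs <- cumsum(c(0, xp))
  idx <- seq_len(n) + h
  (cs[idx + h + 1L] - cs[idx - h]) / w
}

#' Curvature-derived subpeak candidates of a normalized pulse
#'
#' P1 and P2 lie at local maxima of the curvature of the negated pulse,
#' `kappa(-p)`, within zones where the second derivative `p''` is negative
#' (concave regions). The pulse is lightly smoothed (moving average, width 5
#' samples, well below the subpeak spacing) before differentiation, since
#' second differences amplify interpolation noise. Plateaus contribute their
#' left-most sample; the frame endpoints are excluded.
#'
#' @param pulse A `normalized_pulse` or a numeric vector of length 180.
#' @return A list (`candidate_set`): `indices` (strictly increasing, 1-based)
#'   and `curvature_values` (`kappa(-p)` at those indices). May be empty.
#' @export
candidates <- function(pulse) {
  v <- if (inherits(pulse, "normalized_pulse")) pulse$values else as.numeric(pulse)
  n <- length(v)
  stopifnot(n >= 5L)
  s <- moving_average(v, 5L)
  km <- pulse_curvature(-s)
  d2 <- numeric(n)
  i <- 2:(n - 1)
  d2[i] <- s[i + 1] - 2 * s[i] + s[i - 1]
  d2[1] <- s[3] - 2 * s[2] + s[1]
  d2[n] <- s[n] - 2 * s[n - 1] + s[n - 2]
  idx <- local_maxima(km)
  # the concavity gate carries a small absolute tolerance: on segments that
  # are flat or linear to machine precision the sign of the second difference
  # is round-off noise, not curvature
  idx <- idx[d2[idx] < -1e-9]
  idx <- idx[idx > 1L & idx < n]
  structure(list(indices = idx, curvature_values = km[idx]),
            class = "candidate_set")
}
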