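#' Two-Gaussian training target for subpeak designation
#'
#' The designation networks regress, for each of the 180 pulse samples, a
#' score whose target is the sum of two Gaussians centred on the labeled P1
#' and P2 positions, scaled so the maximum is 1 when the two labels
#' coincide: `y(t) = (exp(-(t - p1)^2 / (2 sigma^2)) +
#' exp(-(t - p2)^2 / (2 sigma^2))) / 2`.
#'
#' @param p1,p2 Labeled subpeak indices (1-based, in \[1, 180\]); the (0, 0)
#'   sentinel of a non-calculable pulse is rejected.
#' @param sigma Gaussian standard deviation in samples (default 1).
#' @return Numeric vector of length 180 with values in \[0, 1\].
#' @export
target_vector <- function(p1, p2, sigma = 1) {
  if (p1 <= 0 || p2 <= 0)
    icpr_stop("icpr_noncalculable_label",
              "target vector requires a calculable (p1, p2) label")
  stopifnot(p1 <= PULSE_LEN, p2 <= PULSE_LEN, sigma > 0)
  t <- seq_len(PULSE_LEN)
  (exp(-(t - p1)^2 / (2 * sigma^2)) + exp(-(t - p2)^2 / (2 * sigma^2))) / 2
}

#' Designate P1 and P2 on one pulse
#'
#' In `curvature` mode the network output is read exactly at each
#' curvature-derived candidate index and the two highest-scoring candidates
#' are designated (score ties keep the earlier index). In `nn_output` mode
#' the two highest local maxima of the 180-point output are taken directly.
#' Either way P1 is the earlier of the two designated indices and P2 the
#' later. With fewer than two candidates or local maxima the pulse is
#' returned non-calculable rather than raising an error.
#'
#' @param density Numeric vector of length 180: the network output for this
#'   pulse.
#' @param cands A `candidate_set` from [candidates()] (required in curvature
#'   mode).
#' @param mode `"curvature"` or `"nn_output"`.
#' @return A list with `calculable` plus, when calculable, `i1` and `i2`
#'   (1-based indices, `i1 < i2`).
#' @export
designate <- function(density, cands = NULL, mode = c("curvature", "nn_output")) {
  mode <- match.arg(mode)
  stopifnot(length(density) == PULSE_LEN)
  if (mode == "curvature") {
    if (is.null(cands))
      icpr_stop("icpr_invalid_config", "curvature mode requires a candidate set")
    idx <- cands$indices
  } else {
    idx <- local_maxima(density)
  }
  if (length(idx) < 2L) return(list(calculable = FALSE))
  sc <- density[idx]
  top2 <- idx[order(-sc, idx)][1:2]  # ties keep the earlier index
  list(calculable = TRUE, i1 = min(top2), i2 = max(top2))
}

#' P2/P1 amplitude ratio of a normalized pulse
#'
#' The ratio of relative amplitudes is computed on the \[0, 1\]-normalized
#' pulse, i.e. amplitudes measured above the pulse minimum, which makes it
#' invariant to the raw signal's scale and offset.
#'
#' @param values Numeric pulse of length 180 in \[0, 1\].
#' @param i1,i2 Designated P1 and P2 indices (1-based, `i1 < i2`).
#' @return Positive ratio `values[i2] / values[i1]`.
#' @export
p2p1_ratio <- function(values, i1, i2) {
  stopifnot(length(values) == PULSE_LEN, i1 >= 1, i1 < i2, i2 <= PULSE_LEN)
  if (values[i1] <= 0)
    icpr_stop("icpr_degenerate_designation", "P1 amplitude is zero")
  values[i2] / values[i1]
}

#' Designate subpeaks and compute ratios over a pulse matrix
#'
#' Runs the designation network over all pulses and applies [designate()] and
#' [p2p1_ratio()] per pulse.
#'
#' @param model A trained designation `icpr_model`.
#' @param pulses N x 180 matrix or `pulse_matrix`.
#' @param mode Designation strategy; defaults to the model configuration's.
#' @return Data frame `(pulse_id, i1, i2, ratio, calculable)`; non-calculable
#'   rows carry the 0 sentinel and `NA` ratio.
#' @export
designate_pulses <- function(model, pulses, mode = NULL) {
  stopifnot(inherits(model, "icpr_model"), model$task == "designation")
  if (inherits(pulses, "pulse_matrix")) pulses <- pulses$pulses
  if (is.null(mode)) mode <- model$cfg$mode
  dens <- predict_density(model, pulses)
  n <- nrow(pulses)
  i1 <- integer(n); i2 <- integer(n)
  ratio <- rep(NA_real_, n); calc <- logical(n)
  for (i in seq_len(n)) {
    cs <- if (mode == "curvature") candidates(pulses[i, ]) else NULL
    d <- designate(dens[i, ], cs, mode)
    if (d$calculable && pulses[i, d$i1] > 0) {
      i1[i] <- d$i1; i2[i] <- d$i2
      ratio[i] <- p2p1_ratio(pulses[i, ], d$i1, d$i2)
      calc[i] <- TRUE
    }
  }
  data.frame(pulse_id = seq_len(n), i1 = i1, i2 = i2,
             ratio = ratio, calculable = calc)
}

#' Curvature-only designation baseline
#'
#' Designates the two earliest curvature candidates as P1 and P2, with no
#' neural network involved; the comparison baseline for the learned
#' designators.
#'
#' @param pulses N x 180 matrix or `pulse_matrix`.
#' @return Data frame as in [designate_pulses()].
#' @export
designate_curvature_baseline <- function(pulses) {
  if (inherits(pulses, "pulse_matrix")) pulses <- pulses$pulses
  n <- nrow(pulses)
  i1 <- integer(n); i2 <- integer(n)
  ratio <- rep(NA_real_, n); calc <- logical(n)
  for (i in seq_len(n)) {
    cs <- candidates(pulses[i, ])
    if (length(cs$indices) >= 2L && pulses[i, cs$indices[1]] > 0) {
      i1[i] <- cs$indices[1]; i2[i] <- cs$indices[2]
      ratio[i] <- p2p1_ratio(pulses[i, ], i1[i], i2[i])
      calc[i] <- TRUE
    }
  }
  data.frame(pulse_id = seq_len(n), i1 = i1, i2 = i2,
             ratio = ratio, calculable = calc)
}
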