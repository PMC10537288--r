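#' End-to-end pipeline configuration
#'
#' @param selector Trained selection `icpr_model`.
#' @param designator Trained designation `icpr_model`.
#' @param threshold Selection decision threshold on the sigmoid probability
#'   (typically the Youden-optimal point from [youden_threshold()]).
#' @param mode Designation strategy override (`NULL` uses the designator's).
#' @param L_ms Onset-detector characteristic duration, milliseconds.
#' @param window,min_valid,ci_level Smoothing parameters, see
#'   [smooth_ratio()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(selector, designator, threshold = 0.5,
                            mode = NULL, L_ms = 500,
                            window = 100L, min_valid = 50L, ci_level = 0.95) {
  stopifnot(inherits(selector, "icpr_model"), selector$task == "selection",
            inherits(designator, "icpr_model"),
            designator$task == "designation", is.finite(threshold))
  structure(list(selector = selector, designator = designator,
                 threshold = threshold, mode = mode, L_ms = L_ms,
                 window = as.integer(window), min_valid = as.integer(min_valid),
                 ci_level = ci_level),
            class = "pipeline_config")
}

#' Run the full P2/P1 monitoring framework on a raw record
#'
#' Composes the four pipeline stages in order: band-pass filtering and
#' multiscale onset detection, beat segmentation and 180-sample
#' normalization, neural pulse selection at the configured threshold,
#' subpeak designation with the P2/P1 ratio, and sliding-window smoothing.
#' Pulses rejected by the selector, or whose designation fails (fewer than
#' two candidates), carry a missing raw ratio.
#'
#' @param record A raw [icp_record()].
#' @param cfg A [pipeline_config()].
#' @return A list (`framework_output`): `per_pulse` data frame `(pulse_id,
#'   onset_time_s, selected, i1, i2, ratio)`, `smoothed` (display series,
#'   same length), `n_dropped_beats`.
#' @export
run_framework <- function(record, cfg) {
  stopifnot(inherits(record, "icp_record"), inherits(cfg, "pipeline_config"))
  pm <- preprocess_record(record, L_ms = cfg$L_ms)
  if (nrow(pm$meta) == 0L)
    icpr_stop("icpr_no_beats", "no beats detected in the record")
  keep <- select_pulses(cfg$selector, pm, cfg$threshold)
  des <- data.frame(pulse_id = pm$meta$pulse_id,
                    i1 = 0L, i2 = 0L, ratio = NA_real_, calculable = FALSE)
  if (any(keep)) {
    sel <- designate_pulses(cfg$designator, pm$pulses[keep, , drop = FALSE],
                            mode = cfg$mode)
    des$i1[keep] <- sel$i1
    des$i2[keep] <- sel$i2
    des$ratio[keep] <- sel$ratio
    des$calculable[keep] <- sel$calculable
  }
  smoothed <- smooth_ratio(des$ratio, cfg$window, cfg$min_valid, cfg$ci_level)
  per_pulse <- data.frame(
    pulse_id = pm$meta$pulse_id,
    onset_time_s = (pm$meta$onset_sample - 1) / record$fs,
    selected = keep,
    i1 = des$i1, i2 = des$i2, ratio = des$ratio)
  structure(list(per_pulse = per_pulse, smoothed = smoothed,
                 n_dropped_beats = pm$n_dropped),
            class = "framework_output")
}
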