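#' Raw ICP record container
#'
#' @param samples Numeric vector of pressure samples (mmHg-like units).
#' @param fs Sampling rate in Hz.
#' @return An object of class `icp_record`.
#' @export
icp_record <- function(samples, fs) {
  stopifnot(is.numeric(samples), fs > 0)
  if (length(samples) < 2 * fs)
    icpr_stop("icpr_record_too_short", "record must span at least two seconds")
  structure(list(samples = as.numeric(samples), fs = fs), class = "icp_record")
}

#' Band-pass filter an ICP record
#'
#' Applies a fourth-order Butterworth band-pass (default edges 0.3 and 20 Hz)
#' forward and backward (zero phase), isolating cardiac pulses from electronic
#' high-frequency oscillations, respiratory waves and baseline drift. The
#' zero-phase application means subpeak timing is not skewed by filter delay.
#'
#' @param record An [icp_record()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order of the band-pass prototype.
#' @return A filtered `icp_record` of identical length.
#' @export
bandpass <- function(record, low = 0.3, high = 20, order = 4) {
  stopifnot(inherits(record, "icp_record"))
  fs <- record$fs
  if (fs <= 2 * high)
    icpr_stop("icpr_invalid_config", "sampling rate must exceed twice the upper band edge")
  # require ~3 periods of the lowest passed frequency as filter warm-up
  if (length(record$samples) < ceiling(3 * fs / low))
    icpr_stop("icpr_record_too_short",
              "record shorter than the band-pass warm-up (3 periods of %g Hz)", low)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- record$samples
  n <- length(x)
  # forward-backward filtering with odd (reflected) extension at both ends,
  # long enough for the 0.3 Hz pole transients to die out inside the padding
  pad <- min(n - 1L, ceiling(3 * fs / low))
  xr <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filter(bf, xr)
  y <- rev(signal::filter(bf, rev(y)))
  icp_record(y[pad + seq_len(n)], fs)
}

#' Detect pulse onsets with a modified Scholkmann multiscale trough detector
#'
#' Builds the local-minima scalogram `m(k, i) = 1` iff `x_i < x_{i-k}` and
#' `x_i < x_{i+k}` for window scales `k = 1..L`, picks the scale `lambda`
#' with the largest number of detected minima (smallest scale on ties), and
#' returns the samples that are minima at every scale up to `lambda`. The
#' characteristic duration `L` (default 500 ms) bounds the scale range and is
#' meant to be at least a quarter of the average pulse duration. The detector
#' compares amplitudes only, so it is invariant to signal scaling.
#'
#' @param record A band-passed [icp_record()].
#' @param L_ms Characteristic duration in milliseconds.
#' @return Strictly increasing integer vector of onset samples (1-based).
#'   A constant signal yields an empty result.
#' @export
detect_onsets <- function(record, L_ms = 500) {
  stopifnot(inherits(record, "icp_record"), L_ms > 0)
  x <- record$samples
  n <- length(x)
  L <- max(2L, as.integer(round(L_ms * record$fs / 1000)))
  if (n < 2L * L + 2L) return(integer(0))
  counts <- integer(L)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    counts[k] <- sum(x[i] < x[i - k] & x[i] < x[i + k])
  }
  if (all(counts == 0L)) return(integer(0))
  lambda <- which.max(counts)  # ties resolve to the smallest scale
  keep <- rep(TRUE, n)
  for (k in seq_len(lambda)) {
    m <- rep(FALSE, n)
    i <- (k + 1L):(n - k)
    m[i] <- x[i] < x[i - k] & x[i] < x[i + k]
    keep <- keep & m
  }
  which(keep)
}

#' Segment a record into single beats
#'
#' Beat `j` spans samples `[onset_j, onset_{j+1})`; the tail after the last
#' onset is discarded. Beats shorter than 0.25 s or longer than 2 s (outside
#' 30-240 bpm) are dropped as missed or spurious onsets.
#'
#' @param record An [icp_record()] (typically the raw record, segmented at the
#'   onsets found on its filtered counterpart).
#' @param onsets Strictly increasing onset samples.
#' @return A list with `beats` (list of numeric vectors), `onsets` (the onset
#'   sample of each retained beat) and `n_dropped`.
#' @export
segment_beats <- function(record, onsets) {
  stopifnot(inherits(record, "icp_record"))
  onsets <- as.integer(onsets)
  if (length(onsets) >= 2 && any(diff(onsets) <= 0))
    icpr_stop("icpr_invalid_onsets", "onsets must be strictly increasing")
  if (length(onsets) < 2)
    return(list(beats = list(), onsets = integer(0), n_dropped = 0L))
  fs <- record$fs
  lens <- diff(onsets)
  ok <- lens >= 0.25 * fs & lens <= 2 * fs
  beats <- lapply(which(ok), function(j)
    record$samples[onsets[j]:(onsets[j + 1] - 1L)])
  list(beats = beats, onsets = onsets[which(ok)],
       n_dropped = sum(!ok))
}

#' Normalize a beat to the 180-sample unit-amplitude frame
#'
#' Maps the amplitude to \[0, 1\] by `(x - min) / (max - min)` and resamples to
#' exactly 180 points by piecewise cubic (third-degree) interpolation through
#' all samples on a uniform grid. The min-max anchoring is re-applied after
#' interpolation so the output attains 0 and 1 exactly (cubic interpolation
#' can otherwise overshoot by a small amount).
#'
#' @param beat Numeric vector, length >= 4, non-constant.
#' @param onset_sample Optional raw-record onset for provenance.
#' @return A list (`normalized_pulse`): `values` (180 reals in \[0, 1\]),
#'   `onset_sample`, `duration_samples`, `raw_min`, `raw_max`.
#' @export
normalize_beat <- function(beat, onset_sample = NA_integer_) {
  n <- length(beat)
  if (n < 4L)
    icpr_stop("icpr_degenerate_pulse", "beat too short to normalize")
  mn <- min(beat); mx <- max(beat)
  if (mx <= mn)
    icpr_stop("icpr_degenerate_pulse", "flat beat cannot be normalized")
  y <- (beat - mn) / (mx - mn)
  v <- stats::spline(x = seq(0, 1, length.out = n), y = y,
                     xout = seq(0, 1, length.out = 180L), method = "fmm")$y
  v <- (v - min(v)) / (max(v) - min(v))
  structure(list(values = v, onset_sample = onset_sample,
                 duration_samples = n, raw_min = mn, raw_max = mx),
            class = "normalized_pulse")
}

#' Preprocess a raw ICP record into a pulse matrix
#'
#' Composes [bandpass()], [detect_onsets()], [segment_beats()] and
#' [normalize_beat()] into the N x 180 matrix consumed by the selection and
#' designation networks. Onset detection, segmentation and normalization all
#' operate on the filtered signal, so the networks see pulses free of
#' baseline and respiratory components. Beats that fail normalization (flat
#' segments) are dropped.
#'
#' @param record A raw [icp_record()].
#' @param L_ms Characteristic duration for onset detection, milliseconds.
#' @return A list (`pulse_matrix`): `pulses` (N x 180 matrix), `meta` (data
#'   frame: `pulse_id`, `onset_sample`, `duration_samples`, `raw_min`,
#'   `raw_max`), `n_dropped`.
#' @export
preprocess_record <- function(record, L_ms = 500) {
  filt <- bandpass(record)
  onsets <- detect_onsets(filt, L_ms = L_ms)
  seg <- segment_beats(filt, onsets)
  if (length(seg$beats) == 0L)
    return(structure(list(pulses = matrix(numeric(0), 0, 180),
                          meta = data.frame(), n_dropped = seg$n_dropped),
                     class = "pulse_matrix"))
  rows <- vector("list", length(seg$beats))
  keep <- logical(length(seg$beats))
  for (j in seq_along(seg$beats)) {
    np <- tryCatch(normalize_beat(seg$beats[[j]], seg$onsets[j]),
                   icpr_degenerate_pulse = function(e) NULL)
    if (!is.null(np)) { rows[[j]] <- np; keep[j] <- TRUE }
  }
  rows <- rows[keep]
  pulses <- do.call(rbind, lapply(rows, `[[`, "values"))
  meta <- data.frame(
    pulse_id = seq_along(rows),
    onset_sample = vapply(rows, `[[`, numeric(1), "onset_sample"),
    duration_samples = vapply(rows, `[[`, numeric(1), "duration_samples"),
    raw_min = vapply(rows, `[[`, numeric(1), "raw_min"),
    raw_max = vapply(rows, `[[`, numeric(1), "raw_max"))
  structure(list(pulses = pulses, meta = meta,
                 n_dropped = seg$n_dropped + sum(!keep)),
            class = "pulse_matrix")
}
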