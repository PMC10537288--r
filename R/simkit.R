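#' Pulse template for synthetic ICP beats
#'
#' Describes a single cardiac-cycle intracranial-pressure pulse as a sum of up
#' to three Gaussian bumps, one per subpeak (P1, P2, P3), on top of a constant
#' baseline. Positions and widths are expressed as fractions of the pulse
#' duration so the same template can be rendered at any beat length.
#'
#' @param amplitudes Three non-negative subpeak amplitudes (arbitrary pressure
#'   units). A zero amplitude removes that subpeak.
#' @param positions Three strictly increasing subpeak centres in (0, 1),
#'   fractions of the pulse duration.
#' @param widths Three positive Gaussian standard deviations, fractions of the
#'   pulse duration.
#' @param baseline Constant offset added to the waveform.
#' @return An object of class `pulse_template`.
#' @examples
#' tpl <- pulse_template()          # normal-compliance morphology, P2/P1 < 1
#' p <- make_pulse(tpl, 180)
#' plot(p$values, type = "l")
#' @export
pulse_template <- function(amplitudes = c(1.0, 0.8, 0.5),
                           positions = c(0.22, 0.44, 0.67),
                           widths = c(0.06, 0.06, 0.11),
                           baseline = 0) {
  stopifnot(length(amplitudes) == 3L, length(positions) == 3L,
            length(widths) == 3L, length(baseline) == 1L)
  if (any(amplitudes < 0) || !any(amplitudes > 0))
    icpr_stop("icpr_invalid_template", "need non-negative amplitudes, at least one > 0")
  if (any(diff(positions) <= 0) || any(positions <= 0) || any(positions >= 1))
    icpr_stop("icpr_invalid_template", "subpeak positions must be strictly increasing in (0,1)")
  if (any(widths <= 0))
    icpr_stop("icpr_invalid_template", "subpeak widths must be positive")
  structure(list(amplitudes = as.numeric(amplitudes),
                 positions = as.numeric(positions),
                 widths = as.numeric(widths),
                 baseline = as.numeric(baseline)),
            class = "pulse_template")
}

#' Render a pulse template as a sampled waveform with ground truth
#'
#' Evaluates the Gaussian-sum waveform on `n_samples` points covering one beat
#' and derives the ground-truth subpeak locations from the rendered waveform
#' itself: each configured subpeak is matched to the nearest local maximum of
#' the noiseless waveform (overlapping Gaussians shift the apexes, so truth is
#' what a perfect detector could recover, not the raw template centres). The
#' true P2/P1 ratio is the quotient of the min-max-normalized waveform at the
#' P2 and P1 apexes.
#'
#' @param template A [pulse_template()].
#' @param n_samples Number of samples for the beat (>= 20).
#' @return A list with `values` (length `n_samples`), `apex` (integer sample
#'   index, 1-based, of each subpeak with positive amplitude, `NA` when no
#'   distinct maximum exists), `p1`, `p2` (apex samples of the first and second
#'   subpeak or `NA`), `ratio` (normalized P2/P1 amplitude quotient or `NA`)
#'   and `calculable` (TRUE iff both P1 and P2 have distinct apexes).
#' @export
make_pulse <- function(template, n_samples) {
  if (!inherits(template, "pulse_template"))
    icpr_stop("icpr_invalid_template", "`template` must be a pulse_template")
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 20L)
  t <- (seq_len(n_samples) - 1L) / n_samples
  v <- rep(template$baseline, n_samples)
  for (k in 1:3) {
    a <- template$amplitudes[k]
    if (a > 0)
      v <- v + a * exp(-(t - template$positions[k])^2 / (2 * template$widths[k]^2))
  }
  lm <- local_maxima(v)
  apex <- rep(NA_integer_, 3)
  active <- which(template$amplitudes > 0)
  if (length(lm) > 0) {
    # greedy nearest-maximum assignment, one maximum per subpeak
    avail <- lm
    for (k in active) {
      ctr <- template$positions[k] * n_samples + 1
      if (length(avail) == 0) break
      j <- which.min(abs(avail - ctr))
      # only claim a maximum that is closer to this centre than to any other
      # configured centre, so merged subpeaks do not double-claim one apex
      ctrs <- template$positions[active] * n_samples + 1
      if (which.min(abs(avail[j] - ctrs)) == match(k, active)) {
        apex[k] <- avail[j]
        avail <- avail[-j]
      }
    }
  }
  vn <- (v - min(v)) / (max(v) - min(v))
  calculable <- !is.na(apex[1]) && !is.na(apex[2])
  ratio <- if (calculable) vn[apex[2]] / vn[apex[1]] else NA_real_
  list(values = v, apex = apex, p1 = apex[1], p2 = apex[2],
       ratio = ratio, calculable = calculable)
}

# Realized normalized P2/P1 ratio of a template as a function of the second
# subpeak amplitude; used to invert a target ratio into an a2 value.
realized_ratio <- function(a2, template, n_samples = 200L) {
  tpl <- template
  tpl$amplitudes[2] <- a2
  p <- make_pulse(tpl, n_samples)
  if (!p$calculable) return(NA_real_)
  p$ratio
}

# Solve for the P2 amplitude that realizes `target` on the rendered waveform,
# by inverting a calibration grid of the monotone a2 -> realized-ratio map
# (restricted to a2 values where P2 is actually visible). Targets outside the
# attainable range clamp to the nearest attainable ratio.
solve_a2 <- function(target, template, lower = 0.15, upper = 3.0, by = 0.025) {
  a_grid <- seq(lower, upper, by = by) * template$amplitudes[1]
  r_grid <- vapply(a_grid, realized_ratio, numeric(1), template = template)
  ok <- !is.na(r_grid)
  if (sum(ok) < 2L)
    icpr_stop("icpr_invalid_template", "no P2-visible amplitude exists for this template")
  stats::approx(r_grid[ok], a_grid[ok], xout = target, rule = 2, ties = "ordered")$y
}

#' Configuration for synthetic ICP record generation
#'
#' Bundles the physiological and nuisance parameters of a simulated 100 Hz ICP
#' recording: heart rate with per-beat jitter, an additive respiratory
#' sinusoid, a slow baseline random-walk drift, broadband noise, and a target
#' P2/P1 ratio trajectory that the per-beat pulse templates realize.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz (must exceed 40 Hz, twice the 20 Hz analysis
#'   band edge).
#' @param heart_rate_bpm Mean heart rate, beats per minute, in \[40, 140\].
#' @param hr_jitter Coefficient of variation of the per-beat period.
#' @param resp_freq_hz,resp_amp Respiratory modulation frequency and amplitude.
#' @param drift_amp Standard deviation of the low-passed (< 0.1 Hz) baseline
#'   random walk.
#' @param noise_sd White-noise standard deviation.
#' @param artifact_rate,missing_subpeak_rate Per-beat degradation
#'   probabilities in \[0, 1\], applied by [degrade()].
#' @param ratio_trajectory Function of time (seconds) returning the target
#'   P2/P1 ratio for a beat starting at that time.
#' @param template Base [pulse_template()]; its second amplitude is re-solved
#'   per beat to follow `ratio_trajectory`.
#' @param baseline_icp Mean ICP level (mmHg-like units) added to the record.
#' @param seed Integer seed driving all randomness of the generator.
#' @return An object of class `record_config`.
#' @export
record_config <- function(duration_s = 60,
                          fs = 100,
                          heart_rate_bpm = 70,
                          hr_jitter = 0.03,
                          resp_freq_hz = 0.25,
                          resp_amp = 0.2,
                          drift_amp = 0.3,
                          noise_sd = 0.02,
                          artifact_rate = 0,
                          missing_subpeak_rate = 0,
                          ratio_trajectory = function(t) rep(0.9, length(t)),
                          template = pulse_template(),
                          baseline_icp = 10,
                          seed = 1L) {
  stopifnot(duration_s > 0, fs > 40, heart_rate_bpm >= 40, heart_rate_bpm <= 140,
            hr_jitter >= 0, resp_freq_hz >= 0, resp_amp >= 0, drift_amp >= 0,
            noise_sd >= 0, is.function(ratio_trajectory))
  if (artifact_rate < 0 || artifact_rate > 1 ||
      missing_subpeak_rate < 0 || missing_subpeak_rate > 1)
    icpr_stop("icpr_invalid_config", "degradation rates must lie in [0, 1]")
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
                 resp_freq_hz = resp_freq_hz, resp_amp = resp_amp,
                 drift_amp = drift_amp, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 missing_subpeak_rate = missing_subpeak_rate,
                 ratio_trajectory = ratio_trajectory, template = template,
                 baseline_icp = baseline_icp, seed = as.integer(seed)),
            class = "record_config")
}

#' Generate a synthetic ICP record with per-beat ground truth
#'
#' Concatenates beats rendered from the configured template (second-subpeak
#' amplitude solved per beat so the rendered, normalized P2/P1 ratio follows
#' `ratio_trajectory`), then adds the respiratory sinusoid, low-frequency
#' drift and white noise. Respiration and drift both lie below the 0.3 Hz
#' analysis band edge so the preprocessing filter can be validated against
#' them. Deterministic for a fixed `seed`.
#'
#' @param config A [record_config()].
#' @return A list with `record` (an `icp_record`: `samples`, `fs`) and `truth`,
#'   a data frame with one row per complete beat: `pulse_id`, `onset_sample`
#'   (1-based), `duration_samples`, `p1_sample`, `p2_sample` (raw-record
#'   coordinates), `p1_norm_idx`, `p2_norm_idx` (images in the 180-sample
#'   frame, 1-based; 0 is the non-calculable sentinel), `true_ratio`,
#'   `calculable`.
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "record_config"))
  fs <- config$fs
  n_total <- round(config$duration_s * fs)
  mean_period <- 60 / config$heart_rate_bpm
  if (n_total < round(mean_period * fs))
    icpr_stop("icpr_record_too_short", "duration is shorter than one beat")

  out <- with_seed(config$seed, {
    # per-beat periods
    n_beats_max <- ceiling(config$duration_s / mean_period) + 10L
    periods <- mean_period * (1 + config$hr_jitter * stats::rnorm(n_beats_max))
    periods <- pmax(periods, 0.3)
    beat_len <- pmax(as.integer(round(periods * fs)), 30L)

    # calibration grid: a2 multiplier -> realized normalized ratio
    a2_grid <- seq(0.15, 3.0, by = 0.05) * config$template$amplitudes[1]
    r_grid <- vapply(a2_grid, realized_ratio, numeric(1), template = config$template)
    ok <- !is.na(r_grid)
    a2_grid <- a2_grid[ok]; r_grid <- r_grid[ok]

    signal <- numeric(0)
    onset <- integer(0); dur <- integer(0)
    p1s <- integer(0); p2s <- integer(0)
    p1n <- integer(0); p2n <- integer(0)
    ratio <- numeric(0); calc <- logical(0)
    pos <- 1L
    for (b in seq_len(n_beats_max)) {
      nb <- beat_len[b]
      if (pos + nb - 1L > n_total) break
      t_onset <- (pos - 1L) / fs
      target <- config$ratio_trajectory(t_onset)
      a2 <- stats::approx(r_grid, a2_grid, xout = target, rule = 2,
                          ties = "ordered")$y
      tpl <- config$template
      tpl$amplitudes[2] <- a2
      p <- make_pulse(tpl, nb)
      signal <- c(signal, p$values)
      onset <- c(onset, pos); dur <- c(dur, nb)
      if (p$calculable) {
        p1s <- c(p1s, pos + p$p1 - 1L); p2s <- c(p2s, pos + p$p2 - 1L)
        p1n <- c(p1n, 1L + as.integer(round((p$p1 - 1L) * 179 / (nb - 1L))))
        p2n <- c(p2n, 1L + as.integer(round((p$p2 - 1L) * 179 / (nb - 1L))))
        ratio <- c(ratio, p$ratio); calc <- c(calc, TRUE)
      } else {
        p1s <- c(p1s, NA_integer_); p2s <- c(p2s, NA_integer_)
        p1n <- c(p1n, 0L); p2n <- c(p2n, 0L)
        ratio <- c(ratio, NA_real_); calc <- c(calc, FALSE)
      }
      pos <- pos + nb
    }
    if (length(onset) == 0L)
      icpr_stop("icpr_record_too_short", "duration is shorter than one beat")
    # pad the tail (after the last complete beat) with the baseline level
    if (length(signal) < n_total)
      signal <- c(signal, rep(config$template$baseline, n_total - length(signal)))

    tt <- (seq_len(n_total) - 1) / fs
    if (config$resp_amp > 0 && config$resp_freq_hz > 0)
      signal <- signal + config$resp_amp * sin(2 * pi * config$resp_freq_hz * tt)
    if (config$drift_amp > 0) {
      w <- stats::rnorm(n_total)
      bf <- signal::butter(2, min(0.1 / (fs / 2), 0.99), type = "low")
      d <- signal::filtfilt(bf, w)
      sdd <- stats::sd(d)
      if (sdd > 0) signal <- signal + config$drift_amp * d / sdd
    }
    if (config$noise_sd > 0)
      signal <- signal + stats::rnorm(n_total, sd = config$noise_sd)
    signal <- signal + config$baseline_icp

    truth <- data.frame(pulse_id = seq_along(onset), onset_sample = onset,
                        duration_samples = dur, p1_sample = p1s, p2_sample = p2s,
                        p1_norm_idx = p1n, p2_norm_idx = p2n,
                        true_ratio = ratio, calculable = calc)
    list(record = icp_record(signal, fs), truth = truth)
  })
  if (config$artifact_rate > 0 || config$missing_subpeak_rate > 0)
    out <- degrade(out$record, out$truth, config$artifact_rate,
                   config$missing_subpeak_rate, derive_seed(config$seed, 77L),
                   template = config$template)
  out
}

#' Inject artifacts and missing-subpeak beats into a synthetic record
#'
#' Randomly chosen beats are replaced either by artifact shapes (pressure
#' spikes, flat segments, damped noise bursts - emulating patient movement and
#' electronic perturbations) or by re-rendered beats lacking a distinct P1 or
#' P2. Affected beats are flagged `calculable = FALSE` with the (0, 0)
#' normalized-label sentinel.
#'
#' @param record An `icp_record` from [generate_record()].
#' @param truth Its ground-truth data frame.
#' @param artifact_rate,missing_subpeak_rate Per-beat probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @param template Template used to re-render missing-subpeak beats.
#' @return A list `(record, truth)` with the same shapes as the input.
#' @export
degrade <- function(record, truth, artifact_rate, missing_subpeak_rate, seed,
                    template = pulse_template()) {
  if (artifact_rate < 0 || artifact_rate > 1 ||
      missing_subpeak_rate < 0 || missing_subpeak_rate > 1)
    icpr_stop("icpr_invalid_config", "degradation rates must lie in [0, 1]")
  if (artifact_rate == 0 && missing_subpeak_rate == 0)
    return(list(record = record, truth = truth))
  with_seed(seed, {
    x <- record$samples
    n_beats <- nrow(truth)
    u <- stats::runif(n_beats)
    for (b in seq_len(n_beats)) {
      kind <- if (u[b] < artifact_rate) "artifact"
              else if (u[b] < artifact_rate + missing_subpeak_rate) "missing"
              else next
      i0 <- truth$onset_sample[b]
      nb <- truth$duration_samples[b]
      idx <- i0:(i0 + nb - 1L)
      base <- x[i0]
      if (kind == "artifact") {
        shape <- sample(c("spike", "flat", "noise"), 1L)
        repl <- switch(shape,
          spike = base + 5 * max(template$amplitudes) *
            exp(-((seq_len(nb) / nb) - stats::runif(1, 0.2, 0.8))^2 / (2 * 0.03^2)),
          flat = rep(base, nb),
          noise = base + max(template$amplitudes) * stats::rnorm(nb) *
            exp(-3 * seq_len(nb) / nb))
      } else {
        tpl <- template
        drop_first <- stats::runif(1) < 0.5
        if (drop_first) tpl$amplitudes[1] <- 0 else tpl$amplitudes[2] <- 0
        repl <- make_pulse(tpl, nb)$values + (base - tpl$baseline)
      }
      x[idx] <- repl
      truth$p1_sample[b] <- NA_integer_; truth$p2_sample[b] <- NA_integer_
      truth$p1_norm_idx[b] <- 0L; truth$p2_norm_idx[b] <- 0L
      truth$true_ratio[b] <- NA_real_; truth$calculable[b] <- FALSE
    }
    list(record = icp_record(x, record$fs), truth = truth)
  })
}

#' Simulate a labeled dataset of normalized pulses
#'
#' Renders independent single beats with randomized morphology (subpeak
#' positions, widths, beat length, target P2/P1 ratio), adds white noise,
#' min-max normalizes and resamples each to the 180-sample frame, and attaches
#' ground-truth labels in that frame. A configurable fraction of pulses is
#' non-calculable: beats missing P1 or P2, or artifact shapes (noise bursts,
#' isolated spikes, monotone decays).
#'
#' @param n Number of pulses.
#' @param frac_noncalc Fraction of non-calculable pulses.
#' @param ratio_range Range of target P2/P1 ratios (uniform).
#' @param noise_sd White-noise standard deviation relative to unit pulse
#'   amplitude.
#' @param beat_len_range Range of beat lengths in samples at 100 Hz.
#' @param seed Integer seed.
#' @return A list with `pulses` (n x 180 matrix, rows in \[0, 1\]) and `labels`,
#'   a data frame `(p1, p2, true_ratio, calculable)`; `p1`, `p2` are 1-based
#'   indices in the 180 frame, 0 being the non-calculable sentinel.
#' @export
simulate_pulse_dataset <- function(n, frac_noncalc = 0.1,
                                   ratio_range = c(0.6, 1.4),
                                   noise_sd = 0.02,
                                   beat_len_range = c(75L, 110L),
                                   seed = 1L) {
  stopifnot(n >= 1, frac_noncalc >= 0, frac_noncalc <= 1)
  with_seed(seed, {
    pulses <- matrix(NA_real_, n, 180L)
    p1 <- integer(n); p2 <- integer(n)
    ratio <- rep(NA_real_, n); calc <- logical(n)
    for (i in seq_len(n)) {
      nb <- sample(beat_len_range[1]:beat_len_range[2], 1L)
      noncalc <- stats::runif(1) < frac_noncalc
      if (!noncalc) {
        tpl <- pulse_template(
          amplitudes = c(1, 0.8, stats::runif(1, 0.3, 0.6)),
          positions = pmin(pmax(c(0.22, 0.44, 0.67) +
                                  stats::rnorm(3, sd = 0.02), 0.08), 0.92),
          # P1/P2 are sharp pressure waves; the dicrotic P3 decays slowly
          widths = c(stats::runif(2, 0.04, 0.07), stats::runif(1, 0.08, 0.12)))
        if (any(diff(tpl$positions) < 0.12))  # keep subpeaks resolvable
          tpl$positions <- c(0.22, 0.44, 0.67)
        target <- stats::runif(1, ratio_range[1], ratio_range[2])
        a2 <- tryCatch(solve_a2(target, tpl), icpr_error = function(e) NA_real_)
        if (!is.na(a2)) {
          tpl$amplitudes[2] <- a2
          clean <- make_pulse(tpl, nb)
        } else clean <- list(calculable = FALSE)
        # a calculable pulse must carry clearly resolved subpeaks: two
        # Gaussians closer than about three standard deviations merge into a
        # crest whose apexes no longer mark the component waves, and such
        # beats would not be labeled as showing two distinct subpeaks
        # (they fall back to the canonical well-separated morphology)
        min_sep <- 2.8 * max(tpl$widths[1:2]) * nb
        if (!clean$calculable || (clean$p2 - clean$p1) < min_sep) {
          tpl <- pulse_template(widths = c(0.05, 0.05, 0.07))
          tpl$amplitudes[2] <- solve_a2(target, tpl)
          clean <- make_pulse(tpl, nb)
        }
        # labels live in the 180 frame: re-detect apexes on the noiseless
        # resampled pulse so truth matches what a perfect detector sees
        ref <- normalize_beat(clean$values)
        mapped <- 1L + round((c(clean$p1, clean$p2) - 1L) * 179 / (nb - 1L))
        lm <- local_maxima(ref$values)
        lab <- vapply(mapped, function(m) {
          if (length(lm) == 0) return(m)
          lm[which.min(abs(lm - m))]
        }, numeric(1))
        if (lab[1] >= lab[2]) lab <- mapped  # degenerate re-detection, keep map
        noisy <- clean$values + stats::rnorm(nb, sd = noise_sd)
        np <- tryCatch(normalize_beat(noisy), icpr_degenerate_pulse = function(e) NULL)
        if (is.null(np)) { pulses[i, ] <- ref$values } else pulses[i, ] <- np$values
        p1[i] <- as.integer(lab[1]); p2[i] <- as.integer(lab[2])
        ratio[i] <- ref$values[p2[i]] / ref$values[p1[i]]
        calc[i] <- TRUE
      } else {
        kind <- sample(c("missing_p1", "missing_p2", "spike", "noise", "decay"), 1L)
        v <- switch(kind,
          missing_p1 = {
            tpl <- pulse_template(amplitudes = c(0, 1, stats::runif(1, 0.3, 0.6)))
            make_pulse(tpl, nb)$values
          },
          missing_p2 = {
            tpl <- pulse_template(amplitudes = c(1, 0, stats::runif(1, 0.3, 0.6)))
            make_pulse(tpl, nb)$values
          },
          spike = exp(-((seq_len(nb) / nb) - stats::runif(1, 0.2, 0.8))^2 /
                        (2 * 0.02^2)),
          # band-limited: artifacts reach the classifier through the same
          # 0.3-20 Hz filter as everything else
          noise = moving_average(stats::rnorm(nb, sd = 0.5), 5L),
          decay = exp(-3 * seq_len(nb) / nb))
        v <- v + stats::rnorm(nb, sd = noise_sd)
        np <- tryCatch(normalize_beat(v), icpr_degenerate_pulse = function(e) NULL)
        if (is.null(np)) np <- normalize_beat(stats::rnorm(nb))
        pulses[i, ] <- np$values
        p1[i] <- 0L; p2[i] <- 0L; calc[i] <- FALSE
      }
    }
    list(pulses = pulses,
         labels = data.frame(p1 = p1, p2 = p2, true_ratio = ratio,
                             calculable = calc))
  })
}
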