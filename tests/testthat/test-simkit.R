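test_that("make_pulse places subpeak apexes near the configured positions", {
  # dense analytic evaluation of the Gaussian sum puts the three local maxima
  # near samples 40, 79, 121 for these well-separated centres
  tpl <- pulse_template(amplitudes = c(1.0, 0.8, 0.5),
                        positions = c(0.22, 0.44, 0.67),
                        widths = c(0.07, 0.07, 0.07))
  p <- make_pulse(tpl, 180)
  expect_equal(length(p$values), 180L)
  expect_false(any(is.na(p$apex)))
  expect_lte(abs(p$apex[1] - 40), 2)
  expect_lte(abs(p$apex[2] - 79), 2)
  expect_lte(abs(p$apex[3] - 121), 2)
  heights <- p$values[p$apex]
  expect_true(all(diff(heights) < 0))
  expect_true(p$calculable)
})

test_that("a single-Gaussian template has exactly one local maximum", {
  tpl <- pulse_template(amplitudes = c(1, 0, 0))
  p <- make_pulse(tpl, 180)
  ns <- asNamespace("icpratio")
  expect_length(ns$local_maxima(p$values), 1L)
  expect_false(p$calculable)
})

test_that("narrow separated subpeaks recover the amplitude quotient", {
  # in the non-overlapping limit the normalized apex ratio equals a2/a1
  tpl <- pulse_template(amplitudes = c(1.0, 0.6, 0),
                        positions = c(0.25, 0.65, 0.9),
                        widths = c(0.02, 0.02, 0.02))
  p <- make_pulse(tpl, 360)
  expect_equal(p$ratio, 0.6, tolerance = 1e-3)
})

test_that("invalid templates are rejected", {
  expect_error(pulse_template(positions = c(0.5, 0.4, 0.7)), class = "icpr_error")
  expect_error(pulse_template(widths = c(0.1, -0.1, 0.1)), class = "icpr_error")
  expect_error(pulse_template(amplitudes = c(0, 0, 0)), class = "icpr_error")
})

test_that("generate_record lays out beats per the configured heart rate", {
  g <- generate_record(clean_record_config())
  expect_identical(nrow(g$truth), 60L)
  expect_true(all(diff(g$truth$onset_sample) == 100L))
  expect_length(g$record$samples, 6000L)
  expect_true(all(g$truth$calculable))
  # calculable beats satisfy onset < p1 < p2 < next onset
  expect_true(all(g$truth$onset_sample < g$truth$p1_sample))
  expect_true(all(g$truth$p1_sample < g$truth$p2_sample))
  expect_true(all(utils::head(g$truth$p2_sample, -1) <
                    utils::tail(g$truth$onset_sample, -1)))
})

test_that("generate_record is bit-identical for a fixed seed", {
  cfg <- record_config(duration_s = 30, seed = 17, artifact_rate = 0.05,
                       missing_subpeak_rate = 0.1)
  g1 <- generate_record(cfg)
  g2 <- generate_record(cfg)
  expect_identical(g1$record$samples, g2$record$samples)
  expect_identical(g1$truth, g2$truth)
})

test_that("with no nuisance terms every beat equals the rendered template", {
  cfg <- clean_record_config(duration_s = 20)
  g <- generate_record(cfg)
  tr <- g$truth
  a2 <- NULL
  for (b in seq_len(nrow(tr))) {
    beat <- g$record$samples[tr$onset_sample[b]:(tr$onset_sample[b] + tr$duration_samples[b] - 1L)]
    # constant trajectory: beats are identical renderings (up to baseline)
    if (b == 1L) a2 <- beat else expect_equal(beat, a2, tolerance = 1e-12)
  }
  # and the stored ratio is exactly the normalized apex quotient
  beat <- g$record$samples[tr$onset_sample[1]:(tr$onset_sample[1] + tr$duration_samples[1] - 1L)]
  vn <- (beat - min(beat)) / (max(beat) - min(beat))
  i1 <- tr$p1_sample[1] - tr$onset_sample[1] + 1L
  i2 <- tr$p2_sample[1] - tr$onset_sample[1] + 1L
  # equality up to the float round-trip of adding/removing the ICP baseline
  expect_equal(vn[i2] / vn[i1], tr$true_ratio[1], tolerance = 1e-12)
})

test_that("onset count tracks duration over seeds and heart rates", {
  for (seed in 1:5) {
    hr <- c(50, 70, 90, 110, 60)[seed]
    cfg <- record_config(duration_s = 30, heart_rate_bpm = hr,
                         hr_jitter = 0.05, seed = seed)
    g <- generate_record(cfg)
    expect_true(all(diff(g$truth$onset_sample) > 0))
    expected <- floor(30 / (60 / hr))
    expect_lte(abs(nrow(g$truth) - expected), 2)
  }
})

test_that("degrade with zero rates returns the input unchanged", {
  g <- generate_record(clean_record_config(duration_s = 20))
  d <- degrade(g$record, g$truth, 0, 0, seed = 1)
  expect_identical(d$record, g$record)
  expect_identical(d$truth, g$truth)
})

test_that("degrade flags the expected share of beats as non-calculable", {
  cfg <- record_config(duration_s = 1000, heart_rate_bpm = 60, hr_jitter = 0,
                       resp_amp = 0, drift_amp = 0, noise_sd = 0, seed = 8)
  g <- generate_record(cfg)
  expect_identical(nrow(g$truth), 1000L)
  d <- degrade(g$record, g$truth, 0, 0.1, seed = 9)
  flagged <- sum(!d$truth$calculable)
  # central 99% binomial interval for n = 1000, p = 0.1
  expect_gte(flagged, qbinom(0.005, 1000, 0.1))
  expect_lte(flagged, qbinom(0.995, 1000, 0.1))
  expect_true(all(d$truth$p1_norm_idx[!d$truth$calculable] == 0L))
  expect_true(all(is.na(d$truth$true_ratio[!d$truth$calculable])))
})

test_that("an artifact-replaced beat is non-calculable with sentinel labels", {
  g <- generate_record(clean_record_config(duration_s = 20))
  d <- degrade(g$record, g$truth, 1, 0, seed = 2)  # every beat an artifact
  expect_true(all(!d$truth$calculable))
  expect_true(all(d$truth$p1_norm_idx == 0L & d$truth$p2_norm_idx == 0L))
  expect_false(identical(d$record$samples, g$record$samples))
})

test_that("calculable fraction converges to one minus the missing rate", {
  ds <- simulate_pulse_dataset(600, frac_noncalc = 0.1, seed = 41)
  expect_gte(mean(ds$labels$calculable), 0.85)
  expect_lte(mean(ds$labels$calculable), 0.95)
  ds0 <- simulate_pulse_dataset(50, frac_noncalc = 0, seed = 42)
  expect_true(all(ds0$labels$calculable))
  # calculable labels are ordered and in range; ratios match pulse amplitudes
  with(ds0$labels, {
    expect_true(all(p1 > 1 & p1 < p2 & p2 <= 180))
  })
  i <- which(ds0$labels$calculable)[1]
  expect_equal(ds0$labels$true_ratio[i],
               ds0$pulses[i, ds0$labels$p2[i]] / ds0$pulses[i, ds0$labels$p1[i]],
               tolerance = 0.05)
})

test_that("record and truth files round-trip", {
  g <- generate_record(clean_record_config(duration_s = 20))
  rp <- tempfile(fileext = ".csv"); tp <- tempfile(fileext = ".csv")
  write_icp_record(g$record, rp)
  r2 <- read_icp_record(rp)
  expect_equal(r2$samples, g$record$samples, tolerance = 1e-9)
  expect_identical(r2$fs, 100)
  write_truth(g$truth, tp)
  t2 <- read_truth(tp)
  expect_identical(t2$onset_sample, as.integer(g$truth$onset_sample))
  expect_identical(t2$p1_norm_idx, g$truth$p1_norm_idx)
  expect_identical(t2$calculable, g$truth$calculable)
  expect_equal(t2$true_ratio, g$truth$true_ratio, tolerance = 1e-9)
  unlink(c(rp, tp))
})
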