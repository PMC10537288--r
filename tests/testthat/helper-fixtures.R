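# Shared fixtures, built in code.

# a clean record with no nuisance components, for exact checks
clean_record_config <- function(duration_s = 60, hr = 60, seed = 3) {
  record_config(duration_s = duration_s, heart_rate_bpm = hr, hr_jitter = 0,
                resp_amp = 0, drift_amp = 0, noise_sd = 0, seed = seed)
}

# two-Gaussian pulse on the 180 frame with apexes at a1, a2
two_gauss_pulse <- function(a1 = 40, a2 = 95, w = 12, amp2 = 0.8) {
  t <- seq_len(180)
  exp(-(t - a1)^2 / (2 * w^2)) + amp2 * exp(-(t - a2)^2 / (2 * w^2))
}

# tiny architectures so NN unit tests stay fast
tiny_selector_cfg <- function(kind) {
  selector_config(kind, channels = c(4L, 6L, 8L), lstm_hidden = 6L,
                  dense_width = 8L)
}
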