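# Shared fixtures: tiny deterministic signals and sessions built in code.

# unmodulated profile: exactly periodic beats
flat_profile <- function(mean_hr = 60) {
  autonomic_profile(mean_hr = mean_hr, lf_amp = rep(0, 3),
                    hf_amp = rep(0, 3), noise_sd = 0)
}

# pure-tone rgb trace at the camera frame rate
tone_trace <- function(freq, duration_s = 60, fs = 30, amp = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  out <- data.frame(t_s = t, r_mean = 100, g_mean = 120 - amp * sin(2 * pi * freq * t),
                    b_mean = 100)
  attr(out, "fps") <- fs
  class(out) <- c("rgb_trace", "data.frame")
  out
}

# rms amplitude of the central half of a signal (edge transients trimmed)
central_amp <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2 * mean(mid^2))
}

# ibi_series from an explicit vector of intervals (ms), beats 1 s apart base
ibi_from_ms <- function(ms, start_s = 0) {
  bt <- start_s + cumsum(ms) / 1000
  out <- data.frame(beat_time_s = bt, ibi_ms = ms, accepted = TRUE)
  class(out) <- c("ibi_series", "data.frame")
  out
}

# synthetic ibi series sampled from a sinusoidal modulation of beat times:
# exact IPFM beats for a single-tone profile
tone_ibi <- function(freq = 0.25, amp_ms = 50, duration_s = 140,
                     mean_ibi_ms = 1000) {
  # beats at regular times; interval modulation imposed directly
  n <- floor(duration_s * 1000 / mean_ibi_ms)
  bt <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t <- t + (mean_ibi_ms + amp_ms * sin(2 * pi * freq * t)) / 1000
    bt[i] <- t
  }
  compute_ibi(c(0, bt))
}
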