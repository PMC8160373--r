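test_that("unmodulated IPFM emits exactly periodic beats", {
  b <- generate_beats(flat_profile(60), protocol_config(), seed = 1)
  expect_length(b, 360)
  expect_equal(diff(b), rep(1, 359), tolerance = 1e-9)
  # constant IBI identity: 60000 / mean_hr ms
  b75 <- generate_beats(flat_profile(75), protocol_config(), seed = 1)
  expect_equal(unique(round(diff(b75) * 1000, 6)), 60000 / 75)
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(autonomic_profile(mean_hr = 30))
  expect_error(autonomic_profile(lf_freq = 0.2))
  expect_error(autonomic_profile(hf_amp = c(-0.1, 0, 0)))
  # modulation exceeding unity must be rejected at generation
  big <- autonomic_profile(lf_amp = rep(0.4, 3), hf_amp = rep(0.4, 3),
                           noise_sd = 0.35)
  expect_error(generate_beats(big, seed = 7), "modulation")
})

test_that("beat generation is reproducible and periods modulate HF", {
  p <- healthy_profile()
  b1 <- generate_beats(p, seed = 42)
  b2 <- generate_beats(p, seed = 42)
  expect_identical(b1, b2)
  expect_false(isTRUE(all.equal(b1, generate_beats(p, seed = 43))))
  # healthy default: HF band power of the IBI series lower in MT than Pre-R
  ibi <- compute_ibi(b1)
  segs <- segment_periods(ibi)
  hf <- vapply(segs, function(s) band_power(compute_psd(s), c(0.15, 0.4)),
               numeric(1))
  expect_lt(hf[["mt"]], hf[["pre_r"]])
})

test_that("Welch HF power matches the direct-DFT oracle on exact beats", {
  # single-tone HF modulation, no LF, no noise
  p <- autonomic_profile(mean_hr = 60, lf_amp = rep(0, 3),
                         hf_amp = rep(0.05, 3), noise_sd = 0)
  b <- generate_beats(p, seed = 1)
  ibi <- compute_ibi(b)
  seg <- ibi[ibi$beat_time_s < 140, ]
  class(seg) <- c("ibi_series", "data.frame")
  welch_hf <- band_power(compute_psd(seg), c(0.15, 0.4))
  # oracle: direct DFT of the exact IBI sequence at its mean rate.
  # Power of the sinusoidal component = 2 * |DFT coefficient|^2 / n^2
  x <- seg$ibi_ms - mean(seg$ibi_ms)
  n <- length(x)
  fs_beat <- 1 / mean(seg$ibi_ms) * 1000      # beats per second
  freqs <- (0:(n - 1)) * fs_beat / n
  dft <- abs(fft(x))^2 / n^2
  hf_bins <- freqs >= 0.15 & freqs < 0.4
  oracle <- 2 * sum(dft[hf_bins])
  expect_equal(welch_hf, oracle, tolerance = 0.10)
})

test_that("doubling HF amplitude quadruples HF band power", {
  mk <- function(a) {
    p <- autonomic_profile(mean_hr = 60, lf_amp = rep(0, 3),
                           hf_amp = rep(a, 3), noise_sd = 0)
    ibi <- compute_ibi(generate_beats(p, seed = 1))
    seg <- segment_periods(ibi)$pre_r
    band_power(compute_psd(seg), c(0.15, 0.4))
  }
  expect_equal(mk(0.08) / mk(0.04), 4, tolerance = 0.15)
})

test_that("synthetic ECG places R peaks at beat times", {
  ecg <- synthesize_ecg(c(1, 2, 3), fs = 100, duration_s = 5)
  expect_equal(length(ecg$samples), 500)
  for (b in c(1, 2, 3)) {
    win <- (b * 100 - 5):(b * 100 + 5) + 1
    expect_lte(abs(which.max(ecg$samples[win]) - 6), 5)
    expect_equal(which.max(ecg$samples) >= 1, TRUE)
  }
  # global argmax of each separated QRS is at the R sample
  i_max <- order(ecg$samples, decreasing = TRUE)[1]
  expect_true(i_max %in% c(101, 201, 301))
  expect_error(synthesize_ecg(c(1, 2), fs = -1), "fs")
  empty <- synthesize_ecg(numeric(0), fs = 100, duration_s = 360)
  expect_equal(sum(abs(empty$samples)), 0)
  expect_length(empty$samples, 36000)
})

test_that("R-peak detector round-trips IPFM beats through synthetic ECG", {
  b <- generate_beats(flat_profile(60), seed = 1)
  ecg <- synthesize_ecg(b, fs = 100, duration_s = 360)
  det <- detect_r_peaks(ecg)
  expect_lte(abs(length(det) - 360), 1)
  pr <- pair_beats(det, b, max_lag_ms = 50)
  expect_gt(attr(pr, "match_rate"), 0.99)
})

test_that("rgb trace carries the pulse at the configured transit time", {
  b <- generate_beats(flat_profile(60), seed = 1)
  tr <- synthesize_rgb_trace(b, ptt_ms = 120, noise_sd = 0, drift_amp = 0,
                             seed = 1)
  # cross-correlate negated green pulse with an impulse train at the beats
  fs <- attr(tr, "fps")
  g <- -(tr$g_mean - mean(tr$g_mean))
  train <- numeric(nrow(tr))
  train[pmin(round(b * fs) + 1, length(train))] <- 1
  lags <- -15:15
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(g[(1 + L):length(g)] * train[1:(length(g) - L)])
    else sum(g[1:(length(g) + L)] * train[(1 - L):length(g)])
  }, numeric(1))
  best_lag_ms <- lags[which.max(cc)] / fs * 1000
  expect_lte(abs(best_lag_ms - 120), 1000 / fs + 1e-9)
})

test_that("zero pulse amplitude leaves no cardiac-band power above noise", {
  b <- generate_beats(flat_profile(60), seed = 1)
  tr0 <- synthesize_rgb_trace(b, pulse_amp = 0, noise_sd = 0.2, drift_amp = 2,
                              seed = 1)
  tr1 <- synthesize_rgb_trace(b, pulse_amp = 2, noise_sd = 0.2, drift_amp = 2,
                              seed = 1)
  p0 <- mean(extract_bvp(tr0)$samples^2)
  p1 <- mean(extract_bvp(tr1)$samples^2)
  expect_lt(p0, p1 / 50)
})

test_that("cohort generation respects counts, cutoff and determinism", {
  ch <- generate_cohort(n_mdd = 26, n_healthy = 27, seed = 3)
  expect_length(ch, 53)
  groups <- vapply(ch, function(s) s$group, character(1))
  sds <- vapply(ch, function(s) s$sds_score, numeric(1))
  expect_equal(sum(groups == "mdd"), 26)
  expect_equal(sum(groups == "healthy"), 27)
  expect_true(all(sds[groups == "mdd"] >= 48))
  expect_true(all(sds[groups == "healthy"] < 48))
  # all-healthy cohort: truncation keeps every score under the cutoff
  ch0 <- generate_cohort(n_mdd = 0, n_healthy = 10, seed = 3)
  expect_true(all(vapply(ch0, function(s) s$sds_score, numeric(1)) < 48))
  # deterministic per seed
  ch2 <- generate_cohort(n_mdd = 26, n_healthy = 27, seed = 3)
  expect_identical(vapply(ch2, function(s) s$seed, numeric(1)),
                   vapply(ch, function(s) s$seed, numeric(1)))
  expect_identical(vapply(ch2, function(s) s$profile$mean_hr, numeric(1)),
                   vapply(ch, function(s) s$profile$mean_hr, numeric(1)))
})

test_that("healthy SDS mean sits near the demographic anchor", {
  ch <- generate_cohort(n_mdd = 0, n_healthy = 200, seed = 11)
  m <- mean(vapply(ch, function(s) s$sds_score, numeric(1)))
  expect_gte(m, 31)
  expect_lte(m, 35)
})

test_that("session writer emits the documented plain-text artefacts", {
  dir <- withr::local_tempdir()
  sess <- simulate_session(flat_profile(60), seed = 1)
  paths <- write_session(sess, dir)
  expect_true(all(file.exists(paths)))
  beats <- read.csv(paths[["beats"]])
  expect_equal(beats$beat_time_s, sess$beat_times)
  tr <- read_trace(paths[["trace"]])
  expect_equal(attr(tr, "fps"), 30, tolerance = 1e-6)
  expect_equal(tr$g_mean, sess$rgb_trace$g_mean)
})
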