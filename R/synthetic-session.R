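#' Autonomic modulation profile for the session simulator
#'
#' Describes the instantaneous-heart-rate modulation of a simulated subject:
#' a mean rate plus one low-frequency (LF, ~0.1 Hz) and one high-frequency
#' (HF, ~0.25 Hz) sinusoidal modulation whose amplitudes may differ across
#' the three protocol periods, plus band-limited Gaussian rate noise. The
#' period-specific HF amplitude is the handle that encodes the group
#' phenotype: healthy subjects suppress HF (vagal withdrawal) during the
#' mental task, depressed subjects show a flat HF response.
#'
#' @param mean_hr Mean heart rate, beats/min, in `[40, 180]`.
#' @param lf_freq LF modulation frequency, Hz, in `[0.04, 0.15)`.
#' @param hf_freq HF modulation frequency, Hz, in `[0.15, 0.4)`.
#' @param lf_amp Length-3 non-negative amplitudes (Pre-R, MT, Post-R),
#'   dimensionless fractions of the mean rate.
#' @param hf_amp Same for the HF modulation.
#' @param noise_sd Standard deviation of the band-limited rate noise,
#'   dimensionless.
#' @return An object of class `autonomic_profile`.
#' @seealso [healthy_profile()], [mdd_profile()], [generate_beats()]
#' @export
autonomic_profile <- function(mean_hr = 70, lf_freq = 0.10, hf_freq = 0.25,
                              lf_amp = c(0.05, 0.07, 0.05),
                              hf_amp = c(0.08, 0.02, 0.08),
                              noise_sd = 0.01) {
  stopifnot(mean_hr >= 40, mean_hr <= 180,
            lf_freq >= 0.04, lf_freq < 0.15,
            hf_freq >= 0.15, hf_freq < 0.4,
            length(lf_amp) == 3, length(hf_amp) == 3,
            all(lf_amp >= 0), all(hf_amp >= 0), noise_sd >= 0)
  structure(list(mean_hr = mean_hr, lf_freq = lf_freq, hf_freq = hf_freq,
                 lf_amp = lf_amp, hf_amp = hf_amp, noise_sd = noise_sd),
            class = "autonomic_profile")
}

#' Default healthy-subject profile: HF modulation suppressed during the
#' mental task (0.08, 0.02, 0.08), reflecting task-evoked vagal withdrawal.
#' @inheritParams autonomic_profile
#' @return An `autonomic_profile`.
#' @export
healthy_profile <- function(mean_hr = 70, noise_sd = 0.01) {
  autonomic_profile(mean_hr = mean_hr, hf_amp = c(0.08, 0.02, 0.08),
                    lf_amp = c(0.05, 0.07, 0.05), noise_sd = noise_sd)
}

#' Default depressed-subject profile: flat HF modulation (0.05, 0.05, 0.05)
#' across periods, i.e. no task-evoked parasympathetic response.
#' @inheritParams autonomic_profile
#' @return An `autonomic_profile`.
#' @export
mdd_profile <- function(mean_hr = 70, noise_sd = 0.01) {
  autonomic_profile(mean_hr = mean_hr, hf_amp = c(0.05, 0.05, 0.05),
                    lf_amp = c(0.05, 0.07, 0.05), noise_sd = noise_sd)
}

# Band-limited Gaussian noise: white noise smoothed with a 1 s moving
# average (low-pass ~0.44 Hz), rescaled to unit sd. Mimics broadband
# physiological HRV rather than sampling-grid white noise.
.rate_noise <- function(n, dt, sd) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  k <- max(1L, round(1 / dt))
  sm <- stats::filter(w, rep(1 / k, k), sides = 2, circular = TRUE)
  as.numeric(sm) / stats::sd(sm) * sd
}

#' Generate beat times by integral pulse frequency modulation (IPFM)
#'
#' Integrates the instantaneous rate
#' `r(t) = (mean_hr / 60) * (1 + m(t))` where
#' `m(t) = a_LF(period) sin(2 pi f_LF t) + a_HF(period) sin(2 pi f_HF t) + noise`,
#' and emits a beat each time the integral crosses an integer. With zero
#' modulation this yields exactly equidistant beats at 60/mean_hr seconds.
#'
#' @param profile An [autonomic_profile()].
#' @param protocol A [protocol_config()]; period boundaries select the
#'   period-specific modulation amplitudes.
#' @param seed Integer seed; the generator is bitwise-reproducible.
#' @param dt Integration step, seconds (default 0.01).
#' @return Numeric vector of strictly increasing beat times in seconds from
#'   session start.
#' @export
#' @examples
#' b <- generate_beats(autonomic_profile(mean_hr = 60, lf_amp = rep(0, 3),
#'                                       hf_amp = rep(0, 3), noise_sd = 0),
#'                     protocol_config(), seed = 1)
#' head(diff(b)) # exactly 1 s
generate_beats <- function(profile, protocol = protocol_config(), seed = 0,
                           dt = 0.01) {
  stopifnot(inherits(profile, "autonomic_profile"),
            inherits(protocol, "protocol_config"))
  set.seed(seed)
  tg <- seq(0, protocol$total_s, by = dt)
  period <- pmin(findInterval(tg, protocol$boundaries[2:3]) + 1L, 3L)
  m <- profile$lf_amp[period] * sin(2 * pi * profile$lf_freq * tg) +
       profile$hf_amp[period] * sin(2 * pi * profile$hf_freq * tg) +
       .rate_noise(length(tg), dt, profile$noise_sd)
  if (max(abs(m)) >= 1)
    stop("total rate modulation |m| >= 1: instantaneous rate would be non-positive")
  r <- (profile$mean_hr / 60) * (1 + m)
  # trapezoidal cumulative integral of r(t)
  ci <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
  n_beats <- floor(ci[length(ci)])
  if (n_beats < 1) return(numeric(0))
  stats::approx(ci, tg, xout = seq_len(n_beats), ties = "ordered")$y
}

#' Synthesize a reference single-lead ECG from beat times
#'
#' Places a narrow positive Gaussian QRS-like template (sd 10 ms, ~20 ms
#' wide) at each beat time on a flat baseline. Only the R-peak times matter
#' downstream, so no P/T morphology is modelled.
#'
#' @param beat_times Increasing beat times, seconds.
#' @param fs Sampling rate, Hz (default 100).
#' @param duration_s Signal duration, seconds (default 360).
#' @return An object of class `ecg_signal`: list with `samples`, `fs`, `t`.
#' @export
synthesize_ecg <- function(beat_times, fs = 100, duration_s = 360) {
  if (fs <= 0) stop("fs must be positive")
  stopifnot(!is.unsorted(beat_times, strictly = TRUE) || length(beat_times) <= 1)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  qrs_sd <- 0.010
  half <- ceiling(5 * qrs_sd * fs)
  for (b in beat_times) {
    i0 <- round(b * fs) + 1L
    idx <- max(1L, i0 - half):min(n, i0 + half)
    x[idx] <- x[idx] + exp(-(t[idx] - b)^2 / (2 * qrs_sd^2))
  }
  structure(list(samples = x, fs = fs, t = t), class = "ecg_signal")
}

#' Synthesize a facial mean-RGB trace with a pulsatile green channel
#'
#' The green channel carries a negative-going systolic waveform (blood
#' absorbs green light) delayed by the pulse transit time after each beat,
#' on top of a baseline, slow sinusoidal drift and white sensor noise. Red
#' and blue carry baseline plus noise only.
#'
#' @param beat_times Increasing beat times, seconds.
#' @param fs Frame rate, Hz (default 30).
#' @param duration_s Trace duration, seconds (default 360).
#' @param ptt_ms Pulse transit time from R-wave to facial pulse peak, ms
#'   (default 120).
#' @param pulse_amp Pulse amplitude, tone units (default 2).
#' @param noise_sd White-noise sd per channel, tone units (default 0.2).
#' @param drift_amp,drift_freq Slow drift amplitude (tones) and frequency
#'   (Hz) on the green channel, emulating illumination/motion drift.
#' @param baseline Length-3 RGB baseline tones.
#' @param seed Integer seed for the noise.
#' @return An `rgb_trace`: data.frame with columns `t_s`, `r_mean`,
#'   `g_mean`, `b_mean` and attribute `fps`.
#' @export
synthesize_rgb_trace <- function(beat_times, fs = 30, duration_s = 360,
                                 ptt_ms = 120, pulse_amp = 2, noise_sd = 0.2,
                                 drift_amp = 2, drift_freq = 0.05,
                                 baseline = c(110, 120, 105), seed = 0) {
  stopifnot(fs > 0, pulse_amp >= 0, noise_sd >= 0)
  set.seed(seed + 1L)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  pulse <- numeric(n)
  w_sd <- 0.07                       # systolic upstroke width, seconds
  half <- ceiling(5 * w_sd * fs)
  for (b in beat_times + ptt_ms / 1000) {
    i0 <- round(b * fs) + 1L
    idx <- max(1L, i0 - half):min(n, i0 + half)
    if (i0 > n + half || i0 < 1 - half) next
    pulse[idx] <- pulse[idx] + exp(-(t[idx] - b)^2 / (2 * w_sd^2))
  }
  drift <- drift_amp * sin(2 * pi * drift_freq * t + pi / 5)
  g <- baseline[2] - pulse_amp * pulse + drift + stats::rnorm(n, sd = noise_sd)
  r <- baseline[1] + stats::rnorm(n, sd = noise_sd)
  b_ <- baseline[3] + stats::rnorm(n, sd = noise_sd)
  out <- data.frame(t_s = t, r_mean = r, g_mean = g, b_mean = b_)
  attr(out, "fps") <- fs
  class(out) <- c("rgb_trace", "data.frame")
  out
}

#' Simulate one full screening session
#'
#' Convenience wrapper: IPFM beats, reference ECG and pulsatile RGB trace
#' for one subject, with ground truth retained for validation.
#'
#' @param profile An [autonomic_profile()] (or a `synthetic_subject`, whose
#'   profile and seed are then used).
#' @param protocol A [protocol_config()].
#' @param seed Integer seed.
#' @param ptt_ms Pulse transit time, ms.
#' @param ... Passed to [synthesize_rgb_trace()].
#' @return A `synthetic_session`: list with `beat_times`, `ecg`,
#'   `rgb_trace`, `ptt_ms`, `subject` (may be NULL), `protocol`.
#' @export
simulate_session <- function(profile, protocol = protocol_config(), seed = 0,
                             ptt_ms = 120, ...) {
  subject <- NULL
  if (inherits(profile, "synthetic_subject")) {
    subject <- profile
    seed <- profile$seed
    profile <- profile$profile
  }
  beats <- generate_beats(profile, protocol, seed = seed)
  ecg <- synthesize_ecg(beats, fs = 100, duration_s = protocol$total_s)
  trace <- synthesize_rgb_trace(beats, duration_s = protocol$total_s,
                                ptt_ms = ptt_ms, seed = seed, ...)
  structure(list(beat_times = beats, ecg = ecg, rgb_trace = trace,
                 ptt_ms = ptt_ms, subject = subject, protocol = protocol),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("Synthetic screening session:", length(x$beat_times), "beats over",
      x$protocol$total_s, "s;",
      if (!is.null(x$subject)) paste0("group ", x$subject$group) else "no subject",
      "\n")
  invisible(x)
}

# Truncated-normal sampler by rejection (narrow truncations only).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    x <- x[x >= lower & x <= upper]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Generate a synthetic screening cohort
#'
#' Draws subjects with group-linked Zung SDS scores and autonomic profiles.
#' Healthy SDS ~ normal(33, 5) truncated below the cut-off (48); depressed
#' SDS ~ normal(53, 5) truncated at or above it, anchoring the group means
#' near the clinical demographics (healthy ~32-34, MDD ~53). Profiles start
#' from [healthy_profile()] / [mdd_profile()] and receive per-subject
#' lognormal jitter on every modulation amplitude (sdlog 0.45) plus a
#' normal(70, 7) mean heart rate clamped to [50, 100], so cohorts overlap
#' realistically instead of being linearly separable.
#'
#' @param n_mdd,n_healthy Subject counts (>= 0).
#' @param seed Integer seed; subject seeds are derived deterministically.
#' @param sds_cutoff SDS screening cut-off (default 48).
#' @return A `synthetic_cohort`: list of `synthetic_subject` objects, each
#'   with `id`, `group` ("healthy"/"mdd"), `sds_score`, `profile`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(n_mdd = 3, n_healthy = 3, seed = 1)
#' sapply(cohort, function(s) s$sds_score)
generate_cohort <- function(n_mdd, n_healthy, seed = 0, sds_cutoff = 48) {
  stopifnot(n_mdd >= 0, n_healthy >= 0)
  set.seed(seed)
  groups <- c(rep("mdd", n_mdd), rep("healthy", n_healthy))
  n <- length(groups)
  sds <- numeric(n)
  if (n_mdd > 0)
    sds[groups == "mdd"] <- round(.rtruncnorm(n_mdd, 53, 5, lower = sds_cutoff,
                                              upper = 80))
  if (n_healthy > 0)
    sds[groups == "healthy"] <- round(.rtruncnorm(n_healthy, 33, 5, lower = 20,
                                                  upper = sds_cutoff - 1))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (groups[i] == "mdd") mdd_profile() else healthy_profile()
    jit <- function(a) pmin(a * exp(stats::rnorm(length(a), 0, 0.45)), 0.4)
    prof <- autonomic_profile(
      mean_hr = min(max(stats::rnorm(1, 70, 7), 50), 100),
      lf_amp = jit(base$lf_amp), hf_amp = jit(base$hf_amp),
      noise_sd = base$noise_sd)
    cohort[[i]] <- structure(
      list(id = sprintf("S%03d", i), group = groups[i], sds_score = sds[i],
           profile = prof,
           seed = (seed * 10007L + i) %% 2147483647L),
      class = "synthetic_subject")
  }
  structure(cohort, class = c("synthetic_cohort", "list"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  g <- vapply(x, function(s) s$group, character(1))
  cat("Synthetic cohort:", sum(g == "mdd"), "MDD /", sum(g == "healthy"),
      "healthy subjects\n")
  invisible(x)
}

#' Write session artefacts as plain-text files
#'
#' Writes beats CSV (`beat_time_s`), ECG CSV (`t_s`, `amplitude`), RGB trace
#' CSV (`t_s`, `r_mean`, `g_mean`, `b_mean`) and a small JSON manifest.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beats = file.path(dir, "beats.csv"),
             ecg = file.path(dir, "ecg.csv"),
             trace = file.path(dir, "rgb_trace.csv"),
             manifest = file.path(dir, "session.json"))
  utils::write.csv(data.frame(beat_time_s = session$beat_times),
                   paths["beats"], row.names = FALSE)
  utils::write.csv(data.frame(t_s = session$ecg$t,
                              amplitude = session$ecg$samples),
                   paths["ecg"], row.names = FALSE)
  utils::write.csv(as.data.frame(session$rgb_trace), paths["trace"],
                   row.names = FALSE)
  meta <- list(ptt_ms = session$ptt_ms,
               n_beats = length(session$beat_times),
               protocol = session$protocol[c("pre_r_s", "mt_s", "post_r_s")])
  if (!is.null(session$subject))
    meta$subject <- session$subject[c("id", "group", "sds_score", "seed")]
  jsonlite::write_json(meta, paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an RGB trace CSV written by [write_session()] or [write_trace()]
#' @param path CSV with columns `t_s`, `r_mean`, `g_mean`, `b_mean`.
#' @return An `rgb_trace` data.frame with `fps` attribute inferred from `t_s`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_s", "r_mean", "g_mean", "b_mean") %in% names(df)))
  attr(df, "fps") <- 1 / stats::median(diff(df$t_s))
  class(df) <- c("rgb_trace", "data.frame")
  df
}
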