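# Spectral heart-rate-variability analysis per protocol period and the
# 15-candidate explanatory feature vector.

#' Split an interbeat-interval series into the three protocol periods
#'
#' Each interval is assigned to the period containing its ending beat time;
#' period boundaries are half-open `[start, end)`, and an interval ending
#' exactly at the session end is kept in the last period. Only accepted
#' intervals count toward the per-period minimum.
#'
#' @param ibi An `ibi_series`.
#' @param protocol A [protocol_config()].
#' @param min_intervals Minimum accepted intervals per period (default 20).
#' @return Named list (`pre_r`, `mt`, `post_r`) of `ibi_series`.
#' @export
segment_periods <- function(ibi, protocol = protocol_config(),
                            min_intervals = 20) {
  stopifnot(inherits(ibi, "ibi_series"))
  b <- protocol$boundaries
  t <- ibi$beat_time_s
  period <- findInterval(t, b[2:3]) + 1L
  period[t >= b[4]] <- ifelse(t[t >= b[4]] <= b[4], 3L, NA_integer_)
  out <- lapply(1:3, function(p) {
    seg <- ibi[!is.na(period) & period == p, , drop = FALSE]
    class(seg) <- c("ibi_series", "data.frame")
    seg
  })
  names(out) <- protocol$period_names
  n_acc <- vapply(out, function(s) sum(s$accepted), integer(1))
  if (any(n_acc < min_intervals))
    stop("insufficient-data error: period(s) ",
         paste(names(out)[n_acc < min_intervals], collapse = ", "),
         " have fewer than ", min_intervals, " accepted intervals")
  out
}

# Welch periodogram: Hann window, 50% overlap, density scaling.
# Returns data.frame(freq, density) one-sided; integral ~ variance.
.welch_psd <- function(x, fs, seg_len) {
  n <- length(x)
  L <- min(n, seg_len)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))     # periodic Hann
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  half <- floor(L / 2) + 1L
  dens <- psd[seq_len(half)]
  dens[2:(half - 1)] <- 2 * dens[2:(half - 1)]        # one-sided
  data.frame(freq = (seq_len(half) - 1) * fs / L, density = dens)
}

#' Power spectral density of an interbeat-interval segment
#'
#' Accepted `(beat_time, ibi)` samples are cubic-spline interpolated to a
#' uniform 4 Hz grid over the segment, mean-removed, and analysed with a
#' Welch estimator (Hann window, segment length `min(n, 240)` samples =
#' up to 60 s, 50% overlap). Density is in ms^2/Hz, so band integrals are
#' interval variance in ms^2.
#'
#' @param segment An `ibi_series` (one protocol period).
#' @param fs_resample Resampling rate, Hz (default 4).
#' @param seg_len Welch segment length in resampled samples (default 240).
#' @param min_intervals Minimum accepted intervals (default 20).
#' @return An `hrv_spectrum`: data.frame with `freq` (Hz) and `density`
#'   (ms^2/Hz).
#' @export
compute_psd <- function(segment, fs_resample = 4, seg_len = 240,
                        min_intervals = 20) {
  stopifnot(inherits(segment, "ibi_series"))
  seg <- segment[segment$accepted, ]
  if (nrow(seg) < min_intervals)
    stop("insufficient-data error: fewer than ", min_intervals,
         " accepted intervals")
  tt <- seg$beat_time_s
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs_resample)
  xi <- stats::spline(tt, seg$ibi_ms, xout = grid, method = "fmm")$y
  out <- .welch_psd(xi - mean(xi), fs_resample, seg_len)
  class(out) <- c("hrv_spectrum", "data.frame")
  out
}

#' Band power by trapezoidal integration
#'
#' Integrates the spectral density over `[lo, hi)`; the density is linearly
#' interpolated at the exact band edges so adjacent bands tile the spectrum
#' additively.
#'
#' @param spectrum An `hrv_spectrum` (or any data.frame with `freq`,
#'   `density`).
#' @param band Two-element numeric band edges, Hz.
#' @return Band power, ms^2.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  f <- spectrum$freq; d <- spectrum$density
  if (band[1] < f[1] - 1e-9 || band[2] > f[length(f)] + 1e-9)
    stop("band outside the resolvable spectrum range")
  lo <- max(band[1], f[1]); hi <- min(band[2], f[length(f)])
  inside <- f > lo & f < hi
  fi <- c(lo, f[inside], hi)
  di <- c(stats::approx(f, d, lo)$y, d[inside], stats::approx(f, d, hi)$y)
  sum(diff(fi) * (di[-1] + di[-length(di)]) / 2)
}

#' Per-period LF/HF spectral summary
#'
#' @param segments Named list from [segment_periods()].
#' @param bands A [band_config()].
#' @param ... Passed to [compute_psd()].
#' @return A `period_hrv` data.frame: one row per period with `period`,
#'   `lf_power`, `hf_power` (ms^2) and `lf_hf_ratio`.
#' @export
compute_hrv_periods <- function(segments, bands = band_config(), ...) {
  rows <- lapply(names(segments), function(nm) {
    sp <- compute_psd(segments[[nm]], ...)
    lf <- band_power(sp, bands$lf)
    hf <- band_power(sp, bands$hf)
    data.frame(period = nm, lf_power = lf, hf_power = hf,
               lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("period_hrv", "data.frame")
  out
}

#' The 15 candidate explanatory features
#'
#' Assembles the screening feature vector: LF, HF and LF/HF for each of the
#' three periods (9 values, ms^2 for powers), plus the six percent changes
#' `100 * (X_B - X_A) / X_A` for LF, HF and LF/HF over Pre-R => MT and
#' MT => Post-R. Order is fixed: the nine period values (LF, HF, LF/HF
#' grouped by metric, Pre-R/MT/Post-R within), then the Pre-R => MT deltas,
#' then the MT => Post-R deltas.
#'
#' @param period_hrv A `period_hrv` data.frame from [compute_hrv_periods()]
#'   with rows pre_r, mt, post_r.
#' @return A named numeric `feature_vector` of length 15.
#' @export
compute_features <- function(period_hrv) {
  stopifnot(inherits(period_hrv, "period_hrv"),
            identical(period_hrv$period, c("pre_r", "mt", "post_r")))
  g <- function(metric) stats::setNames(period_hrv[[metric]],
                                        period_hrv$period)
  lf <- g("lf_power"); hf <- g("hf_power"); ratio <- g("lf_hf_ratio")
  pct <- function(a, b, what) {
    if (a == 0) stop("undefined-delta error: zero ", what,
                     " in the reference period")
    100 * (b - a) / a
  }
  out <- c(
    lf_pre_r = lf[["pre_r"]], lf_mt = lf[["mt"]], lf_post_r = lf[["post_r"]],
    hf_pre_r = hf[["pre_r"]], hf_mt = hf[["mt"]], hf_post_r = hf[["post_r"]],
    lfhf_pre_r = ratio[["pre_r"]], lfhf_mt = ratio[["mt"]],
    lfhf_post_r = ratio[["post_r"]],
    pct_lf_pre_mt = pct(lf[["pre_r"]], lf[["mt"]], "LF"),
    pct_hf_pre_mt = pct(hf[["pre_r"]], hf[["mt"]], "HF"),
    pct_lfhf_pre_mt = pct(ratio[["pre_r"]], ratio[["mt"]], "LF/HF"),
    pct_lf_mt_post = pct(lf[["mt"]], lf[["post_r"]], "LF"),
    pct_hf_mt_post = pct(hf[["mt"]], hf[["post_r"]], "HF"),
    pct_lfhf_mt_post = pct(ratio[["mt"]], ratio[["post_r"]], "LF/HF"))
  class(out) <- c("feature_vector", "numeric")
  out
}

#' Feature names of the 15-candidate vector, in canonical order
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("lf_pre_r", "lf_mt", "lf_post_r", "hf_pre_r", "hf_mt", "hf_post_r",
    "lfhf_pre_r", "lfhf_mt", "lfhf_post_r",
    "pct_lf_pre_mt", "pct_hf_pre_mt", "pct_lfhf_pre_mt",
    "pct_lf_mt_post", "pct_hf_mt_post", "pct_lfhf_mt_post")
}
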