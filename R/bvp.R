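# Blood-volume-pulse extraction and interbeat-interval series.

# 4th-order Butterworth band-pass magnitude response (analog prototype,
# band edges lo..hi Hz): |H(f)| = 1 / sqrt(1 + Omega(f)^4) with
# Omega = (f^2 - lo*hi) / (f * (hi - lo)). Zero at DC.
.butter_bp_mag <- function(f, lo, hi) {
  mag <- numeric(length(f))
  nz <- f > 0
  om <- (f[nz]^2 - lo * hi) / (f[nz] * (hi - lo))
  mag[nz] <- 1 / sqrt(1 + om^4)
  mag
}

#' Extract the blood-volume-pulse signal from an RGB trace
#'
#' Works on the (sign-inverted, mean-removed) green channel: computes a
#' symlet-4 MODWT multiresolution analysis to level 4 with reflection
#' boundary, keeps the components whose octave bands intersect the cardiac
#' band (at 30 frames/s: D3, D4 and the smooth S4), and applies a zero-phase
#' 4th-order Butterworth band-pass at 0.6-2.0 Hz. The green channel is
#' inverted because blood absorbs green light, so the systolic peak is a
#' luminance minimum. Output is zero-mean.
#'
#' @param trace An `rgb_trace` (columns `t_s`, `g_mean`; attribute `fps`).
#' @param band Cardiac pass-band, Hz (default `c(0.6, 2.0)`).
#' @param levels MODWT depth (default 4).
#' @return A `bvp_signal`: list with `samples` (dimensionless, zero-mean),
#'   `fs`, `t`.
#' @export
extract_bvp <- function(trace, band = c(0.6, 2.0), levels = 4) {
  fs <- attr(trace, "fps")
  if (is.null(fs)) stop("trace has no fps attribute")
  if (fs <= 2 * band[2]) stop("frame rate violates Nyquist for the cardiac band")
  g <- trace$g_mean
  n <- length(g)
  if (n < 2 * fs) stop("trace too short: need at least 2 s of frames")
  x <- -(g - mean(g))
  xe <- c(x, rev(x))
  M <- length(xe)
  tr <- .modwt_transfer(M, levels)
  # octave band of detail j is [fs/2^(j+1), fs/2^j); keep components that
  # intersect the cardiac band, then band-pass explicitly
  keep <- rep(0, M)
  for (j in seq_len(levels)) {
    blo <- fs / 2^(j + 1); bhi <- fs / 2^j
    if (bhi > band[1] && blo < band[2]) keep <- keep + tr[, j]
  }
  if (fs / 2^(levels + 1) > band[1]) keep <- keep + tr[, levels + 1] # smooth: [0, fs/2^(J+1))
  f <- (0:(M - 1)) / M * fs
  f <- pmin(f, fs - f)                   # alias to [0, fs/2]
  H <- keep * .butter_bp_mag(f, band[1], band[2])
  y <- Re(stats::fft(stats::fft(xe) * H, inverse = TRUE))[seq_len(n)] / M
  y <- y - mean(y)
  structure(list(samples = y, fs = fs, t = trace$t_s), class = "bvp_signal")
}

# centered moving average with symmetric shrinking at the edges
.movavg_centered <- function(x, k) {
  n <- length(x)
  half <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  r <- pmin(half, i - 1L, n - i)
  (cs[i + r + 1] - cs[i - r]) / (2 * r + 1)
}

# parabolic sub-sample refinement of a local maximum at index i
.parabolic_refine <- function(x, i) {
  if (i <= 1 || i >= length(x)) return(0)
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom == 0) return(0)
  d <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  max(min(d, 0.5), -0.5)
}

#' Detect pulse peaks in a BVP signal
#'
#' Adaptive-threshold detector: a 0.75 s moving-average baseline is raised
#' by an elevation `e` (a fraction of the signal amplitude range); each
#' contiguous supra-threshold region contributes one peak (its maximum).
#' The elevation is chosen from `{5, 10, ..., 50}%` to minimize the standard
#' deviation of the resulting interbeat intervals, subject to the implied
#' mean heart rate lying in `[40, 180]` beats/min and the intervals being
#' physiologically regular (coefficient of variation <= 0.35, so narrowband
#' noise with no cardiac structure is rejected rather than parsed as beats).
#' Peak times are refined to sub-frame precision by parabolic interpolation
#' over three samples, since the raw 30 frames/s grid quantizes intervals
#' to 33 ms steps.
#'
#' @param bvp A `bvp_signal` from [extract_bvp()].
#' @param hr_range Plausible mean-heart-rate range, beats/min.
#' @return Numeric vector of beat times, seconds.
#' @export
detect_pulse_peaks <- function(bvp, hr_range = c(40, 180)) {
  stopifnot(inherits(bvp, "bvp_signal"))
  x <- bvp$samples
  fs <- bvp$fs
  rng <- diff(range(x))
  if (rng == 0) stop("signal-quality error: flat BVP signal")
  k <- round(0.75 * fs)
  if (k %% 2 == 0) k <- k + 1
  ma <- .movavg_centered(x, k)
  cands <- list()
  for (e in seq(0.05, 0.50, by = 0.05)) {
    above <- x > ma + e * rng
    if (!any(above)) next
    d <- diff(c(FALSE, above, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1L
    if (length(starts) < 4) next
    peaks_i <- mapply(function(s, en) s + which.max(x[s:en]) - 1L, starts, ends)
    refine <- vapply(peaks_i, function(i) .parabolic_refine(x, i), numeric(1))
    times <- bvp$t[1] + (peaks_i - 1 + refine) / fs
    ibi <- diff(times)
    mhr <- 60 / mean(ibi)
    if (mhr < hr_range[1] || mhr > hr_range[2]) next
    if (stats::sd(ibi) / mean(ibi) > 0.35) next
    cands[[length(cands) + 1]] <- list(times = times, sd = stats::sd(ibi),
                                       mhr = mhr)
  }
  # a genuine pulse gives the same implied heart rate across elevations;
  # threshold-crossing noise does not: require corroboration within 5%
  if (length(cands) > 0) {
    hrs <- vapply(cands, `[[`, numeric(1), "mhr")
    corro <- vapply(seq_along(cands), function(i)
      sum(abs(hrs - hrs[i]) / hrs[i] < 0.05) >= 2, logical(1))
    cands <- cands[corro]
  }
  if (length(cands) == 0)
    stop("signal-quality error: no elevation yields a plausible beat sequence")
  cands[[which.min(vapply(cands, `[[`, numeric(1), "sd"))]]$times
}

#' Interbeat intervals from beat times
#'
#' @param beat_times Strictly increasing beat times, seconds (>= 3 beats).
#' @return An `ibi_series`: data.frame with `beat_time_s` (the interval's
#'   ending beat), `ibi_ms`, and logical `accepted` (all TRUE here).
#' @export
compute_ibi <- function(beat_times) {
  if (length(beat_times) < 3) stop("need at least 3 beats")
  if (is.unsorted(beat_times, strictly = TRUE))
    stop("beat times must be strictly increasing")
  out <- data.frame(beat_time_s = beat_times[-1],
                    ibi_ms = diff(beat_times) * 1000,
                    accepted = TRUE)
  class(out) <- c("ibi_series", "data.frame")
  out
}

#' Flag artifactual interbeat intervals
#'
#' Rejects intervals outside `[300, 2000]` ms, then iteratively rejects
#' intervals deviating more than 30% from the median of their 11 nearest
#' accepted neighbours until no further change (making the operation
#' idempotent). Rejected intervals are excluded from HRV, never
#' interpolated. Warns when more than 20% are rejected; errors above 50%.
#'
#' @param ibi An `ibi_series`.
#' @param abs_range Absolute plausibility bounds, ms.
#' @param rel_tol Relative deviation tolerance from the neighbour median.
#' @param n_neighbours Number of nearest accepted intervals in the median.
#' @return The `ibi_series` with updated `accepted` flags and attribute
#'   `rejection_fraction`.
#' @export
clean_ibi <- function(ibi, abs_range = c(300, 2000), rel_tol = 0.3,
                      n_neighbours = 11) {
  stopifnot(inherits(ibi, "ibi_series"), nrow(ibi) > 0)
  x <- ibi$ibi_ms
  acc <- ibi$accepted & x >= abs_range[1] & x <= abs_range[2]
  repeat {
    changed <- FALSE
    idx_acc <- which(acc)
    if (length(idx_acc) > 1) {
      for (i in idx_acc) {
        others <- idx_acc[idx_acc != i]
        nb <- others[order(abs(others - i))][seq_len(min(n_neighbours, length(others)))]
        med <- stats::median(x[nb])
        if (abs(x[i] - med) / med > rel_tol) {
          acc[i] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ibi$accepted <- acc
  frac <- 1 - mean(acc)
  attr(ibi, "rejection_fraction") <- frac
  if (frac > 0.5) stop("session rejected: more than 50% of intervals artifactual")
  if (frac > 0.2) warning("session-quality warning: more than 20% of intervals rejected")
  ibi
}
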