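# Camera-vs-ECG validation: R-peak detection, beat pairing and agreement
# statistics (Pearson, RMSE, Bland-Altman limits), plus the SDS-logit
# correlation.

# running maximum over a centered window of w samples
.runmax <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  out <- x
  for (s in seq_len(half)) {
    out <- pmax(out, c(x[-seq_len(s)], rep(-Inf, s)),
                c(rep(-Inf, s), x[seq_len(n - s)]))
  }
  out
}

#' Detect R-peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: band-pass 5-15 Hz (zero-phase Butterworth),
#' differentiate, square, 150 ms moving-window integration, then an
#' adaptive threshold (a fraction of the locally-running maximum of the
#' integrated signal, making detection invariant to amplitude scaling) with
#' a 250 ms refractory period. Peak times are refined to sub-sample
#' precision by a parabolic fit on the raw signal.
#'
#' @param ecg An `ecg_signal` (list with `samples`, `fs`) or numeric vector
#'   with `fs` given.
#' @param fs Sampling rate, Hz (taken from the object if present).
#' @param threshold_frac Fraction of the running maximum of the integrated
#'   signal used as detection threshold (default 0.4).
#' @return Numeric vector of R-peak times, seconds.
#' @export
detect_r_peaks <- function(ecg, fs = NULL, threshold_frac = 0.4) {
  if (inherits(ecg, "ecg_signal")) { fs <- ecg$fs; x <- ecg$samples }
  else x <- as.numeric(ecg)
  if (is.null(fs) || fs < 100) stop("need fs >= 100 Hz")
  if (stats::sd(x) == 0) stop("flat-signal error: ECG has no variation")
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  k <- max(1L, round(0.150 * fs))
  integ <- .movavg_centered(sq, if (k %% 2 == 0) k + 1L else k)
  thr <- threshold_frac * pmax(.runmax(integ, round(2 * fs)),
                               0.1 * max(integ))
  above <- integ > thr
  dgn <- diff(c(FALSE, above, FALSE))
  starts <- which(dgn == 1); ends <- which(dgn == -1) - 1L
  if (length(starts) == 0) stop("flat-signal error: no QRS candidates")
  half_w <- round(0.100 * fs)
  n <- length(x)
  peaks <- vapply(seq_along(starts), function(i) {
    lo <- max(1L, starts[i] - half_w); hi <- min(n, ends[i] + half_w)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  peaks <- unique(peaks)
  # refractory: drop the smaller of any pair closer than 250 ms
  keep <- rep(TRUE, length(peaks))
  i <- 2
  while (i <= length(peaks)) {
    prev <- max(which(keep[seq_len(i - 1)]))
    if ((peaks[i] - peaks[prev]) / fs < 0.250) {
      if (x[peaks[i]] > x[peaks[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
    i <- i + 1
  }
  peaks <- peaks[keep]
  refine <- vapply(peaks, function(i) .parabolic_refine(x, i), numeric(1))
  (peaks - 1 + refine) / fs
}

#' Pair camera and ECG beats for interval comparison
#'
#' Each reference (ECG) beat is matched to its nearest camera beat within
#' `max_lag_ms`; duplicate matches keep the closer beat. Paired interbeat
#' intervals are formed only where both interval endpoints are matched to
#' consecutive camera beats, so a missed beat removes the two intervals it
#' touches. A constant camera delay (pulse transit time) cancels in the
#' differencing and does not bias the paired intervals.
#'
#' @param camera_beats,ecg_beats Increasing beat times, seconds.
#' @param max_lag_ms Maximum pairing lag, ms (default 500).
#' @return A `paired_ibi` data.frame with `ref_ibi_ms`, `cam_ibi_ms` and
#'   attributes `match_rate` and `n_matched`.
#' @export
pair_beats <- function(camera_beats, ecg_beats, max_lag_ms = 500) {
  stopifnot(!is.unsorted(camera_beats), !is.unsorted(ecg_beats))
  ne <- length(ecg_beats)
  match_idx <- rep(NA_integer_, ne)
  if (length(camera_beats) > 0 && ne > 0) {
    pos <- findInterval(ecg_beats, camera_beats)
    for (i in seq_len(ne)) {
      cand <- unique(pmin(pmax(c(pos[i], pos[i] + 1L), 1L),
                          length(camera_beats)))
      d <- abs(camera_beats[cand] - ecg_beats[i])
      j <- cand[which.min(d)]
      if (min(d) * 1000 <= max_lag_ms) match_idx[i] <- j
    }
    # resolve duplicates: keep the closer ECG beat
    for (j in unique(stats::na.omit(match_idx))) {
      hits <- which(match_idx == j)
      if (length(hits) > 1) {
        d <- abs(ecg_beats[hits] - camera_beats[j])
        match_idx[hits[-which.min(d)]] <- NA_integer_
      }
    }
  }
  ok <- !is.na(match_idx)
  pair_ok <- ok[-ne] & ok[-1] & (diff(match_idx) == 1L)
  pair_ok[is.na(pair_ok)] <- FALSE
  ref_ibi <- diff(ecg_beats)[pair_ok] * 1000
  cam_ibi <- diff(camera_beats)[match_idx[c(pair_ok, FALSE)]] * 1000
  out <- data.frame(ref_ibi_ms = ref_ibi, cam_ibi_ms = cam_ibi)
  attr(out, "match_rate") <- mean(ok)
  attr(out, "n_matched") <- sum(ok)
  class(out) <- c("paired_ibi", "data.frame")
  if (mean(ok) < 0.8)
    warning("alignment warning: beat match rate below 80%")
  out
}

#' Agreement statistics between camera and reference interbeat intervals
#'
#' Pearson correlation (two-sided test), RMSE, mean difference (bias,
#' camera minus reference), the sample standard deviation of the
#' differences (n - 1) and the Bland-Altman 95% limits of agreement
#' `bias +/- 1.96 sd`.
#'
#' @param pairs A `paired_ibi` data.frame from [pair_beats()] (or any
#'   data.frame with `ref_ibi_ms`, `cam_ibi_ms`).
#' @return An `agreement_stats` list: `r`, `p_value`, `rmse`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_pairs`.
#' @export
agreement_stats <- function(pairs) {
  cam <- pairs$cam_ibi_ms; ref <- pairs$ref_ibi_ms
  n <- length(cam)
  if (n < 3) stop("need at least 3 paired intervals")
  d <- cam - ref
  if (stats::sd(cam) == 0 || stats::sd(ref) == 0) {
    r <- NA_real_; p <- NA_real_
    warning("zero variance in a series: correlation undefined")
  } else {
    ct <- stats::cor.test(cam, ref)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  sdd <- stats::sd(d)
  bias <- mean(d)
  structure(list(r = r, p_value = p,
                 rmse = sqrt(mean(d^2)), bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n_pairs = n), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("IBI agreement over %d pairs: r = %.3f (p = %.2g), RMSE = %.2f ms\n",
              x$n_pairs, x$r, x$p_value, x$rmse))
  cat(sprintf("  Bland-Altman: bias %.2f ms, 95%% LoA [%.2f, %.2f] (sd %.2f)\n",
              x$bias, x$loa_low, x$loa_high, x$sd_diff))
  invisible(x)
}

#' Correlate screening logits with self-rated depression scores
#'
#' @param logits Per-subject logit scores.
#' @param sds_scores Per-subject Zung SDS scores.
#' @return List with Pearson `r` and two-sided `p_value`.
#' @export
correlate_scores <- function(logits, sds_scores) {
  stopifnot(length(logits) == length(sds_scores))
  if (length(logits) < 3) stop("need at least 3 subjects")
  if (stats::sd(logits) == 0 || stats::sd(sds_scores) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(logits, sds_scores)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
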