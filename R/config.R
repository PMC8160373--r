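#' Measurement protocol configuration
#'
#' The screening session is split into three contiguous periods: a pre-task
#' rest ("Pre-R"), a random-number-generation mental task ("MT") and a
#' post-task rest ("Post-R"). Defaults are 140 s + 100 s + 120 s = 360 s.
#' Period boundaries are half-open `[start, end)`.
#'
#' @param pre_r_s Duration of the pre-task rest period, seconds.
#' @param mt_s Duration of the mental-task period, seconds.
#' @param post_r_s Duration of the post-task rest period, seconds.
#' @return An object of class `protocol_config`: a list with the three
#'   durations, the total duration and the period boundary vector.
#' @export
#' @examples
#' p <- protocol_config()
#' p$total_s # 360
protocol_config <- function(pre_r_s = 140, mt_s = 100, post_r_s = 120) {
  stopifnot(pre_r_s > 0, mt_s > 0, post_r_s > 0)
  out <- list(
    pre_r_s = pre_r_s, mt_s = mt_s, post_r_s = post_r_s,
    total_s = pre_r_s + mt_s + post_r_s,
    boundaries = cumsum(c(0, pre_r_s, mt_s, post_r_s)),
    period_names = c("pre_r", "mt", "post_r")
  )
  class(out) <- "protocol_config"
  out
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Screening protocol: Pre-R", x$pre_r_s, "s | MT", x$mt_s,
      "s | Post-R", x$post_r_s, "s (total", x$total_s, "s)\n")
  invisible(x)
}

#' Heart-rate-variability frequency bands
#'
#' Standard short-term HRV bands: low frequency (LF, sympathetic plus
#' parasympathetic) and high frequency (HF, parasympathetic). Bands are
#' half-open `[lo, hi)` so the 0.15 Hz edge belongs to HF only.
#'
#' @param lf Two-element numeric, LF band edges in Hz. Default `c(0.04, 0.15)`.
#' @param hf Two-element numeric, HF band edges in Hz. Default `c(0.15, 0.40)`.
#' @return An object of class `band_config`.
#' @export
band_config <- function(lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  stopifnot(length(lf) == 2, length(hf) == 2,
            lf[1] < lf[2], hf[1] < hf[2], lf[2] <= hf[1], lf[1] > 0)
  structure(list(lf = lf, hf = hf), class = "band_config")
}

#' Default analysis configuration
#'
#' Collects the pipeline-wide constants in one place: the three-period
#' protocol, the LF/HF bands, the cardiac pass-band used for blood-volume
#' pulse extraction, the nominal camera frame rate and the Zung self-rating
#' depression scale (SDS) screening cut-off.
#'
#' @return A list with elements `protocol`, `bands`, `bvp_band` (Hz),
#'   `fps` (frames/s), `ecg_fs` (Hz) and `sds_cutoff` (SDS units; scores at
#'   or above it are treated as suspected MDD).
#' @export
default_config <- function() {
  list(
    protocol = protocol_config(),
    bands = band_config(),
    bvp_band = c(0.6, 2.0),
    fps = 30,
    ecg_fs = 100,
    sds_cutoff = 48
  )
}
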