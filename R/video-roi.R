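# Frame stream -> facial ROI -> per-frame mean RGB trace.
#
# Face detection and landmark location are pluggable backends. The package
# ships the synthetic backend, which operates on frames rendered by
# render_frames(): it segments face pixels against the background and
# derives cheek/chin landmarks from the detected box. Production backends
# (Haar cascade detection, neural landmark models) plug into the same
# contract but are not bundled; no detector training happens here.
#
# Conventions: 0-based pixel coordinates, origin top-left, x right, y down;
# boxes are half-open [x0, x1) x [y0, y1).

#' Face geometry for synthetic frame rendering
#'
#' @param width,height Frame size in pixels (default 320 x 180; desk-scale
#'   stand-in for the nominal 1920 x 1080 capture).
#' @param center Ellipse center `(x, y)`, pixels, 0-based.
#' @param semi_axes Ellipse semi-axes `(a_x, a_y)`, pixels.
#' @param background Length-3 RGB background tones.
#' @return A `face_geometry` list.
#' @export
face_geometry <- function(width = 320, height = 180, center = c(160, 90),
                          semi_axes = c(45, 62), background = c(40, 40, 40)) {
  structure(list(width = width, height = height, center = center,
                 semi_axes = semi_axes, background = background),
            class = "face_geometry")
}

#' Render a synthetic frame stream from an RGB trace
#'
#' Produces small RGB frames in which pixels inside a face ellipse take the
#' trace's per-frame RGB values (quantized to 256 tones by rounding) on a
#' uniform background; the ellipse center optionally follows a slow
#' horizontal sinusoidal motion. Gives the detection/tracking/extraction
#' chain a fully known ground truth.
#'
#' @param rgb_trace An `rgb_trace` (from [synthesize_rgb_trace()] or read
#'   from CSV).
#' @param geometry A [face_geometry()].
#' @param motion_amp_px Amplitude of the sinusoidal center motion, pixels.
#' @param motion_freq_hz Motion frequency, Hz (default 0.1).
#' @param blank_frames Optional integer indices of frames rendered as pure
#'   background (simulated detection dropouts).
#' @return A `frame_stream`: list with `frames` (list of height x width x 3
#'   integer arrays), `fps`, `width`, `height`, `geometry`,
#'   `true_centers` (n x 2 matrix).
#' @export
render_frames <- function(rgb_trace, geometry = face_geometry(),
                          motion_amp_px = 0, motion_freq_hz = 0.1,
                          blank_frames = integer(0)) {
  fps <- attr(rgb_trace, "fps")
  n <- nrow(rgb_trace)
  w <- geometry$width; h <- geometry$height
  cx0 <- geometry$center[1]; cy0 <- geometry$center[2]
  ax <- geometry$semi_axes[1]; ay <- geometry$semi_axes[2]
  if (cx0 - ax - motion_amp_px < 0 || cx0 + ax + motion_amp_px >= w ||
      cy0 - ay < 0 || cy0 + ay >= h)
    stop("face ellipse (plus motion) outside frame bounds")
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), w), h, w)
  bg <- geometry$background
  frames <- vector("list", n)
  centers <- matrix(0, n, 2)
  t <- rgb_trace$t_s
  for (i in seq_len(n)) {
    cx <- cx0 + motion_amp_px * sin(2 * pi * motion_freq_hz * t[i])
    centers[i, ] <- c(cx, cy0)
    fr <- array(0L, c(h, w, 3))
    fr[, , 1] <- bg[1]; fr[, , 2] <- bg[2]; fr[, , 3] <- bg[3]
    if (!(i %in% blank_frames)) {
      mask <- ((xg - cx) / ax)^2 + ((yg - cy0) / ay)^2 <= 1
      vals <- round(c(rgb_trace$r_mean[i], rgb_trace$g_mean[i],
                      rgb_trace$b_mean[i]))
      vals <- pmin(pmax(vals, 0), 255)
      for (ch in 1:3) {
        pl <- fr[, , ch]; pl[mask] <- vals[ch]; fr[, , ch] <- pl
      }
    }
    frames[[i]] <- fr
  }
  structure(list(frames = frames, fps = fps, width = w, height = h,
                 geometry = geometry, true_centers = centers),
            class = "frame_stream")
}

#' The synthetic detection/landmark backend
#'
#' Detection segments non-background pixels (channel-wise absolute
#' difference from the border-estimated background above a tone threshold)
#' and returns their bounding box and centroid; landmark placement derives
#' the left-cheek (A), right-cheek (B) and chin-top (C) points from fixed
#' anatomical fractions of the face box, mirroring where a 68-point
#' landmark model puts indices 2, 14 and 8.
#'
#' @param min_pixels Minimum face-pixel count for a valid detection.
#' @param tone_threshold Minimum summed RGB deviation from background.
#' @return A `roi_backend` list with functions `detect(frame)` ->
#'   list(found, box, centroid) and `landmarks(box)` -> 3 x 2 matrix
#'   (rows A, B, C).
#' @export
synthetic_backend <- function(min_pixels = 50, tone_threshold = 20) {
  detect <- function(frame) {
    h <- dim(frame)[1]; w <- dim(frame)[2]
    bg <- apply(array(frame[c(1, h), , , drop = FALSE], c(2 * w, 3)), 2,
                stats::median)
    dev <- abs(frame[, , 1] - bg[1]) + abs(frame[, , 2] - bg[2]) +
           abs(frame[, , 3] - bg[3])
    mask <- dev > tone_threshold
    if (sum(mask) < min_pixels) return(list(found = FALSE))
    ij <- which(mask, arr.ind = TRUE)
    cols <- ij[, 2] - 1L; rows <- ij[, 1] - 1L      # 0-based
    list(found = TRUE,
         box = c(x0 = min(cols), y0 = min(rows),
                 x1 = max(cols) + 1L, y1 = max(rows) + 1L),
         centroid = c(mean(cols), mean(rows)))
  }
  landmarks <- function(box) {
    w <- box[["x1"]] - box[["x0"]]; h <- box[["y1"]] - box[["y0"]]
    m <- rbind(A = c(box[["x0"]] + 0.20 * w, box[["y0"]] + 0.55 * h),
               B = c(box[["x0"]] + 0.80 * w, box[["y0"]] + 0.55 * h),
               C = c(box[["x0"]] + 0.50 * w, box[["y0"]] + 0.82 * h))
    colnames(m) <- c("x", "y")
    m
  }
  structure(list(detect = detect, landmarks = landmarks),
            class = "roi_backend")
}

#' Detect the face in one frame
#'
#' Delegates to the backend's detector. Returns the face bounding box, or a
#' no-face sentinel (`found = FALSE`) for frames where the backend finds
#' nothing; such frames are flagged and later interpolated.
#'
#' @param frame A height x width x 3 array (tones 0-255).
#' @param backend An `roi_backend` (default [synthetic_backend()]).
#' @return List with `found`, and when found `box` (0-based, half-open)
#'   and `centroid`.
#' @export
detect_face <- function(frame, backend = synthetic_backend()) {
  backend$detect(frame)
}

#' Track the face box across a frame stream
#'
#' Translation tracker against the backend detector: every frame's face
#' centroid displacement from the first detected frame translates the
#' initial box. On a frame with no detection the previous box is carried
#' and the frame is flagged for trace interpolation.
#'
#' @param stream A `frame_stream`.
#' @param initial_box Box from [detect_face()] on the first valid frame
#'   (default: detect it here).
#' @param backend An `roi_backend`.
#' @return List with `boxes` (n x 4 matrix x0, y0, x1, y1), `flagged`
#'   (logical, no-face frames), `centers` (n x 2).
#' @export
track_roi <- function(stream, initial_box = NULL,
                      backend = synthetic_backend()) {
  n <- length(stream$frames)
  det0 <- NULL
  first_ok <- NA_integer_
  for (i in seq_len(n)) {
    d <- backend$detect(stream$frames[[i]])
    if (d$found) { det0 <- d; first_ok <- i; break }
  }
  if (is.null(det0)) stop("tracking lost: no face found in any frame")
  if (is.null(initial_box)) initial_box <- det0$box
  boxes <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  centers <- matrix(NA_real_, n, 2)
  flagged <- logical(n)
  ref_centroid <- det0$centroid
  last_shift <- c(0, 0)
  for (i in seq_len(n)) {
    d <- if (i == first_ok) det0 else backend$detect(stream$frames[[i]])
    if (d$found) {
      last_shift <- d$centroid - ref_centroid
      centers[i, ] <- d$centroid
    } else {
      flagged[i] <- TRUE
    }
    boxes[i, ] <- initial_box + last_shift[c(1, 2, 1, 2)]
  }
  list(boxes = boxes, flagged = flagged, centers = centers)
}

#' Smooth a landmark track with a centered moving average
#'
#' A 0.3 s moving-average window (9 frames at 30 frames/s; even counts are
#' rounded up to the next odd so the filter stays centered) suppresses
#' head-motion jitter; edges shrink the window symmetrically, so constant
#' tracks are fixed points.
#'
#' @param track Numeric matrix, one row per frame, columns are landmark
#'   coordinates (e.g. ax, ay, bx, by, cx, cy).
#' @param fps Frame rate.
#' @param window_s Window length, seconds (default 0.3).
#' @return Matrix of the same shape.
#' @export
smooth_landmarks <- function(track, fps = 30, window_s = 0.3) {
  stopifnot(window_s > 0)
  k <- round(window_s * fps)
  if (k %% 2 == 0) k <- k + 1
  apply(as.matrix(track), 2, .movavg_centered, k = k)
}

#' Build the ROI rectangle from the three landmarks
#'
#' The box spans horizontally from A (left cheek) to B (right cheek) and
#' vertically from the cheek line down to C (chin-top/philtrum region),
#' inset by 5% per side to avoid edge pixels; this covers the cheek and
#' nose territory of the facial arteries.
#'
#' @param A,B,C Length-2 numeric landmark coordinates `(x, y)`.
#' @param inset Per-side inset fraction (default 0.05).
#' @return Numeric box `c(x0, y0, x1, y1)`, half-open.
#' @export
#' @examples
#' build_roi(c(100, 200), c(300, 200), c(200, 300))
#' # x in [110, 290], y in [205, 295]
build_roi <- function(A, B, C, inset = 0.05) {
  x0 <- unname(min(A[1], B[1])); x1 <- unname(max(A[1], B[1]))
  y0 <- unname(min(A[2], B[2])); y1 <- unname(C[2])
  w <- x1 - x0; h <- y1 - y0
  if (w <= 0 || h <= 0) stop("degenerate ROI: landmarks give a zero-area box")
  c(x0 = x0 + inset * w, y0 = y0 + inset * h,
    x1 = x1 - inset * w, y1 = y1 - inset * h)
}

#' Mean-RGB trace over per-frame ROIs
#'
#' Arithmetic mean of each channel over the ROI pixels of every frame.
#' Frames flagged as detection dropouts get linearly interpolated values;
#' a dropout gap longer than 1 s rejects the session (longer gaps corrupt
#' the HRV spectrum).
#'
#' @param stream A `frame_stream`.
#' @param rois n x 4 matrix of boxes (`x0, y0, x1, y1`, 0-based half-open),
#'   or a single box recycled.
#' @param flagged Optional logical vector of frames to interpolate.
#' @return An `rgb_trace` with attributes `fps` and `n_interpolated`.
#' @export
extract_green_trace <- function(stream, rois, flagged = NULL) {
  n <- length(stream$frames)
  if (is.null(dim(rois))) rois <- matrix(rois, n, 4, byrow = TRUE)
  stopifnot(nrow(rois) == n)
  if (is.null(flagged)) flagged <- logical(n)
  vals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (flagged[i]) next
    bx <- rois[i, ]
    cols <- (floor(bx[1]) + 1L):ceiling(bx[3])   # 1-based, half-open right
    rows <- (floor(bx[2]) + 1L):ceiling(bx[4])
    cols <- cols[cols >= 1 & cols <= stream$width]
    rows <- rows[rows >= 1 & rows <= stream$height]
    if (length(cols) == 0 || length(rows) == 0) stop("empty ROI")
    fr <- stream$frames[[i]]
    for (ch in 1:3) vals[i, ch] <- mean(fr[rows, cols, ch])
  }
  if (any(flagged)) {
    runs <- rle(flagged)
    if (any(runs$lengths[runs$values] > stream$fps))
      stop("session rejected: face lost for more than 1 s")
    for (ch in 1:3)
      vals[, ch] <- stats::approx(which(!flagged), vals[!flagged, ch],
                                  xout = seq_len(n), rule = 2)$y
  }
  out <- data.frame(t_s = (seq_len(n) - 1) / stream$fps,
                    r_mean = vals[, 1], g_mean = vals[, 2], b_mean = vals[, 3])
  attr(out, "fps") <- stream$fps
  attr(out, "n_interpolated") <- sum(flagged)
  class(out) <- c("rgb_trace", "data.frame")
  out
}

#' Full frame-stream to RGB-trace chain
#'
#' Detect, track, place and smooth landmarks, build per-frame ROIs and
#' extract the mean-RGB trace.
#'
#' @param stream A `frame_stream`.
#' @param backend An `roi_backend`.
#' @return An `rgb_trace` (attributes `fps`, `n_interpolated`).
#' @export
frames_to_trace <- function(stream, backend = synthetic_backend()) {
  tr <- track_roi(stream, backend = backend)
  lm <- t(apply(tr$boxes, 1, function(b) as.vector(t(backend$landmarks(
    stats::setNames(b, c("x0", "y0", "x1", "y1")))))))
  lm_s <- smooth_landmarks(lm, fps = stream$fps)
  rois <- t(apply(lm_s, 1, function(r)
    build_roi(r[1:2], r[3:4], r[5:6])))
  extract_green_trace(stream, rois, flagged = tr$flagged)
}
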