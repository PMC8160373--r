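# End-to-end orchestration: session manifest -> screening report, and
# cohort-level cross-validated evaluation.

#' Session manifest
#'
#' Bundles everything needed to reproduce one screening run: the input
#' (an in-memory `rgb_trace`/`frame_stream`/`synthetic_session` or a trace
#' CSV path), the protocol and band configuration, the model choice and
#' the seed.
#'
#' @param input An `rgb_trace`, `frame_stream`, `synthetic_session`, or a
#'   path to a trace CSV.
#' @param subject_id Subject identifier string.
#' @param protocol A [protocol_config()].
#' @param bands A [band_config()].
#' @param model A `screening_model` (default [published_model()]).
#' @param seed Integer seed recorded for provenance.
#' @return A `session_manifest` list.
#' @export
session_manifest <- function(input, subject_id = "anonymous",
                             protocol = protocol_config(),
                             bands = band_config(),
                             model = published_model(), seed = 0) {
  if (is.character(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  structure(list(input = input, subject_id = subject_id,
                 protocol = protocol, bands = bands, model = model,
                 seed = seed,
                 version = as.character(utils::packageVersion("rppgscreen"))),
            class = "session_manifest")
}

# resolve a manifest input to an rgb_trace
.resolve_trace <- function(input, backend = synthetic_backend()) {
  if (is.character(input)) return(read_trace(input))
  if (inherits(input, "rgb_trace")) return(input)
  if (inherits(input, "synthetic_session")) return(input$rgb_trace)
  if (inherits(input, "frame_stream")) return(frames_to_trace(input, backend))
  stop("unsupported input type for screening session")
}

#' Run one full screening session
#'
#' Executes the pipeline: (frames ->) green trace -> blood-volume pulse ->
#' pulse peaks -> cleaned interbeat intervals -> per-period LF/HF spectra
#' -> 15-candidate feature vector -> logistic screening score. Stage
#' failures propagate with a stage tag and never emit a screening label.
#'
#' @param manifest A [session_manifest()] (or any object accepted as its
#'   `input`).
#' @param out_dir Optional directory; when given, intermediates (trace,
#'   BVP, IBI, features) are persisted as CSV and the report as JSON.
#' @return A `session_report`: list with `subject_id`, `features`
#'   (named length-15 vector), `result` (logit, p, label), `quality`
#'   (rejection fraction, interpolated frames), `n_beats`.
#' @export
run_screening_session <- function(manifest, out_dir = NULL) {
  if (!inherits(manifest, "session_manifest"))
    manifest <- session_manifest(manifest)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  trace <- stage("video_roi", .resolve_trace(manifest$input))
  bvp <- stage("bvp_extract", extract_bvp(trace))
  beats <- stage("pulse_peaks", detect_pulse_peaks(bvp))
  ibi <- stage("ibi", clean_ibi(compute_ibi(beats)))
  segments <- stage("segment", segment_periods(ibi, manifest$protocol))
  phrv <- stage("hrv", compute_hrv_periods(segments, manifest$bands))
  features <- stage("features", compute_features(phrv))
  result <- stage("screening",
                  score(manifest$model, unclass(features)))
  report <- structure(list(
    subject_id = manifest$subject_id,
    features = features,
    result = result,
    quality = list(
      rejection_fraction = attr(ibi, "rejection_fraction"),
      n_interpolated = attr(trace, "n_interpolated") %||% 0L),
    n_beats = length(beats),
    protocol = manifest$protocol,
    seed = manifest$seed), class = "session_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(trace),
                     file.path(out_dir, "trace.csv"), row.names = FALSE)
    utils::write.csv(data.frame(t_s = bvp$t, amplitude = bvp$samples),
                     file.path(out_dir, "bvp.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ibi),
                     file.path(out_dir, "ibi.csv"), row.names = FALSE)
    utils::write.csv(data.frame(feature = names(features),
                                value = as.numeric(features)),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      subject_id = report$subject_id,
      logit = result$logit, p = result$p, label = result$label,
      quality = report$quality, n_beats = report$n_beats),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_report <- function(x, ...) {
  cat("Screening report for", x$subject_id, "\n")
  cat(sprintf("  logit %.3f  p %.3f  label %s\n",
              x$result$logit, x$result$p, x$result$label))
  cat(sprintf("  %d beats, %.1f%% intervals rejected, %d frames interpolated\n",
              x$n_beats, 100 * x$quality$rejection_fraction,
              x$quality$n_interpolated))
  invisible(x)
}

#' Feature matrix for a synthetic cohort
#'
#' Simulates a trace-level session per subject and runs the measurement
#' pipeline to its 15-feature vector.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param protocol A [protocol_config()].
#' @param bands A [band_config()].
#' @param render Use rendered frames instead of the trace directly
#'   (slower; default FALSE).
#' @return List with `X` (n x 15 feature matrix), `y` (1 = MDD),
#'   `sds` (SDS scores), `ids`.
#' @export
cohort_features <- function(cohort, protocol = protocol_config(),
                            bands = band_config(), render = FALSE) {
  n <- length(cohort)
  X <- matrix(NA_real_, n, 15, dimnames = list(NULL, feature_names()))
  y <- integer(n); sds <- numeric(n); ids <- character(n)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    sess <- simulate_session(s, protocol = protocol)
    input <- if (render) render_frames(sess$rgb_trace) else sess$rgb_trace
    rep_i <- run_screening_session(
      session_manifest(input, subject_id = s$id, protocol = protocol,
                       bands = bands, seed = s$seed))
    X[i, ] <- as.numeric(rep_i$features)
    y[i] <- as.integer(s$group == "mdd")
    sds[i] <- s$sds_score
    ids[i] <- s$id
  }
  list(X = X, y = y, sds = sds, ids = ids)
}

#' Cohort-level cross-validated evaluation
#'
#' Computes features for every subject, chooses the model size on the MRMR
#' ranking by cross-validated accuracy, and evaluates the chosen model with
#' stratified k-fold cross-validation pooled into a single confusion
#' matrix, with ROC analysis of the pooled out-of-fold logits.
#'
#' @param cohort A `synthetic_cohort`, or a precomputed list with `X`, `y`
#'   (as returned by [cohort_features()]).
#' @param folds Number of CV folds (default 5).
#' @param seed Fold-assignment seed (default 0).
#' @param max_k Largest model size scanned (default 6, keeping roughly ten
#'   subjects per explanatory variable at the 53-subject design size).
#' @return A `cohort_evaluation` list: `metrics` (a `cv_metrics`),
#'   `selection` (accuracy curve + MRMR ranking), `features`.
#' @export
run_cohort_evaluation <- function(cohort, folds = 5, seed = 0, max_k = 6) {
  feats <- if (inherits(cohort, "synthetic_cohort"))
    cohort_features(cohort) else cohort
  if (length(unique(feats$y)) < 2)
    stop("stratification error: cohort has a single class")
  sel <- select_model_size(feats$X, feats$y, max_k = max_k,
                           folds = folds, seed = seed)
  top <- sel$ranking$feature[seq_len(sel$k)]
  metrics <- evaluate_cv(feats$X[, top, drop = FALSE], feats$y,
                         folds = folds, seed = seed)
  structure(list(metrics = metrics, selection = sel, features = feats,
                 selected_features = top),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat("Cohort evaluation (", length(x$features$y), " subjects, k = ",
      x$selection$k, ": ", paste(x$selected_features, collapse = ", "),
      ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}
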