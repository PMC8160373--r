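# MRMR feature selection, logistic screening model, cross-validated
# metrics and ROC analysis.

# Equal-frequency quartile discretization; returns integer bins. Collapses
# duplicated quantile breaks; a single-bin (zero-entropy) result is
# signalled via attribute.
.quartile_bin <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.25), type = 7))
  if (length(br) < 2) {
    b <- rep(1L, length(x))
    attr(b, "degenerate") <- TRUE
    return(b)
  }
  as.integer(cut(x, br, include.lowest = TRUE))
}

# Mutual information (nats) between two discrete vectors.
.mi_discrete <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}

# MI between a numeric feature (quartile-binned) and a vector that is used
# as-is when already discrete (few unique values) or binned otherwise.
.mi_feature <- function(x, y) {
  bx <- .quartile_bin(x)
  by <- if (length(unique(y)) <= 8) y else .quartile_bin(y)
  .mi_discrete(bx, by)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy MRMR with the quotient (MIQ) scheme: the first feature maximizes
#' relevance `MI(f; label)`; subsequent picks maximize
#' `MI(f; label) / (mean MI(f; selected) + 1e-12)`. Mutual information is
#' estimated after equal-frequency quartile discretization of continuous
#' variables. Ties are broken by higher relevance, then input order, so the
#' ranking is deterministic. Constant (zero-entropy) features are excluded
#' with a warning.
#'
#' @param features Numeric matrix or data.frame, one column per feature.
#' @param labels Binary class labels (0/1, logical or 2-level factor).
#' @param k Number of features to rank (default: all usable).
#' @return A data.frame `feature`, `score`, `relevance` in selection order.
#' @export
mrmr_rank <- function(features, labels, k = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(as.logical(labels))
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  usable <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X)))
    if (isTRUE(attr(.quartile_bin(X[, j]), "degenerate"))) usable[j] <- FALSE
  if (any(!usable))
    warning("excluding constant (zero-entropy) feature(s): ",
            paste(colnames(X)[!usable], collapse = ", "))
  idx <- which(usable)
  if (is.null(k)) k <- length(idx)
  k <- min(k, length(idx))
  rel <- vapply(idx, function(j) .mi_feature(X[, j], y), numeric(1))
  # pairwise feature MI filled lazily
  nf <- length(idx)
  red <- matrix(NA_real_, nf, nf)
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(nf)
  for (step in seq_len(k)) {
    sc <- vapply(remaining, function(i) {
      if (length(selected) == 0) return(rel[i])
      for (s in selected)
        if (is.na(red[i, s]))
          red[i, s] <<- red[s, i] <<- .mi_feature(X[, idx[i]], X[, idx[s]])
      rel[i] / (mean(red[i, selected]) + 1e-12)
    }, numeric(1))
    ord <- order(-sc, -rel[remaining], remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, sc[ord[1]])
    remaining <- setdiff(remaining, pick)
  }
  data.frame(feature = colnames(X)[idx[selected]],
             score = scores, relevance = rel[selected])
}

#' Fit the logistic screening model
#'
#' Unpenalized maximum-likelihood logistic regression (iteratively
#' reweighted least squares via [stats::glm()], tight convergence, at most
#' 100 iterations). Complete separation is detected explicitly (any
#' coefficient magnitude above 50 on unstandardized screening features, or
#' all fitted probabilities pinned at 0/1) and raised as an error instead
#' of returning a silently diverged fit.
#'
#' @param X Numeric matrix/data.frame of predictors with column names.
#' @param y Binary outcome (1/TRUE = suspected case).
#' @param on_separation `"error"` (default) raises complete separation as
#'   an error; `"tolerate"` returns the iteration-capped fit flagged with
#'   `meta$separated = TRUE` — the divergent ML fit still defines a valid
#'   decision boundary, which cross-validation uses for held-out scoring.
#' @return A `screening_model`: intercept, named coefficients and fit
#'   metadata; supports `print()`, `coef()`, `summary()`, `predict()`.
#' @export
fit_lra <- function(X, y, on_separation = c("error", "tolerate")) {
  on_separation <- match.arg(on_separation)
  X <- as.data.frame(X)
  if (is.null(names(X))) names(X) <- paste0("x", seq_along(X))
  y <- as.integer(as.logical(if (is.factor(y)) as.integer(y) - 1 else y))
  stopifnot(nrow(X) == length(y))
  dat <- cbind(.y = y, X)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- stats::coef(fit)
  p <- stats::fitted(fit)
  separated <- any(abs(beta[-1]) > 50) ||
    all(abs(p - y) < 1e-8) && any(p < 1e-8 | p > 1 - 1e-8)
  if (separated && on_separation == "error")
    stop("complete separation detected: logistic ML estimate does not exist")
  structure(list(intercept = unname(beta[1]),
                 coefficients = beta[-1],
                 feature_names = names(X),
                 glm = fit,
                 meta = list(n = length(y), source = "fit_lra",
                             separated = separated)),
            class = "screening_model")
}

#' The published four-variable screening model
#'
#' The fixed fitted logistic screening equation:
#' `logit = -1.2895 + 0.0013 HF_MT + 0.0051 %dLF(Pre-R=>MT)
#'  - 0.0001 %dHF(Pre-R=>MT) - 0.0004 %dHF(MT=>Post-R)`,
#' with HF_MT in ms^2 and the deltas in percent. A non-negative logit is
#' read as suspected MDD.
#'
#' @return A `screening_model` with the four named coefficients.
#' @export
#' @examples
#' m <- published_model()
#' score(m, c(hf_mt = 0, pct_lf_pre_mt = 0, pct_hf_pre_mt = 0,
#'            pct_hf_mt_post = 0))$logit # -1.2895
published_model <- function() {
  structure(list(
    intercept = -1.2895,
    coefficients = c(hf_mt = 0.0013, pct_lf_pre_mt = 0.0051,
                     pct_hf_pre_mt = -0.0001, pct_hf_mt_post = -0.0004),
    feature_names = c("hf_mt", "pct_lf_pre_mt", "pct_hf_pre_mt",
                      "pct_hf_mt_post"),
    glm = NULL,
    meta = list(source = "published")),
    class = "screening_model")
}

#' @export
print.screening_model <- function(x, digits = 4, ...) {
  cat("Logistic screening model (", x$meta$source, ")\n", sep = "")
  cat("  logit = ", format(x$intercept, digits = digits), sep = "")
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]
    cat(if (b >= 0) " + " else " - ", format(abs(b), digits = digits),
        " * ", nm, sep = "")
  }
  cat("\n  decision: logit >= 0 => suspected_mdd\n")
  invisible(x)
}

#' @export
coef.screening_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.screening_model <- function(object, ...) {
  print(object)
  if (!is.null(object$glm)) {
    cat("\nFit details:\n")
    print(stats::coef(summary(object$glm)))
  }
  invisible(object)
}

#' Write a screening model as JSON (intercept, named coefficients,
#' provenance) readable by [read_model()].
#' @param model A `screening_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "screening_model"))
  jsonlite::write_json(list(intercept = model$intercept,
                            coefficients = as.list(model$coefficients),
                            source = model$meta$source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a screening model written by [write_model()]
#' @param path JSON path.
#' @return A `screening_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path)
  cf <- unlist(j$coefficients)
  structure(list(intercept = j$intercept, coefficients = cf,
                 feature_names = names(cf), glm = NULL,
                 meta = list(source = j$source %||% "json")),
            class = "screening_model")
}

#' Score a subject with a screening model
#'
#' Computes the logit (linear predictor), the logistic probability and the
#' screening label; a non-negative logit maps to `suspected_mdd`.
#'
#' @param model A `screening_model`.
#' @param features Named numeric vector (or 1-row data.frame / matrix with
#'   named columns) containing at least the model's features.
#' @return A `screening_result` data.frame with `logit`, `p`, `label`
#'   (one row per input row).
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "screening_model"))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  features <- as.matrix(features)
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing) > 0)
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  Xm <- features[, model$feature_names, drop = FALSE]
  logit <- as.numeric(model$intercept + Xm %*% model$coefficients)
  out <- data.frame(logit = logit, p = stats::plogis(logit),
                    label = ifelse(logit >= 0, "suspected_mdd", "healthy"))
  class(out) <- c("screening_result", "data.frame")
  out
}

#' @export
predict.screening_model <- function(object, newdata, ...) {
  score(object, newdata)
}

# stratified fold assignment, deterministic per seed
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated screening metrics
#'
#' Stratified k-fold cross-validation of [fit_lra()]: out-of-fold logits are
#' pooled into a single confusion matrix at the decision cutoff 0, from
#' which sensitivity, specificity, PPV and NPV are computed. The pooled
#' logits also yield an ROC AUC and Youden-optimal cutoff.
#'
#' @param X Predictor matrix/data.frame.
#' @param y Binary outcome (1 = case).
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed (default 0).
#' @return A `cv_metrics` list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `confusion` (TP/FP/TN/FN), `fold_assignment`, `logits`, `auc`,
#'   `optimal_cutoff`.
#' @export
evaluate_cv <- function(X, y, folds = 5, seed = 0) {
  X <- as.data.frame(X)
  y <- as.integer(as.logical(if (is.factor(y)) as.integer(y) - 1 else y))
  if (min(table(y)) < folds)
    stop("degenerate folds: a class has fewer members than folds")
  fa <- .stratified_folds(y, folds, seed)
  logits <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fa != f
    m <- fit_lra(X[tr, , drop = FALSE], y[tr], on_separation = "tolerate")
    logits[!tr] <- score(m, as.matrix(X[!tr, , drop = FALSE]))$logit
  }
  pred <- as.integer(logits >= 0)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  roc <- roc_analysis(logits, y)
  structure(list(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    fold_assignment = fa, logits = logits,
    auc = roc$auc, optimal_cutoff = roc$optimal_cutoff,
    folds = folds, seed = seed), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(paste0("%d-fold CV: sensitivity %.2f | specificity %.2f | ",
                     "PPV %.2f | NPV %.2f | AUC %.2f\n"),
              x$folds, x$sensitivity, x$specificity, x$ppv, x$npv, x$auc))
  cat("  confusion:", paste(names(x$confusion), x$confusion, collapse = " "),
      "\n")
  invisible(x)
}

#' Choose the screening-model size on the MRMR ranking
#'
#' For `k = 1..max_k`, fits the logistic model on the top-k MRMR features
#' and computes the cross-validated accuracy, defined as the mean of
#' sensitivity, specificity, PPV and NPV. Returns the smallest k attaining
#' the maximum. A k whose fit fails (e.g. separation in a fold) scores NA
#' and cannot be selected.
#'
#' @inheritParams evaluate_cv
#' @param max_k Largest model size to consider.
#' @return List with `k` (the chosen size), `accuracy_curve` (length
#'   `max_k`), `ranking` (the MRMR table).
#' @export
select_model_size <- function(X, y, max_k = NULL, folds = 5, seed = 0) {
  X <- as.data.frame(X)
  if (is.null(max_k)) max_k <- ncol(X)
  stopifnot(max_k <= ncol(X))
  ranking <- mrmr_rank(X, y, k = max_k)
  acc <- rep(NA_real_, max_k)
  for (k in seq_len(max_k)) {
    feats <- ranking$feature[seq_len(k)]
    cv <- tryCatch(evaluate_cv(X[, feats, drop = FALSE], y, folds, seed),
                   error = function(e) NULL)
    if (!is.null(cv))
      acc[k] <- mean(c(cv$sensitivity, cv$specificity, cv$ppv, cv$npv))
  }
  if (all(is.na(acc))) stop("no model size could be cross-validated")
  list(k = which.max(acc), accuracy_curve = acc, ranking = ranking)
}

#' ROC analysis of screening logits
#'
#' AUC by the rank (Mann-Whitney) statistic with ties counted 1/2 —
#' identical to the trapezoidal area under the empirical ROC curve — and
#' the optimal decision cutoff maximizing Youden's J (sensitivity +
#' specificity - 1), taking the lowest threshold on ties.
#'
#' @param logits Numeric scores (higher = more case-like).
#' @param labels Binary labels (1 = case).
#' @return List with `auc`, `optimal_cutoff` and `curve` (data.frame of
#'   threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(logits, labels) {
  y <- as.integer(as.logical(if (is.factor(labels)) as.integer(labels) - 1
                             else labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(logits)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(logits))
  sens <- vapply(thr, function(ct) mean(logits[y == 1] >= ct), numeric(1))
  spec <- vapply(thr, function(ct) mean(logits[y == 0] < ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # thr sorted ascending: lowest tie
  list(auc = auc, optimal_cutoff = thr[best],
       curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec))
}
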