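test_that("MRMR ranks a label-identical feature first", {
  set.seed(10)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(perfect = y + 0, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  rk <- mrmr_rank(X, y)
  expect_identical(rk$feature[1], "perfect")
})

test_that("MRMR penalizes a duplicated informative feature", {
  set.seed(11)
  n <- 200
  y <- rep(0:1, each = n / 2)
  strong <- y + rnorm(n, sd = 0.4)
  weak <- y + rnorm(n, sd = 2)
  X <- cbind(strong = strong, dup = strong + rnorm(n, sd = 0.01),
             weak = weak, noise = rnorm(n))
  rk <- mrmr_rank(X, y)
  expect_identical(rk$feature[1], "strong")
  expect_lt(which(rk$feature == "weak"), which(rk$feature == "dup"))
})

test_that("greedy MRMR equals the exhaustive criterion oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 100
    y <- rep(0:1, each = n / 2)
    X <- cbind(a = y + rnorm(n, sd = 1),
               b = y + rnorm(n, sd = 0.5),
               c = rnorm(n),
               d = y * 0.5 + rnorm(n),
               e = rnorm(n, sd = 2))
    expect_identical(mrmr_rank(X, y)$feature, oracle_mrmr(X, y, 5))
  }
})

test_that("constant features are excluded with a warning", {
  set.seed(12)
  X <- cbind(flat = rep(1, 50), ok = rnorm(50))
  y <- rep(0:1, 25)
  expect_warning(rk <- mrmr_rank(X, y), "zero-entropy")
  expect_identical(rk$feature, "ok")
})

test_that("logistic fit recovers known coefficients and flags separation", {
  set.seed(13)
  n <- 2000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(-1, 0.5, -0.25)
  p <- plogis(beta[1] + beta[2] * X$x1 + beta[3] * X$x2)
  y <- rbinom(n, 1, p)
  m <- fit_lra(X, y)
  se <- coef(summary(m$glm))[, "Std. Error"]
  expect_lt(abs(coef(m)[["(Intercept)"]] - beta[1]), 3 * se[1])
  expect_lt(abs(coef(m)[["x1"]] - beta[2]), 3 * se[2])
  expect_lt(abs(coef(m)[["x2"]] - beta[3]), 3 * se[3])
  # null data: coefficients within 3 SE of zero
  y0 <- rep(0:1, each = n / 2)
  m0 <- fit_lra(X, sample(y0))
  se0 <- coef(summary(m0$glm))[, "Std. Error"]
  expect_true(all(abs(coef(m0)) < 3 * se0))
  # perfectly separated toy set
  Xs <- data.frame(x = c(-3, -2, -1, 1, 2, 3))
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_lra(Xs, ys), "separation")
})

test_that("in-sample scores reproduce glm fitted probabilities", {
  set.seed(14)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- rbinom(80, 1, plogis(X$a - X$b))
  m <- fit_lra(X, y)
  expect_equal(score(m, as.matrix(X))$p, unname(fitted(m$glm)),
               tolerance = 1e-8)
})

test_that("the published screening model is the fixed four-variable equation", {
  m <- published_model()
  expect_length(m$coefficients, 4)
  zero <- c(hf_mt = 0, pct_lf_pre_mt = 0, pct_hf_pre_mt = 0,
            pct_hf_mt_post = 0)
  res <- score(m, zero)
  expect_equal(res$logit, -1.2895)
  expect_equal(res$p, 1 / (1 + exp(1.2895)))
  expect_identical(res$label, "healthy")
  # coefficient values and signs
  expect_equal(unname(m$coefficients),
               c(0.0013, 0.0051, -0.0001, -0.0004))
})

test_that("scoring follows the logit decision rule and monotonicity", {
  m <- published_model()
  # logit exactly 0 -> p = 0.5, suspected (>= convention)
  feats <- c(hf_mt = 1.2895 / 0.0013, pct_lf_pre_mt = 0, pct_hf_pre_mt = 0,
             pct_hf_mt_post = 0)
  r <- score(m, feats)
  expect_equal(r$logit, 0)
  expect_equal(r$p, 0.5)
  expect_identical(r$label, "suspected_mdd")
  # doubling a positively weighted feature strictly increases p
  f2 <- feats; f2[["hf_mt"]] <- 2 * f2[["hf_mt"]]
  expect_gt(score(m, f2)$p, r$p)
  expect_error(score(m, c(hf_mt = 1)), "missing feature")
  # predict() method routes through score()
  expect_equal(predict(m, feats)$logit, 0)
})

test_that("cross-validation pools folds into one confusion matrix", {
  set.seed(15)
  # perfectly separable in CV: wide margin
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- data.frame(x = y * 10 + rnorm(n, sd = 0.5))
  cv <- evaluate_cv(X, y, folds = 5, seed = 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(sum(cv$confusion), n)
  # shuffled labels: metrics near chance
  set.seed(16)
  n <- 200
  X2 <- data.frame(a = rnorm(n), b = rnorm(n))
  y2 <- sample(rep(0:1, each = n / 2))
  cv2 <- evaluate_cv(X2, y2, folds = 5, seed = 2)
  for (v in c(cv2$sensitivity, cv2$specificity, cv2$ppv, cv2$npv)) {
    expect_gte(v, 0.35); expect_lte(v, 0.65)
  }
  # Bayes consistency of pooled PPV with prevalence
  with(as.list(cv2$confusion), {
    expect_equal(cv2$ppv, tp / (tp + fp))
    expect_equal(cv2$npv, tn / (tn + fn))
  })
  expect_error(evaluate_cv(X2, rep(1, n)), "folds|class")
})

test_that("fold assignment is stratified and seed-reproducible", {
  y <- rep(0:1, c(27, 26))
  X <- data.frame(x = rnorm(53) + y)
  cv_a <- evaluate_cv(X, y, seed = 7)
  cv_b <- evaluate_cv(X, y, seed = 7)
  expect_identical(cv_a$fold_assignment, cv_b$fold_assignment)
  expect_identical(cv_a$logits, cv_b$logits)
  cv_c <- evaluate_cv(X, y, seed = 8)
  expect_false(identical(cv_a$fold_assignment, cv_c$fold_assignment))
  # every fold holds both classes
  for (f in 1:5) {
    expect_true(all(table(y[cv_a$fold_assignment == f]) > 0))
  }
})

test_that("model-size selection finds a known support", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 240
    # label = thresholded sum of exactly four features, with a margin, so
    # the four-variable model saturates accuracy and extra features tie
    X4 <- matrix(rnorm(4 * n * 3), ncol = 4)
    s <- rowSums(X4)
    keep <- which(abs(s) > 1)[1:n]
    X <- data.frame(s1 = X4[keep, 1], s2 = X4[keep, 2], s3 = X4[keep, 3],
                    s4 = X4[keep, 4], n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n))
    y <- as.integer(s[keep] > 0)
    sel <- select_model_size(X, y, max_k = 8, seed = seed)
    expect_length(sel$accuracy_curve, 8)
    if (sel$k == 4) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # single informative feature -> k* = 1
  set.seed(30)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X1 <- data.frame(sig = y * 4 + rnorm(n), a = rnorm(n), b = rnorm(n))
  expect_equal(select_model_size(X1, y, max_k = 3, seed = 1)$k, 1)
})

test_that("ROC analysis matches rank statistics and pROC", {
  # logits identical to labels -> AUC 1
  expect_equal(roc_analysis(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  # random logits: AUC ~ 0.5
  set.seed(17)
  n <- 2000
  lg <- rnorm(n); y <- rep(0:1, n / 2)
  expect_lt(abs(roc_analysis(lg, y)$auc - 0.5), 0.03)
  # equals Mann-Whitney U / (n1 n0) and pROC's AUC on arbitrary data
  set.seed(18)
  lg2 <- rnorm(300) + rep(0:1, 150); y2 <- rep(0:1, 150)
  a <- roc_analysis(lg2, y2)$auc
  w <- wilcox.test(lg2[y2 == 1], lg2[y2 == 0], exact = FALSE)$statistic
  expect_equal(a, unname(w) / (150 * 150))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(y2, lg2, quiet = TRUE, direction = "<")
  expect_equal(a, as.numeric(pROC::auc(pr)))
  expect_error(roc_analysis(lg2, rep(1, 300)), "classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(19)
  lg <- rnorm(100); y <- rbinom(100, 1, plogis(lg))
  a1 <- roc_analysis(lg, y)$auc
  expect_equal(roc_analysis(exp(lg), y)$auc, a1)
  expect_equal(roc_analysis(5 * lg - 3, y)$auc, a1)
})

test_that("the Youden-optimal cutoff takes the lowest tied threshold", {
  lg <- c(-2, -1, 1, 2)
  y <- c(0, 0, 1, 1)
  ro <- roc_analysis(lg, y)
  # J is maximal (=1) at thresholds 1 (and only there among candidates >= gap)
  expect_equal(ro$optimal_cutoff, 1)
})
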