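two_blob_features <- function(n = 20, gap = 4, seed = 31) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 0, 0.3), n / 2, 2),
             matrix(rnorm(n, gap, 0.3), n / 2, 2))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

test_that("the SVM separates linearly separable classes perfectly", {
  d <- two_blob_features()
  cl <- fit_classifier(d$x, d$y, classifier_spec("svm"))
  expect_equal(mean(predict_grades(cl, d$x) == d$y), 1.0)
})

test_that("the SVM decision respects max-margin geometry on a hand-solved set", {
  # two colinear pairs: the maximum-margin separator is the axis x1 = 0
  x <- matrix(c(-2, 0, -1, 0, 1, 0, 2, 0), 4, 2, byrow = TRUE)
  y <- c(0L, 0L, 1L, 1L)
  cl <- fit_classifier(x, y, classifier_spec("svm", C = 10))
  probe <- matrix(c(-0.4, 0, 0.4, 0, -1.5, 0, 1.5, 0), 4, 2, byrow = TRUE)
  expect_equal(predict_grades(cl, probe), c(0L, 1L, 0L, 1L))
})

test_that("seeded stochastic heads are reproducible", {
  d <- two_blob_features(n = 40, gap = 2)
  for (kind in c("random_forest", "xgboost")) {
    c1 <- fit_classifier(d$x, d$y, classifier_spec(kind, seed = 9))
    c2 <- fit_classifier(d$x, d$y, classifier_spec(kind, seed = 9))
    expect_identical(predict_grades(c1, d$x), predict_grades(c2, d$x))
    expect_identical(predict_scores(c1, d$x), predict_scores(c2, d$x))
  }
})

test_that("scores behave as probabilities and argmax matches hard predictions", {
  set.seed(32)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- sample(0:2, 60, replace = TRUE)
  for (kind in c("svm", "random_forest", "xgboost", "softmax_head")) {
    cl <- fit_classifier(x, y, classifier_spec(kind))
    sc <- predict_scores(cl, x)
    expect_equal(dim(sc), c(60L, 3L))
    expect_equal(rowSums(sc), rep(1, 60), tolerance = 1e-6)
    expect_identical(predict_grades(cl, x), cl$classes[max.col(sc, ties.method = "first")])
    # empty batches pass through without error
    empty <- predict_scores(cl, x[0, , drop = FALSE])
    expect_equal(nrow(empty), 0L)
    expect_length(predict_grades(cl, x[0, , drop = FALSE]), 0L)
  }
})

test_that("an unconstrained forest memorizes 10 distinct points", {
  set.seed(33)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(0:1, 5)
  cl <- fit_classifier(x, y, classifier_spec("random_forest", n_estimators = 200L))
  expect_equal(predict_grades(cl, x), y)
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_classifier(x, rep(0L, 10)), "at least two classes")
  x[3, 1] <- NaN
  expect_error(fit_classifier(x, rep(0:1, 5)), "non-finite")
  d <- two_blob_features()
  cl <- fit_classifier(d$x, d$y, classifier_spec("svm"))
  expect_error(predict_scores(cl, d$x[, 1, drop = FALSE]), "dimension")
})

test_that("precision and recall follow their one-vs-rest definitions", {
  # 10 predicted positives of which 9 are true -> precision 0.9
  ya <- c(rep(1L, 9), rep(0L, 11))
  pa <- c(rep(1L, 10), rep(0L, 10))
  ra <- compute_metrics(ya, pa)
  expect_equal(ra$per_class$precision[ra$per_class$class == 1], 0.9)
  # 10 actual positives of which 8 are found -> recall 0.8
  yb <- c(rep(1L, 10), rep(0L, 10))
  pb <- c(rep(1L, 8), rep(0L, 12))
  rb <- compute_metrics(yb, pb)
  expect_equal(rb$per_class$recall[rb$per_class$class == 1], 0.8)
})

test_that("perfect and inverted score orderings give AUC 1 and 0", {
  y <- rep(c(0L, 1L), each = 5)
  sc_perfect <- cbind(rev(seq(0.1, 1, length.out = 10)), seq(0.1, 1, length.out = 10))
  r <- compute_metrics(y, y, sc_perfect)
  expect_equal(r$accuracy, 1.0)
  expect_equal(unname(r$auc_per_class), c(1, 1))
  r_inv <- compute_metrics(y, y, sc_perfect[, c(2, 1)])
  expect_equal(unname(r_inv$auc_per_class), c(0, 0))
})

test_that("accuracy identity: confusion trace equals pooled TP-based accuracy", {
  set.seed(34)
  y_true <- sample(0:4, 200, replace = TRUE)
  y_pred <- ifelse(runif(200) < 0.6, y_true, sample(0:4, 200, replace = TRUE))
  r <- compute_metrics(y_true, y_pred)
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  # pooled TP/TN/FP/FN over one-vs-rest also reproduce it
  K <- 5; n <- 200
  tp <- diag(r$confusion); fp <- colSums(r$confusion) - tp
  fn <- rowSums(r$confusion) - tp; tn <- n - tp - fp - fn
  pooled <- (sum(tp) + sum(tn)) / (sum(tp) + sum(tn) + sum(fp) + sum(fn))
  expect_equal(r$accuracy, sum(tp) / n)
  expect_equal(pooled, (sum(tp) + sum(tn)) / (K * n))
})

test_that("reported F1 is the harmonic mean of reported precision and recall", {
  set.seed(35)
  y_true <- sample(0:3, 120, replace = TRUE)
  y_pred <- ifelse(runif(120) < 0.5, y_true, sample(0:3, 120, replace = TRUE))
  r <- compute_metrics(y_true, y_pred)
  pc <- r$per_class
  for (k in seq_len(nrow(pc))) {
    p <- pc$precision[k]; rec <- pc$recall[k]
    if (!is.na(rec) && p + rec > 0)
      expect_equal(pc$f1[k], 2 * p * rec / (p + rec), tolerance = 1e-12)
  }
})

test_that("random score orderings give chance-level AUC on balanced labels", {
  set.seed(36)
  y <- rep(c(0L, 1L), each = 25)
  aucs <- replicate(1000, {
    sc1 <- runif(50)
    r <- compute_metrics(y, y, cbind(1 - sc1, sc1))
    unname(r$auc_per_class[2])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("metrics are invariant to sample order", {
  set.seed(37)
  y_true <- sample(0:2, 90, replace = TRUE)
  y_pred <- sample(0:2, 90, replace = TRUE)
  sc <- matrix(runif(270), 90, 3)
  sc <- sc / rowSums(sc)
  r1 <- compute_metrics(y_true, y_pred, sc)
  perm <- sample(90)
  r2 <- compute_metrics(y_true[perm], y_pred[perm], sc[perm, ])
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$macro_f1, r2$macro_f1)
  expect_equal(r1$auc_per_class, r2$auc_per_class)
})

test_that("one-vs-rest AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  y_true <- sample(0:2, 80, replace = TRUE)
  sc <- matrix(runif(240), 80, 3); sc <- sc / rowSums(sc)
  r <- compute_metrics(y_true, max.col(sc) - 1L, sc)
  for (k in 0:2) {
    ref <- suppressMessages(pROC::auc(pROC::roc(y_true == k, sc[, k + 1],
                                                direction = "<", quiet = TRUE)))
    expect_equal(unname(r$auc_per_class[as.character(k)]), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("a class absent from the truth is flagged and excluded from macros", {
  y_true <- c(0L, 0L, 1L, 1L)
  y_pred <- c(0L, 2L, 1L, 1L)
  expect_warning(r <- compute_metrics(y_true, y_pred, classes = 0:2),
                 "absent from y_true")
  expect_true(is.na(r$per_class$recall[r$per_class$class == 2]))
  expect_equal(r$macro_recall, mean(r$per_class$recall[1:2]))
})

test_that("reports serialize to JSON and CSV", {
  y <- rep(0:1, each = 10)
  r <- compute_metrics(y, y, cbind(rep(1:0, each = 10), rep(0:1, each = 10)))
  dir <- tempfile("report_")
  js <- file.path(tempdir(), "report.json")
  write_report(r, js, csv_dir = dir)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$accuracy, 1)
  expect_true(file.exists(file.path(dir, "confusion.csv")))
  unlink(c(js, dir), recursive = TRUE)
})

test_that("the SVM grid search returns a grid-member optimum", {
  d <- two_blob_features(n = 30, gap = 3)
  gs <- svm_grid_search(d$x, d$y, C_grid = c(0.5, 5), folds = 2L, seed = 4)
  expect_true(gs$C %in% c(0.5, 5))
  expect_true(all(gs$accuracy$accuracy >= 0 & gs$accuracy$accuracy <= 1))
})
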