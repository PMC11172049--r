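#' Classical classifier head specification
#'
#' Describes one of the four heads that classify the pooled Wavelet-CNN
#' features: an RBF-kernel SVM, a random forest, gradient-boosted trees
#' (XGBoost), or a plain multinomial softmax head.  Tree-based heads
#' default to 10 estimators to limit overfitting on the modest feature
#' sets they see.
#'
#' @param kind One of `"svm"`, `"random_forest"`, `"xgboost"`,
#'   `"softmax_head"`.
#' @param C SVM misclassification penalty (soft-margin trade-off).
#' @param gamma RBF kernel width; `NULL` means `1/d` for `d` features.
#' @param n_estimators Number of trees / boosting rounds for the tree
#'   heads.
#' @param seed Seed for the stochastic heads.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm", "random_forest", "xgboost", "softmax_head"),
                            C = 1, gamma = NULL, n_estimators = 10L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, C = C, gamma = gamma,
                 n_estimators = as.integer(n_estimators), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a classifier head on feature vectors
#'
#' @param features `n x d` numeric matrix (e.g. from
#'   [extract_features()]).  All entries must be finite.
#' @param labels Integer grades, one per row; at least two distinct
#'   classes must be present.
#' @param spec A [classifier_spec()].
#' @return A fitted head of class `wcnn_classifier` exposing hard
#'   predictions and per-class scores via [predict_grades()] and
#'   [predict_scores()].
#' @export
fit_classifier <- function(features, labels, spec = classifier_spec()) {
  features <- as.matrix(features)
  if (!all(is.finite(features)))
    stop("features contain non-finite values; refusing to fit", call. = FALSE)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least two classes to fit a classifier", call. = FALSE)
  d <- ncol(features)
  restore <- local_rng(spec$seed)
  on.exit(restore(), add = TRUE)
  yf <- factor(labels, levels = classes)
  # margin-based heads need commensurate feature scales; tree heads do not
  scaler <- NULL
  if (spec$kind %in% c("svm", "softmax_head")) {
    mu <- colMeans(features)
    sdv <- apply(features, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    scaler <- list(mu = mu, sd = sdv)
    features <- scale_features(features, scaler)
  }
  fit <- switch(spec$kind,
    svm = e1071::svm(features, yf, kernel = "radial",
                     cost = spec$C, gamma = spec$gamma %||% (1 / d),
                     probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(features, yf, ntree = spec$n_estimators),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(features,
                                     label = match(labels, classes) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = length(classes),
                                       nthread = 1L, seed = spec$seed),
                         data = dtrain, nrounds = spec$n_estimators, verbose = 0)
    },
    softmax_head = {
      df <- data.frame(y = yf, features)
      nnet::multinom(y ~ ., data = df, trace = FALSE,
                     MaxNWts = (d + 2L) * length(classes) + 10L, maxit = 200)
    })
  structure(list(kind = spec$kind, fit = fit, classes = classes, d = d,
                 spec = spec, scaler = scaler),
            class = "wcnn_classifier")
}

scale_features <- function(features, scaler) {
  sweep(sweep(features, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

#' Predict grades or per-class scores from a fitted head
#'
#' `predict_grades` returns hard class labels; `predict_scores` the
#' `n x K` matrix of per-class scores (class probabilities for every
#' head), with columns ordered by grade.  For every head the argmax of the
#' score rows equals the hard prediction.
#'
#' @param classifier A fitted `wcnn_classifier`.
#' @param features `n x d` matrix; `d` must match the training dimension.
#' @return An integer vector of grades, or an `n x K` numeric matrix.
#' @export
predict_grades <- function(classifier, features) {
  sc <- predict_scores(classifier, features)
  if (nrow(sc) == 0L) return(integer(0))
  classifier$classes[max.col(sc, ties.method = "first")]
}

#' @rdname predict_grades
#' @export
predict_scores <- function(classifier, features) {
  stopifnot(inherits(classifier, "wcnn_classifier"))
  features <- as.matrix(features)
  K <- length(classifier$classes)
  if (nrow(features) == 0L)
    return(matrix(numeric(0), 0L, K, dimnames = list(NULL, classifier$classes)))
  if (ncol(features) != classifier$d)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(features), classifier$d), call. = FALSE)
  if (!is.null(classifier$scaler))
    features <- scale_features(features, classifier$scaler)
  lev <- as.character(classifier$classes)
  sc <- switch(classifier$kind,
    svm = {
      pr <- stats::predict(classifier$fit, features, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, lev, drop = FALSE]
    },
    random_forest = {
      p <- stats::predict(classifier$fit, features, type = "prob")
      p[, lev, drop = FALSE]
    },
    xgboost = {
      p <- stats::predict(classifier$fit, xgboost::xgb.DMatrix(features))
      if (is.null(dim(p))) p <- matrix(p, nrow(features), K, byrow = TRUE)
      dimnames(p) <- list(NULL, lev)
      p
    },
    softmax_head = {
      df <- data.frame(features)
      colnames(df) <- paste0("X", seq_len(ncol(features)))
      p <- stats::predict(classifier$fit, newdata = df, type = "probs")
      if (is.null(dim(p))) {      # two-class multinom returns P(second level)
        p <- cbind(1 - p, p)
      }
      colnames(p) <- lev
      p
    })
  sc <- as.matrix(sc)
  dimnames(sc) <- list(NULL, lev)
  sc
}

#' Evaluation report for multiclass grading
#'
#' Computes the full evaluation suite over hard predictions and per-class
#' scores: the K x K confusion matrix (rows = true grade, columns =
#' predicted), per-class one-vs-rest precision, recall and F1 from the
#' per-class TP/FP/TN/FN counts, their unweighted macro averages, overall
#' accuracy, and one-vs-rest ROC curves with trapezoidal AUC per class
#' plus the macro AUC.
#'
#' Degenerate cases follow common practice and are surfaced: a class with
#' no predicted positives gets precision 0 with a warning; a class absent
#' from `y_true` gets `NA` recall/F1/AUC and is excluded from the macro
#' averages with a warning.
#'
#' @param y_true Integer grades.
#' @param y_pred Integer predicted grades, same length.
#' @param scores Optional `n x K` score matrix (class order = sorted grade
#'   order) for the ROC/AUC block.
#' @param classes Grade set; defaults to the sorted union of `y_true` and
#'   `y_pred`.
#' @return An object of class `evaluation_report`.
#' @examples
#' r <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' r$accuracy
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  n <- length(y_true)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  K <- length(classes)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  lab <- as.character(classes)
  confusion <- matrix(0L, K, K, dimnames = list(true = lab, predicted = lab))
  ti <- match(y_true, classes); pi <- match(y_pred, classes)
  for (i in seq_len(n)) confusion[ti[i], pi[i]] <- confusion[ti[i], pi[i]] + 1L
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  present <- rowSums(confusion) > 0L
  precision <- recall <- f1 <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (tp[k] + fp[k] == 0L) {
      warning(sprintf("class %s: no predicted positives; precision reported as 0", lab[k]),
              call. = FALSE)
      precision[k] <- 0
    } else precision[k] <- tp[k] / (tp[k] + fp[k])
    if (!present[k]) {
      warning(sprintf("class %s absent from y_true; recall/F1 undefined, excluded from macro",
                      lab[k]), call. = FALSE)
    } else {
      recall[k] <- tp[k] / (tp[k] + fn[k])
      f1[k] <- if (precision[k] + recall[k] > 0)
        2 * precision[k] * recall[k] / (precision[k] + recall[k]) else 0
    }
  }
  auc <- rep(NA_real_, K); roc <- vector("list", K); names(roc) <- lab
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != n || ncol(scores) != K)
      stop(sprintf("scores must be %d x %d", n, K), call. = FALSE)
    for (k in seq_len(K)) {
      pos <- ti == k
      if (!any(pos) || all(pos)) next
      rc <- roc_points(scores[, k], pos)
      roc[[k]] <- rc
      auc[k] <- trapezoid_auc(rc$fpr, rc$tpr)
    }
  }
  macro <- function(v) if (any(present)) mean(v[present]) else NA_real_
  structure(list(
    confusion = confusion, classes = classes,
    per_class = data.frame(class = classes, precision = precision,
                           recall = recall, f1 = f1, auc = auc,
                           support = rowSums(confusion)),
    macro_precision = macro(precision), macro_recall = macro(recall),
    macro_f1 = macro(f1),
    accuracy = sum(tp) / n,
    auc_per_class = stats::setNames(auc, lab),
    macro_auc = if (any(!is.na(auc))) mean(auc, na.rm = TRUE) else NA_real_,
    roc_curves = roc, n = n),
    class = "evaluation_report")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return The F1 score `2 * p * r / (p + r)` (0 when both are 0).
#' @examples
#' f1_score(0.857, 0.849)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

# one-vs-rest ROC by threshold sweep over the positive-class score
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tps <- cumsum(pos); fps <- cumsum(!pos)
  # collapse ties: keep the last point of each distinct score value
  keep <- c(diff(score[ord]) != 0, TRUE)
  tpr <- c(0, tps[keep]) / sum(positive)
  fpr <- c(0, fps[keep]) / sum(!positive)
  data.frame(fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples, %d classes\n", x$n, length(x$classes)))
  cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  macro precision/recall/F1: %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  if (!is.na(x$macro_auc)) cat(sprintf("  macro one-vs-rest AUC: %.4f\n", x$macro_auc))
  cat("  confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the scalar metrics and per-class table to JSON, and optionally
#' the confusion matrix and ROC points to CSV files alongside.
#'
#' @param report An `evaluation_report`.
#' @param json_path Path for the JSON report.
#' @param csv_dir Optional directory for `confusion.csv` and
#'   `roc_class<k>.csv` files.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_dir = NULL) {
  obj <- list(accuracy = report$accuracy,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1,
              macro_auc = report$macro_auc,
              per_class = report$per_class,
              confusion = unclass(report$confusion),
              n = report$n)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$confusion, file.path(csv_dir, "confusion.csv"))
    for (k in seq_along(report$roc_curves)) {
      rc <- report$roc_curves[[k]]
      if (!is.null(rc))
        utils::write.csv(rc, file.path(csv_dir, sprintf("roc_class%s.csv",
                                                        report$classes[k])),
                         row.names = FALSE)
    }
  }
  invisible(json_path)
}

#' Small grid search for SVM hyper-parameters
#'
#' Cross-validated accuracy over a (C, gamma) grid, returning the best
#' pair.  Intended for modest feature sets.
#'
#' @param features `n x d` matrix.
#' @param labels Integer grades.
#' @param C_grid,gamma_grid Candidate values; `NULL` gamma entries mean
#'   `1/d`.
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @return A list with `C`, `gamma` and the CV `accuracy` table.
#' @export
svm_grid_search <- function(features, labels, C_grid = c(0.1, 1, 10),
                            gamma_grid = NULL, folds = 3L, seed = 1L) {
  features <- as.matrix(features)
  d <- ncol(features)
  if (is.null(gamma_grid)) gamma_grid <- c(0.1 / d, 1 / d, 10 / d)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  fold <- sample(rep_len(seq_len(folds), nrow(features)))
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      cl <- fit_classifier(features[tr, , drop = FALSE], labels[tr],
                           classifier_spec("svm", C = grid$C[g], gamma = grid$gamma[g],
                                           seed = seed))
      acc[f] <- mean(predict_grades(cl, features[!tr, , drop = FALSE]) == labels[!tr])
    }
    grid$accuracy[g] <- mean(acc)
  }
  best <- grid[which.max(grid$accuracy), ]
  list(C = best$C, gamma = best$gamma, accuracy = grid)
}
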