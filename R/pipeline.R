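#' Fit a Wavelet CNN grader
#'
#' High-level fitting interface: builds the network for `config`, trains
#' it on a batch of preprocessed images, and returns a classed model
#' object with the usual accessor methods (`print`, `summary`, `predict`,
#' `plot`).
#'
#' @param x `H x W x C x N` array of preprocessed images.
#' @param y Integer grades in `0..(num_classes - 1)`.
#' @param config A [wcnn_config()].
#' @param train A [wcnn_train_config()].
#' @return An object of class `wavelet_cnn` with components `network`
#'   (the trained `wcnn_network`), `history`, `config` and `classes`.
#' @examples
#' \donttest{
#' cfg <- wcnn_tiny_config(input_side = 32, block_widths = c(8, 16, 24))
#' ph <- lapply(0:4, function(g) render_phantom(g, phantom_config(32), seed = g + 1))
#' x <- array(0, c(32, 32, 3, 5))
#' for (i in 1:5) x[, , , i] <- ph[[i]]$image
#' fit <- wavelet_cnn(x, 0:4, cfg, wcnn_train_config(max_epochs = 2))
#' predict(fit, x, type = "class")
#' }
#' @export
wavelet_cnn <- function(x, y, config = wcnn_config(),
                        train = wcnn_train_config()) {
  net <- build_network(config)
  net <- wcnn_train(net, x, y, train)
  structure(list(network = net, history = net$history, config = config,
                 train_config = train,
                 classes = seq_len(config$num_classes) - 1L),
            class = "wavelet_cnn")
}

#' @export
print.wavelet_cnn <- function(x, ...) {
  print(x$network)
  if (!is.null(x$history))
    cat(sprintf("  final training accuracy: %.3f (epoch %d)\n",
                max(x$history$accuracy), nrow(x$history)))
  invisible(x)
}

#' @export
summary.wavelet_cnn <- function(object, ...) {
  print(object)
  cat("\nLayer table:\n")
  print(wcnn_layer_table(object$network))
  invisible(object)
}

#' Predict from a fitted Wavelet CNN
#'
#' @param object A `wavelet_cnn` fit.
#' @param newdata `H x W x C x N` array.
#' @param type `"class"` for hard grades, `"prob"` for softmax
#'   probabilities, `"feature"` for the GAP feature matrix.
#' @param ... Unused.
#' @return Grades, an `N x K` probability matrix, or an `N x d` feature
#'   matrix.
#' @export
predict.wavelet_cnn <- function(object, newdata,
                                type = c("class", "prob", "feature"), ...) {
  type <- match.arg(type)
  if (type == "feature") return(extract_features(object$network, newdata))
  p <- wcnn_predict_probs(object$network, newdata)
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' @export
plot.wavelet_cnn <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "b", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Run the full grading pipeline end to end
#'
#' Generates a synthetic phantom dataset, splits it (stratified 80/20),
#' balances the training partition by augmentation, preprocesses and
#' loads both partitions, trains the Wavelet CNN, extracts GAP features,
#' fits the requested classifier heads on the training features, and
#' evaluates each head on the held-out test set.  All stage seeds derive
#' from the single `seed` argument, so a rerun reproduces every metric.
#'
#' @param seed Master seed.
#' @param n_per_class Phantoms per grade.
#' @param phantom A [phantom_config()] (its `seed` is overridden).
#' @param model A [wcnn_config()]; its `input_side` must match
#'   `preprocess$crop_side`.
#' @param train A [wcnn_train_config()].
#' @param preprocess A [preprocess_config()]; `NULL` derives one from the
#'   model input side (resize to `9/8` of the side, crop back).
#' @param split A [split_config()].
#' @param aug An [augmentation_config()].
#' @param heads Character vector of classifier kinds to compare.
#' @param out_dir Optional directory: phantom PNGs, per-head JSON
#'   reports, confusion/ROC CSVs and a provenance file are written there.
#' @return A list with `reports` (per head), `summary` (data.frame of
#'   accuracy / macro-F1 / macro-AUC per head), `best_head`, `history`,
#'   `model` (the `wavelet_cnn` fit) and the split manifests.
#' @export
wcnn_e2e <- function(seed = 1L, n_per_class = 50L,
                     phantom = phantom_config(),
                     model = wcnn_tiny_config(),
                     train = wcnn_train_config(max_epochs = 30L, batch_size = 25L),
                     preprocess = NULL, split = split_config(),
                     aug = augmentation_config(),
                     heads = c("svm", "random_forest", "xgboost", "softmax_head"),
                     out_dir = tempfile("wcnn_e2e_")) {
  seed <- as.integer(seed)
  phantom$seed <- seed
  split$seed <- seed + 1L
  aug$seed <- seed + 2L
  model$seed <- seed + 3L
  train$seed <- seed + 4L
  if (is.null(preprocess)) {
    side <- model$input_side
    preprocess <- preprocess_config(resize_side = as.integer(round(side * 9 / 8)),
                                    crop_side = side, seed = seed + 6L)
  }
  if (preprocess$crop_side != model$input_side)
    stop("preprocess$crop_side must equal model$input_side", call. = FALSE)
  if (phantom$image_side < preprocess$crop_side)
    phantom$image_side <- preprocess$resize_side
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- generate_dataset(n_per_class, phantom, file.path(out_dir, "images"))
  parts <- split_manifest(manifest, split)
  train_manifest <- balance_classes(parts$train, aug)

  tr <- load_images(train_manifest, preprocess, training = TRUE)
  te <- load_images(parts$test, preprocess, training = FALSE)

  fit <- wavelet_cnn(tr$x, tr$y, model, train)
  ftr <- predict(fit, tr$x, type = "feature")
  fte <- predict(fit, te$x, type = "feature")

  reports <- list()
  for (h in heads) {
    cl <- fit_classifier(ftr, tr$y, classifier_spec(h, seed = seed + 5L))
    pred <- predict_grades(cl, fte)
    sc <- predict_scores(cl, fte)
    reports[[h]] <- compute_metrics(te$y, pred, sc, classes = fit$classes)
  }
  summary_df <- data.frame(
    head = names(reports),
    accuracy = vapply(reports, `[[`, 0, "accuracy"),
    macro_f1 = vapply(reports, `[[`, 0, "macro_f1"),
    macro_auc = vapply(reports, `[[`, 0, "macro_auc"),
    row.names = NULL)
  best_head <- summary_df$head[which.max(summary_df$macro_f1)]

  for (h in names(reports))
    write_report(reports[[h]], file.path(out_dir, paste0("report_", h, ".json")),
                 csv_dir = file.path(out_dir, paste0("eval_", h)))
  provenance <- list(seed = seed, n_per_class = n_per_class,
                     model = unclass(model), train = unclass(train),
                     preprocess = list(resize_side = preprocess$resize_side,
                                       crop_side = preprocess$crop_side,
                                       seed = preprocess$seed),
                     split = unclass(split), heads = heads,
                     timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)

  list(reports = reports, summary = summary_df, best_head = best_head,
       history = fit$history, model = fit,
       train_manifest = train_manifest, test_manifest = parts$test,
       out_dir = out_dir)
}
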