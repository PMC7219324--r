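#' Predict one sample from its 30-view set
#'
#' Runs a forward pass on every view, averages the 30 per-view softmax
#' vectors and takes the argmax (ties broken toward the lowest class index
#' in the fixed vocabulary order).
#'
#' @param net Model (anything with a [predict_logits()] method).
#' @param views A [test_views()] result with exactly 30 views (10 temporal x
#'   3 spatial); any other count is a protocol error.
#' @param view_batch Number of views forwarded per batch.
#' @return List with `label` (class name), `label_index`, `mean_softmax` and
#'   `view_softmax` (n_views x n_classes matrix).
#' @export
predict_sample <- function(net, views, view_batch = 10L) {
  stopifnot(inherits(views, "view_set"))
  if (views$n_views != 30L)
    stop("inference protocol requires exactly 30 views, got ", views$n_views)
  probs <- NULL
  for (from in seq(1L, views$n_views, by = view_batch)) {
    idx <- from:min(from + view_batch - 1L, views$n_views)
    vs_list <- lapply(idx, function(i) get_view(views, i))
    xs <- stack_batch(lapply(vs_list, function(v) frames_to_tensor(v$slow)))
    xf <- stack_batch(lapply(vs_list, function(v) frames_to_tensor(v$fast)))
    logits <- predict_logits(net, xs, xf)
    probs <- rbind(probs, t(softmax_cols(logits)))
  }
  mean_softmax <- colMeans(probs)
  label_index <- which.max(mean_softmax)  # which.max takes the first maximum
  list(label = behavior_classes()[label_index], label_index = label_index,
       mean_softmax = mean_softmax, view_softmax = probs)
}

#' Evaluate a model over a labeled dataset with the 30-view protocol
#'
#' Computes top-1 accuracy over per-sample view-averaged predictions, views
#' accuracy over all individual view argmaxes, the confusion matrix (rows =
#' ground truth, vocabulary order) and per-class rates.
#'
#' @param net Model.
#' @param data A `synthetic_dataset` or list with `clips` and `labels`, or a
#'   manifest data.frame (then `data_dir` locates the clips).
#' @param data_dir Directory for manifest-relative clip paths.
#' @param scale,crop_size,window_len Inference protocol geometry.
#' @param slow_stride,fast_stride Pathway strides.
#' @param view_batch Views per forward batch.
#' @return An `eval_report`: `top1_accuracy`, `views_accuracy`, `confusion`,
#'   `per_class_rate`, `n_samples`.
#' @export
evaluate <- function(net, data, data_dir = NULL, scale = 240L,
                     crop_size = 240L, window_len = 64L,
                     slow_stride = 8L, fast_stride = 2L, view_batch = 10L) {
  vocab <- behavior_classes()
  if (is.data.frame(data)) {
    validate_manifest(data)
    paths <- if (is.null(data_dir)) data$clip_path
             else file.path(data_dir, data$clip_path)
    clips <- vector("list", nrow(data))
    keep <- logical(nrow(data))
    for (i in seq_len(nrow(data))) {
      clips[[i]] <- tryCatch(read_clip(paths[i], fps = data$fps[i]),
                             error = function(e) {
                               warning("failed to read clip ", paths[i],
                                       ": ", conditionMessage(e))
                               NULL
                             })
      keep[i] <- !is.null(clips[[i]])
    }
    labels <- data$label[keep]
    clips <- clips[keep]
  } else {
    clips <- data$clips
    labels <- data$labels
  }
  if (!all(labels %in% vocab)) stop("labels outside the class vocabulary")
  k <- length(vocab)
  confusion <- matrix(0L, k, k, dimnames = list(truth = vocab, predicted = vocab))
  n_views_total <- 0L
  n_views_correct <- 0L
  for (i in seq_along(clips)) {
    vs <- test_views(clips[[i]], scale = scale, crop_size = crop_size,
                     window_len = window_len, slow_stride = slow_stride,
                     fast_stride = fast_stride)
    pred <- predict_sample(net, vs, view_batch = view_batch)
    truth <- match(labels[i], vocab)
    confusion[truth, pred$label_index] <- confusion[truth, pred$label_index] + 1L
    view_labels <- max.col(pred$view_softmax, ties.method = "first")
    n_views_correct <- n_views_correct + sum(view_labels == truth)
    n_views_total <- n_views_total + nrow(pred$view_softmax)
  }
  m <- metrics_from_confusion(confusion)
  structure(list(top1_accuracy = m$top1,
                 views_accuracy = n_views_correct / n_views_total,
                 confusion = confusion,
                 per_class_rate = m$per_class_rate,
                 n_samples = length(clips)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("top-1 accuracy: %.2f%%   views accuracy: %.2f%%   (n = %d)\n",
              100 * x$top1_accuracy, 100 * x$views_accuracy, x$n_samples))
  cat("confusion (rows = ground truth):\n")
  print(x$confusion)
  cat("per-class rate (%):\n")
  print(round(100 * x$per_class_rate, 2))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Top-1 accuracy is `trace / total`; the per-class rate is the row-wise
#' (ground-truth-conditioned) diagonal proportion, i.e. per-class recall.
#' Rows summing to zero (classes absent from the evaluation set) yield `NA`.
#'
#' @param confusion Square matrix of non-negative counts, rows = ground
#'   truth.
#' @return List with `top1` and `per_class_rate` (proportions in `[0, 1]`).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix entries must be non-negative")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix has no observations")
  rs <- rowSums(confusion)
  per_class <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  names(per_class) <- rownames(confusion)
  list(top1 = sum(diag(confusion)) / total, per_class_rate = per_class)
}

#' Write an evaluation report
#'
#' Emits the metrics as JSON (with the confusion matrix) and the confusion
#' matrix alone as CSV.
#'
#' @param report An `eval_report`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      top1_accuracy = report$top1_accuracy,
      views_accuracy = report$views_accuracy,
      per_class_rate = as.list(report$per_class_rate),
      n_samples = report$n_samples,
      confusion = report$confusion
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(report$confusion, csv_path)
  invisible(report)
}
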