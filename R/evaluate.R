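# Evaluation harness: confusion-matrix metrics, the feature-ablation
# experiment (retrain with one block deleted) and the sliding-window-size
# sweep.

#' Tally a confusion matrix
#'
#' A residue is called a site when its predicted probability is greater
#' than or equal to the threshold.
#'
#' @param y_true Integer 0/1 labels.
#' @param y_prob Predicted site probabilities.
#' @param threshold Decision threshold in (0, 1).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("y_true and y_prob have different lengths", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  call_ <- as.integer(y_prob >= threshold)
  y <- as.integer(y_true)
  structure(list(
    tp = sum(y == 1L & call_ == 1L),
    fp = sum(y == 0L & call_ == 1L),
    tn = sum(y == 0L & call_ == 0L),
    fn = sum(y == 1L & call_ == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp=", x$tp, " fp=", x$fp, " tn=", x$tn,
      " fn=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Ratios with a zero denominator are reported as 0 (with a warning unless
#' `quiet = TRUE`).
#'
#' @param counts A `confusion_counts` object.
#' @param quiet Suppress zero-denominator warnings.
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts, quiet = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0L) stop("no samples to evaluate", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) warning(what, " undefined (zero denominator); reporting 0",
                          call. = FALSE)
      0
    } else num / den
  }
  precision <- ratio(counts$tp, counts$tp + counts$fp, "precision")
  recall <- ratio(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (precision + recall == 0) {
    if (!quiet) warning("F1 undefined (precision + recall = 0); reporting 0",
                        call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (counts$tp + counts$tn) / n,
                 precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2pr/(p+r)`; 0 when both are 0.
#'
#' @param precision,recall Scalars in [0, 1].
#' @return Scalar F1.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Evaluate a trained model on a dataset partition
#'
#' @param model A `han_model`.
#' @param dataset The `han_dataset` the model was trained on.
#' @param partition `"test"` (default) or `"train"`.
#' @param threshold Decision threshold (defaults to the model's config).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, dataset, partition = "test",
                           threshold = model$config$threshold) {
  stopifnot(inherits(model, "han_model"), inherits(dataset, "han_dataset"))
  tab <- dataset$fragments[dataset$fragments$split == partition, , drop = FALSE]
  if (nrow(tab) == 0L) stop("partition '", partition, "' is empty", call. = FALSE)
  p <- forward_rows(dataset, tab, model$params)
  classification_metrics(confusion_counts(tab$label, p, threshold),
                         quiet = TRUE)
}

#' Feature-ablation experiment
#'
#' Deletes one feature block from the fused input (shrinking the input
#' width; with `mode = "zero"` the block is zero-filled instead), retrains
#' the model from scratch under the otherwise identical configuration and
#' seed, and evaluates on the test partition. Dropping every block in turn
#' mirrors the published ablation variants (sequence one-hot, PSSM,
#' secondary structure, hydropathy, location, pre-training vector).
#'
#' @param records Labeled [protein_record]s.
#' @param feature_source Feature source.
#' @param config Baseline [han_config()].
#' @param drop Block to delete: one of
#'   `"one_hot", "pssm", "ss9", "hydropathy", "rel_pos", "embedding"`.
#' @param mode `"delete"` (default; removes the columns) or `"zero"`.
#' @return A `metrics_report` for the ablated model on the test split.
#' @export
ablate_feature <- function(records, feature_source, config, drop,
                           mode = c("delete", "zero")) {
  mode <- match.arg(mode)
  if (!(drop %in% BLOCK_NAMES)) {
    stop("unknown feature block: ", drop, call. = FALSE)
  }
  cfg <- if (mode == "delete") {
    vals <- unclass(config)
    vals$blocks <- setdiff(config$blocks, drop)
    do.call(han_config, vals)
  } else config
  source <- if (mode == "zero") zeroed_source(feature_source, drop) else feature_source
  ds <- build_dataset(records, source, cfg)
  model <- han_train(ds, cfg)
  evaluate_model(model, ds)
}

# Wrap a feature source so one block is zero-filled after featurization.
zeroed_source <- function(source, drop) {
  structure(list(kind = "zeroed", inner = source, drop = drop),
            class = "han_feature_source")
}

#' Sliding-window size sweep
#'
#' Rebuilds fragments and retrains the model for each window size under
#' the same seed, evaluating on the test partition.
#'
#' @param records Labeled [protein_record]s.
#' @param feature_source Feature source.
#' @param config Baseline [han_config()].
#' @param sizes Odd window lengths (default the published sweep
#'   7, 9, 11, 13, 15).
#' @return Data frame with one row per size: `w`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
window_sweep <- function(records, feature_source, config,
                         sizes = c(7L, 9L, 11L, 13L, 15L)) {
  if (any(sizes %% 2L == 0L)) {
    stop("window sizes must be odd: ", paste(sizes[sizes %% 2L == 0L],
                                             collapse = ", "), call. = FALSE)
  }
  rows <- lapply(sizes, function(w) {
    vals <- unclass(config)
    vals$w <- as.integer(w)
    cfg <- do.call(han_config, vals)
    ds <- build_dataset(records, feature_source, cfg)
    model <- han_train(ds, cfg)
    m <- evaluate_model(model, ds)
    data.frame(w = w, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  do.call(rbind, rows)
}
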