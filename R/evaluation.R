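#' Confusion matrix of a prediction set
#'
#' @param preds an `rm_predictions` data.frame (columns `predicted`,
#'   `truth`).
#' @param positive_label the positive class (PD by convention).
#' @return list of class `confusion_matrix` with counts `tp`, `fp`, `tn`,
#'   `fn`; the four counts partition the predictions.
#' @export
confusion <- function(preds, positive_label = "PD") {
  rm_assert(nrow(preds) > 0, "no predictions to score",
            "restmotion_data_error")
  labels <- unique(c(preds$predicted, preds$truth))
  if (length(setdiff(labels, positive_label)) > 1) {
    rm_stop(sprintf("unknown label(s): %s",
                    paste(setdiff(labels, positive_label), collapse = ", ")),
            "restmotion_data_error")
  }
  pos <- preds$truth == positive_label
  hat <- preds$predicted == positive_label
  structure(list(tp = sum(pos & hat), fn = sum(pos & !hat),
                 fp = sum(!pos & hat), tn = sum(!pos & !hat),
                 positive = positive_label),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Performance metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`. A metric whose denominator is
#' zero is flagged undefined (`NA`).
#'
#' @param cm a `confusion_matrix`.
#' @return list of class `metric_set` with the four metrics.
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  rm_assert(total > 0, "empty confusion matrix", "restmotion_data_error")
  structure(list(
    sensitivity = safe_ratio(cm$tp, cm$tp + cm$fn),
    specificity = safe_ratio(cm$tn, cm$tn + cm$fp),
    precision = safe_ratio(cm$tp, cm$tp + cm$fp),
    accuracy = (cm$tp + cm$tn) / total
  ), class = "metric_set")
}

#' Stratified ~50/50 subject split
#'
#' Splits by subject (no subject on both sides), stratified by class; each
#' class contributes `ceiling(n_class * train_fraction)` subjects to
#' training, so 27 subjects (15 + 12) split 14 train / 13 test at the
#' default fraction.
#'
#' @param table a `feature_table`, one row per subject.
#' @param seed integer; the split is drawn from the "split" substream.
#' @param train_fraction fraction of each class allocated to training.
#' @return list with `train` and `test` feature tables.
#' @export
split_subjects <- function(table, seed = 1, train_fraction = 0.5) {
  rm_assert(train_fraction > 0 && train_fraction < 1,
            "train_fraction must be in (0, 1)")
  classes <- unique(table$label)
  counts <- table(table$label)
  if (any(counts < 2)) {
    rm_stop("every class needs at least 2 subjects to split",
            "restmotion_split_error")
  }
  with_substream(seed, "split", {
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(table$label == cl)
      sample(idx, ceiling(length(idx) * train_fraction))
    }))
  })
  train_idx <- sort(train_idx)
  out <- list(train = table[train_idx, , drop = FALSE],
              test = table[-train_idx, , drop = FALSE])
  out <- lapply(out, function(t) {
    rownames(t) <- NULL
    class(t) <- c("feature_table", "data.frame")
    t
  })
  out
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin to folds.
fold_assignment <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_substream(seed, "folds", {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated metrics for one classifier
#'
#' Stratified k-fold cross-validation; the per-fold confusion matrices are
#' pooled and the metrics computed from the pooled matrix (robust to folds
#' that miss a class at small n).
#'
#' @param spec a [classifier_spec()].
#' @param table a normalized `feature_table`.
#' @param folds number of folds (default 10); must not exceed the row count.
#' @param seed integer seed for the fold assignment.
#' @param positive_label the positive class.
#' @return a `metric_set` with the pooled `confusion_matrix` attached as
#'   attribute `confusion`.
#' @export
crossvalidate <- function(spec, table, folds = 10, seed = 1,
                          positive_label = "PD") {
  rm_assert(folds >= 2 && folds <= nrow(table),
            "folds must be between 2 and the number of rows")
  assign <- fold_assignment(table$label, folds, seed)
  preds <- list()
  for (f in sort(unique(assign))) {
    train <- table[assign != f, , drop = FALSE]
    test <- table[assign == f, , drop = FALSE]
    class(train) <- class(test) <- c("feature_table", "data.frame")
    if (length(unique(train$label)) < 2) next # degenerate fold, skipped
    model <- train_classifier(spec, train, positive_label)
    preds[[length(preds) + 1]] <- predict_classifier(model, test)
  }
  pooled <- do.call(rbind, preds)
  class(pooled) <- c("rm_predictions", "data.frame")
  cm <- confusion(pooled, positive_label)
  out <- metrics(cm)
  attr(out, "confusion") <- cm
  out
}

#' Run the full classifier x feature-percentage benchmark
#'
#' Implements the evaluation protocol on a subject-level feature table:
#' Z-score normalize, split subjects ~50/50 stratified, rank features with
#' ReliefF (training rows only by default), then for every classifier and
#' every percentage subset report (i) "training accuracy" = pooled tenfold
#' cross-validation accuracy on the training half and (ii) sensitivity,
#' specificity, precision and accuracy of a single evaluation on the held-out
#' half.
#'
#' @param table subject-level `feature_table` (e.g. from
#'   [cohort_features()]).
#' @param classifiers character vector of classifier kinds.
#' @param percentages subsets to evaluate, each in `{10, ..., 100}`.
#' @param folds cross-validation folds on the training half.
#' @param seed master seed (split, folds and forests derive substreams).
#' @param rank_on `"train"` (leak-free, default) or `"all"` rows.
#' @param train_fraction passed to [split_subjects()].
#' @param positive_label the positive class.
#' @return data.frame of class `evaluation_report`, one row per classifier x
#'   percentage, with metric and confusion-count columns; attributes
#'   `ranking`, `split` (subject ids), `seed`.
#' @export
run_experiment <- function(table,
                           classifiers = CLASSIFIER_KINDS,
                           percentages = seq(10, 100, by = 10),
                           folds = 10, seed = 1, rank_on = c("train", "all"),
                           train_fraction = 0.5, positive_label = "PD") {
  rank_on <- match.arg(rank_on)
  norm <- zscore_normalize(table)
  halves <- split_subjects(norm, seed, train_fraction)
  ranked <- relieff_rank(if (rank_on == "train") halves$train else norm)
  total <- length(ranked$order)
  folds <- min(folds, nrow(halves$train))
  rows <- list()
  for (kind in classifiers) {
    spec <- classifier_spec(kind, seed = derive_seed(seed, paste0("clf-", kind)))
    for (pct in percentages) {
      keep <- percent_subset(ranked, pct, total)
      cols <- c("subject_id", "label", "hy")
      tr <- halves$train[, c(cols, keep), drop = FALSE]
      te <- halves$test[, c(cols, keep), drop = FALSE]
      class(tr) <- class(te) <- c("feature_table", "data.frame")
      cv <- crossvalidate(spec, tr, folds = folds, seed = seed,
                          positive_label = positive_label)
      model <- train_classifier(spec, tr, positive_label)
      cm <- confusion(predict_classifier(model, te), positive_label)
      ms <- metrics(cm)
      rows[[length(rows) + 1]] <- data.frame(
        classifier = kind, pct = pct, n_features = length(keep),
        train_accuracy = cv$accuracy,
        sensitivity = ms$sensitivity, specificity = ms$specificity,
        precision = ms$precision, accuracy = ms$accuracy,
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("evaluation_report", "data.frame")
  attr(report, "ranking") <- ranked
  attr(report, "split") <- list(train = halves$train$subject_id,
                                test = halves$test$subject_id)
  attr(report, "seed") <- seed
  report
}
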