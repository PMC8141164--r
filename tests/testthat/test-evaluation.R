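make_preds <- function(predicted, truth) {
  structure(data.frame(subject_id = sprintf("S%02d", seq_along(truth)),
                       predicted = predicted, truth = truth),
            class = c("rm_predictions", "data.frame"))
}

test_that("confusion counts partition predictions", {
  all_right <- make_preds(rep(c("PD", "healthy"), each = 5),
                          rep(c("PD", "healthy"), each = 5))
  cm <- confusion(all_right)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 5, tn = 5, fp = 0, fn = 0))
  inverted <- make_preds(rep(c("healthy", "PD"), each = 5),
                         rep(c("PD", "healthy"), each = 5))
  cmi <- confusion(inverted)
  expect_equal(cmi$tp + cmi$tn, 0)
  expect_equal(cmi$fp + cmi$fn, 10)
  set.seed(14)
  truth <- sample(c("PD", "healthy"), 50, replace = TRUE)
  predicted <- sample(c("PD", "healthy"), 50, replace = TRUE)
  cm <- confusion(make_preds(predicted, truth))
  # counting oracle
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:50) {
    if (truth[i] == "PD" && predicted[i] == "PD") tp <- tp + 1
    if (truth[i] != "PD" && predicted[i] == "PD") fp <- fp + 1
    if (truth[i] != "PD" && predicted[i] != "PD") tn <- tn + 1
    if (truth[i] == "PD" && predicted[i] != "PD") fn <- fn + 1
  }
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 50)
  expect_error(confusion(make_preds(c("PD", "weird"), c("PD", "healthy"))),
               class = "restmotion_data_error")
})

test_that("metrics match hand arithmetic and flag undefined ratios", {
  cm <- structure(list(tp = 7, fn = 1, fp = 1, tn = 9, positive = "PD"),
                  class = "confusion_matrix")
  ms <- metrics(cm)
  expect_equal(ms$sensitivity, 0.875)
  expect_equal(ms$specificity, 0.9)
  expect_equal(ms$precision, 0.875)
  expect_equal(ms$accuracy, 16 / 18)
  even <- structure(list(tp = 1, fn = 1, fp = 1, tn = 1, positive = "PD"),
                    class = "confusion_matrix")
  expect_true(all(unlist(metrics(even)) == 0.5))
  nospec <- structure(list(tp = 3, fn = 1, fp = 0, tn = 0, positive = "PD"),
                      class = "confusion_matrix")
  expect_true(is.na(metrics(nospec)$specificity))
})

test_that("stratified 50/50 split honours sizes and never mixes subjects", {
  tab <- cached_default_table() # 15 PD + 12 healthy
  halves <- split_subjects(tab, seed = 3)
  expect_equal(nrow(halves$train), 14)
  expect_equal(nrow(halves$test), 13)
  expect_equal(sum(halves$train$label == "PD"), 8)
  expect_equal(sum(halves$train$label == "healthy"), 6)
  expect_length(intersect(halves$train$subject_id, halves$test$subject_id), 0)
  expect_setequal(c(halves$train$subject_id, halves$test$subject_id),
                  tab$subject_id)
  again <- split_subjects(tab, seed = 3)
  expect_identical(halves$train$subject_id, again$train$subject_id)

  four <- make_feature_table(matrix(rnorm(8), ncol = 2),
                             rep(c("PD", "healthy"), 2))
  h4 <- split_subjects(four, seed = 1)
  expect_equal(nrow(h4$train), 2)
  expect_equal(sort(unique(h4$train$label)), c("PD", "healthy"))
  lone <- make_feature_table(matrix(rnorm(6), ncol = 2),
                             c("PD", "healthy", "healthy"))
  expect_error(split_subjects(lone), class = "restmotion_split_error")
})

test_that("cross-validation pools folds and matches a leave-one-out oracle", {
  tab <- make_blob_table(10, 4, sep = 6, seed = 15)
  spec <- classifier_spec("KNN")
  cv <- crossvalidate(spec, tab, folds = 10, seed = 2)
  expect_equal(cv$accuracy, 1) # separable construction
  cm <- attr(cv, "confusion")
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(tab))

  # folds = n is leave-one-out: manual loop oracle
  small <- make_blob_table(5, 3, sep = 1.5, seed = 16) # overlapping
  loo <- crossvalidate(spec, small, folds = nrow(small), seed = 7)
  correct <- 0
  for (i in seq_len(nrow(small))) {
    train <- small[-i, , drop = FALSE]
    class(train) <- c("feature_table", "data.frame")
    model <- train_classifier(spec, train)
    p <- predict_classifier(model, small[i, , drop = FALSE])
    if (p$predicted == p$truth) correct <- correct + 1
  }
  expect_equal(loo$accuracy, correct / nrow(small))
  expect_error(crossvalidate(spec, small, folds = 99),
               class = "restmotion_config_error")
})

test_that("run_experiment reports 4 classifiers x 10 percentages reproducibly", {
  tab <- cached_default_table()
  report <- run_experiment(tab, seed = 5)
  expect_s3_class(report, "evaluation_report")
  expect_equal(nrow(report), 40)
  expect_setequal(unique(report$classifier), c("KNN", "SVM", "RF", "NB"))
  expect_equal(sort(unique(report$pct)), seq(10, 100, by = 10))
  expect_equal(report$n_features[report$pct == 10][1], 11)
  expect_equal(report$n_features[report$pct == 100][1], 108)
  # test-half confusion always covers the 13 held-out subjects
  expect_true(all(report$tp + report$fp + report$tn + report$fn == 13))
  split <- attr(report, "split")
  expect_length(intersect(split$train, split$test), 0)
  report2 <- run_experiment(tab, seed = 5)
  expect_identical(report, report2)
})
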