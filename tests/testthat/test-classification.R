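planted_tables <- function(seed = 50, n_train = 60, n_test = 40) {
  # features 1-3 separate the classes cleanly; the rest are noise
  train <- random_feature_table(n_train, 10, seed = seed, planted = 1:3,
                                shift = 6)
  test <- random_feature_table(n_test, 10, seed = seed + 1, planted = 1:3,
                               shift = 6)
  list(train = train, test = test,
       train_labels = attr(train, "region_label"),
       test_labels = attr(test, "region_label"))
}

test_that("RFE keeps the separating feature and honors the cap", {
  d <- planted_tables()
  for (m in bank_methods()) {
    model <- train_with_rfe(d$train, d$train_labels, classifier_spec(m),
                            rfe_config(max_features = 5), seed = 1)
    expect_lte(length(model$selected_features), 5L)
    expect_true(d$train$descriptors$id[1] %in% model$selected_features)
  }
})

test_that("training is deterministic given the seed", {
  d <- planted_tables(seed = 60)
  for (m in c("bagged_trees", "svm", "naive_bayes")) {
    m1 <- train_with_rfe(d$train, d$train_labels, classifier_spec(m),
                         rfe_config(), seed = 42)
    m2 <- train_with_rfe(d$train, d$train_labels, classifier_spec(m),
                         rfe_config(), seed = 42)
    expect_identical(m1$selected_features, m2$selected_features)
    expect_identical(predict(m1, d$test)$label, predict(m2, d$test)$label)
  }
})

test_that("a cleanly separable test set is classified perfectly", {
  d <- planted_tables(seed = 70)
  for (m in bank_methods()) {
    model <- train_with_rfe(d$train, d$train_labels, classifier_spec(m),
                            rfe_config(), seed = 3)
    preds <- predict(model, d$test)
    expect_identical(preds$label, d$test_labels)
    expect_true(all(is.finite(preds$score)))
    expect_true(all(preds$score >= 0 & preds$score <= 1))
  }
})

test_that("training input contracts are enforced", {
  d <- planted_tables(seed = 80)
  expect_error(
    train_with_rfe(d$train, rep("head", 60), classifier_spec("lda")),
    "each class")
  bad <- d$train
  bad$values[1, 1] <- NaN
  expect_error(
    train_with_rfe(bad, d$train_labels, classifier_spec("lda")),
    "non-finite")
  # fewer features than the cap: use all, with a warning
  narrow <- pancradiomics:::subset_features(d$train, 1:3)
  expect_warning(
    model <- train_with_rfe(narrow, d$train_labels, classifier_spec("knn"),
                            rfe_config(max_features = 5)),
    "fewer features")
  expect_identical(length(model$selected_features), 3L)
})

test_that("prediction demands the selected descriptors", {
  d <- planted_tables(seed = 90)
  model <- train_with_rfe(d$train, d$train_labels, classifier_spec("lda"),
                          rfe_config(max_features = 2), seed = 1)
  stripped <- pancradiomics:::subset_features(
    d$test, !d$test$descriptors$id %in% model$selected_features[1])
  expect_error(predict(model, stripped), "lacks selected")
})

test_that("single-feature data breaks no method", {
  d <- planted_tables(seed = 95)
  one <- pancradiomics:::subset_features(d$train, 1)
  one_test <- pancradiomics:::subset_features(d$test, 1)
  for (m in bank_methods()) {
    expect_warning(
      model <- train_with_rfe(one, d$train_labels, classifier_spec(m),
                              rfe_config(max_features = 5), seed = 2),
      "fewer features")
    preds <- predict(model, one_test)
    rep <- evaluate_predictions(preds, d$test_labels)
    expect_gt(rep$accuracy, 50)  # the planted feature separates classes
  }
})

test_that("evaluation metrics derive from the confusion matrix", {
  # perfect prediction on a 10 + 10 split
  truth <- rep(c("head", "body_tail"), each = 10)
  preds <- data.frame(case_id = sprintf("c%02d", 1:20),
                      score = c(runif(10, 0.6, 1), runif(10, 0, 0.4)),
                      label = truth)
  rep <- evaluate_predictions(preds, truth)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$auc, 1.0)
  expect_identical(sum(rep$confusion), 20L)

  # accuracy re-derivable from confusion to machine precision
  set.seed(2)
  lab2 <- sample(c("head", "body_tail"), 30, replace = TRUE)
  sc <- runif(30)
  pr2 <- data.frame(case_id = 1:30, score = sc,
                    label = ifelse(sc >= 0.5, "head", "body_tail"))
  r2 <- evaluate_predictions(pr2, lab2)
  cm <- r2$confusion
  expect_equal(r2$accuracy,
               100 * (cm["head", "head"] + cm["body_tail", "body_tail"]) /
                 sum(cm))
  # marginals match class counts
  expect_identical(as.integer(colSums(cm)),
                   as.integer(table(factor(lab2, c("head", "body_tail")))))
  expect_error(evaluate_predictions(pr2, lab2[-1]), "lengths")
})

test_that("ROC is monotone and AUC matches pROC and is transform-invariant", {
  set.seed(13)
  truth <- rep(c("head", "body_tail"), c(25, 25))
  score <- c(rnorm(25, 1), rnorm(25))
  preds <- data.frame(case_id = 1:50, score = plogis(score),
                      label = ifelse(score >= 0, "head", "body_tail"))
  rep <- evaluate_predictions(preds, truth)
  expect_true(all(diff(rep$roc$fpr) >= 0))
  expect_true(all(diff(rep$roc$tpr) >= 0))
  ref <- suppressMessages(
    pROC::auc(pROC::roc(truth == "head", preds$score)))
  expect_equal(rep$auc, as.numeric(ref), tolerance = 1e-12)
  # strictly monotone score transform leaves the AUC unchanged
  preds2 <- preds
  preds2$score <- preds$score^3
  expect_equal(evaluate_predictions(preds2, truth)$auc, rep$auc)
})

test_that("labels independent of truth give chance AUC", {
  set.seed(4)
  n <- 4000
  truth <- rep(c("head", "body_tail"), each = n / 2)
  sc <- runif(n)
  preds <- data.frame(case_id = seq_len(n), score = sc,
                      label = ifelse(sc >= 0.5, "head", "body_tail"))
  rep <- evaluate_predictions(preds, truth)
  expect_equal(rep$auc, 0.5, tolerance = 0.03)
  expect_equal(rep$accuracy, 50, tolerance = 5)
})

test_that("the bank reports all seven methods and the best one", {
  d <- planted_tables(seed = 99)
  bank <- run_bank(d$train, d$train_labels, d$test, d$test_labels,
                   rfe_config(), seed = 5)
  expect_identical(length(bank$reports), 7L)
  expect_identical(sort(names(bank$reports)), sort(bank_methods()))
  expect_true(bank$best_method %in% bank_methods())
  for (r in bank$reports) expect_gt(r$accuracy, 50)
})
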