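#' Recursive-feature-elimination configuration
#'
#' @param max_features largest number of features a fitted model may retain
#'   (default 5, the overfitting guard for ~100-case cohorts).
#' @param step features removed per elimination round: an integer >= 1, or a
#'   fraction in (0, 1) meaning that share of the features still above the
#'   target is removed each round (useful on thousands of columns).
#' @return An object of class `rfe_config`.
#' @export
rfe_config <- function(max_features = 5L, step = 1) {
  max_features <- as.integer(max_features)
  if (max_features < 1L) stop("max_features must be >= 1", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step must be a positive number", call. = FALSE)
  }
  structure(list(max_features = max_features, step = step),
            class = "rfe_config")
}

#' Classifier specification
#'
#' The seven-method bank: Gaussian naive Bayes, k-nearest neighbours (k = 5,
#' Euclidean on z-scored features), K-means used as a supervised
#' nearest-class-centroid rule, linear-kernel support vector machine, linear
#' regression on a 0/1 response thresholded at 0.5, ensembled bagged trees
#' (50 trees, every predictor offered at each split) and linear discriminant
#' analysis. Features are z-scored inside every method's pipeline with
#' train-set statistics only, so the test set never leaks into the scaling.
#'
#' @param method one of `"naive_bayes"`, `"knn"`, `"kmeans"`, `"svm"`,
#'   `"linear_regression"`, `"bagged_trees"`, `"lda"`.
#' @param hyperparameters named list of method-specific overrides
#'   (`k` for knn, `cost` for svm, `num_trees` for bagged trees).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(method, hyperparameters = list()) {
  methods <- c("naive_bayes", "knn", "kmeans", "svm", "linear_regression",
               "bagged_trees", "lda")
  method <- match.arg(method, methods)
  defaults <- switch(method,
    knn = list(k = 5L),
    svm = list(cost = 1),
    bagged_trees = list(num_trees = 50L),
    list()
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(method = method, hyperparameters = hp),
            class = "classifier_spec")
}

#' The seven methods of the classifier bank
#'
#' @return Character vector of the method identifiers accepted by
#'   [classifier_spec()].
#' @export
bank_methods <- function() {
  c("naive_bayes", "knn", "kmeans", "svm", "linear_regression",
    "bagged_trees", "lda")
}

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% c("head", "body_tail")
  if (any(bad)) {
    stop("labels must be 'head' or 'body_tail'", call. = FALSE)
  }
  factor(labels, levels = c("head", "body_tail"))
}

# ---- method fits: each returns a closure scoring P(head) in [0, 1] --------

fit_method <- function(method, x, y, hp, seed) {
  df <- as.data.frame(x)
  switch(method,
    naive_bayes = {
      fit <- e1071::naiveBayes(df, y)
      list(fit = fit, score = function(newx) {
        predict(fit, as.data.frame(newx), type = "raw")[, "head"]
      })
    },
    knn = {
      k <- hp$k
      list(fit = list(train = x, y = y, k = k), score = function(newx) {
        pred <- class::knn(x, newx, y, k = k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "head", pr, 1 - pr)
      })
    },
    kmeans = {
      cen <- rbind(head = colMeans(x[y == "head", , drop = FALSE]),
                   body_tail = colMeans(x[y == "body_tail", , drop = FALSE]))
      list(fit = list(centroids = cen), score = function(newx) {
        dh <- sqrt(rowSums(sweep(newx, 2L, cen["head", ])^2))
        db <- sqrt(rowSums(sweep(newx, 2L, cen["body_tail", ])^2))
        ifelse(dh + db > 0, db / (dh + db), 0.5)
      })
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "linear", cost = hp$cost,
                        scale = FALSE)
      list(fit = fit, score = function(newx) {
        dvm <- attr(predict(fit, newx, decision.values = TRUE),
                    "decision.values")
        # orient decision values so positive means head
        flip <- if (startsWith(colnames(dvm)[1], "head/")) 1 else -1
        stats::plogis(flip * dvm[, 1])
      })
    },
    linear_regression = {
      y01 <- as.numeric(y == "head")
      fit <- lm(y01 ~ ., data = df)
      list(fit = fit, score = function(newx) {
        cf <- coef(fit)
        cf[is.na(cf)] <- 0
        pmin(pmax(cf[1] + as.matrix(newx) %*% cf[-1], 0), 1)[, 1]
      })
    },
    bagged_trees = {
      fit <- ranger::ranger(
        x = df, y = y, num.trees = hp$num_trees, mtry = ncol(df),
        probability = TRUE, importance = "impurity", seed = seed,
        min.node.size = 5
      )
      list(fit = fit, score = function(newx) {
        predict(fit, data = as.data.frame(newx))$predictions[, "head"]
      })
    },
    lda = {
      # collinearity warnings are routine on correlated radiomic columns;
      # the discriminant is still defined through the generalized inverse
      fit <- withCallingHandlers(
        MASS::lda(x, grouping = y),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      list(fit = fit, score = function(newx) {
        predict(fit, newx)$posterior[, "head"]
      })
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

# importance of each current column, higher = more crucial; model-based where
# the method has coefficients, univariate |Welch t| otherwise
rank_features_for <- function(method, fitted, x, y) {
  p <- ncol(x)
  model_rank <- switch(method,
    svm = {
      w <- crossprod(fitted$fit$coefs, fitted$fit$SV)
      abs(as.numeric(w))[seq_len(p)]
    },
    linear_regression = {
      cf <- coef(fitted$fit)[-1]
      cf[is.na(cf)] <- 0
      abs(as.numeric(cf))
    },
    lda = abs(fitted$fit$scaling[, 1]),
    bagged_trees = as.numeric(ranger::importance(fitted$fit)),
    NULL
  )
  if (is.null(model_rank)) {
    w <- welch_columns(x[y == "head", , drop = FALSE],
                       x[y == "body_tail", , drop = FALSE])
    model_rank <- abs(w$t)
  }
  model_rank[!is.finite(model_rank)] <- 0
  model_rank
}

#' Train one classifier with recursive feature elimination
#'
#' Features are z-scored with train statistics, then the lowest-ranked
#' features are recursively eliminated until at most `max_features` remain,
#' and the model is refit on the survivors. Ranking is the absolute model
#' coefficient for methods that have one (SVM, linear regression, LDA),
#' impurity importance for bagged trees, and the absolute univariate Welch t
#' statistic for the coefficient-free methods (naive Bayes, KNN, K-means).
#' If a method cannot be fit on the current working set (e.g. LDA while more
#' features than cases remain), that round falls back to the univariate
#' ranking; the final refit always uses the actual method. Deterministic
#' given `seed`.
#'
#' @param train_table a filtered [feature_table()] (finite, non-constant).
#' @param labels per-case labels, `"head"` / `"body_tail"`, both present.
#' @param spec a [classifier_spec()].
#' @param rfe an [rfe_config()].
#' @param seed integer seed controlling any stochastic fit component.
#' @return An object of class `radiomics_model` with the selected descriptor
#'   ids, the train scaling and the fitted decision function.
#' @export
train_with_rfe <- function(train_table, labels, spec,
                           rfe = rfe_config(), seed = 1L) {
  stopifnot(inherits(train_table, "feature_table"),
            inherits(spec, "classifier_spec"), inherits(rfe, "rfe_config"))
  y <- as_class_factor(labels)
  if (length(y) != nrow(train_table$values)) {
    stop("one label per case required", call. = FALSE)
  }
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least two cases of each class", call. = FALSE)
  }
  v <- train_table$values
  if (any(!is.finite(v))) {
    stop("train table contains non-finite values; run filter_features()",
         call. = FALSE)
  }
  set.seed(seed)
  center <- colMeans(v)
  scale_ <- apply(v, 2L, sd)
  scale_[scale_ == 0] <- 1
  x_all <- sweep(sweep(v, 2L, center), 2L, scale_, `/`)

  target <- rfe$max_features
  current <- seq_len(ncol(x_all))
  if (length(current) < target) {
    warning("fewer features than max_features; using all", call. = FALSE)
    target <- length(current)
  }
  while (length(current) > target) {
    n_over <- length(current) - target
    n_drop <- if (rfe$step >= 1) {
      min(as.integer(rfe$step), n_over)
    } else {
      max(1L, min(floor(rfe$step * length(current)), n_over))
    }
    xs <- x_all[, current, drop = FALSE]
    fitted <- tryCatch(
      fit_method(spec$method, xs, y, spec$hyperparameters, seed),
      error = function(e) NULL
    )
    ranks <- if (is.null(fitted)) {
      w <- welch_columns(xs[y == "head", , drop = FALSE],
                         xs[y == "body_tail", , drop = FALSE])
      abs(w$t)
    } else {
      rank_features_for(spec$method, fitted, xs, y)
    }
    drop_local <- order(ranks, seq_along(ranks))[seq_len(n_drop)]
    current <- current[-drop_local]
  }
  xs <- x_all[, current, drop = FALSE]
  final <- fit_method(spec$method, xs, y, spec$hyperparameters, seed)
  structure(
    list(spec = spec, rfe = rfe, seed = seed,
         selected_features = colnames(v)[current],
         center = center[current], scale = scale_[current],
         fitted = final, levels = levels(y)),
    class = "radiomics_model"
  )
}

#' @export
print.radiomics_model <- function(x, ...) {
  cat(sprintf("<radiomics_model> %s, %d selected features:\n  %s\n",
              x$spec$method, length(x$selected_features),
              paste(x$selected_features, collapse = "\n  ")))
  invisible(x)
}

#' Predict tumor region for new cases
#'
#' Scores are the model's head-class score in `[0, 1]`; the predicted label
#' is head when the score is at least 0.5 (an exact 0.5 resolves to head).
#'
#' @param object a [train_with_rfe()] model.
#' @param test_table a [feature_table()] containing every selected
#'   descriptor (extra columns are ignored).
#' @param ... unused.
#' @return data.frame with `case_id`, `score`, `label`.
#' @export
predict.radiomics_model <- function(object, test_table, ...) {
  stopifnot(inherits(test_table, "feature_table"))
  missing <- setdiff(object$selected_features, colnames(test_table$values))
  if (length(missing) > 0) {
    stop("test table lacks selected descriptors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- test_table$values[, object$selected_features, drop = FALSE]
  x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  score <- as.numeric(object$fitted$score(x))
  score[!is.finite(score)] <- 0.5
  data.frame(
    case_id = test_table$case_ids,
    score = score,
    label = ifelse(score >= 0.5, "head", "body_tail"),
    stringsAsFactors = FALSE
  )
}

round_half_up <- function(x) floor(x + 0.5)

#' Evaluate predictions against the true labels
#'
#' Builds the 2x2 predicted-by-true confusion matrix (positive class: head),
#' accuracy, sensitivity (head recall) and specificity (body/tail recall) as
#' percentages (full precision kept, integer reporting rounded half up), the
#' ROC curve from a score-threshold sweep, and the trapezoid AUC.
#'
#' @param predictions data.frame from [predict.radiomics_model()] (`label`
#'   and `score` columns), case order matching `truth`.
#' @param truth character vector of true labels.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  truth <- as_class_factor(truth)
  if (nrow(predictions) != length(truth)) {
    stop("predictions and truth have different lengths", call. = FALSE)
  }
  pred <- factor(predictions$label, levels = c("head", "body_tail"))
  confusion <- table(predicted = pred, true = truth)
  tp <- confusion["head", "head"]
  fp <- confusion["head", "body_tail"]
  fn <- confusion["body_tail", "head"]
  tn <- confusion["body_tail", "body_tail"]
  n <- sum(confusion)
  accuracy <- 100 * (tp + tn) / n
  sensitivity <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  specificity <- if (tn + fp > 0) 100 * tn / (tn + fp) else NaN

  roc <- roc_points(predictions$score, truth)
  structure(
    list(confusion = confusion,
         accuracy = accuracy, sensitivity = sensitivity,
         specificity = specificity,
         accuracy_pct = round_half_up(accuracy),
         sensitivity_pct = round_half_up(sensitivity),
         specificity_pct = round_half_up(specificity),
         roc = roc, auc = trapezoid_auc(roc)),
    class = "evaluation_report"
  )
}

# threshold sweep: head predicted when score >= threshold
roc_points <- function(score, truth) {
  pos <- truth == "head"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    called <- score >= t
    c(fpr = if (n_neg > 0) sum(called & !pos) / n_neg else 0,
      tpr = if (n_pos > 0) sum(called & pos) / n_pos else 0)
  }, numeric(2)))
  pts <- rbind(pts, c(1, 1))
  data.frame(threshold = c(thr, -Inf), fpr = pts[, 1], tpr = pts[, 2])
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]
  tpr <- roc$tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> accuracy %d%%, sensitivity %d%%, specificity %d%%, AUC %.3f\n",
    x$accuracy_pct, x$sensitivity_pct, x$specificity_pct, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Train and evaluate the seven-classifier bank
#'
#' Fits every method of the bank on the training cohort with RFE, scores the
#' held-out cohort, and reports one [evaluate_predictions()] per method plus
#' the argmax-accuracy method.
#'
#' @param train_table,train_labels filtered training [feature_table()] and
#'   its labels.
#' @param test_table,test_labels held-out cohort and labels.
#' @param rfe an [rfe_config()].
#' @param seed integer seed.
#' @param methods character vector of methods (default all seven).
#' @return An object of class `bank_result`: `reports` (named list of
#'   evaluation reports), `models`, `best_method`.
#' @export
run_bank <- function(train_table, train_labels, test_table, test_labels,
                     rfe = rfe_config(), seed = 1L, methods = bank_methods()) {
  reports <- list()
  models <- list()
  for (m in methods) {
    model <- train_with_rfe(train_table, train_labels, classifier_spec(m),
                            rfe, seed)
    preds <- predict(model, test_table)
    reports[[m]] <- evaluate_predictions(preds, test_labels)
    models[[m]] <- model
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  structure(
    list(reports = reports, models = models,
         best_method = names(which.max(acc))),
    class = "bank_result"
  )
}

#' @export
print.bank_result <- function(x, ...) {
  for (m in names(x$reports)) {
    r <- x$reports[[m]]
    cat(sprintf("%-18s accuracy %3d%%  sens %3d%%  spec %3d%%  AUC %.3f\n",
                m, r$accuracy_pct, r$sensitivity_pct, r$specificity_pct,
                r$auc))
  }
  cat("best method:", x$best_method, "\n")
  invisible(x)
}
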