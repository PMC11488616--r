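#' Gradient-boosted tree hyperparameters
#'
#' Fixed hyperparameter set for the XGBoost classifier. The defaults are the
#' values selected once by grid search on a separate conversational dataset
#' and then held fixed; every field can be overridden. `n_estimators` is the
#' number of boosting rounds; `gamma` (minimum split loss) and
#' `min_child_weight` regularize tree growth.
#'
#' @param max_depth Maximum tree depth (default 3).
#' @param n_estimators Boosting rounds (default 700).
#' @param learning_rate Shrinkage per round (default 0.1).
#' @param subsample Row subsampling fraction per tree (default 0.6).
#' @param colsample_bytree Column subsampling fraction per tree (default 1.0).
#' @param gamma Minimum loss reduction to split (default 5).
#' @param min_child_weight Minimum child hessian weight (default 1).
#' @param random_seed Seed passed to the booster (default 0).
#' @return A list of class `xgb_hyperparameters`.
#' @export
xgb_hyperparameters <- function(max_depth = 3, n_estimators = 700,
                                learning_rate = 0.1, subsample = 0.6,
                                colsample_bytree = 1.0, gamma = 5,
                                min_child_weight = 1, random_seed = 0L) {
  structure(
    list(max_depth = max_depth, n_estimators = n_estimators,
         learning_rate = learning_rate, subsample = subsample,
         colsample_bytree = colsample_bytree, gamma = gamma,
         min_child_weight = min_child_weight,
         random_seed = as.integer(random_seed)),
    class = "xgb_hyperparameters"
  )
}

#' Subject-grouped repeated random subsampling plan
#'
#' Draws `n_folds` independent train/test partitions of the *subjects* (not
#' the assessments): each fold places `max(1, round-half-up(test_fraction *
#' n_subjects))` subjects in the test side and the rest in the train side.
#' All assessments of a subject follow the subject, so data from one person
#' never appear on both sides of a split. Folds are drawn independently -
#' this is repeated random subsampling, not a k-fold partition, so test sets
#' may overlap across folds. The plan is a pure function of the seed.
#'
#' @param subject_ids Character vector of unique subject ids (>= 2).
#' @param n_folds Number of subsampling iterations (default 100).
#' @param test_fraction Fraction of subjects per test side (default 0.10).
#' @param seed Integer seed.
#' @return A list of class `split_plan` with `folds` (each a list with
#'   `train` and `test` subject-id vectors), `n_folds`, `test_fraction`,
#'   `seed`.
#' @export
make_split_plan <- function(subject_ids, n_folds = 100, test_fraction = 0.10,
                            seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < 2L) stop("need at least 2 subjects to split")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  n_test <- max(1L, as.integer(floor(test_fraction * n + 0.5)))
  if (n_test >= n) stop("test side would leave an empty training side")
  folds <- withr_seed(seed, {
    lapply(seq_len(n_folds), function(i) {
      test <- sample(subject_ids, n_test)
      list(train = setdiff(subject_ids, test), test = test)
    })
  })
  structure(
    list(folds = folds, n_folds = n_folds, test_fraction = test_fraction,
         seed = as.integer(seed), subjects = subject_ids),
    class = "split_plan"
  )
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Train the gradient-boosted classifier
#'
#' Fits a binary XGBoost model (logistic objective) with AD as the positive
#' class, single-threaded and seeded so that identical inputs give identical
#' models.
#'
#' @param x Numeric feature matrix with column names.
#' @param labels Character/factor vector over `"AD"` / `"HC"`.
#' @param hp An [xgb_hyperparameters()] object.
#' @return An object of class `speech_classifier`.
#' @export
train_classifier <- function(x, labels, hp = xgb_hyperparameters()) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c("AD", "HC")))
  if (length(unique(labels)) < 2L) {
    stop("single-class training set: both AD and HC examples are required")
  }
  y <- as.integer(labels == "AD")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    max_depth = hp$max_depth,
    learning_rate = hp$learning_rate,
    subsample = hp$subsample,
    colsample_bytree = hp$colsample_bytree,
    min_split_loss = hp$gamma,
    min_child_weight = hp$min_child_weight,
    seed = hp$random_seed,
    nthread = 1
  )
  booster <- xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                                verbose = 0)
  structure(
    list(booster = booster, feature_names = colnames(x), hp = hp),
    class = "speech_classifier"
  )
}

#' Predict AD probabilities
#'
#' @param object A `speech_classifier`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric vector of P(AD) per row.
#' @export
predict.speech_classifier <- function(object, newdata, ...) {
  dm <- xgboost::xgb.DMatrix(newdata[, object$feature_names, drop = FALSE],
                             nthread = 1)
  as.numeric(predict(object$booster, dm))
}

#' Per-feature gain importance
#'
#' Gain-based importance of every training feature (the information-gain
#' contribution of the feature across all splits that use it, normalized to
#' sum to 1 per model). Features never used by the model get importance 0,
#' so the vector always covers the full feature space.
#'
#' @param object A `speech_classifier`.
#' @return Named non-negative numeric vector over all training features.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "speech_classifier"))
  out <- stats::setNames(numeric(length(object$feature_names)),
                         object$feature_names)
  imp <- xgboost::xgb.importance(model = object$booster)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney statistic), with ties handled by midranks. AD is the
#' positive class.
#'
#' @param scores Numeric classifier scores.
#' @param labels Character vector over `"AD"` / `"HC"`.
#' @return AUC in \[0, 1\], or `NA` when either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "AD"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)  # ties.method = "average" = midrank
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics from confusion counts
#'
#' With AD as the positive class: precision = TP/(TP+FP), recall
#' (sensitivity) = TP/(TP+FN), specificity = TN/(FP+TN), f1 =
#' 2 * precision * recall / (precision + recall), accuracy =
#' (TP+TN)/total. A metric whose denominator is zero is `NA` ("undefined")
#' and is excluded from fold aggregates. AUC is computed from `scores` and
#' `labels` when supplied.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @param scores Optional per-assessment scores for AUC.
#' @param labels Optional labels parallel to `scores`.
#' @return Named list with `precision`, `recall`, `specificity`, `f1`,
#'   `accuracy`, `auc`.
#' @export
#' @examples
#' compute_metrics(tp = 42, fp = 8, tn = 40, fn = 10)
compute_metrics <- function(tp, fp, tn, fn, scores = NULL, labels = NULL) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, fp + tn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- div(tp + tn, tp + fp + tn + fn)
  auc <- if (!is.null(scores)) roc_auc(scores, labels) else NA_real_
  list(precision = precision, recall = recall, specificity = specificity,
       f1 = f1, accuracy = accuracy, auc = auc)
}

#' Run the repeated random subsampling validation
#'
#' For every fold of the plan: trains on all assessments of the train-side
#' subjects, scores the test-side assessments, thresholds at 0.5 into a
#' confusion matrix (AD positive), computes the metrics and the per-feature
#' gain importance. Subject disjointness is asserted on every fold. A fold
#' whose test side contains a single class gets `NA` AUC (logged); its
#' confusion-based metrics are still computed. Aggregates are arithmetic
#' means and standard deviations across folds, skipping undefined values;
#' a pooled AUC over all test predictions is reported alongside the
#' fold-averaged one. Importances of features absent from a fold's model
#' count as 0 in that fold before averaging.
#'
#' @param fm A `feature_matrix` (or a list with `x`, `labels`,
#'   `subject_id`).
#' @param plan A [make_split_plan()] object whose subjects all appear in
#'   `fm`.
#' @param hp An [xgb_hyperparameters()] object.
#' @param threshold Probability cutoff for the confusion matrix
#'   (default 0.5).
#' @return An object of class `validation_report`.
#' @export
run_validation <- function(fm, plan, hp = xgb_hyperparameters(),
                           threshold = 0.5) {
  x <- fm$x; labels <- as.character(fm$labels); subj <- fm$subject_id
  stopifnot(nrow(x) == length(labels), length(labels) == length(subj))
  if (!all(plan$subjects %in% subj)) {
    stop("split plan contains subjects absent from the feature matrix")
  }
  metric_names <- c("precision", "recall", "specificity", "f1", "accuracy",
                    "auc")
  n_folds <- length(plan$folds)
  fold_metrics <- matrix(NA_real_, n_folds, length(metric_names),
                         dimnames = list(NULL, metric_names))
  importance <- matrix(0, n_folds, ncol(x),
                       dimnames = list(NULL, colnames(x)))
  folds <- vector("list", n_folds)
  pooled_scores <- numeric(0); pooled_labels <- character(0)
  for (i in seq_len(n_folds)) {
    fold <- plan$folds[[i]]
    if (length(intersect(fold$train, fold$test))) {
      stop("subject leakage: fold ", i, " has subjects on both sides")
    }
    in_train <- subj %in% fold$train
    in_test <- subj %in% fold$test
    stopifnot(!any(in_train & in_test))
    clf <- train_classifier(x[in_train, , drop = FALSE], labels[in_train], hp)
    scores <- predict(clf, x[in_test, , drop = FALSE])
    truth <- labels[in_test]
    pred <- ifelse(scores >= threshold, "AD", "HC")
    tp <- sum(pred == "AD" & truth == "AD")
    fp <- sum(pred == "AD" & truth == "HC")
    tn <- sum(pred == "HC" & truth == "HC")
    fn <- sum(pred == "HC" & truth == "AD")
    m <- compute_metrics(tp, fp, tn, fn, scores, truth)
    if (is.na(m$auc)) {
      message("fold ", i, ": single-class test set, AUC undefined")
    }
    fold_metrics[i, ] <- unlist(m)[metric_names]
    importance[i, ] <- feature_importance(clf)
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, truth)
    folds[[i]] <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                       metrics = m, n_test = sum(in_test))
  }
  agg <- data.frame(
    metric = metric_names,
    mean = apply(fold_metrics, 2, mean, na.rm = TRUE),
    sd = apply(fold_metrics, 2, stats::sd, na.rm = TRUE),
    n_defined = apply(fold_metrics, 2, function(v) sum(!is.na(v))),
    row.names = NULL
  )
  imp_table <- data.frame(
    feature = colnames(x),
    mean_importance = colMeans(importance),
    sd_importance = apply(importance, 2, stats::sd),
    row.names = NULL
  )
  structure(
    list(
      folds = folds,
      fold_metrics = fold_metrics,
      aggregate = agg,
      importance = imp_table,
      importance_by_fold = importance,
      nonzero_importance_count = sum(colSums(importance > 0) > 0),
      pooled_auc = roc_auc(pooled_scores, pooled_labels),
      plan = plan[c("n_folds", "test_fraction", "seed")],
      hp = hp
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", length(x$folds), " folds\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-11s %.3f (SD = %.3f, %d/%d folds)\n", agg$metric[i],
                agg$mean[i], agg$sd[i], agg$n_defined[i], length(x$folds)))
  }
  cat(sprintf("  pooled AUC  %.3f\n", x$pooled_auc))
  cat("  features with nonzero importance in >=1 fold: ",
      x$nonzero_importance_count, "\n", sep = "")
  invisible(x)
}

#' Top-k features by averaged importance
#'
#' Orders features by mean gain importance across folds, descending; ties
#' are broken by feature name (lexicographic), so the result is
#' deterministic. If fewer than `k` features have nonzero mean importance,
#' all nonzero ones are returned with a message.
#'
#' @param report A `validation_report`.
#' @param k Number of features (default 10).
#' @return Data frame `feature`, `mean_importance`, `sd_importance` with at
#'   most `k` rows.
#' @export
top_k_features <- function(report, k = 10) {
  imp <- report$importance
  imp <- imp[order(-imp$mean_importance, imp$feature), , drop = FALSE]
  nonzero <- sum(imp$mean_importance > 0)
  if (k > nonzero) {
    message("only ", nonzero, " features have nonzero averaged importance")
    k <- nonzero
  }
  out <- imp[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a validation report
#'
#' Writes the report as JSON (per-fold confusion counts and metrics,
#' aggregates, pooled AUC, nonzero-importance count, plan and
#' hyperparameters) and, optionally, the averaged importance table as
#' tab-delimited text.
#'
#' @param report A `validation_report`.
#' @param json_path Output JSON path.
#' @param importance_path Optional output path for the importance table.
#' @export
write_validation_report <- function(report, json_path,
                                    importance_path = NULL) {
  payload <- list(
    plan = report$plan,
    hyperparameters = unclass(report$hp),
    aggregate = report$aggregate,
    pooled_auc = report$pooled_auc,
    nonzero_importance_count = report$nonzero_importance_count,
    folds = lapply(report$folds, function(f) {
      c(f[c("tp", "fp", "tn", "fn", "n_test")], f$metrics)
    })
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(importance_path)) {
    utils::write.table(report$importance, importance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
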