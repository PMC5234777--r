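# Random-forest classifiers for the three per-pair outcomes, with the
# evaluation machinery around them: k-fold cross-validation, robustness to
# training-set subsampling, sham self-combination controls, Gini feature
# importance and a two-sample contrast of predicted groups.
#
# One independent model is trained per outcome (synergy, general
# effectiveness, each genotype-selectivity). AUC is the rank (Mann-Whitney)
# statistic over pooled out-of-fold probabilities; hard calls use the
# ensemble vote fraction at a configurable threshold (default 0.5).

#' Train a random-forest classifier for one outcome
#'
#' @param X Numeric feature matrix (pairs x features), no missing values.
#' @param y Logical (or 0/1) outcome vector, both classes present.
#' @param outcome Name of the outcome (recorded in the bundle).
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param seed Integer seed; `NULL` continues the current RNG stream (used
#'   internally by [cross_validate()]).
#' @return An object of class `rf_bundle`: the fitted forest plus the
#'   feature ordering record, hyperparameters and seed. Prediction-time
#'   matrices are aligned by feature name, not position.
#' @export
train_model <- function(X, y, outcome = "synergy", ntree = 500L,
                        mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (anyNA(y)) stop("outcome vector contains missing values", call. = FALSE)
  y <- factor(as.logical(y), levels = c(FALSE, TRUE))
  if (nlevels(droplevels(y)) < 2) {
    stop(sprintf("cannot train '%s': only one class present", outcome),
         call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (!is.null(seed)) set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                       mtry = mtry, importance = FALSE)
  structure(list(forest = forest, outcome = outcome,
                 feature_order = colnames(X),
                 hyper = list(ntree = ntree, mtry = mtry),
                 seed = seed),
            class = "rf_bundle")
}

#' Predict outcome probabilities from a trained bundle
#'
#' @param object An `rf_bundle`.
#' @param newdata Feature matrix; columns are matched to the bundle's
#'   feature ordering by name.
#' @param ... Unused.
#' @return Vector of predicted positive-class vote fractions in `[0,1]`.
#' @export
predict.rf_bundle <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_order, colnames(newdata))
  if (length(missing)) {
    stop(sprintf("newdata missing feature(s): %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  p <- stats::predict(object$forest,
                      newdata[, object$feature_order, drop = FALSE],
                      type = "prob")
  unname(p[, "TRUE"])
}

#' @export
print.rf_bundle <- function(x, ...) {
  cat(sprintf("random-forest bundle for outcome '%s': %d trees, mtry %d, %d features\n",
              x$outcome, x$hyper$ntree, x$hyper$mtry, length(x$feature_order)))
  invisible(x)
}

# Rank-statistic AUC (Mann-Whitney with midranks for ties).
auc_rank <- function(probs, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  calls <- probs >= threshold
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  tn <- sum(!calls & !labels); fn <- sum(!calls & labels)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' k-fold cross-validation of a random-forest outcome model
#'
#' Folds are a seeded random partition (optionally stratified by class).
#' Out-of-fold probabilities are pooled; AUC is the rank statistic over the
#' pool and the confusion-derived metrics are computed at the vote
#' threshold. Folds that end up with a single class are flagged in the
#' per-fold breakdown but still contribute to the pooled AUC.
#'
#' @inheritParams train_model
#' @param k Number of folds (must not exceed the sample count).
#' @param threshold Vote-fraction threshold for hard calls.
#' @param stratified Stratify fold assignment by class.
#' @return An object of class `eval_report`: pooled `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `fdr`, the confusion counts, a per-fold
#'   breakdown data.frame, the pooled out-of-fold probabilities and the
#'   fold assignment.
#' @export
cross_validate <- function(X, y, k = 10L, threshold = 0.5, seed = 1L,
                           outcome = "synergy", ntree = 500L, mtry = NULL,
                           stratified = FALSE) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- length(y)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop(sprintf("cannot cross-validate '%s': only one class present", outcome),
         call. = FALSE)
  }
  set.seed(seed)
  if (stratified) {
    folds <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  probs <- rep(NA_real_, n)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    bundle <- train_model(X[!test, , drop = FALSE], y[!test],
                          outcome = outcome, ntree = ntree, mtry = mtry,
                          seed = NULL)
    probs[test] <- predict(bundle, X[test, , drop = FALSE])
    single_class <- length(unique(y[test])) < 2
    cm <- confusion_metrics(probs[test], y[test], threshold)
    fold_rows[[f]] <- data.frame(fold = f, n = sum(test),
                                 single_class = single_class,
                                 auc = if (single_class) NA_real_ else
                                   auc_rank(probs[test], y[test]),
                                 accuracy = cm$accuracy,
                                 sensitivity = cm$sensitivity,
                                 specificity = cm$specificity)
  }
  cm <- confusion_metrics(probs, y, threshold)
  structure(c(list(outcome = outcome, auc = auc_rank(probs, y)), cm,
              list(folds = do.call(rbind, fold_rows), probs = probs,
                   fold_assignment = folds, threshold = threshold,
                   k = k, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s' (seed %d):\n", x$k, x$outcome,
              x$seed))
  cat(sprintf("  AUC %.4f  accuracy %.4f  sensitivity %.4f  specificity %.4f  FDR %.4f\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$fdr))
  invisible(x)
}

#' Robustness of the model to training-set subsampling
#'
#' For each training fraction below 1 the labelled set is repeatedly split
#' (stratified by class) into a training subsample of that size and the
#' held-out remainder used for evaluation; metrics are averaged over the
#' repetitions. Fraction 1.0 reduces to a single [cross_validate()] run.
#'
#' @inheritParams cross_validate
#' @param fractions Training fractions in (0, 1], one output row each.
#' @param reps Repetitions per fraction below 1.
#' @return Data.frame sorted by fraction with mean and standard deviation of
#'   accuracy, sensitivity and specificity.
#' @export
robustness_curve <- function(X, y, fractions = c(0.25, 0.5, 0.75, 1),
                             reps = 10L, seed = 1L, threshold = 0.5,
                             outcome = "synergy", ntree = 500L, mtry = NULL,
                             k = 10L) {
  stopifnot(all(fractions > 0 & fractions <= 1), reps >= 1)
  X <- as.matrix(X)
  y <- as.logical(y)
  fractions <- sort(fractions)
  set.seed(seed)
  rows <- lapply(fractions, function(f) {
    if (f == 1) {
      cv <- cross_validate(X, y, k = k, threshold = threshold, seed = seed,
                           outcome = outcome, ntree = ntree, mtry = mtry)
      return(data.frame(fraction = 1, reps = 1L,
                        accuracy = cv$accuracy, accuracy_sd = NA_real_,
                        sensitivity = cv$sensitivity, sensitivity_sd = NA_real_,
                        specificity = cv$specificity, specificity_sd = NA_real_))
    }
    mets <- replicate(reps, {
      train_idx <- unlist(lapply(c(TRUE, FALSE), function(cls) {
        idx <- which(y == cls)
        sample(idx, max(1L, round(f * length(idx))))
      }))
      test_idx <- setdiff(seq_along(y), train_idx)
      bundle <- train_model(X[train_idx, , drop = FALSE], y[train_idx],
                            outcome = outcome, ntree = ntree, mtry = mtry,
                            seed = NULL)
      cm <- confusion_metrics(predict(bundle, X[test_idx, , drop = FALSE]),
                              y[test_idx], threshold)
      c(cm$accuracy, cm$sensitivity, cm$specificity)
    })
    data.frame(fraction = f, reps = reps,
               accuracy = mean(mets[1, ]), accuracy_sd = stats::sd(mets[1, ]),
               sensitivity = mean(mets[2, ], na.rm = TRUE),
               sensitivity_sd = stats::sd(mets[2, ], na.rm = TRUE),
               specificity = mean(mets[3, ], na.rm = TRUE),
               specificity_sd = stats::sd(mets[3, ], na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Sham self-combination control
#'
#' Builds the sham feature vector of every drug in the GI50 matrix, applies
#' the trained model, and reports the fraction of shams called negative.
#' Shams should not be synergistic, so the rate of a sound synergy model is
#' close to 1.
#'
#' @param bundle Trained `rf_bundle`.
#' @param gi50 Drug-by-cell-line GI50 matrix.
#' @param threshold Vote threshold above which a sham counts as a
#'   (spurious) positive call.
#' @param transform GI50 transform used at training time.
#' @return List with `rate` (fraction called negative), `n` shams evaluated,
#'   `positive_drugs` (the offenders) and the per-sham probabilities.
#' @export
sham_control <- function(bundle, gi50, threshold = 0.5, transform = "log10") {
  shams <- make_sham_features(gi50, transform = transform)
  probs <- predict(bundle, shams)
  positive <- probs >= threshold
  list(rate = mean(!positive), n = nrow(shams),
       positive_drugs = rownames(gi50)[positive],
       probs = stats::setNames(probs, rownames(gi50)))
}

#' Gini feature importance of a trained bundle
#'
#' Mean-decrease-Gini importances of the forest, normalized to sum to one
#' and sorted decreasing. Ranking is deterministic for a fixed training
#' seed and identical for a serialized-and-reloaded bundle.
#'
#' @param bundle Trained `rf_bundle`.
#' @return Data.frame with `feature` and `importance` (sums to 1), sorted
#'   decreasing with ties broken by feature name.
#' @export
feature_importance <- function(bundle) {
  imp <- randomForest::importance(bundle$forest, type = 2)[, 1]
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp)[ord],
             row.names = NULL)
}

#' Contrast a statistic between predicted-positive and predicted-negative pairs
#'
#' Two-sided two-sample Kolmogorov-Smirnov comparison of a per-pair
#' statistic (e.g. the GI50-profile correlation of the two drugs across the
#' mutant-BRAF lines) between pairs the model calls positive and the rest.
#'
#' @param values Per-pair statistic.
#' @param predicted Logical predicted labels, same length.
#' @return List with the KS statistic `D`, `p.value` and group sizes.
#' @export
contrast_predicted_groups <- function(values, predicted) {
  predicted <- as.logical(predicted)
  stopifnot(length(values) == length(predicted))
  keep <- !is.na(values) & !is.na(predicted)
  values <- values[keep]; predicted <- predicted[keep]
  if (!any(predicted) || all(predicted)) {
    stop("both predicted groups must be non-empty", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(values[predicted], values[!predicted],
                                        alternative = "two.sided"))
  list(D = unname(ks$statistic), p.value = ks$p.value,
       n_positive = sum(predicted), n_negative = sum(!predicted))
}
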