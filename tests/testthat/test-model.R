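# A linearly separable toy problem: one informative feature plus noise.
toy_problem <- function(n = 40, p = 6, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- X[, 1] > 0
  X[, 1] <- X[, 1] + ifelse(y, 2, -2)
  rownames(X) <- sprintf("p%02d", seq_len(n))
  list(X = X, y = y)
}

test_that("training learns a separable problem and refuses one class", {
  tp <- toy_problem()
  bundle <- train_model(tp$X, tp$y, seed = 7)
  expect_equal(unname(predict(bundle, tp$X) >= 0.5), tp$y)
  expect_error(train_model(tp$X, rep(TRUE, nrow(tp$X)), outcome = "synergy"),
               "synergy")
  expect_error(train_model(cbind(tp$X, bad = NA), tp$y), "missing")
})

test_that("bundles serialize and reload with identical predictions", {
  tp <- toy_problem()
  bundle <- train_model(tp$X, tp$y, seed = 7)
  path <- tempfile(fileext = ".rds")
  saveRDS(bundle, path)
  back <- readRDS(path)
  expect_identical(predict(back, tp$X), predict(bundle, tp$X))
  expect_identical(feature_importance(back), feature_importance(bundle))
  # prediction aligns newdata columns by name
  shuffled <- tp$X[, rev(colnames(tp$X))]
  expect_identical(predict(bundle, shuffled), predict(bundle, tp$X))
  expect_error(predict(bundle, tp$X[, -2]), "missing feature")
})

test_that("rank-statistic AUC matches a brute-force concordance oracle", {
  auc_rank <- synergyscreen:::auc_rank
  expect_equal(auc_rank(c(1, 1, 0, 0, 1, 0), c(1, 1, 0, 0, 1, 0)), 1)
  expect_equal(auc_rank(c(0, 0, 1, 1, 0, 1), c(1, 1, 0, 0, 1, 0)), 0)
  set.seed(406)
  for (i in 1:20) {
    probs <- round(runif(6), 1)  # rounding forces ties
    labels <- c(TRUE, sample(c(TRUE, FALSE), 4, replace = TRUE), FALSE)
    expect_equal(auc_rank(probs, labels), auc_oracle(probs, labels))
  }
  # invariant under strictly monotone transforms of the probabilities
  probs <- runif(20); labels <- runif(20) > 0.5
  expect_equal(auc_rank(probs, labels), auc_rank(plogis(5 * probs - 2), labels))
})

test_that("cross-validation metrics reconcile with their confusion counts", {
  tp <- toy_problem(n = 60)
  cv <- cross_validate(tp$X, tp$y, k = 5, seed = 11, ntree = 100)
  expect_equal(cv$accuracy, (cv$tp + cv$tn) / length(tp$y))
  expect_equal(cv$sensitivity, cv$tp / (cv$tp + cv$fn))
  expect_equal(cv$specificity, cv$tn / (cv$tn + cv$fp))
  expect_equal(cv$fdr, cv$fp / (cv$fp + cv$tp))
  expect_true(all(c(cv$auc, cv$accuracy, cv$sensitivity, cv$specificity,
                    cv$fdr) >= 0))
  expect_equal(nrow(cv$folds), 5)
  expect_gt(cv$auc, 0.9)  # separable problem
  # deterministic rerun
  cv2 <- cross_validate(tp$X, tp$y, k = 5, seed = 11, ntree = 100)
  expect_identical(cv$probs, cv2$probs)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(cross_validate(tp$X, tp$y, k = 100), "exceeds")
})

test_that("robustness curve is sorted and consistent at fraction one", {
  tp <- toy_problem(n = 60)
  rc <- robustness_curve(tp$X, tp$y, fractions = c(0.5, 0.25, 1), reps = 3,
                         seed = 13, ntree = 100, k = 5)
  expect_equal(rc$fraction, c(0.25, 0.5, 1))
  cv <- cross_validate(tp$X, tp$y, k = 5, seed = 13, ntree = 100)
  expect_equal(rc$accuracy[rc$fraction == 1], cv$accuracy, tolerance = 0.15)
  expect_true(all(rc$accuracy >= 0 & rc$accuracy <= 1))
})

test_that("sham control evaluates one sham per drug", {
  gi50 <- matrix(10^runif(40, -1, 1), 5, 8,
                 dimnames = list(paste0("d", 1:5), paste0("c", 1:8)))
  n_feat <- 16
  set.seed(8)
  X <- matrix(rnorm(30 * n_feat), 30, n_feat,
              dimnames = list(NULL, c(paste0("mu_c", 1:8),
                                      paste0("delta_c", 1:8))))
  y <- X[, 1] > 0
  bundle <- train_model(X, y, ntree = 50, seed = 3)
  got <- sham_control(bundle, gi50)
  expect_equal(got$n, 5)
  expect_length(got$probs, 5)
  expect_equal(got$rate, 1 - length(got$positive_drugs) / 5)
})

test_that("feature importances are a normalized deterministic ranking", {
  tp <- toy_problem()
  bundle <- train_model(tp$X, tp$y, seed = 7, ntree = 200)
  imp <- feature_importance(bundle)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_true(all(diff(imp$importance) <= 0))
  expect_equal(imp$feature[1], "f1")  # the planted informative feature
})

test_that("group contrast matches a brute-force ECDF oracle", {
  same <- contrast_predicted_groups(rep(c(1, 2, 3), 2),
                                    rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$D, 0)
  sep <- contrast_predicted_groups(c(1:5, 11:15), rep(c(TRUE, FALSE), each = 5))
  expect_equal(sep$D, 1)
  set.seed(407)
  x <- rnorm(5); y <- rnorm(5, 1)
  got <- contrast_predicted_groups(c(x, y), rep(c(TRUE, FALSE), each = 5))
  expect_equal(got$D, ks_oracle(x, y), tolerance = 1e-12)
  expect_error(contrast_predicted_groups(1:4, rep(TRUE, 4)), "non-empty")
})
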