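test_that("the hyperparameter grid enumerates powers of two over the exponent range", {
  expect_length(grid_values(-8, 8, 0.5), 33)
  expect_equal(grid_values(0, 0, 0.5), 1)
  expect_equal(grid_values(-1, 1, 1), c(0.5, 1, 2))
  expect_error(grid_values(0, 1, 0), class = "boldhurst_invalid_input")
})

separable_fm <- function(seed = 17) {
  make_toy_fm(n_mci = 10, n_hc = 10, k = 2, affected = 1:2, shift = 10,
              sd = 0.5, seed = seed)
}

test_that("a separable toy problem is classified perfectly at mid-grid points", {
  fm <- separable_fm()
  train <- boldhurst:::subset_features(fm, c(1:8, 11:18))
  test <- boldhurst:::subset_features(fm, c(9:10, 19:20))
  out <- train_predict(train, test, gamma = 0.5, C = 1)
  expect_identical(out$predicted_label, test$groups)
  self <- train_predict(train, train, gamma = 0.5, C = 1)
  expect_identical(self$predicted_label, train$groups)
  # MCI-positive orientation of decision values
  expect_true(all(self$decision_value[self$true_label == "MCI"] > 0))
})

test_that("swapping training labels flips every decision-value sign", {
  fm <- make_toy_fm(n_mci = 8, n_hc = 8, k = 3, affected = 1, shift = 2, seed = 18)
  train <- boldhurst:::subset_features(fm, 1:14)
  test <- boldhurst:::subset_features(fm, 15:16)
  swapped <- train
  swapped$groups <- ifelse(train$groups == "MCI", "HC", "MCI")
  a <- train_predict(train, test, gamma = 0.25, C = 2)
  b <- train_predict(swapped, test, gamma = 0.25, C = 2)
  expect_equal(b$decision_value, -a$decision_value, tolerance = 1e-8)
})

test_that("single-class training sets are rejected", {
  fm <- make_toy_fm(n_mci = 6, n_hc = 6, seed = 19)
  mci_only <- boldhurst:::subset_features(fm, 1:6)
  expect_error(train_predict(mci_only, fm, gamma = 1, C = 1),
               class = "boldhurst_invalid_input")
})

test_that("LOOCV runs one fold per subject and a one-point grid equals loocv_at_point", {
  fm <- make_toy_fm(n_mci = 7, n_hc = 7, k = 5, affected = 1:2, shift = 2, seed = 20)
  at <- loocv_at_point(fm, gamma = 0.5, C = 1)
  expect_identical(nrow(at$outcomes), 14L)
  expect_identical(at$outcomes$held_out_id, fm$subject_ids)
  cv <- grid_search(fm, gammas = 0.5, Cs = 1)
  expect_equal(cv$accuracy, at$accuracy)
  expect_equal(unname(cv$per_point_accuracy[1, 1]), at$accuracy)
})

test_that("the best grid accuracy dominates fixed points, with order-free tie-breaks", {
  fm <- make_toy_fm(n_mci = 8, n_hc = 8, k = 4, affected = 1, shift = 1.5, seed = 21)
  g <- grid_values(-2, 2, 1); C <- grid_values(-2, 2, 1)
  cv <- grid_search(fm, g, C)
  expect_identical(dim(cv$per_point_accuracy), c(5L, 5L))
  expect_true(all(cv$per_point_accuracy <= max(cv$per_point_accuracy)))
  expect_equal(cv$accuracy, max(cv$per_point_accuracy))
  # reversing the grid axes must select the same (gamma, C)
  cv2 <- grid_search(fm, rev(g), rev(C))
  expect_equal(cv2$best_gamma, cv$best_gamma)
  expect_equal(cv2$best_C, cv$best_C)
})

test_that("grid search is deterministic", {
  fm <- make_toy_fm(n_mci = 6, n_hc = 6, k = 4, affected = 1, shift = 1.5, seed = 22)
  a <- grid_search(fm, grid_values(-1, 1, 1), grid_values(-1, 1, 1))
  b <- grid_search(fm, grid_values(-1, 1, 1), grid_values(-1, 1, 1))
  expect_identical(a$fold_outcomes$predicted_label, b$fold_outcomes$predicted_label)
  expect_identical(a$per_point_accuracy, b$per_point_accuracy)
  expect_identical(a$retention$counts, b$retention$counts)
})

test_that("confusion metrics use MCI as the positive class", {
  mk <- function(n_mci_ok, n_mci, n_hc_ok, n_hc) {
    data.frame(
      true_label = c(rep("MCI", n_mci), rep("HC", n_hc)),
      predicted_label = c(rep("MCI", n_mci_ok), rep("HC", n_mci - n_mci_ok),
                          rep("HC", n_hc_ok), rep("MCI", n_hc - n_hc_ok)))
  }
  cm <- confusion_metrics(mk(53, 64, 50, 60))
  expect_equal(round(100 * cm$sensitivity, 1), 82.8)
  expect_equal(round(100 * cm$specificity, 1), 83.3)
  expect_equal(round(100 * cm$accuracy, 1), 83.1)
  all_ok <- confusion_metrics(mk(5, 5, 5, 5))
  expect_equal(unlist(all_ok), c(accuracy = 1, sensitivity = 1, specificity = 1))
  all_mci <- confusion_metrics(mk(5, 5, 0, 5))
  expect_equal(all_mci$sensitivity, 1); expect_equal(all_mci$specificity, 0)
})

test_that("AUC is the tie-aware Mann-Whitney concordance probability", {
  out <- function(pos, neg) data.frame(
    true_label = c(rep("MCI", length(pos)), rep("HC", length(neg))),
    decision_value = c(pos, neg))
  expect_equal(roc_auc(out(c(3, 2), c(1, 0)))$auc, 1)
  expect_equal(roc_auc(out(c(3, 1), c(2, 0)))$auc, 0.75)
  # label swap complements the area
  expect_equal(roc_auc(out(c(2, 0), c(3, 1)))$auc, 0.25)
  set.seed(23)
  for (i in 1:20) {
    pos <- sample(round(rnorm(sample(3:30, 1)), 1))  # rounded values force ties
    neg <- sample(round(rnorm(sample(3:30, 1)), 1))
    expect_equal(roc_auc(out(pos, neg))$auc, auc_brute(pos, neg),
                 tolerance = 1e-12)
  }
  # ROC curve endpoints
  curve <- roc_auc(out(c(3, 1), c(2, 0)))$curve
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1); expect_equal(curve$tpr[nrow(curve)], 1)
})

test_that("retention thresholds follow ceiling(fraction x folds)", {
  mk_out <- function(n_folds, retained) {
    d <- data.frame(held_out_id = as.character(seq_len(n_folds)))
    d$retained_features <- I(retained)
    d
  }
  out <- mk_out(124, replicate(124, c(1L, 3L), simplify = FALSE))
  r <- retention_analysis(out, n_features = 5)
  expect_identical(r$threshold, 118L)
  expect_identical(r$stable, c(1L, 3L))
  r100 <- retention_analysis(mk_out(100, replicate(100, 2L, simplify = FALSE)),
                             n_features = 3)
  expect_identical(r100$threshold, 95L)
  expect_identical(r100$stable, 2L)
  # a feature retained in every fold is always stable
  expect_true(1L %in% r$stable)
})

test_that("fold-level selection and training ignore the held-out subject entirely", {
  fm <- make_toy_fm(n_mci = 8, n_hc = 8, k = 6, affected = 1:2, shift = 1.5,
                    seed = 24)
  poisoned <- fm
  i <- 3L
  poisoned$values[i, ] <- 1e6  # sentinel garbage in the held-out row
  # other folds see the sentinel row in training and may hit the
  # empty-selection fallback; fold i must be unaffected
  f1 <- boldhurst:::loocv_folds(fm)[[i]]
  f2 <- suppressWarnings(boldhurst:::loocv_folds(poisoned))[[i]]
  expect_identical(f1$sel$retained, f2$sel$retained)
  expect_identical(f1$sel$p_values, f2$sel$p_values)
  expect_identical(f1$train_x, f2$train_x)
  expect_identical(f1$train_y, f2$train_y)
})

test_that("holdout validation honours split sizes and separates a strong effect", {
  fm <- make_toy_fm(n_mci = 16, n_hc = 15, k = 6, affected = 1:3, shift = 3,
                    seed = 25)
  hv <- holdout_validation(fm, n_train_mci = 10, n_train_hc = 10,
                           n_test_mci = 6, n_test_hc = 5,
                           gammas = grid_values(-2, 2, 1),
                           Cs = grid_values(-2, 2, 1), seed = 4)
  expect_identical(nrow(hv$outcomes), 11L)
  expect_length(intersect(hv$train_ids, hv$test_ids), 0)
  expect_gte(hv$accuracy, 0.75)
  expect_error(
    holdout_validation(fm, n_train_mci = 50, n_train_hc = 10,
                       n_test_mci = 6, n_test_hc = 5),
    class = "boldhurst_invalid_input")
})
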