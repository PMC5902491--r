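# Nested leave-one-out SVM classification. Feature selection (t-test +
# Fisher score) and feature standardization are re-fit inside every
# training fold, so the held-out subject never influences them; the
# (gamma, C) grid search scores each point by LOOCV accuracy and reports
# the best point, as in the original grid-search protocol. That maximum
# is optimistically biased as an estimate of generalization accuracy; the
# full per-point accuracy table is kept so callers can report unbiased
# summaries (e.g. the per-point median) instead.

#' Power-of-two grid values
#'
#' @param lo_exp,hi_exp inclusive exponent range.
#' @param step exponent step (> 0).
#' @return numeric vector `2^seq(lo_exp, hi_exp, step)`; the default
#'   -8..8 by 0.5 gives the 33 values of the standard 33 x 33 grid.
#' @export
grid_values <- function(lo_exp = -8, hi_exp = 8, step = 0.5) {
  if (step <= 0) stop_invalid("step must be > 0")
  2^seq(lo_exp, hi_exp, by = step)
}

# z-score columns by training mean/SD; constant columns are centred only.
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

# Fit an SVM and return MCI-oriented decision values for `test`.
svm_decision <- function(train_x, train_y, test_x, gamma, C, kernel) {
  fit <- e1071::svm(train_x, train_y, scale = FALSE, kernel = kernel,
                    gamma = gamma, cost = C)
  pr <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value toward the first factor level seen in
  # training; flip so that positive always means MCI
  if (!grepl("^MCI/", colnames(dv)[1L])) dv <- -dv
  list(predicted = as.character(pr), decision_value = as.numeric(dv[, 1L]))
}

#' Train on one set, predict another
#'
#' Fits a soft-margin SVM at a single `(gamma, C)` point on the training
#' view and predicts the test view. Features may first be restricted to a
#' retained set; standardization (z-score) parameters are estimated on the
#' training rows only and applied unchanged to the test rows. Decision
#' values are oriented so that positive means MCI.
#'
#' @param train,test [feature_matrix()] views.
#' @param gamma RBF kernel width parameter.
#' @param C soft-margin penalty.
#' @param features optional integer column indices to use (default: all).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @return data.frame with `held_out_id`, `true_label`, `predicted_label`,
#'   `decision_value`.
#' @export
train_predict <- function(train, test, gamma, C, features = NULL,
                          kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  if (length(unique(train$groups)) < 2L) {
    stop_invalid("training set contains a single class")
  }
  if (is.null(features)) features <- seq_len(ncol(train$values))
  st <- standardize_train_test(train$values[, features, drop = FALSE],
                               test$values[, features, drop = FALSE])
  y <- factor(train$groups, levels = c("MCI", "HC"))
  dec <- svm_decision(st$train, y, st$test, gamma, C, kernel)
  data.frame(held_out_id = test$subject_ids,
             true_label = test$groups,
             predicted_label = dec$predicted,
             decision_value = dec$decision_value,
             stringsAsFactors = FALSE)
}

# Precompute everything (gamma, C)-independent for each LOOCV fold:
# the per-fold feature selection and the standardized train/test features.
loocv_folds <- function(fm, alpha = 0.05) {
  n <- nrow(fm$values)
  if (n < 2L) stop_invalid("LOOCV needs >= 2 subjects")
  if (length(unique(fm$groups)) < 2L) stop_invalid("both classes required")
  lapply(seq_len(n), function(i) {
    train <- subset_features(fm, -i)
    sel <- select_features(train, alpha)
    st <- standardize_train_test(
      train$values[, sel$retained, drop = FALSE],
      fm$values[i, sel$retained, drop = FALSE])
    list(i = i, sel = sel,
         train_x = st$train,
         train_y = factor(train$groups, levels = c("MCI", "HC")),
         test_x = st$test)
  })
}

#' Leave-one-out CV accuracy at one grid point
#'
#' Runs N folds: fold i selects features on the other N-1 subjects, trains
#' at `(gamma, C)` and predicts subject i. Fold-level feature selection can
#' be precomputed once with the internal fold cache and shared across grid
#' points, which is what [grid_search()] does.
#'
#' @param fm a [feature_matrix()].
#' @param gamma,C SVM hyperparameters.
#' @param alpha t-test selection level.
#' @param kernel `"radial"` or `"linear"`.
#' @param folds optional precomputed fold cache (internal use).
#' @return list with `accuracy` and `outcomes` (data.frame of per-fold
#'   predictions, decision values and retained feature indices).
#' @export
loocv_at_point <- function(fm, gamma, C, alpha = 0.05,
                           kernel = c("radial", "linear"), folds = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(folds)) folds <- loocv_folds(fm, alpha)
  res <- lapply(folds, function(f) {
    dec <- svm_decision(f$train_x, f$train_y, f$test_x, gamma, C, kernel)
    data.frame(held_out_id = fm$subject_ids[f$i],
               true_label = fm$groups[f$i],
               predicted_label = dec$predicted,
               decision_value = dec$decision_value,
               stringsAsFactors = FALSE)
  })
  outcomes <- do.call(rbind, res)
  outcomes$retained_features <- I(lapply(folds, function(f) f$sel$retained))
  list(accuracy = mean(outcomes$predicted_label == outcomes$true_label),
       outcomes = outcomes)
}

#' Grid-search nested LOOCV
#'
#' Evaluates LOOCV accuracy at every `(gamma, C)` pair of the grid
#' (default 33 x 33, exponents -8..8 by 0.5) and reports the best point,
#' with ties broken deterministically toward the smallest `C`, then the
#' smallest `gamma`. Confusion metrics, pooled-decision-value ROC/AUC and
#' per-feature retention counts are computed from the best point's folds
#' (retention is a per-fold quantity and identical across grid points).
#'
#' @param fm a [feature_matrix()].
#' @param gammas,Cs grid axes (default [grid_values()]).
#' @param alpha t-test selection level.
#' @param kernel `"radial"` or `"linear"`.
#' @param stability_fraction fraction of folds a feature must survive to be
#'   reported stable (default 0.95).
#' @return object of class `cv_result`: list with `best_gamma`, `best_C`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `roc`,
#'   `per_point_accuracy` (gamma x C matrix), `fold_outcomes`,
#'   `retention`, `selection_p_values`, `selection_fisher_scores`.
#' @export
grid_search <- function(fm, gammas = grid_values(), Cs = grid_values(),
                        alpha = 0.05, kernel = c("radial", "linear"),
                        stability_fraction = 0.95) {
  kernel <- match.arg(kernel)
  if (!length(gammas) || !length(Cs)) stop_invalid("grid must be non-empty")
  folds <- loocv_folds(fm, alpha)
  n <- length(folds)
  truth <- fm$groups
  acc <- matrix(NA_real_, length(gammas), length(Cs),
                dimnames = list(gamma = signif(gammas, 6), C = signif(Cs, 6)))
  for (gi in seq_along(gammas)) {
    for (ci in seq_along(Cs)) {
      correct <- 0L
      for (f in folds) {
        dec <- svm_decision(f$train_x, f$train_y, f$test_x,
                            gammas[gi], Cs[ci], kernel)
        correct <- correct + (dec$predicted == truth[f$i])
      }
      acc[gi, ci] <- correct / n
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(Cs[best[, 2L]], gammas[best[, 1L]]), , drop = FALSE][1L, ]
  best_gamma <- gammas[best[1L]]; best_C <- Cs[best[2L]]
  at_best <- loocv_at_point(fm, best_gamma, best_C, alpha, kernel, folds)
  cm <- confusion_metrics(at_best$outcomes)
  roc <- roc_auc(at_best$outcomes)
  retention <- retention_analysis(at_best$outcomes,
                                  n_features = ncol(fm$values),
                                  stability_fraction = stability_fraction)
  sel_p <- do.call(rbind, lapply(folds, function(f) f$sel$p_values))
  sel_fs <- do.call(rbind, lapply(folds, function(f) f$sel$fisher_scores))
  structure(list(
    best_gamma = best_gamma, best_C = best_C,
    accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    auc = roc$auc, roc = roc$curve,
    per_point_accuracy = acc,
    fold_outcomes = at_best$outcomes,
    retention = retention,
    selection_p_values = sel_p,
    selection_fisher_scores = sel_fs,
    kernel = kernel, alpha = alpha
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Nested LOOCV (%s kernel): accuracy %.1f%%, sensitivity %.1f%%, ",
    "specificity %.1f%%, AUC %.3f\n  best point gamma = %g, C = %g; ",
    "%d stable feature(s) at threshold %d/%d folds\n"),
    x$kernel, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    x$auc, x$best_gamma, x$best_C,
    length(x$retention$stable), x$retention$threshold, x$retention$n_folds))
  invisible(x)
}

#' Confusion metrics with MCI as the positive class
#'
#' @param outcomes data.frame with `true_label` and `predicted_label`.
#' @return list with `accuracy`, `sensitivity` (correct rate among MCI) and
#'   `specificity` (correct rate among HC).
#' @export
confusion_metrics <- function(outcomes) {
  if (!nrow(outcomes)) stop_invalid("no outcomes")
  correct <- outcomes$predicted_label == outcomes$true_label
  mci <- outcomes$true_label == "MCI"
  list(accuracy = mean(correct),
       sensitivity = mean(correct[mci]),
       specificity = mean(correct[!mci]))
}

#' Empirical ROC curve and AUC from decision values
#'
#' Pools the per-fold decision values (oriented MCI-positive) and computes
#' the empirical ROC and its area. The AUC is computed as the normalized
#' Mann-Whitney rank statistic — the probability that a random MCI subject
#' outscores a random HC subject, with ties counted one half.
#'
#' @param outcomes data.frame with `true_label` and `decision_value`.
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr` sorted
#'   along decreasing threshold).
#' @export
roc_auc <- function(outcomes) {
  pos <- outcomes$decision_value[outcomes$true_label == "MCI"]
  neg <- outcomes$decision_value[outcomes$true_label == "HC"]
  if (!length(pos) || !length(neg)) stop_invalid("both classes required for ROC")
  if (!all(is.finite(c(pos, neg)))) stop_invalid("decision values must be finite")
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  )
  list(auc = auc, curve = curve)
}

#' Feature retention stability over CV folds
#'
#' Counts, for every feature, the number of folds whose training-set
#' selection retained it; features retained in at least
#' `ceiling(stability_fraction * n_folds)` folds form the stable set (with
#' 124 folds and fraction 0.95 the threshold is 118).
#'
#' @param outcomes fold outcomes carrying a `retained_features` list column.
#' @param n_features total number of candidate features.
#' @param stability_fraction stability fraction (default 0.95).
#' @return list with `counts` (per feature), `threshold`, `stable`
#'   (feature indices), `n_folds`.
#' @export
retention_analysis <- function(outcomes, n_features,
                               stability_fraction = 0.95) {
  folds <- outcomes$retained_features
  n_folds <- length(folds)
  counts <- tabulate(unlist(folds), nbins = n_features)
  threshold <- as.integer(ceiling(stability_fraction * n_folds))
  list(counts = counts, threshold = threshold,
       stable = which(counts >= threshold), n_folds = n_folds)
}

#' Holdout validation with an internal two-fold search
#'
#' Randomly splits the cohort (stratified, seeded) into a training subset
#' (default 42 MCI + 40 HC) and a test subset (default 22 MCI + 20 HC).
#' `(gamma, C)` is chosen by the mean accuracy of an internal two-fold
#' cross-prediction inside the training subset — the training set is evenly
#' divided in two, each half (with its own feature selection) trains a
#' model that predicts the other half. The final model re-selects features
#' on the full training subset and is scored once on the held-out test
#' subset.
#'
#' @param fm a [feature_matrix()].
#' @param n_train_mci,n_train_hc,n_test_mci,n_test_hc split sizes; they
#'   must not exceed the available group counts.
#' @param gammas,Cs grid axes.
#' @param alpha t-test selection level.
#' @param kernel `"radial"` or `"linear"`.
#' @param seed split seed.
#' @return list with `accuracy`, `best_gamma`, `best_C`, `outcomes`,
#'   `inner_accuracy` (gamma x C matrix), `train_ids`, `test_ids`.
#' @export
holdout_validation <- function(fm, n_train_mci = 42L, n_train_hc = 40L,
                               n_test_mci = 22L, n_test_hc = 20L,
                               gammas = grid_values(), Cs = grid_values(),
                               alpha = 0.05, kernel = c("radial", "linear"),
                               seed = 1L) {
  kernel <- match.arg(kernel)
  mci <- which(fm$groups == "MCI"); hc <- which(fm$groups == "HC")
  if (n_train_mci + n_test_mci > length(mci) ||
      n_train_hc + n_test_hc > length(hc)) {
    stop_invalid("split sizes exceed available subjects (",
                 length(mci), " MCI, ", length(hc), " HC)")
  }
  idx <- with_seed(seed, {
    mci_s <- sample(mci); hc_s <- sample(hc)
    train <- c(mci_s[seq_len(n_train_mci)], hc_s[seq_len(n_train_hc)])
    test <- c(mci_s[n_train_mci + seq_len(n_test_mci)],
              hc_s[n_train_hc + seq_len(n_test_hc)])
    # even internal halves, stratified by group
    halfA <- c(mci_s[seq_len(n_train_mci)][seq_len(n_train_mci) %% 2L == 1L],
               hc_s[seq_len(n_train_hc)][seq_len(n_train_hc) %% 2L == 1L])
    list(train = train, test = test, halfA = halfA,
         halfB = setdiff(train, halfA))
  })
  half <- list(subset_features(fm, idx$halfA), subset_features(fm, idx$halfB))
  half_sel <- lapply(half, select_features, alpha = alpha)
  inner <- matrix(NA_real_, length(gammas), length(Cs),
                  dimnames = list(gamma = signif(gammas, 6), C = signif(Cs, 6)))
  for (gi in seq_along(gammas)) {
    for (ci in seq_along(Cs)) {
      accs <- vapply(1:2, function(a) {
        b <- 3L - a
        out <- train_predict(half[[a]], half[[b]], gammas[gi], Cs[ci],
                             features = half_sel[[a]]$retained, kernel = kernel)
        mean(out$predicted_label == out$true_label)
      }, numeric(1))
      inner[gi, ci] <- mean(accs)
    }
  }
  best <- which(inner == max(inner), arr.ind = TRUE)
  best <- best[order(Cs[best[, 2L]], gammas[best[, 1L]]), , drop = FALSE][1L, ]
  train_fm <- subset_features(fm, idx$train)
  test_fm <- subset_features(fm, idx$test)
  sel <- select_features(train_fm, alpha)
  out <- train_predict(train_fm, test_fm, gammas[best[1L]], Cs[best[2L]],
                       features = sel$retained, kernel = kernel)
  list(accuracy = mean(out$predicted_label == out$true_label),
       best_gamma = gammas[best[1L]], best_C = Cs[best[2L]],
       outcomes = out, inner_accuracy = inner,
       train_ids = fm$subject_ids[idx$train],
       test_ids = fm$subject_ids[idx$test])
}
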