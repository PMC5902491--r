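# Univariate discriminative feature selection: a two-sample pooled t-test
# (p < alpha, uncorrected) retains features, and the Fisher score ranks
# them. Always applied to training subjects only; the cross-validation
# driver passes fold views so no held-out row is ever seen here.

#' Two-group summary statistics of one feature
#'
#' Group means and variances feeding the Fisher score. Variances use the
#' population convention (divide by n), matching the classical Fisher-score
#' form in which each group variance is weighted by its sample count.
#'
#' @param feature numeric vector.
#' @param groups character vector, `"MCI"` / `"HC"`, same length.
#' @return list with `n1`, `n2`, `m1`, `m2`, `m` (pooled mean), `var1`,
#'   `var2`; group 1 is MCI.
#' @export
group_stats <- function(feature, groups) {
  stopifnot(length(feature) == length(groups))
  g1 <- feature[groups == "MCI"]
  g2 <- feature[groups == "HC"]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_invalid("each group needs >= 2 members (got ",
                 length(g1), " MCI, ", length(g2), " HC)")
  }
  pop_var <- function(x) mean((x - mean(x))^2)
  list(n1 = length(g1), n2 = length(g2),
       m1 = mean(g1), m2 = mean(g2), m = mean(feature),
       var1 = pop_var(g1), var2 = pop_var(g2))
}

#' Fisher score of a feature
#'
#' Between-group over within-group variance ratio
#' \deqn{FS = \frac{n_1 (m_1 - m)^2 + n_2 (m_2 - m)^2}
#'            {n_1 \sigma_1^2 + n_2 \sigma_2^2}}
#' with group counts \eqn{n_k}, group means \eqn{m_k}, pooled mean \eqn{m}
#' and population group variances \eqn{\sigma_k^2}. Larger scores indicate
#' stronger univariate discrimination.
#'
#' @param stats result of [group_stats()].
#' @return non-negative scalar.
#' @export
fisher_score <- function(stats) {
  den <- stats$n1 * stats$var1 + stats$n2 * stats$var2
  if (den <= 0) {
    stop(errorCondition("both groups constant: Fisher score undefined",
                        class = c("boldhurst_degenerate_feature", "error")))
  }
  (stats$n1 * (stats$m1 - stats$m)^2 + stats$n2 * (stats$m2 - stats$m)^2) / den
}

#' Two-sample pooled-variance t-test of one feature
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-tailed. Degenerate features (zero pooled variance) return `p = 1`
#' when the means agree and `p = 0` (flagged) when they differ.
#'
#' @param feature numeric vector.
#' @param groups `"MCI"` / `"HC"` labels; MCI is group 1.
#' @return list with `t`, `p`, and logical `degenerate`.
#' @export
two_sample_t <- function(feature, groups) {
  g1 <- feature[groups == "MCI"]
  g2 <- feature[groups == "HC"]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_invalid("each group needs >= 2 members")
  }
  if (stats::var(g1) + stats::var(g2) == 0) {
    if (mean(g1) == mean(g2)) return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(g1) - mean(g2)) * Inf, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(g1, g2, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Select discriminative features on a training set
#'
#' Retains every feature whose two-tailed pooled t-test p-value is below
#' `alpha` (uncorrected), ordered by descending Fisher score; the score and
#' p-value of every feature are recorded. When nothing passes, the single
#' best-Fisher-score feature is retained instead (a fold must still emit a
#' prediction) and a `boldhurst_empty_selection` warning is raised.
#'
#' @param fm a [feature_matrix()] restricted to training subjects (the
#'   caller is responsible for passing a fold view).
#' @param alpha significance level of the t-test filter (default 0.05).
#' @return object of class `selection_result`: list with `retained`
#'   (ordered column indices), `p_values`, `fisher_scores`, `alpha`,
#'   `fallback` flag.
#' @export
select_features <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  K <- ncol(fm$values)
  p <- numeric(K)
  fs <- numeric(K)
  for (j in seq_len(K)) {
    p[j] <- two_sample_t(fm$values[, j], fm$groups)$p
    st <- group_stats(fm$values[, j], fm$groups)
    fs[j] <- if (st$n1 * st$var1 + st$n2 * st$var2 > 0) fisher_score(st) else NA_real_
  }
  pass <- which(p < alpha)
  fallback <- FALSE
  if (!length(pass)) {
    warning(warningCondition(
      sprintf("no feature passed the t-test filter at alpha=%g; falling back to the top Fisher-score feature", alpha),
      class = "boldhurst_empty_selection"))
    pass <- which.max(fs)
    fallback <- TRUE
  }
  retained <- pass[order(fs[pass], decreasing = TRUE)]
  structure(list(retained = retained, p_values = p, fisher_scores = fs,
                 alpha = alpha, fallback = fallback),
            class = "selection_result")
}
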