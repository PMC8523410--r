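#' Receiver operating characteristic curve
#'
#' Sweeps every distinct score value as a decision threshold (predict
#' positive when `score >= threshold`), from `+Inf` down, giving a curve
#' from (0, 0) to (1, 1) that is monotone in both coordinates. The area
#' under the curve is computed by the trapezoidal rule, which equals the
#' tie-corrected rank statistic \eqn{U/(n_+ n_-)} (concordant pairs plus
#' half of the tied pairs).
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels (logical, or 0/1), both classes present.
#' @return an object of class `usj_roc`: list with `thresholds`,
#'   `sensitivity`, `one_minus_specificity` (aligned vectors) and
#'   `auroc`.
#' @export
roc <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  if (length(scores) != length(labels)) stopf("length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present to sweep a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg,
                numeric(1))
  auroc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  structure(list(thresholds = thr, sensitivity = sens,
                 one_minus_specificity = fpr, auroc = auroc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "usj_roc")
}

#' @export
print.usj_roc <- function(x, ...) {
  cat(sprintf("<usj_roc> AUROC %.3f (%d positive / %d negative)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Maximizes Youden's index J = sensitivity + specificity - 1 over the
#' curve's thresholds; ties are broken toward higher sensitivity.
#'
#' @param curve a `usj_roc`.
#' @return list with `sensitivity` and `specificity` (both %), the
#'   `threshold` achieving them, and `youden_j`.
#' @export
youden_optimum <- function(curve) {
  stopifnot(inherits(curve, "usj_roc"))
  j <- curve$sensitivity - curve$one_minus_specificity
  best <- which(j == max(j))
  best <- best[which.max(curve$sensitivity[best])]
  list(sensitivity = 100 * curve$sensitivity[best],
       specificity = 100 * (1 - curve$one_minus_specificity[best]),
       threshold = curve$thresholds[best], youden_j = max(j))
}

#' One-vs-rest ROC analysis for a multi-class prediction
#'
#' Builds one ROC curve per class, scoring each sample by that class's
#' predicted probability against the binary truth "is this class". The
#' macro-average AUROC is the unweighted mean of the per-class areas.
#' Classes absent from the truth are skipped with a warning.
#'
#' @param cls_prob N x K matrix of class probabilities.
#' @param true_labels length-N vector of labels from `class_names`.
#' @param class_names ordered class names matching the columns.
#' @return list with `per_class` (named list of `usj_roc`) and
#'   `macro_auroc`.
#' @export
multiclass_roc <- function(cls_prob, true_labels,
                           class_names = lesion_classes) {
  stopifnot(ncol(cls_prob) == length(class_names))
  curves <- list()
  for (k in seq_along(class_names)) {
    pos <- true_labels == class_names[k]
    if (!any(pos) || all(pos)) {
      warning(sprintf("class '%s' absent from truth (or only class); %s",
                      class_names[k], "skipped"))
      next
    }
    curves[[class_names[k]]] <- roc(cls_prob[, k], pos)
  }
  list(per_class = curves,
       macro_auroc = mean(vapply(curves, `[[`, numeric(1), "auroc")))
}

#' Bootstrap confidence interval for an AUROC
#'
#' Percentile interval over seeded case resamples (stratification-free
#' resampling of (score, label) pairs; resamples with a single class are
#' redrawn).
#'
#' @param scores,labels as in [roc()].
#' @param n_resamples bootstrap resamples.
#' @param level confidence level.
#' @param rng_seed integer seed.
#' @return numeric vector `c(lower, upper)`.
#' @export
auroc_ci <- function(scores, labels, n_resamples = 2000, level = 0.95,
                     rng_seed = 0) {
  labels <- labels > 0
  n <- length(scores)
  with_seed(rng_seed, {
    stat <- vapply(seq_len(n_resamples), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(labels[idx]) && any(!labels[idx])) break
      }
      roc(scores[idx], labels[idx])$auroc
    }, numeric(1))
    unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Paired resampling comparison of two metric samples
#'
#' Two-sided p-value for the mean paired difference under the sign-flip
#' permutation null (each pair's difference is equally likely to carry
#' either sign). With `n <= max_exact` pairs all `2^n` sign assignments
#' are enumerated exactly; otherwise `n_resamples` random assignments
#' are drawn, seeded.
#'
#' @param a,b equal-length paired samples.
#' @param n_resamples Monte Carlo resamples when enumeration is
#'   infeasible.
#' @param rng_seed integer seed.
#' @param max_exact enumeration limit on the number of pairs.
#' @return p-value in (0, 1\].
#' @export
compare_paired <- function(a, b, n_resamples = 2000, rng_seed = 0,
                           max_exact = 14) {
  if (length(a) != length(b)) stopf("paired samples differ in length")
  d <- a - b
  n <- length(d)
  obs <- abs(mean(d))
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    return(mean(stat >= obs - 1e-12))
  }
  with_seed(rng_seed, {
    hits <- vapply(seq_len(n_resamples), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      abs(mean(s * d)) >= obs - 1e-12
    }, logical(1))
    (1 + sum(hits)) / (1 + n_resamples)
  })
}
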