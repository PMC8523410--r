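#' Jaccard index between two binary masks
#'
#' Area of the intersection divided by the area of the union. Symmetric
#' in its arguments. If both masks are empty the index is defined as 1
#' (identical empty segmentations), a convention that cannot arise when
#' the reference mask contains a lesion.
#'
#' @param pred_mask,ref_mask binary matrices of the same shape.
#' @return fraction in \[0, 1\].
#' @export
jaccard <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stopf("mask shapes differ: %s vs %s",
          paste(dim(pred_mask), collapse = "x"),
          paste(dim(ref_mask), collapse = "x"))
  a <- pred_mask > 0
  b <- ref_mask > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Confusion matrix of a multi-class prediction
#'
#' @param true_labels,predicted_labels equal-length vectors of labels
#'   drawn from `class_names`.
#' @param class_names ordered class labels (rows = true, columns =
#'   predicted).
#' @return an object of class `usj_confusion`: integer K x K matrix with
#'   dimnames `true` x `predicted`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_names = lesion_classes) {
  if (length(true_labels) != length(predicted_labels))
    stopf("label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad))
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tt <- factor(true_labels, levels = class_names)
  pp <- factor(predicted_labels, levels = class_names)
  cm <- table(true = tt, predicted = pp)
  structure(matrix(as.integer(cm), length(class_names),
                   dimnames = list(true = class_names,
                                   predicted = class_names)),
            class = "usj_confusion")
}

#' Accuracies from a confusion matrix
#'
#' Per-class accuracy is the diagonal count over the row sum (the recall
#' of each true class), overall accuracy the trace over the total, both
#' as percentages. A class with no test examples yields `NA`.
#'
#' @param cm a `usj_confusion` or plain K x K count matrix (rows = true).
#' @return list with `overall` (%) and `per_class` (named % vector).
#' @export
accuracy_from_confusion <- function(cm) {
  m <- unclass(cm)
  if (sum(m) == 0) stopf("confusion matrix holds no counts")
  rs <- rowSums(m)
  per <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  names(per) <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  list(overall = 100 * sum(diag(m)) / sum(m), per_class = per)
}

#' @export
print.usj_confusion <- function(x, ...) {
  cat("<usj_confusion>\n")
  print(unclass(x))
  acc <- accuracy_from_confusion(x)
  cat(sprintf("overall accuracy %.1f%%\n", acc$overall))
  invisible(x)
}
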