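#' Evaluate a trained system on a test set
#'
#' Runs the full test protocol: for every test record, `n_user_inputs`
#' simulated user inputs are generated (seeds 0..n-1 offset by the image
#' index so each image sees a fixed, reproducible set of input styles)
#' and the network is applied to each. Segmentation is scored by the
#' per-image Jaccard index against the reference mask; classification by
#' the confusion matrix over all (record, input) pairs, per-class and
#' overall accuracy, the benign/malignant ROC (scored by the summed
#' malignant-class probability when the model is four-class) with its
#' Youden-optimal operating point and bootstrap AUROC interval, and
#' one-vs-rest ROC curves with macro-average AUROC for the four-class
#' task.
#'
#' @param net a trained `usj_network`.
#' @param records nonempty list of test `usj_record`.
#' @param input_mode `"two_click"` (simulated bounding box transformed to
#'   one foreground + four corner background clicks) or `"one_click"`
#'   (a single foreground click, background map filled with 255).
#'   Ignored for the `cls_only` variant, which sees lesion-centered
#'   patches.
#' @param n_user_inputs simulated user inputs per test image.
#' @param rng_seed base seed for the input simulation and bootstrap.
#' @param threshold foreground threshold on the probability map.
#' @param jitter_frac,enlarge_frac bounding-box simulation parameters
#'   (two-click mode).
#' @return an object of class `usj_eval_report`.
#' @export
evaluate_system <- function(net, records,
                            input_mode = c("two_click", "one_click"),
                            n_user_inputs = 5, rng_seed = 0,
                            threshold = 0.5, jitter_frac = 0.1,
                            enlarge_frac = 0.1) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(net, "usj_network"))
  if (length(records) == 0) stopf("empty test set")
  cfg <- net$config
  classes <- if (cfg$n_classes == 2) c("benign", "malignant")
  else lesion_classes
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    true_cls <- classes[.record_label_index(rec, cfg$n_classes)]
    if (cfg$variant == "cls_only") {
      ps <- cfg$patch_size
      x <- array(extract_patch(rec, size = ps) / 255, c(ps, ps, 1, 1))
      pred <- predict(net, x)
      rows[[length(rows) + 1]] <- tibble::tibble(
        record = i, input = 1L, label = rec$label, true_class = true_cls,
        size_mm = rec$lesion_size_mm, ji = NA_real_,
        pred_class = classes[which.max(pred$cls_prob[1, ])],
        malignant_score = sum(pred$cls_prob[1, is_malignant_class(
          classes)]),
        cls_prob = list(pred$cls_prob[1, ]))
      next
    }
    n_px <- nrow(rec$image)
    x <- array(0, c(n_px, n_px, 3, n_user_inputs))
    for (j in seq_len(n_user_inputs)) {
      s <- rng_seed + 1000L * i + (j - 1L)
      clicks <- if (input_mode == "one_click") {
        one_click_input(rec$mask, s)
      } else {
        bbox_to_clicks(simulate_bbox(rec$mask, jitter_frac,
                                     enlarge_frac, s))
      }
      x[, , , j] <- unclass(encode_input(rec$image, clicks))
    }
    pred <- predict(net, x)
    for (j in seq_len(n_user_inputs)) {
      sp <- if (n_user_inputs == 1) pred$seg_prob else pred$seg_prob[, , j]
      ji <- if (is.null(sp)) NA_real_
      else jaccard(predicted_mask(sp, threshold), rec$mask)
      if (!is.null(pred$cls_prob)) {
        cp <- pred$cls_prob[j, ]
        rows[[length(rows) + 1]] <- tibble::tibble(
          record = i, input = j, label = rec$label,
          true_class = true_cls, size_mm = rec$lesion_size_mm, ji = ji,
          pred_class = classes[which.max(cp)],
          malignant_score = sum(cp[is_malignant_class(classes)]),
          cls_prob = list(cp))
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          record = i, input = j, label = rec$label,
          true_class = true_cls, size_mm = rec$lesion_size_mm, ji = ji,
          pred_class = NA_character_, malignant_score = NA_real_,
          cls_prob = list(NULL))
      }
    }
  }
  per_input <- do.call(rbind, rows)
  report <- list(input_mode = input_mode, variant = cfg$variant,
                 n_classes = cfg$n_classes,
                 n_user_inputs = as.integer(n_user_inputs),
                 per_input = per_input)
  if (!all(is.na(per_input$ji))) {
    report$mean_ji <- mean(per_input$ji)
    report$sd_ji <- sd(per_input$ji)
  }
  if (!all(is.na(per_input$pred_class))) {
    report$confusion <- confusion(per_input$true_class,
                                  per_input$pred_class, classes)
    report$accuracy <- accuracy_from_confusion(report$confusion)
    bin_truth <- if (cfg$n_classes == 2) {
      per_input$true_class == "malignant"
    } else {
      is_malignant(per_input$label)
    }
    if (any(bin_truth) && !all(bin_truth)) {
      report$binary_roc <- roc(per_input$malignant_score, bin_truth)
      report$youden <- youden_optimum(report$binary_roc)
      report$binary_auroc_ci <- auroc_ci(per_input$malignant_score,
                                         bin_truth,
                                         rng_seed = rng_seed + 7L)
    }
    if (cfg$n_classes == 4) {
      probs <- do.call(rbind, per_input$cls_prob)
      report$multiclass <- multiclass_roc(probs, per_input$true_class,
                                          classes)
    }
  }
  structure(report, class = "usj_eval_report")
}

is_malignant_class <- function(classes) {
  classes %in% c("malignant", "metastasis", "hcc")
}

#' @export
print.usj_eval_report <- function(x, ...) {
  cat(sprintf("<usj_eval_report> %s variant, %s mode, %d predictions\n",
              x$variant, x$input_mode, nrow(x$per_input)))
  if (!is.null(x$mean_ji))
    cat(sprintf("  mean JI %.1f%% +/- %.1f\n", 100 * x$mean_ji,
                100 * x$sd_ji))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy %.1f%%\n", x$accuracy$overall))
  if (!is.null(x$binary_roc))
    cat(sprintf(paste0("  benign/malignant AUROC %.3f ",
                       "(sens %.1f%%, spec %.1f%% at Youden optimum)\n"),
                x$binary_roc$auroc, x$youden$sensitivity,
                x$youden$specificity))
  if (!is.null(x$multiclass))
    cat(sprintf("  macro-average one-vs-rest AUROC %.3f\n",
                x$multiclass$macro_auroc))
  invisible(x)
}

#' Tidy the per-prediction results of an evaluation report
#'
#' @param x a `usj_eval_report`.
#' @param ... unused.
#' @return tibble with one row per (record, user input): label, lesion
#'   size, Jaccard index, predicted class and malignant score.
#' @export
tidy.usj_eval_report <- function(x, ...) {
  x$per_input[, setdiff(names(x$per_input), "cls_prob")]
}

#' One-row summary of an evaluation report
#'
#' @param x a `usj_eval_report`.
#' @param ... unused.
#' @return one-row tibble: mean/sd Jaccard index, overall accuracy,
#'   binary AUROC with confidence bounds, Youden sensitivity and
#'   specificity, macro AUROC.
#' @export
glance.usj_eval_report <- function(x, ...) {
  tibble::tibble(
    input_mode = x$input_mode, variant = x$variant,
    n_predictions = nrow(x$per_input),
    mean_ji = x$mean_ji %||% NA_real_,
    sd_ji = x$sd_ji %||% NA_real_,
    accuracy = if (is.null(x$accuracy)) NA_real_ else x$accuracy$overall,
    binary_auroc = if (is.null(x$binary_roc)) NA_real_
    else x$binary_roc$auroc,
    auroc_lo = if (is.null(x$binary_auroc_ci)) NA_real_
    else x$binary_auroc_ci[1],
    auroc_hi = if (is.null(x$binary_auroc_ci)) NA_real_
    else x$binary_auroc_ci[2],
    youden_sensitivity = if (is.null(x$youden)) NA_real_
    else x$youden$sensitivity,
    youden_specificity = if (is.null(x$youden)) NA_real_
    else x$youden$specificity,
    macro_auroc = if (is.null(x$multiclass)) NA_real_
    else x$multiclass$macro_auroc)
}

#' Serialize an evaluation report to JSON (and back)
#'
#' The JSON round-trip preserves every metric and the per-prediction
#' table; ROC curves are stored as aligned coordinate vectors.
#'
#' @param x a `usj_eval_report`.
#' @param path file path.
#' @return `read_eval_report` returns the restored `usj_eval_report`.
#' @export
write_eval_report <- function(x, path) {
  ser_roc <- function(r) if (is.null(r)) NULL else
    list(thresholds = r$thresholds, sensitivity = r$sensitivity,
         one_minus_specificity = r$one_minus_specificity,
         auroc = r$auroc, n_pos = r$n_pos, n_neg = r$n_neg)
  per <- x$per_input
  per$cls_prob <- lapply(per$cls_prob, function(p)
    if (is.null(p)) numeric() else unname(p))
  out <- list(
    input_mode = x$input_mode, variant = x$variant,
    n_classes = x$n_classes, n_user_inputs = x$n_user_inputs,
    mean_ji = x$mean_ji, sd_ji = x$sd_ji,
    confusion = if (is.null(x$confusion)) NULL else
      list(counts = unclass(x$confusion),
           classes = rownames(x$confusion)),
    accuracy = x$accuracy, binary_roc = ser_roc(x$binary_roc),
    youden = x$youden, binary_auroc_ci = x$binary_auroc_ci,
    multiclass = if (is.null(x$multiclass)) NULL else
      list(per_class = lapply(x$multiclass$per_class, ser_roc),
           macro_auroc = x$multiclass$macro_auroc),
    per_input = per)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser_roc <- function(r) if (is.null(r)) NULL else
    structure(list(thresholds = as.numeric(r$thresholds),
                   sensitivity = r$sensitivity,
                   one_minus_specificity = r$one_minus_specificity,
                   auroc = r$auroc, n_pos = r$n_pos, n_neg = r$n_neg),
              class = "usj_roc")
  cp <- j$per_input$cls_prob
  per <- tibble::as_tibble(j$per_input[setdiff(names(j$per_input),
                                               "cls_prob")])
  per$cls_prob <- if (is.matrix(cp)) {
    lapply(seq_len(nrow(cp)), function(i) as.numeric(cp[i, ]))
  } else {
    lapply(cp, function(p) if (length(p) == 0) NULL else as.numeric(p))
  }
  out <- list(input_mode = j$input_mode, variant = j$variant,
              n_classes = j$n_classes, n_user_inputs = j$n_user_inputs,
              mean_ji = j$mean_ji, sd_ji = j$sd_ji,
              per_input = per)
  if (!is.null(j$confusion)) {
    cm <- matrix(as.integer(unlist(j$confusion$counts)),
                 length(j$confusion$classes), byrow = FALSE,
                 dimnames = list(true = j$confusion$classes,
                                 predicted = j$confusion$classes))
    out$confusion <- structure(cm, class = "usj_confusion")
    out$accuracy <- list(overall = j$accuracy$overall,
                         per_class = unlist(j$accuracy$per_class))
  }
  out$binary_roc <- deser_roc(j$binary_roc)
  if (!is.null(j$youden)) out$youden <- j$youden
  if (!is.null(j$binary_auroc_ci))
    out$binary_auroc_ci <- as.numeric(j$binary_auroc_ci)
  if (!is.null(j$multiclass))
    out$multiclass <- list(
      per_class = lapply(j$multiclass$per_class, deser_roc),
      macro_auroc = j$multiclass$macro_auroc)
  structure(out, class = "usj_eval_report")
}
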