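#' Training configuration
#'
#' SGD-with-momentum protocol: a constant learning rate for the first
#' half of the iterations and a second (usually 10x smaller) rate for
#' the second half, 0.9 momentum, 5e-4 weight decay, focal losses, and
#' flip/scale/brightness-contrast augmentation.
#'
#' The `desk` profile (2,000 iterations, batch 8, learning rates
#' 1e-2 / 1e-3) is sized for CPU-scale phantom experiments. The `paper`
#' profile reproduces the clinical-scale schedule: 150,000 iterations at
#' 5e-4 / 5e-5 for the segmentation and joint networks, and 40,000
#' iterations at 1e-3 / 1e-4 for the classification-only network.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param variant network variant the schedule is for (the
#'   classification-only network has its own paper-profile schedule).
#' @param iterations,lr_first_half,lr_second_half,batch_size overrides of
#'   the profile defaults.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution and fully connected
#'   weights.
#' @param gamma_focal focusing exponent of both focal losses.
#' @param alpha_per_class per-class weights of the classification focal
#'   loss; `NULL` means normalized inverse class frequency of the
#'   training set.
#' @param seed integer seed controlling minibatch sampling, click-sequence
#'   choice and augmentation.
#' @param augment logical; apply data augmentation.
#' @param scale_range,brightness,contrast_range,flip_prob augmentation
#'   parameters: isotropic scale factor range, additive brightness
#'   amplitude (0--255 units), multiplicative contrast gain range, and
#'   horizontal flip probability.
#' @return an object of class `usj_train_config`.
#' @export
train_config <- function(profile = c("desk", "paper"),
                         variant = c("joint", "seg_only", "cls_only"),
                         iterations = NULL,
                         lr_first_half = NULL, lr_second_half = NULL,
                         batch_size = 8, momentum = 0.9,
                         weight_decay = 5e-4, gamma_focal = 2,
                         alpha_per_class = NULL, seed = 0,
                         augment = TRUE, scale_range = c(0.8, 1.2),
                         brightness = 20, contrast_range = c(0.8, 1.25),
                         flip_prob = 0.5) {
  profile <- match.arg(profile)
  variant <- match.arg(variant)
  if (profile == "desk") {
    iterations <- iterations %||% 2000L
    lr_first_half <- lr_first_half %||% 1e-2
    lr_second_half <- lr_second_half %||% 1e-3
  } else if (variant == "cls_only") {
    iterations <- iterations %||% 40000L
    lr_first_half <- lr_first_half %||% 1e-3
    lr_second_half <- lr_second_half %||% 1e-4
  } else {
    iterations <- iterations %||% 150000L
    lr_first_half <- lr_first_half %||% 5e-4
    lr_second_half <- lr_second_half %||% 5e-5
  }
  if (iterations <= 0) stopf("iterations must be positive")
  if (lr_first_half <= 0 || lr_second_half <= 0)
    stopf("learning rates must be positive")
  if (!is.null(alpha_per_class) && any(alpha_per_class <= 0))
    stopf("alpha_per_class entries must be positive")
  structure(list(profile = profile, variant = variant,
                 iterations = as.integer(iterations),
                 lr_first_half = lr_first_half,
                 lr_second_half = lr_second_half,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, gamma_focal = gamma_focal,
                 alpha_per_class = alpha_per_class, seed = seed,
                 augment = augment, scale_range = scale_range,
                 brightness = brightness, contrast_range = contrast_range,
                 flip_prob = flip_prob), class = "usj_train_config")
}

#' Learning rate at a given iteration
#'
#' The first-half rate applies through iteration `ceil(iterations/2)`,
#' the second-half rate afterwards.
#'
#' @param config a [train_config()].
#' @param iteration 1-based iteration index.
#' @return numeric learning rate.
#' @export
lr_at <- function(config, iteration) {
  ifelse(iteration <= ceiling(config$iterations / 2),
         config$lr_first_half, config$lr_second_half)
}

#' Augment a training record and its clicks
#'
#' With probability `flip_prob` the image, mask and click coordinates are
#' flipped horizontally; the canvas is then scaled isotropically (bilinear
#' for the image, nearest-neighbor for the mask, so it stays binary) and
#' center-cropped or edge-padded back to the original size; finally a
#' random brightness offset and contrast gain are applied to the image
#' channel only. Click coordinates are transformed analytically and the
#' distance maps recomputed from them, preserving exact Euclidean
#' semantics. The class label is untouched.
#'
#' @param record a `usj_record`.
#' @param clicks a `usj_clicks` in the record's coordinate frame.
#' @param rng_seed integer seed.
#' @param scale_range,brightness,contrast_range,flip_prob see
#'   [train_config()].
#' @return list with transformed `image`, `mask`, `clicks`, `label`.
#' @export
augment <- function(record, clicks, rng_seed,
                    scale_range = c(0.8, 1.2), brightness = 20,
                    contrast_range = c(0.8, 1.25), flip_prob = 0.5) {
  img <- record$image + 0
  mask <- record$mask
  fg <- clicks$foreground
  bg <- clicks$background
  n <- nrow(img)
  with_seed(rng_seed, {
    if (runif(1) < flip_prob) {
      img <- img[, n:1]
      mask <- mask[, n:1]
      if (nrow(fg)) fg[, 2] <- n - 1L - fg[, 2]
      if (nrow(bg)) bg[, 2] <- n - 1L - bg[, 2]
    }
    s <- runif(1, scale_range[1], scale_range[2])
    n_new <- max(8L, as.integer(round(n * s)))
    if (n_new != n) {
      s_eff <- n_new / n
      simg <- as.matrix(EBImage::resize(img, w = n_new, h = n_new))
      smask <- as.matrix(EBImage::resize(mask + 0, w = n_new, h = n_new,
                                         filter = "none"))
      o <- as.integer(floor((n_new - n) / 2))
      if (n_new >= n) {
        img <- simg[o + seq_len(n), o + seq_len(n)]
        mask <- smask[o + seq_len(n), o + seq_len(n)]
      } else {
        pad_to <- function(m, fill) {
          out <- matrix(fill, n, n)
          out[(-o) + seq_len(n_new), (-o) + seq_len(n_new)] <- m
          out
        }
        img <- pad_to(simg, stats::median(simg[c(1, n_new), ]))
        mask <- pad_to(smask, 0)
      }
      tx <- function(m) {
        if (!nrow(m)) return(m)
        m2 <- round((m + 0.5) * s_eff - 0.5) - o
        matrix(as.integer(pmin(pmax(m2, 0), n - 1L)), ncol = 2,
               dimnames = dimnames(m))
      }
      fg <- tx(fg)
      bg <- tx(bg)
    }
    img <- (img - 128) * runif(1, contrast_range[1], contrast_range[2]) +
      128 + runif(1, -brightness, brightness)
    img <- pmin(pmax(img, 0), 255)
    mask <- (mask > 0.5) * 1L
    if (!any(mask > 0)) {
      # lesion scaled/cropped out of the canvas: fall back to the
      # untransformed record rather than emit an unusable sample
      return(list(image = record$image + 0, mask = record$mask,
                  clicks = clicks, label = record$label))
    }
    fg <- fg[!duplicated(fg), , drop = FALSE]
    bg <- bg[!duplicated(bg), , drop = FALSE]
    list(image = img, mask = mask,
         clicks = click_set(fg, bg), label = record$label)
  })
}

#' Attach precomputed click sequences to training records
#'
#' Generates the per-image simulated user-input sequences used during
#' training (by default 15 per image).
#'
#' @param records list of `usj_record`.
#' @param n_sequences sequences per image.
#' @param d_min,d_max background-band limits in pixels.
#' @param rng_seed integer seed.
#' @return the records, each with a `clicks` element added.
#' @export
prepare_training_set <- function(records, n_sequences = 15, d_min = 5,
                                 d_max = 40, rng_seed = 1) {
  for (i in seq_along(records)) {
    records[[i]]$clicks <- generate_click_sequences(
      records[[i]]$mask, n_sequences, d_min, d_max,
      rng_seed + 1000L * i)
  }
  records
}

# class index of a record under the network's label space
.record_label_index <- function(record, n_classes) {
  if (n_classes == 4) match(record$label, lesion_classes)
  else 1L + is_malignant(record$label)
}

#' Train a network
#'
#' Minibatch SGD with momentum and weight decay on the focal losses: the
#' pixelwise focal loss for the segmentation branch, the alpha-balanced
#' focal loss for the classification branch, and their unweighted sum for
#' the joint network. The learning rate steps from `lr_first_half` to
#' `lr_second_half` after `ceil(iterations/2)` iterations. For the
#' segmentation and joint variants each sampled record is paired with one
#' of its precomputed click sequences (see [prepare_training_set()]);
#' the classification-only variant trains on lesion-centered patches.
#'
#' @param net a `usj_network` from [build_network()].
#' @param records list of `usj_record`; for seg/joint variants each must
#'   carry a `clicks` element.
#' @param config a [train_config()].
#' @return list with the trained `network` and `log`, a tibble of class
#'   `usj_train_log` with per-iteration losses and the learning-rate
#'   trace.
#' @export
train_network <- function(net, records, config) {
  stopifnot(inherits(net, "usj_network"),
            inherits(config, "usj_train_config"))
  if (length(records) == 0) stopf("empty training set")
  variant <- net$config$variant
  n_classes <- net$config$n_classes
  if (variant != "cls_only" &&
        is.null(records[[1]]$clicks))
    stopf("records carry no click sequences; run prepare_training_set()")
  labels <- vapply(records, .record_label_index, integer(1),
                   n_classes = n_classes)
  alpha <- config$alpha_per_class
  if (is.null(alpha)) {
    freq <- tabulate(labels, n_classes)
    freq[freq == 0] <- 1
    alpha <- (1 / freq) / sum(1 / freq)
  }
  net <- .clone_network(net)
  vel <- .zero_like(.trainable(net))
  log_it <- integer(config$iterations)
  log_seg <- log_cls <- log_joint <- log_lr <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    lr <- lr_at(config, it)
    batch <- with_seed(config$seed * 100003L + it, {
      idx <- sample.int(length(records),
                        min(config$batch_size, length(records)))
      lapply(idx, function(i) {
        rec <- records[[i]]
        cl <- if (variant == "cls_only") NULL
        else rec$clicks[[sample.int(length(rec$clicks), 1)]]
        list(rec = rec, clicks = cl,
             aug_seed = sample.int(2^30, 1))
      })
    })
    samp <- lapply(batch, function(b) {
      cl <- b$clicks %||% click_set(cbind(0L, 0L))
      if (config$augment) {
        augment(b$rec, cl, b$aug_seed, config$scale_range,
                config$brightness, config$contrast_range,
                config$flip_prob)
      } else {
        list(image = b$rec$image, mask = b$rec$mask, clicks = cl,
             label = b$rec$label)
      }
    })
    if (variant == "cls_only") {
      ps <- net$config$patch_size
      x <- array(0, c(ps, ps, 1, length(samp)))
      for (j in seq_along(samp))
        x[, , 1, j] <- extract_patch(samp[[j]], size = ps) / 255
    } else {
      n_px <- nrow(samp[[1]]$image)
      x <- array(0, c(n_px, n_px, 3, length(samp)))
      for (j in seq_along(samp))
        x[, , , j] <- unclass(encode_input(samp[[j]]$image,
                                           samp[[j]]$clicks))
    }
    y_lab <- vapply(samp, .record_label_index, integer(1),
                    n_classes = n_classes)
    fw <- net_forward(net, x, training = TRUE)
    seg_l <- 0
    cls_l <- 0
    dseg <- NULL
    dcls <- NULL
    if (!is.null(fw$seg_logit)) {
      masks <- array(0, dim(fw$seg_logit))
      for (j in seq_along(samp)) masks[, , 1, j] <- samp[[j]]$mask
      p <- sigmoid(fw$seg_logit)
      seg_l <- focal_loss_pixelwise(p, masks, config$gamma_focal)
      dseg <- focal_seg_logit_grad(fw$seg_logit, masks,
                                   config$gamma_focal)
    }
    if (!is.null(fw$cls_logit)) {
      cp <- softmax_rows(fw$cls_logit)
      cls_l <- focal_loss_classification(cp, y_lab, alpha,
                                         config$gamma_focal)
      dcls <- focal_cls_logit_grad(cp, y_lab, alpha, config$gamma_focal)
    }
    total <- joint_loss(seg_l, cls_l)
    if (!is.finite(total))
      stopf("training diverged at iteration %d (loss %g)", it, total)
    grads <- net_backward(net, fw$cache, dseg, dcls)
    upd <- .sgd_step(.trainable(net), grads, vel, lr, config$momentum,
                     config$weight_decay)
    net <- .set_trainable(net, upd$params)
    vel <- upd$vel
    log_it[it] <- it
    log_lr[it] <- lr
    log_seg[it] <- seg_l
    log_cls[it] <- cls_l
    log_joint[it] <- total
  }
  log <- tibble::tibble(iteration = log_it, lr = log_lr,
                        seg_loss = log_seg, cls_loss = log_cls,
                        joint_loss = log_joint)
  class(log) <- c("usj_train_log", class(log))
  list(network = net, log = log)
}

# --- parameter plumbing -----------------------------------------------------

.trainable <- function(net) {
  keep <- intersect(c("enc", "dec", "seg_head", "cls_head"), names(net))
  net[keep]
}

.set_trainable <- function(net, params) {
  for (nm in names(params)) net[[nm]] <- .merge_params(net[[nm]],
                                                       params[[nm]])
  net
}

# overwrite numeric leaves (w, b, gamma, beta), keeping stats/k intact
.merge_params <- function(old, new) {
  if (is.numeric(new)) return(new)
  nms <- names(new)
  if (is.null(nms)) {
    for (i in seq_along(new))
      old[[i]] <- .merge_params(old[[i]], new[[i]])
  } else {
    for (nm in nms) {
      if (nm %in% c("stats", "k")) next
      old[[nm]] <- .merge_params(old[[nm]], new[[nm]])
    }
  }
  old
}

.zero_like <- function(x) {
  if (is.numeric(x)) return(x * 0)
  if (is.list(x)) {
    out <- lapply(x[setdiff(names(x) %||% seq_along(x),
                            c("stats", "k"))],
                  .zero_like)
    return(out)
  }
  NULL
}

.sgd_step <- function(params, grads, vel, lr, momentum, wd) {
  step <- function(p, g, v, nm) {
    if (is.numeric(p)) {
      decay <- if (identical(nm, "w")) wd * p else 0
      v <- momentum * v - lr * (g + decay)
      return(list(p = p + v, v = v))
    }
    nms <- names(p) %||% seq_along(p)
    for (k in nms) {
      if (k %in% c("stats", "k")) next
      if (is.null(g[[k]])) next
      r <- step(p[[k]], g[[k]], v[[k]], k)
      p[[k]] <- r$p
      v[[k]] <- r$v
    }
    list(p = p, v = v)
  }
  r <- step(params, grads, vel, NULL)
  list(params = r$p, vel = r$v)
}

# deep-copy a network, including the batch-norm running statistics
# environments, so training never mutates its input
.clone_network <- function(net) {
  copy <- function(x) {
    if (is.environment(x)) {
      e <- new.env(parent = emptyenv())
      e$rm <- x$rm
      e$rv <- x$rv
      return(e)
    }
    if (is.list(x)) return(lapply(x, copy))
    x
  }
  structure(copy(unclass(net)), class = "usj_network")
}
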