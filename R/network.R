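#' Network configuration
#'
#' Describes one of the three network variants:
#' \describe{
#'   \item{`seg_only`}{encoder + bilinear-upsampling decoder producing a
#'     per-pixel foreground logit map from the three-channel click-encoded
#'     input.}
#'   \item{`cls_only`}{a VGG-style convolutional stack with batch
#'     normalization (two convolutions per down-sampling stage) over a
#'     single-channel lesion patch, ending in fully connected layers.}
#'   \item{`joint`}{the shared-encoder two-branch network: the segmentation
#'     decoder plus a classification branch that pools the deepest
#'     shared features (concatenated global average and max pooling)
#'     into fully connected layers.}
#' }
#' All variants use (convolution, batch normalization, ReLU) blocks with
#' 2x2 max-pool down-sampling, and the decoder restores resolution with
#' fixed bilinear interpolation only (no learned transposed convolutions).
#'
#' @param variant one of `"seg_only"`, `"cls_only"`, `"joint"`.
#' @param n_classes 2 (benign/malignant) or 4 (cyst/hemangioma/
#'   metastasis/hcc).
#' @param profile `"desk"` (small: 4 stages, widths 16-32-64-128, under
#'   two million parameters, for CPU-scale experiments) or `"paper"`
#'   (5 stages, widths 32-512).
#' @param encoder_widths,encoder_depth,fc_widths optional overrides of the
#'   profile's channel widths, number of down-sampling stages (>= 2), and
#'   classification-branch hidden widths.
#' @return an object of class `usj_net_config`.
#' @export
network_config <- function(variant = c("joint", "seg_only", "cls_only"),
                           n_classes = 4,
                           profile = c("desk", "paper"),
                           encoder_widths = NULL,
                           encoder_depth = NULL,
                           fc_widths = NULL) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  if (!n_classes %in% c(2, 4)) stopf("n_classes must be 2 or 4")
  defaults <- if (profile == "desk") {
    list(widths = c(16, 32, 64, 128), fc = c(64, 32))
  } else {
    list(widths = c(32, 64, 128, 256, 512), fc = c(256, 128))
  }
  widths <- encoder_widths %||% defaults$widths
  depth <- encoder_depth %||% length(widths)
  if (depth < 2) stopf("encoder_depth must be >= 2")
  if (length(widths) != depth)
    stopf("encoder_widths must have one entry per down-sampling stage")
  structure(list(
    variant = variant, n_classes = as.integer(n_classes),
    profile = profile, encoder_widths = widths,
    encoder_depth = as.integer(depth),
    fc_widths = fc_widths %||% defaults$fc,
    conv_per_stage = if (variant == "cls_only") 2L else 1L,
    input_channels = if (variant == "cls_only") 1L else 3L,
    patch_size = 64L), class = "usj_net_config")
}

#' Build a network from a configuration
#'
#' Instantiates seeded He-initialized weights for the configured variant.
#' The early convolutional layers are randomly initialized (no transfer
#' from an external pretrained network); optional self-pretraining is
#' available by passing a previously trained network of the same
#' configuration as `warm_start`.
#'
#' @param config a [network_config()].
#' @param rng_seed integer seed for the weight initialization.
#' @param warm_start optional `usj_network` whose weights are copied.
#' @return an object of class `usj_network`.
#' @export
build_network <- function(config, rng_seed = 0, warm_start = NULL) {
  stopifnot(inherits(config, "usj_net_config"))
  if (!is.null(warm_start)) {
    stopifnot(inherits(warm_start, "usj_network"))
    if (!identical(warm_start$config[names(config)], config))
      stopf("warm_start configuration differs from the requested one")
    return(warm_start)
  }
  w <- config$encoder_widths
  depth <- config$encoder_depth
  with_seed(rng_seed, {
    enc <- list()
    c_in <- config$input_channels
    for (i in seq_len(depth)) {
      blocks <- list()
      for (j in seq_len(config$conv_per_stage)) {
        blocks[[j]] <- c(conv_init(3, c_in, w[i]), bn_init(w[i]))
        c_in <- w[i]
      }
      enc[[i]] <- blocks
    }
    net <- list(config = config, enc = enc)
    if (config$variant %in% c("seg_only", "joint")) {
      dec <- list()
      dec_w <- pmax(8, w %/% 2)
      c_up <- w[depth]                     # pooled deepest features
      for (i in rev(seq_len(depth))) {
        c_cat <- c_up + w[i]               # upsampled + skip
        dec[[i]] <- c(conv_init(3, c_cat, dec_w[i]), bn_init(dec_w[i]))
        c_up <- dec_w[i]
      }
      net$dec <- dec
      net$seg_head <- conv_init(1, dec_w[1], 1)
    }
    if (config$variant %in% c("cls_only", "joint")) {
      fc <- list()
      d_in <- 2L * w[depth]        # concatenated average + max pooling
      for (k in seq_along(config$fc_widths)) {
        fc[[k]] <- fc_init(d_in, config$fc_widths[k])
        d_in <- config$fc_widths[k]
      }
      fc[[length(fc) + 1]] <- fc_init(d_in, config$n_classes)
      net$cls_head <- fc
    }
    structure(net, class = "usj_network")
  })
}

#' Number of learnable parameters of a network
#'
#' @param net a `usj_network`.
#' @return integer parameter count (weights, biases, batch-norm scales and
#'   shifts; running statistics excluded).
#' @export
n_parameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.environment(x)) return()
    if (is.numeric(x)) { n <<- n + length(x); return() }
    if (is.list(x)) {
      nms <- names(x) %||% rep("", length(x))
      for (i in seq_along(x))
        if (!nms[i] %in% c("config", "k", "stats")) walk(x[[i]])
    }
  }
  walk(unclass(net))
  n
}

#' @export
print.usj_network <- function(x, ...) {
  cat(sprintf("<usj_network> %s, %d classes, %s profile, %s parameters\n",
              x$config$variant, x$config$n_classes, x$config$profile,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- forward / backward -----------------------------------------------------

.block_forward <- function(block, x, training) {
  z <- conv_forward(block, x)
  bn <- bn_forward(block, z, training)
  a <- relu_forward(bn$y)
  list(y = a, cache = list(x = x, z = z, bn = bn$cache, a = bn$y))
}

.block_backward <- function(block, cache, dy) {
  dz_bn <- relu_backward(cache$a, dy)
  bnb <- bn_backward(block, cache$bn, dz_bn)
  cv <- conv_backward(block, cache$x, bnb$dx)
  list(dx = cv$dx,
       grads = list(w = cv$dw, b = cv$db, gamma = bnb$dgamma,
                    beta = bnb$dbeta))
}

# Full forward pass. x: (H, W, C, N). Returns logits and caches.
net_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  d <- dim(x)
  if (d[1] %% 2^cfg$encoder_depth != 0 || d[2] %% 2^cfg$encoder_depth != 0)
    stopf("input size %dx%d must be divisible by 2^%d = %d",
          d[1], d[2], cfg$encoder_depth, 2^cfg$encoder_depth)
  if (d[3] != cfg$input_channels)
    stopf("expected %d input channels, got %d", cfg$input_channels, d[3])
  caches <- list(enc = list(), pool = list(), skip = list())
  z <- x
  for (i in seq_len(cfg$encoder_depth)) {
    bl_caches <- list()
    for (j in seq_along(net$enc[[i]])) {
      fw <- .block_forward(net$enc[[i]][[j]], z, training)
      z <- fw$y
      bl_caches[[j]] <- fw$cache
    }
    caches$enc[[i]] <- bl_caches
    caches$skip[[i]] <- z                  # pre-pool activation
    mp <- .maxpool2_forward(z)
    caches$pool[[i]] <- list(idx = mp$idx, xdim = dim(z))
    z <- mp$y
  }
  deepest <- z                             # pooled deepest shared features
  seg_logit <- NULL
  cls_logit <- NULL
  if (!is.null(net$dec)) {
    caches$dec <- list()
    for (i in rev(seq_len(cfg$encoder_depth))) {
      up <- .upsample2_forward(z)
      cat_in <- concat_channels(up, caches$skip[[i]])
      fw <- .block_forward(net$dec[[i]], cat_in, training)
      caches$dec[[i]] <- list(block = fw$cache, updim = dim(z),
                              c_up = dim(up)[3])
      z <- fw$y
    }
    caches$seg_in <- z
    seg_logit <- conv_forward(net$seg_head, z)
  }
  if (!is.null(net$cls_head)) {
    gmp <- gmp_forward(deepest)
    pooled <- cbind(gap_forward(deepest), gmp$y)
    caches$gap_dim <- dim(deepest)
    caches$gmp_idx <- gmp$idx
    acts <- list(pooled)
    h <- pooled
    nf <- length(net$cls_head)
    for (k in seq_len(nf)) {
      h <- fc_forward(net$cls_head[[k]], h)
      if (k < nf) {
        pre <- h
        h <- relu_forward(h)
        acts[[k + 1]] <- list(pre = pre, post = h)
      }
    }
    caches$fc <- acts
    cls_logit <- h
  }
  list(seg_logit = seg_logit, cls_logit = cls_logit, cache = caches)
}

# Backward pass; dseg: same shape as seg_logit (or NULL), dcls: (N, K) or
# NULL. Returns gradients in the same nested structure as the network.
net_backward <- function(net, cache, dseg = NULL, dcls = NULL) {
  cfg <- net$config
  grads <- list()
  ddeepest <- NULL

  if (!is.null(net$cls_head) && !is.null(dcls)) {
    nf <- length(net$cls_head)
    gfc <- vector("list", nf)
    dh <- dcls
    for (k in rev(seq_len(nf))) {
      x_in <- if (k == 1) cache$fc[[1]] else cache$fc[[k]]$post
      fb <- fc_backward(net$cls_head[[k]], x_in, dh)
      gfc[[k]] <- list(w = fb$dw, b = fb$db)
      dh <- fb$dx
      if (k > 1) dh <- relu_backward(cache$fc[[k]]$pre, dh)
    }
    grads$cls_head <- gfc
    C <- cache$gap_dim[3]
    ddeepest <- gap_backward(dh[, seq_len(C), drop = FALSE],
                             cache$gap_dim) +
      gmp_backward(dh[, C + seq_len(C), drop = FALSE], cache$gmp_idx,
                   cache$gap_dim)
  }

  dskip <- vector("list", cfg$encoder_depth)
  dz <- NULL
  if (!is.null(net$dec) && !is.null(dseg)) {
    sh <- conv_backward(net$seg_head, cache$seg_in, dseg)
    grads$seg_head <- list(w = sh$dw, b = sh$db)
    dz <- sh$dx
    gdec <- vector("list", cfg$encoder_depth)
    for (i in seq_len(cfg$encoder_depth)) {
      bb <- .block_backward(net$dec[[i]], cache$dec[[i]]$block, dz)
      gdec[[i]] <- bb$grads
      sp <- split_channels(bb$dx, cache$dec[[i]]$c_up)
      dskip[[i]] <- sp$b
      dz <- .upsample2_backward(sp$a, cache$dec[[i]]$updim)
    }
    grads$dec <- gdec
  }
  dpool <- dz
  if (!is.null(ddeepest)) {
    dpool <- if (is.null(dpool)) ddeepest else dpool + ddeepest
  }

  genc <- vector("list", cfg$encoder_depth)
  for (i in rev(seq_len(cfg$encoder_depth))) {
    dz <- .maxpool2_backward(dpool, cache$pool[[i]]$idx,
                             cache$pool[[i]]$xdim)
    if (!is.null(dskip[[i]])) dz <- dz + dskip[[i]]
    bl <- net$enc[[i]]
    gbl <- vector("list", length(bl))
    for (j in rev(seq_along(bl))) {
      bb <- .block_backward(bl[[j]], cache$enc[[i]][[j]], dz)
      gbl[[j]] <- bb$grads
      dz <- bb$dx
    }
    genc[[i]] <- gbl
    dpool <- dz
  }
  grads$enc <- genc
  grads
}

#' Run inference on encoded inputs
#'
#' Applies the network in inference mode (batch-norm running statistics,
#' fully deterministic). Segmentation logits pass through the logistic
#' map; classification logits through softmax.
#'
#' @param object a `usj_network`.
#' @param encoded an `usj_encoded` (H x W x 3), a plain 3-d array, or a
#'   4-d batch array (H, W, C, N).
#' @param ... unused.
#' @return an object of class `usj_prediction` with `seg_prob` (H x W
#'   matrix, or H x W x N for batches; `NULL` for `cls_only`) and
#'   `cls_prob` (N x K matrix of class probabilities; `NULL` for
#'   `seg_only`).
#' @export
predict.usj_network <- function(object, encoded, ...) {
  x <- unclass(encoded)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1, 1)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  fw <- net_forward(object, x, training = FALSE)
  seg_prob <- NULL
  if (!is.null(fw$seg_logit)) {
    seg_prob <- sigmoid(fw$seg_logit)
    d <- dim(seg_prob)
    dim(seg_prob) <- c(d[1], d[2], d[4])
    if (dim(seg_prob)[3] == 1) seg_prob <- seg_prob[, , 1]
  }
  cls_prob <- if (!is.null(fw$cls_logit)) softmax_rows(fw$cls_logit)
  structure(list(seg_prob = seg_prob, cls_prob = cls_prob,
                 classes = if (object$config$n_classes == 2)
                   c("benign", "malignant") else lesion_classes),
            class = "usj_prediction")
}

#' Binarize a predicted probability map
#'
#' @param pred a `usj_prediction` or a probability matrix.
#' @param threshold foreground threshold (default 0.5).
#' @return 0/1 integer matrix (or array for batches).
#' @export
predicted_mask <- function(pred, threshold = 0.5) {
  p <- if (inherits(pred, "usj_prediction")) pred$seg_prob else pred
  if (is.null(p)) stopf("prediction carries no segmentation map")
  (p >= threshold) * 1L
}
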