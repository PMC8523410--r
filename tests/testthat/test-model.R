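test_that("network variants expose the expected heads and shapes", {
  joint <- build_network(network_config("joint", 4), rng_seed = 0)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  pred <- predict(joint, x)
  expect_equal(dim(pred$seg_prob), c(64, 64))
  expect_length(pred$cls_prob, 4)
  seg <- build_network(network_config("seg_only", 4), rng_seed = 0)
  expect_null(seg$cls_head)
  expect_null(predict(seg, x)$cls_prob)
  cls <- build_network(network_config("cls_only", 4), rng_seed = 0)
  expect_null(cls$dec)
  expect_gt(length(cls$enc[[1]]), 1)   # VGG-style double convolutions
  pc <- predict(cls, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_null(pc$seg_prob)
  expect_length(pc$cls_prob, 4)
})

test_that("the desk profile stays under two million parameters", {
  for (v in c("joint", "seg_only", "cls_only")) {
    net <- build_network(network_config(v, 4, profile = "desk"), 0)
    expect_lt(n_parameters(net), 2e6)
    expect_gt(n_parameters(net), 1e4)
  }
})

test_that("predictions are valid probabilities and deterministic", {
  net <- build_network(network_config("joint", 4), rng_seed = 1)
  set.seed(5)
  for (i in 1:10) {
    x <- array(runif(32 * 32 * 3), c(32, 32, 3, 2))
    p <- predict(net, x)
    expect_true(all(p$seg_prob >= 0 & p$seg_prob <= 1))
    expect_true(all(abs(rowSums(p$cls_prob) - 1) < 1e-5))
  }
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(predict(net, x), predict(net, x))
  expect_error(predict(net, array(0, c(30, 30, 3, 1))), "divisible")
})

test_that("incompatible configurations are rejected", {
  expect_error(network_config("joint", n_classes = 3), "2 or 4")
  expect_error(network_config("joint", encoder_widths = c(8, 16),
                              encoder_depth = 3), "one entry per")
  expect_error(network_config("joint", encoder_widths = 8,
                              encoder_depth = 1), ">= 2")
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- network_config("joint", 4, encoder_widths = c(4, 8),
                        encoder_depth = 2)
  net <- build_network(cfg, rng_seed = 3)
  set.seed(9)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  masks <- array((runif(8 * 8 * 2) > 0.6) * 1, c(8, 8, 1, 2))
  labs <- c(2L, 4L)
  alpha <- rep(0.25, 4)
  loss_of <- function(n) {
    fw <- usjoint:::net_forward(n, x, training = TRUE)
    usjoint:::focal_loss_pixelwise(usjoint:::sigmoid(fw$seg_logit),
                                   masks, 2) +
      focal_loss_classification(usjoint:::softmax_rows(fw$cls_logit),
                                labs, alpha, 2)
  }
  fw <- usjoint:::net_forward(net, x, training = TRUE)
  dseg <- usjoint:::focal_seg_logit_grad(fw$seg_logit, masks, 2)
  dcls <- usjoint:::focal_cls_logit_grad(
    usjoint:::softmax_rows(fw$cls_logit), labs, alpha, 2)
  grads <- usjoint:::net_backward(net, fw$cache, dseg, dcls)
  eps <- 1e-5
  check <- function(getter, setter, g) {
    v <- getter(net)
    ii <- sample(length(v), min(4, length(v)))
    for (i in ii) {
      vp <- v; vp[i] <- v[i] + eps
      vm <- v; vm[i] <- v[i] - eps
      fdg <- (loss_of(setter(net, vp)) - loss_of(setter(net, vm))) /
        (2 * eps)
      expect_lt(abs(fdg - g[i]) / max(abs(fdg), abs(g[i]), 1e-8), 1e-4)
    }
  }
  check(function(n) n$enc[[1]][[1]]$w,
        function(n, v) { n$enc[[1]][[1]]$w[] <- v; n },
        grads$enc[[1]][[1]]$w)
  check(function(n) n$enc[[2]][[1]]$gamma,
        function(n, v) { n$enc[[2]][[1]]$gamma <- v; n },
        grads$enc[[2]][[1]]$gamma)
  check(function(n) n$dec[[1]]$w,
        function(n, v) { n$dec[[1]]$w[] <- v; n },
        grads$dec[[1]]$w)
  check(function(n) n$seg_head$w,
        function(n, v) { n$seg_head$w[] <- v; n },
        grads$seg_head$w)
  check(function(n) n$cls_head[[1]]$w,
        function(n, v) { n$cls_head[[1]]$w[] <- v; n },
        grads$cls_head[[1]]$w)
})

test_that("lesion patches are centered and twice the lesion size", {
  spec <- desk_spec()
  rec <- list(image = matrix(50L, 256, 256), mask = matrix(0L, 256, 256))
  rec$mask[119:138, 124:143] <- 1L   # 20 px square lesion
  p <- extract_patch(rec, size = 64)
  expect_equal(attr(p, "side_px"), 40)
  expect_equal(dim(p), c(64, 64))
  # corner lesion: still square via edge replication
  rec2 <- list(image = matrix(50L, 64, 64), mask = matrix(0L, 64, 64))
  rec2$mask[1:6, 1:6] <- 1L
  p2 <- extract_patch(rec2, size = 64)
  expect_equal(dim(p2), c(64, 64))
  # patch side tracks the tight box on generated phantoms
  set.seed(1)
  for (seed in 1:20) {
    r <- generate_phantom(spec, sample(lesion_classes, 1), seed)
    tb <- tight_box(r$mask)
    side <- attr(extract_patch(r), "side_px")
    expect_equal(side, max(2 * max(tb$bottom - tb$top + 1,
                                   tb$right - tb$left + 1), 8))
  }
})

test_that("checkpoints round-trip through save and load", {
  net <- build_network(network_config("joint", 4, encoder_widths = c(4, 8),
                                      encoder_depth = 2), rng_seed = 2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  expect_identical(predict(net, x), predict(net2, x))
  expect_equal(n_parameters(net), n_parameters(net2))
})
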