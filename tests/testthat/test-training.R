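test_that("focal losses match direct formula evaluation", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    p <- runif(n)
    m <- rbinom(n, 1, 0.5)
    g <- sample(c(0, 0.5, 1, 2, 5), 1)
    expect_equal(focal_loss_pixelwise(p, m, g), focal_pix_oracle(p, m, g),
                 tolerance = 1e-8)
    K <- sample(2:5, 1)
    pr <- runif(K)
    pr <- pr / sum(pr)
    lab <- sample(K, 1)
    al <- runif(K, 0.1, 1)
    expect_equal(focal_loss_classification(pr, lab, al, g),
                 focal_cls_oracle(pr, lab, al, g), tolerance = 1e-8)
  }
})

test_that("focal losses reduce to cross-entropy at gamma = 0", {
  set.seed(4)
  p <- runif(50)
  m <- rbinom(50, 1, 0.5)
  ce <- -mean(ifelse(m == 1, log(p), log(1 - p)))
  expect_lt(abs(focal_loss_pixelwise(p, m, 0) - ce), 1e-10)
  pr <- c(0.2, 0.5, 0.3)
  expect_lt(abs(focal_loss_classification(pr, 2, 1, 0) - (-log(0.5))),
            1e-10)
})

test_that("hand-derived focal loss point values hold", {
  # single pixel, mask = 1, p = 0.5, gamma = 2: (1-0.5)^2 * ln 2 = ln2/4
  expect_equal(focal_loss_pixelwise(0.5, 1, 2), 0.25 * log(2),
               tolerance = 1e-8)
  # alpha = 0.25, p_true = 0.5, gamma = 2: 0.25 * 0.25 * ln 2
  expect_equal(focal_loss_classification(c(0.5, 0.5), 1, c(0.25, 0.25), 2),
               0.25 * 0.25 * log(2), tolerance = 1e-8)
  # perfect predictions cost (almost) nothing
  expect_lt(focal_loss_pixelwise(rep(1, 9), rep(1, 9), 2), 1e-6)
  expect_equal(focal_loss_classification(c(1, 0), 1, 1, 2), 0,
               tolerance = 1e-6)
})

test_that("the joint loss is the plain sum of its components", {
  expect_equal(joint_loss(0.3, 0.7), 1.0)
  expect_equal(joint_loss(0, 0), 0)
  expect_error(joint_loss(Inf, 1))
})

test_that("loss gradients match finite differences", {
  set.seed(8)
  z <- matrix(rnorm(30), 5, 6)
  m <- matrix(rbinom(30, 1, 0.4), 5, 6)
  g <- usjoint:::focal_seg_logit_grad(z, m, 2)
  eps <- 1e-6
  for (i in sample(30, 6)) {
    zp <- z; zp[i] <- z[i] + eps
    zm <- z; zm[i] <- z[i] - eps
    fdg <- (focal_loss_pixelwise(usjoint:::sigmoid(zp), m, 2) -
              focal_loss_pixelwise(usjoint:::sigmoid(zm), m, 2)) / (2 * eps)
    expect_lt(abs(fdg - g[i]), 1e-7)
  }
  zl <- matrix(rnorm(8), 2, 4)
  labs <- c(3L, 1L)
  al <- c(0.1, 0.2, 0.3, 0.4)
  pr <- usjoint:::softmax_rows(zl)
  gc <- usjoint:::focal_cls_logit_grad(pr, labs, al, 2)
  for (i in seq_along(zl)) {
    zp <- zl; zp[i] <- zl[i] + eps
    zm <- zl; zm[i] <- zl[i] - eps
    fdg <- (focal_loss_classification(usjoint:::softmax_rows(zp), labs,
                                      al, 2) -
              focal_loss_classification(usjoint:::softmax_rows(zm), labs,
                                        al, 2)) / (2 * eps)
    expect_lt(abs(fdg - gc[i]), 1e-7)
  }
})

test_that("the learning rate steps down exactly at the half-way point", {
  cfg <- train_config("desk", "joint", iterations = 1000)
  expect_equal(lr_at(cfg, 1), cfg$lr_first_half)
  expect_equal(lr_at(cfg, 500), cfg$lr_first_half)
  expect_equal(lr_at(cfg, 501), cfg$lr_second_half)
  # clinical-scale schedules
  pj <- train_config("paper", "joint")
  expect_equal(c(pj$iterations, pj$lr_first_half, pj$lr_second_half),
               c(150000, 5e-4, 5e-5))
  pc <- train_config("paper", "cls_only")
  expect_equal(c(pc$iterations, pc$lr_first_half, pc$lr_second_half),
               c(40000, 1e-3, 1e-4))
  expect_equal(pj$momentum, 0.9)
  expect_equal(pj$weight_decay, 5e-4)
})

test_that("augmentation preserves structure and recomputes clicks", {
  rec <- generate_phantom(desk_spec(), "hemangioma", 5)
  clicks <- generate_click_sequences(rec$mask, 1, 2, 10, 1)[[1]]
  # identity settings: bitwise identity
  id <- augment(rec, clicks, 1, scale_range = c(1, 1), brightness = 0,
                contrast_range = c(1, 1), flip_prob = 0)
  expect_equal(id$image, rec$image + 0)
  expect_identical(id$mask, rec$mask)
  expect_equal(id$clicks, clicks)
  # forced flip is an involution on the geometry
  f1 <- augment(rec, clicks, 2, scale_range = c(1, 1), brightness = 0,
                contrast_range = c(1, 1), flip_prob = 1)
  f2 <- augment(list(image = f1$image, mask = f1$mask,
                     label = rec$label), f1$clicks, 3,
                scale_range = c(1, 1), brightness = 0,
                contrast_range = c(1, 1), flip_prob = 1)
  expect_equal(f2$image, rec$image + 0)
  expect_identical(f2$mask, rec$mask)
  expect_setequal(paste(f2$clicks$foreground[, 1],
                        f2$clicks$foreground[, 2]),
                  paste(clicks$foreground[, 1], clicks$foreground[, 2]))
  # general augmentation keeps the mask binary and the label fixed
  set.seed(2)
  for (s in 1:10) {
    a <- augment(rec, clicks, s)
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_identical(a$label, rec$label)
    expect_true(all(a$image >= 0 & a$image <= 255))
  }
})

test_that("training is reproducible and the overfit run learns", {
  ds <- small_dataset()
  recs <- prepare_training_set(ds$train[c(1, 5, 9, 13, 17, 21, 25, 29)],
                               rng_seed = 4)
  net <- build_network(network_config("joint", 4), rng_seed = 0)
  cfg <- train_config("desk", "joint", iterations = 25, seed = 0)
  f1 <- train_network(net, recs, cfg)
  f2 <- train_network(net, recs, cfg)
  expect_identical(f1$log$joint_loss, f2$log$joint_loss)
  expect_true(all(is.finite(f1$log$joint_loss)))
  expect_true(all(f1$log$joint_loss >= 0))
  expect_equal(f1$log$lr[1], cfg$lr_first_half)
  # fixed small batch, no augmentation: the graph can (over)fit
  ofit_cfg <- train_config("desk", "joint", iterations = 500,
                           batch_size = 8, seed = 0, augment = FALSE)
  ofit <- train_network(net, recs, ofit_cfg)
  first <- mean(head(ofit$log$joint_loss, 10))
  last <- mean(tail(ofit$log$joint_loss, 10))
  expect_lt(last, 0.10 * first)
  expect_lt(tail(ofit$log$joint_loss, 1), head(ofit$log$joint_loss, 1))
})
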