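test_that("jaccard index counts intersection over union", {
  m <- disc_mask(16, 4)
  expect_equal(jaccard(m, m), 1)
  empty <- matrix(0L, 16, 16)
  other <- disc_mask(16, 2, 3, 3)
  expect_equal(jaccard(other, m), 0)
  # 2x2 block against the same block shifted by one column:
  # overlap 2, union 6
  a <- matrix(0L, 4, 4)
  a[2:3, 2:3] <- 1L
  b <- matrix(0L, 4, 4)
  b[2:3, 3:4] <- 1L
  expect_equal(jaccard(a, b), 1 / 3)
  # symmetry and flip invariance
  set.seed(6)
  for (i in 1:20) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(jaccard(x, y), jaccard(y, x))
    expect_equal(jaccard(x[, 8:1], y[, 8:1]), jaccard(x, y))
  }
  expect_error(jaccard(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("confusion matrices tabulate true against predicted labels", {
  cm <- confusion(c("cyst", "hcc"), c("cyst", "hcc"))
  expect_equal(diag(unclass(cm)), c(cyst = 1, hemangioma = 0,
                                    metastasis = 0, hcc = 1))
  cm0 <- confusion(character(0), character(0))
  expect_true(all(unclass(cm0) == 0))
  expect_error(confusion("cyst", "carcinoid"), "unknown")
  expect_error(confusion(c("cyst", "hcc"), "cyst"), "length")
  acc <- accuracy_from_confusion(confusion(rep("cyst", 3),
                                           rep("cyst", 3)))
  expect_equal(acc$overall, 100)
  expect_true(is.na(acc$per_class[["hcc"]]))
})

test_that("ROC curves match the pair-counting oracle", {
  # perfect separation
  expect_equal(roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auroc, 1)
  # scores carrying no information: tie convention gives 1/2
  expect_equal(roc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auroc, 0.5)
  # six-point toy set against brute-force pair counting
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2)
  lb <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc(sc, lb)$auroc, auc_pair_oracle(sc, lb),
               tolerance = 1e-12)
  # random instances, ties included
  set.seed(7)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    r <- roc(s, l)
    expect_lt(abs(r$auroc - auc_pair_oracle(s, l)), 1e-10)
    # curve endpoints and monotonicity
    expect_equal(r$sensitivity[1], 0)
    expect_equal(tail(r$sensitivity, 1), 1)
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_true(all(diff(r$one_minus_specificity) >= 0))
  }
  expect_error(roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:20) {
    s <- runif(40)
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc(s, l)$auroc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("the Youden optimum matches exhaustive threshold search", {
  r <- roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  y <- youden_optimum(r)
  expect_equal(c(y$sensitivity, y$specificity), c(100, 100))
  set.seed(9)
  for (i in 1:25) {
    s <- round(runif(20), 2)
    l <- c(0, 1, rbinom(18, 1, 0.5))
    y <- youden_optimum(roc(s, l))
    # exhaustive search over every candidate threshold
    best <- -Inf
    for (t in c(Inf, unique(s))) {
      sens <- sum(s >= t & l == 1) / sum(l == 1)
      spec <- sum(s < t & l == 0) / sum(l == 0)
      best <- max(best, sens + spec - 1)
    }
    expect_equal(y$youden_j, best, tolerance = 1e-12)
    expect_equal(y$sensitivity / 100 + y$specificity / 100 - 1,
                 y$youden_j, tolerance = 1e-12)
  }
})

test_that("one-vs-rest ROC reduces to binary ROC per class", {
  set.seed(10)
  probs <- matrix(runif(8 * 4), 8, 4)
  probs <- probs / rowSums(probs)
  labs <- c("cyst", "hemangioma", "metastasis", "hcc",
            "cyst", "hemangioma", "metastasis", "hcc")
  mc <- multiclass_roc(probs, labs)
  expect_length(mc$per_class, 4)
  for (k in seq_along(lesion_classes)) {
    ref <- roc(probs[, k], labs == lesion_classes[k])
    expect_equal(mc$per_class[[lesion_classes[k]]]$auroc, ref$auroc)
  }
  expect_equal(mc$macro_auroc,
               mean(vapply(mc$per_class, `[[`, numeric(1), "auroc")))
  # one-hot perfection
  onehot <- diag(4)[match(labs, lesion_classes), ]
  mc2 <- multiclass_roc(onehot, labs)
  expect_true(all(vapply(mc2$per_class, `[[`, numeric(1),
                         "auroc") == 1))
  w <- capture_warnings(multiclass_roc(probs[1:4, ], rep("cyst", 4)))
  expect_true(all(grepl("absent", w)))
  expect_length(w, 4)   # every class is degenerate when truth is constant
})

test_that("paired comparison matches exhaustive sign-flip enumeration", {
  expect_gte(compare_paired(1:8, 1:8), 0.9)
  a <- c(10, 11, 12, 13, 14, 15)
  b <- c(1, 2, 1, 2, 1, 2)
  expect_lte(compare_paired(a, b), 2^-5)
  # hand enumeration for three pairs: d = (1, 2, 3), mean 2;
  # |sum of signed d| >= 6 for sign vectors (+,+,+) and (-,-,-): p = 2/8
  expect_equal(compare_paired(c(2, 3, 4), c(1, 1, 1)), 2 / 8)
  # Monte Carlo path approximates the exact answer
  set.seed(2)
  d <- rnorm(30, 0.2)
  p_mc <- compare_paired(d, rep(0, 30), n_resamples = 4000, rng_seed = 1)
  expect_true(p_mc > 0 && p_mc <= 1)
  expect_error(compare_paired(1:3, 1:4), "length")
})

test_that("bootstrap AUROC intervals behave sanely", {
  set.seed(11)
  s <- c(rnorm(30, 1), rnorm(30))
  l <- rep(c(1, 0), each = 30)
  ci <- auroc_ci(s, l, n_resamples = 200, rng_seed = 3)
  point <- roc(s, l)$auroc
  expect_lt(ci[1], point)
  expect_gt(ci[2], point)
  expect_true(all(ci >= 0 & ci <= 1))
  expect_identical(ci, auroc_ci(s, l, n_resamples = 200, rng_seed = 3))
})

test_that("evaluate_system runs the five-input protocol deterministically", {
  ds <- small_dataset()
  net <- build_network(network_config("joint", 4), rng_seed = 1)
  rep1 <- evaluate_system(net, ds$test[c(1, 3, 5, 7)], "two_click", rng_seed = 5)
  expect_equal(nrow(rep1$per_input), 5 * 4)
  expect_true(all(rep1$per_input$ji >= 0 & rep1$per_input$ji <= 1))
  rep2 <- evaluate_system(net, ds$test[c(1, 3, 5, 7)], "two_click", rng_seed = 5)
  expect_equal(glance(rep1), glance(rep2))
  expect_identical(unclass(rep1$confusion), unclass(rep2$confusion))
  one <- evaluate_system(net, ds$test[c(1, 3, 5, 7)], "one_click", rng_seed = 5)
  expect_equal(nrow(one$per_input), 20)
  td <- tidy(rep1)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("record", "input", "ji", "pred_class") %in%
                    names(td)))
})

test_that("evaluation reports survive a JSON round trip", {
  ds <- small_dataset()
  net <- build_network(network_config("joint", 4), rng_seed = 1)
  rep1 <- evaluate_system(net, ds$test[c(1, 3, 5, 7)], "two_click", rng_seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep1, f)
  rep2 <- read_eval_report(f)
  expect_equal(glance(rep1), glance(rep2))
  expect_equal(unclass(rep1$confusion), unclass(rep2$confusion))
  expect_equal(rep1$binary_roc$auroc, rep2$binary_roc$auroc)
  expect_equal(rep1$multiclass$macro_auroc, rep2$multiclass$macro_auroc)
  expect_equal(tidy(rep1), tidy(rep2))
})
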