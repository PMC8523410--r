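test_that("foreground clicks land in the lesion and cover the sample space", {
  m1 <- matrix(0L, 8, 8)
  m1[3, 5] <- 1L
  expect_equal(simulate_foreground_clicks(m1, 1),
               cbind(row = 2L, col = 4L), ignore_attr = TRUE)
  mask <- disc_mask(32, 6)
  for (seed in 1:25) {
    cl <- simulate_foreground_clicks(mask, seed)
    expect_true(all(mask[cl + 1L] == 1))
    expect_true(nrow(cl) >= 1 && nrow(cl) <= 5)
    expect_false(anyDuplicated(cl) > 0)
  }
  expect_error(simulate_foreground_clicks(matrix(0L, 4, 4), 1), "empty")
})

test_that("two-pixel mask inclusion frequencies match exact enumeration", {
  m2 <- matrix(0L, 6, 6)
  m2[2, 2] <- 1L
  m2[5, 3] <- 1L
  n_draw <- 10000
  hits <- matrix(0, 2, 1)
  for (s in seq_len(n_draw)) {
    cl <- simulate_foreground_clicks(m2, s)
    key <- paste(cl[, 1], cl[, 2])
    hits[1] <- hits[1] + ("1 1" %in% key)
    hits[2] <- hits[2] + ("4 2" %in% key)
  }
  # enumeration: k ~ U{1..5} capped at 2; k = 1 picks each pixel w.p. 1/2,
  # k >= 2 includes both -> P(include) = 1/5 * 1/2 + 4/5 = 0.9
  p <- 0.9
  sigma <- sqrt(p * (1 - p) / n_draw)
  for (i in 1:2) expect_lt(abs(hits[i] / n_draw - p), 3 * sigma)
})

test_that("background clicks stay in the distance band", {
  mask <- disc_mask(32, 6)
  d <- usjoint:::lesion_distance(mask)
  for (seed in 1:25) {
    cl <- simulate_background_clicks(mask, d_min = 2, d_max = 8,
                                     rng_seed = seed)
    if (nrow(cl) == 0) next
    expect_true(all(mask[cl + 1L] == 0))
    dd <- d[cl + 1L]
    expect_true(all(dd >= 2 & dd <= 8))
    expect_lte(nrow(cl), 10)
  }
  # lesion filling all but a margin below d_min: empty band, warning
  full <- matrix(1L, 8, 8)
  full[1, 1] <- 0L
  expect_warning(out <- simulate_background_clicks(full, 2, 5, 1),
                 "band")
  expect_equal(nrow(out), 0)
  expect_error(simulate_background_clicks(mask, 5, 2, 1), "d_min")
})

test_that("click sequences are sized, paired and reproducible", {
  mask <- disc_mask(32, 6)
  seqs <- generate_click_sequences(mask, 15, 2, 10, 3)
  expect_length(seqs, 15)
  for (s in seqs) {
    expect_s3_class(s, "usj_clicks")
    expect_true(nrow(s$foreground) >= 1 && nrow(s$foreground) <= 5)
    expect_true(nrow(s$background) >= 0 && nrow(s$background) <= 10)
  }
  expect_identical(seqs, generate_click_sequences(mask, 15, 2, 10, 3))
  expect_length(generate_click_sequences(mask, 0, 2, 10, 3), 0)
})

test_that("distance maps match the brute-force oracle", {
  # single click: zero at the click
  dm <- distance_map(cbind(3L, 4L), c(8, 8))
  expect_equal(dm[4, 5], 0)
  # empty clicks: the 255 fill
  expect_equal(distance_map(matrix(integer(), 0, 2), c(64, 64)),
               matrix(255, 64, 64))
  # two opposite corners on a 5x5 grid
  cl <- rbind(c(0L, 0L), c(4L, 4L))
  expect_equal(distance_map(cl, c(5, 5)), distance_map_oracle(cl, c(5, 5)))
  expect_error(distance_map(cbind(9L, 0L), c(8, 8)), "outside")
})

test_that("input encoding stacks image and distance maps scaled to [0,1]", {
  img <- matrix(128L, 16, 16)
  cl <- click_set(cbind(8L, 8L), cbind(c(0L, 15L), c(0L, 15L)))
  enc <- encode_input(img, cl)
  expect_equal(dim(enc), c(16, 16, 3))
  expect_equal(enc[, , 1], img / 255, ignore_attr = TRUE)
  expect_equal(enc[, , 2] * 255,
               distance_map_oracle(cl$foreground, c(16, 16)),
               ignore_attr = TRUE)
  # no background clicks: channel 2 is the constant 255 fill
  enc1 <- encode_input(img, click_set(cbind(8L, 8L)))
  expect_true(all(enc1[, , 3] == 1))
  # 3x3 with one centered click against the oracle
  enc3 <- encode_input(matrix(0L, 3, 3), click_set(cbind(1L, 1L)))
  expect_equal(enc3[, , 2] * 255,
               distance_map_oracle(cbind(1L, 1L), c(3, 3)),
               ignore_attr = TRUE)
})

test_that("simulated bounding boxes contain the lesion", {
  mask <- disc_mask(32, 6, 10, 20)
  tb <- tight_box(mask)
  b0 <- simulate_bbox(mask, jitter_frac = 0, enlarge_frac = 0,
                      rng_seed = 1)
  expect_equal(b0[c("top", "left", "bottom", "right")],
               tb[c("top", "left", "bottom", "right")])
  for (seed in 1:50) {
    b <- simulate_bbox(mask, rng_seed = seed)
    px <- which(mask == 1, arr.ind = TRUE) - 1L
    expect_true(all(px[, 1] >= b$top & px[, 1] <= b$bottom &
                      px[, 2] >= b$left & px[, 2] <= b$right))
  }
})

test_that("bounding boxes transform to one center and four corner clicks", {
  b <- list(top = 10L, left = 10L, bottom = 20L, right = 30L)
  cl <- bbox_to_clicks(b)
  expect_equal(unname(cl$foreground), cbind(15L, 20L),
               ignore_attr = TRUE)
  expect_equal(nrow(cl$background), 4)
  expect_setequal(paste(cl$background[, 1], cl$background[, 2]),
                  c("10 10", "10 30", "20 10", "20 30"))
  # degenerate 2x2 box still yields 1 + 4 clicks
  cl2 <- bbox_to_clicks(list(top = 0L, left = 0L, bottom = 1L,
                             right = 1L))
  expect_equal(nrow(cl2$foreground) + nrow(cl2$background), 5)
  # corner clicks of a simulated box on a convex lesion lie outside it
  mask <- disc_mask(32, 6)
  for (seed in 1:20) {
    cc <- bbox_to_clicks(simulate_bbox(mask, rng_seed = seed))
    expect_true(all(mask[cc$background + 1L] == 0))
    expect_equal(mask[cc$foreground + 1L], 1L)  # center hits the disc
  }
})

test_that("one-click mode yields a single foreground click, no background", {
  m1 <- matrix(0L, 8, 8)
  m1[3, 5] <- 1L
  expect_equal(one_click_input(m1, 1)$foreground, cbind(row = 2L, col = 4L),
               ignore_attr = TRUE)
  mask <- disc_mask(32, 6)
  cl <- one_click_input(mask, 9)
  expect_equal(nrow(cl$foreground), 1)
  expect_equal(nrow(cl$background), 0)
  expect_equal(mask[cl$foreground + 1L], 1L)
  enc <- encode_input(matrix(0L, 32, 32), cl)
  expect_true(all(enc[, , 3] == 1))
})

test_that("clicks and boxes survive a JSON round trip", {
  cl <- click_set(cbind(c(3L, 5L), c(4L, 6L)), cbind(1L, 1L))
  f <- withr::local_tempfile(fileext = ".json")
  write_clicks(cl, f)
  expect_equal(read_clicks(f), cl)
  b <- simulate_bbox(disc_mask(16, 4), rng_seed = 2)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_bbox(b, f2)
  b2 <- read_bbox(f2)
  expect_equal(b2[c("top", "left", "bottom", "right")],
               b[c("top", "left", "bottom", "right")])
})
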