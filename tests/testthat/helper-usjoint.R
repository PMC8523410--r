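# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# small 64 px phantom spec at 1 mm/px so clinical size distributions fit
desk_spec <- function() {
  if (is.null(.fixture_cache$spec))
    .fixture_cache$spec <- phantom_spec(image_size = 64, pixel_spacing = 1)
  .fixture_cache$spec
}

# memoized small dataset shared across test files
small_dataset <- function(n_per_class = 10, seed = 7) {
  key <- sprintf("ds_%d_%d", n_per_class, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_dataset(desk_spec(), n_per_class,
                                              0.2, seed)
  .fixture_cache[[key]]
}

# a single small lesion mask: filled disc of radius r on an n x n grid
disc_mask <- function(n = 32, r = 6, cr = NULL, cc = NULL) {
  cr <- cr %||% (n / 2)
  cc <- cc %||% (n / 2)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rows - cr)^2 + (cols - cc)^2 <= r^2) * 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Euclidean distance map oracle (double loop over pixels and
# clicks), deliberately independent of the package implementation
distance_map_oracle <- function(clicks, shape) {
  H <- shape[1]
  W <- shape[2]
  out <- matrix(255, H, W)
  if (nrow(clicks) == 0) return(out)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      best <- Inf
      for (k in seq_len(nrow(clicks))) {
        d <- sqrt((i - 1 - clicks[k, 1])^2 + (j - 1 - clicks[k, 2])^2)
        if (d < best) best <- d
      }
      out[i, j] <- min(best, 255)
    }
  }
  out
}

# pair-counting AUROC oracle: (concordant + half-tied) / (n+ * n-)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# direct (independent) evaluations of the focal losses
focal_pix_oracle <- function(p, mask, gamma, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  tot <- 0
  for (i in seq_along(p)) {
    pt <- if (mask[i] > 0) p[i] else 1 - p[i]
    tot <- tot + (-(1 - pt)^gamma * log(pt))
  }
  tot / length(p)
}

focal_cls_oracle <- function(prob, label, alpha, gamma, eps = 1e-7) {
  py <- min(max(prob[label], eps), 1 - eps)
  -alpha[label] * (1 - py)^gamma * log(py)
}
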