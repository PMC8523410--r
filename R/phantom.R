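#' Lesion class labels
#'
#' The four focal hepatic lesion types modelled by the phantom simulator,
#' in canonical order. Cyst and hemangioma are benign; metastasis and
#' hepatocellular carcinoma (HCC) are malignant.
#'
#' @export
lesion_classes <- c("cyst", "hemangioma", "metastasis", "hcc")

#' Map lesion classes to the benign/malignant dichotomy
#'
#' @param label character vector of class labels.
#' @return logical vector, `TRUE` for malignant classes (metastasis, hcc).
#' @export
is_malignant <- function(label) {
  stopifnot(all(label %in% lesion_classes))
  label %in% c("metastasis", "hcc")
}

#' Phantom specification
#'
#' Parameters of the synthetic B-mode phantom generator. Lesion sizes
#' (longest dimension, mm) are drawn from class-specific truncated
#' log-normal distributions whose *truncated* mean and standard deviation
#' are moment-matched to `class_size_means` / `class_size_sds`; the floor
#' of 4 mm avoids sub-resolution lesions and the ceiling keeps lesions
#' inside the field of view. Each class has an echogenicity phenotype:
#' a contrast offset relative to the background parenchyma, a margin blur
#' sigma (sharp vs. ill-defined), an internal heterogeneity amplitude,
#' a boundary irregularity amplitude, and (for metastasis) a peripheral
#' hypoechoic halo.
#'
#' @param image_size side of the square image in pixels (>= 64).
#' @param pixel_spacing mm per pixel.
#' @param class_size_means,class_size_sds named numeric vectors (mm) over
#'   `lesion_classes`; defaults are the mean longest dimensions of clinical
#'   cysts (16.8 +/- 14.9), hemangiomas (17.4 +/- 14.5), metastases
#'   (26.2 +/- 15.7) and HCCs (23.3 +/- 14.7).
#' @param size_min_mm truncation floor of the size distribution (mm).
#' @param size_max_mm truncation ceiling (mm); default 80% of the field of
#'   view so every drawn lesion fits in the image.
#' @param background_echo mean parenchyma intensity, 0--255 scale.
#' @param speckle_scale coefficient of variation of the multiplicative
#'   speckle field (smoothed Rayleigh amplitude noise).
#' @param contrast,margin_sigma,heterogeneity,irregularity,halo_depth named
#'   per-class phenotype parameters: intensity offset (0--255 units), margin
#'   Gaussian blur sigma (px), internal texture amplitude (intensity units),
#'   relative radial boundary perturbation, and halo depth (intensity units).
#' @return an object of class `usj_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256,
                         pixel_spacing = 0.5,
                         class_size_means = c(cyst = 16.8, hemangioma = 17.4,
                                              metastasis = 26.2, hcc = 23.3),
                         class_size_sds = c(cyst = 14.9, hemangioma = 14.5,
                                            metastasis = 15.7, hcc = 14.7),
                         size_min_mm = 4,
                         size_max_mm = 0.8 * image_size * pixel_spacing,
                         background_echo = 90,
                         speckle_scale = 0.25,
                         contrast = c(cyst = -65, hemangioma = 45,
                                      metastasis = -35, hcc = -15),
                         margin_sigma = c(cyst = 0.5, hemangioma = 0.7,
                                          metastasis = 2.5, hcc = 2.0),
                         heterogeneity = c(cyst = 0, hemangioma = 8,
                                           metastasis = 10, hcc = 28),
                         irregularity = c(cyst = 0.03, hemangioma = 0.05,
                                          metastasis = 0.18, hcc = 0.22),
                         halo_depth = c(cyst = 0, hemangioma = 0,
                                        metastasis = 18, hcc = 0)) {
  if (image_size < 64) stopf("image_size must be >= 64 (got %d)", image_size)
  if (pixel_spacing <= 0) stopf("pixel_spacing must be positive")
  for (nm in c("class_size_means", "class_size_sds", "contrast",
               "margin_sigma", "heterogeneity", "irregularity",
               "halo_depth")) {
    v <- get(nm)
    if (!all(lesion_classes %in% names(v)))
      stopf("%s must be named over all of: %s", nm,
            paste(lesion_classes, collapse = ", "))
  }
  if (any(class_size_means <= 0)) stopf("all size means must be positive")
  if (!(size_min_mm > 0 && size_min_mm < size_max_mm))
    stopf("need 0 < size_min_mm < size_max_mm")
  spec <- list(
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    class_size_means = class_size_means[lesion_classes],
    class_size_sds = class_size_sds[lesion_classes],
    size_min_mm = size_min_mm, size_max_mm = size_max_mm,
    background_echo = background_echo, speckle_scale = speckle_scale,
    contrast = contrast[lesion_classes],
    margin_sigma = margin_sigma[lesion_classes],
    heterogeneity = heterogeneity[lesion_classes],
    irregularity = irregularity[lesion_classes],
    halo_depth = halo_depth[lesion_classes])
  spec$size_lnorm <- lapply(setNames(lesion_classes, lesion_classes),
                            function(cl) .match_trunc_lnorm(
                              spec$class_size_means[[cl]],
                              spec$class_size_sds[[cl]],
                              size_min_mm, size_max_mm))
  structure(spec, class = "usj_phantom_spec")
}

#' @export
print.usj_phantom_spec <- function(x, ...) {
  cat(sprintf("<usj_phantom_spec> %dx%d px @ %.2f mm/px, background %g\n",
              x$image_size, x$image_size, x$pixel_spacing,
              x$background_echo))
  cat("  size means (mm):",
      paste(sprintf("%s=%.1f", lesion_classes, x$class_size_means),
            collapse = ", "), "\n")
  invisible(x)
}

# E[X^k ; L <= X <= U] for X ~ lognormal(mu, sig), and the normalizer.
.lnorm_partial_moment <- function(k, mu, sig, L, U) {
  exp(k * mu + k^2 * sig^2 / 2) *
    (pnorm((mu + k * sig^2 - log(L)) / sig) -
       pnorm((mu + k * sig^2 - log(U)) / sig))
}

.trunc_lnorm_moments <- function(mu, sig, L, U) {
  z <- pnorm((log(U) - mu) / sig) - pnorm((log(L) - mu) / sig)
  m1 <- .lnorm_partial_moment(1, mu, sig, L, U) / z
  m2 <- .lnorm_partial_moment(2, mu, sig, L, U) / z
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve for (mu, sigma) such that the [L, U]-truncated lognormal has the
# requested mean and sd. Degenerate sd = 0 is carried through as a point
# mass at the (clamped) mean.
.match_trunc_lnorm <- function(mean_mm, sd_mm, L, U) {
  if (sd_mm <= 0) {
    return(list(mu = log(min(max(mean_mm, L), U)), sigma = 0, L = L, U = U))
  }
  s2 <- log(1 + (sd_mm / mean_mm)^2)        # untruncated-moment start
  start <- c(log(mean_mm) - s2 / 2, sqrt(s2))
  obj <- function(p) {
    m <- .trunc_lnorm_moments(p[1], exp(p[2]), L, U)
    (m[["mean"]] / mean_mm - 1)^2 + (m[["sd"]] / sd_mm - 1)^2
  }
  fit <- optim(c(start[1], log(start[2])), obj,
               control = list(maxit = 2000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), L = L, U = U)
}

#' Draw lesion sizes from a class size distribution
#'
#' Samples longest-dimension sizes (mm) from the truncated log-normal
#' distribution of the given class, by inverse-CDF so the truncation is
#' exact.
#'
#' @param spec a [phantom_spec()].
#' @param label one of [lesion_classes].
#' @param n number of draws.
#' @param rng_seed integer seed.
#' @return numeric vector of sizes in mm, all within the spec's bounds.
#' @export
draw_lesion_sizes <- function(spec, label, n, rng_seed) {
  stopifnot(inherits(spec, "usj_phantom_spec"), label %in% lesion_classes)
  p <- spec$size_lnorm[[label]]
  if (p$sigma == 0) return(rep(exp(p$mu), n))
  with_seed(rng_seed, {
    lo <- stats::plnorm(p$L, p$mu, p$sigma)
    hi <- stats::plnorm(p$U, p$mu, p$sigma)
    stats::qlnorm(runif(n, lo, hi), p$mu, p$sigma)
  })
}

# Gaussian blur of a plain matrix via EBImage, returned as a matrix.
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma,
                           radius = max(3, 2 * ceiling(2.5 * sigma) + 1)))
}

# Star-convex lesion boundary: ellipse radius modulated by low-frequency
# harmonics. Returns a radius function of the polar angle.
.lesion_radius_fn <- function(a, b, phi, irregularity) {
  nh <- sample(2:4, 1)
  amp <- runif(nh, 0.3, 1)
  pha <- runif(nh, 0, 2 * pi)
  kk <- sample(2:5, nh)
  g <- function(theta) {
    s <- rep(0, length(theta))
    for (i in seq_len(nh)) s <- s + amp[i] * sin(kk[i] * theta + pha[i])
    s / max(abs(s), 1e-9)
  }
  function(theta) {
    psi <- theta - phi
    re <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    re * (1 + irregularity * g(theta))
  }
}

# Maximum caliper diameter of a point set (max pairwise distance over the
# convex hull).
.max_caliper <- function(xy) {
  if (nrow(xy) == 1) return(0)
  h <- grDevices::chull(xy)
  max(stats::dist(xy[h, , drop = FALSE]))
}

#' Generate one synthetic lesion phantom
#'
#' Renders a speckled B-mode-like image containing a single lesion of the
#' requested class with its ground-truth binary mask. The lesion is a
#' randomly deformed ellipse whose longest dimension is drawn from the
#' class size distribution; the interior intensity, margin sharpness,
#' heterogeneity and (for metastasis) peripheral halo follow the class
#' phenotype; multiplicative smoothed-Rayleigh speckle covers the whole
#' image.
#'
#' @param spec a [phantom_spec()].
#' @param label lesion class, one of [lesion_classes].
#' @param rng_seed integer seed; output is deterministic per
#'   (spec, label, seed).
#' @return an object of class `usj_record`: list with `image` (integer
#'   matrix, 0--255), `mask` (0/1 integer matrix), `label`,
#'   `lesion_size_mm` (longest mask dimension times pixel spacing) and
#'   `pixel_spacing`.
#' @export
generate_phantom <- function(spec, label, rng_seed) {
  stopifnot(inherits(spec, "usj_phantom_spec"))
  if (!label %in% lesion_classes)
    stopf("unknown label '%s'", label)
  n <- spec$image_size
  size_mm <- draw_lesion_sizes(spec, label, 1, rng_seed)
  s_px <- size_mm / spec$pixel_spacing
  half <- ceiling(s_px / 2) + 2
  if (2 * half + 2 >= n)
    stopf(paste("image of %d px cannot contain a lesion of %.1f mm",
                "at %.2f mm/px"), n, size_mm, spec$pixel_spacing)
  with_seed(rng_seed + 1L, {
    # shape: deformed ellipse, rescaled so its caliper diameter is exact
    ratio <- runif(1, 0.65, 0.95)
    phi <- runif(1, 0, pi)
    rfun <- .lesion_radius_fn(1, ratio, phi, spec$irregularity[[label]])
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    rb <- rfun(th)
    bxy <- cbind(rb * cos(th), rb * sin(th))
    scale <- s_px / .max_caliper(bxy)
    cr <- runif(1, half + 1, n - half)         # center row/col
    cc <- runif(1, half + 1, n - half)

    # rasterize: pixel centers at integer coords, star-convex test
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    dr <- rows - cr
    dc <- cols - cc
    theta <- atan2(dc, dr)
    mask <- (sqrt(dr^2 + dc^2) <= scale * rfun(as.vector(theta))) * 1L
    dim(mask) <- c(n, n)
    if (sum(mask) == 0) mask[round(cr), round(cc)] <- 1L

    # echogenicity phenotype
    soft <- .gblur(mask + 0, spec$margin_sigma[[label]])
    img <- matrix(spec$background_echo, n, n)
    bg <- .gblur(matrix(rnorm(n * n), n, n), 8)   # slow parenchyma drift
    img <- img + 5 * bg / max(sd(bg), 1e-9)
    img <- img + spec$contrast[[label]] * soft
    het <- spec$heterogeneity[[label]]
    if (het > 0) {
      tex <- .gblur(matrix(rnorm(n * n), n, n), 1.5)
      img <- img + het * (tex / max(sd(tex), 1e-9)) * soft
    }
    hd <- spec$halo_depth[[label]]
    if (hd > 0) {
      ring <- .gblur(mask + 0, 3) * (1 - mask)
      img <- img - 2.5 * hd * ring
    }

    # multiplicative smoothed-Rayleigh speckle, unit mean
    ray <- matrix(sqrt(-2 * log(runif(n * n))), n, n)   # Rayleigh(1)
    sm <- .gblur(ray, 0.8)
    sp <- 1 + spec$speckle_scale * (sm - mean(sm)) / max(sd(sm), 1e-9)
    img <- img * pmax(sp, 0)

    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), n, n)
    structure(list(image = img, mask = mask, label = label,
                   lesion_size_mm = lesion_size_px(mask) *
                     spec$pixel_spacing,
                   pixel_spacing = spec$pixel_spacing),
              class = "usj_record")
  })
}

#' Longest dimension of a binary mask in pixels
#'
#' Maximum caliper diameter over the mask's pixel centers, plus one pixel
#' to account for pixel extent.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return length in pixels.
#' @export
lesion_size_px <- function(mask) {
  xy <- which(mask > 0, arr.ind = TRUE)
  if (nrow(xy) == 0) stopf("mask is empty")
  .max_caliper(xy) + 1
}

#' @export
print.usj_record <- function(x, ...) {
  cat(sprintf("<usj_record> %s, %dx%d px, lesion %.1f mm (%d px of mask)\n",
              x$label, nrow(x$image), ncol(x$image), x$lesion_size_mm,
              sum(x$mask)))
  invisible(x)
}

#' Generate a balanced phantom dataset with a stratified train/test split
#'
#' Generates `n_per_class` phantoms per lesion class, then holds out a test
#' set stratified across lesion-area deciles within each class (the test
#' lesions span the class size range rather than being a simple random
#' draw). Train and test sets are disjoint, and the whole procedure is
#' deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class phantoms per class (>= 2).
#' @param split_fraction fraction of each class held out for testing,
#'   in (0, 1).
#' @param rng_seed integer seed.
#' @return list with `train` and `test` (lists of `usj_record`), and the
#'   generating `spec`.
#' @export
generate_dataset <- function(spec, n_per_class, split_fraction = 0.2,
                             rng_seed = 1) {
  stopifnot(inherits(spec, "usj_phantom_spec"))
  if (n_per_class < 2) stopf("n_per_class must be >= 2")
  if (!(split_fraction > 0 && split_fraction < 1))
    stopf("split_fraction must lie in (0, 1)")
  train <- list()
  test <- list()
  for (ci in seq_along(lesion_classes)) {
    cl <- lesion_classes[ci]
    recs <- lapply(seq_len(n_per_class), function(i)
      generate_phantom(spec, cl, rng_seed + ci * 100000L + i))
    areas <- vapply(recs, function(r) sum(r$mask), numeric(1))
    n_test <- round(n_per_class * split_fraction)
    n_groups <- max(1, min(10, n_test))
    grp <- ceiling(rank(areas, ties.method = "first") /
                     (n_per_class / n_groups))
    grp <- pmin(pmax(grp, 1), n_groups)
    take <- rep(n_test %/% n_groups, n_groups)
    extra <- n_test %% n_groups
    if (extra > 0) take[seq_len(extra)] <- take[seq_len(extra)] + 1
    test_idx <- with_seed(rng_seed + ci, unlist(lapply(
      seq_len(n_groups), function(g) {
        cand <- which(grp == g)
        sample(cand, min(take[g], length(cand)))
      })))
    # top up if some decile was short
    short <- n_test - length(test_idx)
    if (short > 0) {
      rest <- setdiff(seq_len(n_per_class), test_idx)
      test_idx <- c(test_idx, with_seed(rng_seed + 50L + ci,
                                        sample(rest, short)))
    }
    test <- c(test, recs[sort(test_idx)])
    train <- c(train, recs[setdiff(seq_len(n_per_class), test_idx)])
  }
  list(train = train, test = test, spec = spec)
}
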