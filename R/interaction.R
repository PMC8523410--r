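#' Construct a click set
#'
#' A click set pairs foreground clicks (inside the lesion) with background
#' clicks (surrounding tissue). Clicks are 0-based (row, col) pixel
#' coordinates stored as two-column integer matrices.
#'
#' @param foreground,background integer matrices with columns (row, col);
#'   may have zero rows.
#' @return an object of class `usj_clicks`.
#' @export
click_set <- function(foreground, background = matrix(integer(), 0, 2)) {
  fg <- .as_click_matrix(foreground)
  bg <- .as_click_matrix(background)
  if (anyDuplicated(fg) || anyDuplicated(bg))
    stopf("clicks must be distinct within each polarity")
  structure(list(foreground = fg, background = bg), class = "usj_clicks")
}

.as_click_matrix <- function(x) {
  if (is.null(x)) x <- matrix(integer(), 0, 2)
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("row", "col")))
  x
}

#' @export
print.usj_clicks <- function(x, ...) {
  cat(sprintf("<usj_clicks> %d foreground, %d background\n",
              nrow(x$foreground), nrow(x$background)))
  invisible(x)
}

# 0-based (row, col) coordinates of mask foreground pixels
.mask_pixels <- function(mask) {
  which(mask > 0, arr.ind = TRUE) - 1L
}

#' Simulate foreground user clicks inside a lesion
#'
#' Draws a click count uniformly from 1--5, then that many distinct pixels
#' uniformly without replacement from the lesion's foreground pixels
#' (capped at the number of available pixels).
#'
#' @param mask binary lesion mask (nonempty).
#' @param rng_seed integer seed; the draw is deterministic per seed.
#' @return integer matrix of 0-based (row, col) clicks.
#' @export
simulate_foreground_clicks <- function(mask, rng_seed) {
  px <- .mask_pixels(mask)
  if (nrow(px) == 0) stopf("mask is empty: no lesion to click on")
  with_seed(rng_seed, {
    k <- min(sample.int(5, 1), nrow(px))
    px[sample.int(nrow(px), k), , drop = FALSE]
  })
}

#' Euclidean distance from every background pixel to the lesion
#'
#' @param mask binary lesion mask.
#' @return matrix of distances (px) to the nearest lesion pixel; 0 on the
#'   lesion itself.
#' @keywords internal
lesion_distance <- function(mask) {
  d <- EBImage::distmap(1 - (mask > 0))
  d[mask > 0] <- 0
  d
}

#' Simulate background user clicks near a lesion
#'
#' Draws a click count uniformly from 0--10, then that many distinct pixels
#' uniformly from the background band whose Euclidean distance to the
#' lesion lies in `[d_min, d_max]` (capped at the band size). A zero count
#' models a user who provides no background clicks.
#'
#' @param mask binary lesion mask (nonempty).
#' @param d_min,d_max band limits in pixels, `0 < d_min < d_max`.
#' @param rng_seed integer seed.
#' @return integer matrix of 0-based (row, col) clicks; possibly 0 rows.
#'   If the band is empty (lesion fills the image) an empty matrix is
#'   returned with a warning.
#' @export
simulate_background_clicks <- function(mask, d_min = 5, d_max = 40,
                                       rng_seed = 1) {
  if (!any(mask > 0)) stopf("mask is empty")
  if (!(d_min > 0 && d_min < d_max)) stopf("need 0 < d_min < d_max")
  d <- lesion_distance(mask)
  band <- which(mask == 0 & d >= d_min & d <= d_max, arr.ind = TRUE) - 1L
  if (nrow(band) == 0) {
    warning("no background band pixels available; returning no clicks")
    return(.as_click_matrix(NULL))
  }
  with_seed(rng_seed, {
    m <- min(sample.int(11, 1) - 1L, nrow(band))
    if (m == 0) return(.as_click_matrix(NULL))
    band[sample.int(nrow(band), m), , drop = FALSE]
  })
}

#' Generate simulated click sequences for an image
#'
#' Produces `n_sequences` independent click sets, each pairing one
#' foreground draw (1--5 clicks in the lesion) with one background draw
#' (0--10 clicks in the surrounding band). These play the role of the
#' pre-generated user-input sequences used during training.
#'
#' @inheritParams simulate_background_clicks
#' @param n_sequences number of click sets.
#' @return list of `usj_clicks`.
#' @export
generate_click_sequences <- function(mask, n_sequences = 15, d_min = 5,
                                     d_max = 40, rng_seed = 1) {
  if (n_sequences == 0) return(list())
  lapply(seq_len(n_sequences), function(i) {
    click_set(simulate_foreground_clicks(mask, rng_seed + 2L * i),
              simulate_background_clicks(mask, d_min, d_max,
                                         rng_seed + 2L * i + 1L))
  })
}

#' One-click test-mode user input
#'
#' A single foreground click drawn uniformly from the lesion, with no
#' background clicks (the background distance map is then the constant
#' 255 fill).
#'
#' @inheritParams simulate_foreground_clicks
#' @return a `usj_clicks` with one foreground and zero background clicks.
#' @export
one_click_input <- function(mask, rng_seed) {
  px <- .mask_pixels(mask)
  if (nrow(px) == 0) stopf("mask is empty")
  i <- with_seed(rng_seed, sample.int(nrow(px), 1))
  click_set(px[i, , drop = FALSE])
}

#' Euclidean distance map of a click set
#'
#' Each pixel holds the minimum Euclidean distance between its center and
#' any click, truncated at 255. With no clicks the map is the constant
#' 255 fill, the convention for "no background clicks provided".
#'
#' @param clicks integer matrix of 0-based (row, col) clicks (possibly
#'   0 rows).
#' @param shape integer vector (H, W).
#' @return H x W numeric matrix with values in \[0, 255\].
#' @export
distance_map <- function(clicks, shape) {
  H <- shape[1]; W <- shape[2]
  clicks <- .as_click_matrix(clicks)
  if (nrow(clicks) == 0) return(matrix(255, H, W))
  if (any(clicks[, 1] < 0 | clicks[, 1] >= H |
            clicks[, 2] < 0 | clicks[, 2] >= W))
    stopf("click outside the %dx%d image", H, W)
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- matrix(Inf, H, W)
  for (i in seq_len(nrow(clicks))) {
    d <- pmin(d, sqrt((rows - clicks[i, 1])^2 + (cols - clicks[i, 2])^2))
  }
  pmin(d, 255)
}

#' Encode an image and click set as the network's three-channel input
#'
#' Channel 0 is the image, channel 1 the foreground-click distance map,
#' channel 2 the background-click distance map (constant 255 when there
#' are no background clicks); every channel is divided by 255 into
#' \[0, 1\].
#'
#' @param image intensity matrix on the 0--255 scale.
#' @param clicks a `usj_clicks`.
#' @return H x W x 3 array, class `usj_encoded`.
#' @export
encode_input <- function(image, clicks) {
  stopifnot(inherits(clicks, "usj_clicks"))
  shape <- dim(image)
  x <- array(0, c(shape[1], shape[2], 3))
  x[, , 1] <- image / 255
  x[, , 2] <- distance_map(clicks$foreground, shape) / 255
  x[, , 3] <- distance_map(clicks$background, shape) / 255
  structure(x, class = c("usj_encoded", "array"))
}

#' Tight axis-aligned bounding box of a mask
#'
#' @param mask binary mask (nonempty).
#' @return list with 0-based `top`, `left`, `bottom`, `right` (inclusive).
#' @export
tight_box <- function(mask) {
  px <- .mask_pixels(mask)
  if (nrow(px) == 0) stopf("mask is empty")
  list(top = min(px[, 1]), left = min(px[, 2]),
       bottom = max(px[, 1]), right = max(px[, 2]))
}

#' Simulate a two-click bounding-box user input
#'
#' Starting from the tight box of the lesion, each corner coordinate is
#' perturbed by a uniform positional error proportional to the box side,
#' then the box is enlarged symmetrically so that it includes the lesion,
#' and finally clamped to the image. The guarantee that the returned box
#' contains every mask pixel is enforced by construction.
#'
#' @param mask binary lesion mask (nonempty).
#' @param jitter_frac positional-error amplitude as a fraction of the box
#'   side.
#' @param enlarge_frac symmetric enlargement per side as a fraction of the
#'   box side.
#' @param rng_seed integer seed.
#' @return list with 0-based integer `top`, `left`, `bottom`, `right`,
#'   class `usj_bbox`.
#' @export
simulate_bbox <- function(mask, jitter_frac = 0.1, enlarge_frac = 0.1,
                          rng_seed = 1) {
  tb <- tight_box(mask)
  H <- nrow(mask); W <- ncol(mask)
  hh <- tb$bottom - tb$top + 1
  ww <- tb$right - tb$left + 1
  with_seed(rng_seed, {
    top <- tb$top + runif(1, -jitter_frac, jitter_frac) * hh
    bottom <- tb$bottom + runif(1, -jitter_frac, jitter_frac) * hh
    left <- tb$left + runif(1, -jitter_frac, jitter_frac) * ww
    right <- tb$right + runif(1, -jitter_frac, jitter_frac) * ww
    top <- top - enlarge_frac * hh
    bottom <- bottom + enlarge_frac * hh
    left <- left - enlarge_frac * ww
    right <- right + enlarge_frac * ww
    # the box must include the lesion
    top <- min(top, tb$top); bottom <- max(bottom, tb$bottom)
    left <- min(left, tb$left); right <- max(right, tb$right)
    box <- list(top = max(0L, as.integer(floor(top))),
                left = max(0L, as.integer(floor(left))),
                bottom = min(H - 1L, as.integer(ceiling(bottom))),
                right = min(W - 1L, as.integer(ceiling(right))))
    structure(box, class = "usj_bbox")
  })
}

#' Transform a bounding box into the five-click representation
#'
#' The two-click (bounding box) test mode is fed to the network as one
#' foreground click at the box center and four background clicks at its
#' corners.
#'
#' @param box a list with 0-based `top`, `left`, `bottom`, `right`.
#' @return a `usj_clicks` with 1 foreground and 4 background clicks.
#' @export
bbox_to_clicks <- function(box) {
  if (!(box$top < box$bottom && box$left < box$right))
    stopf("invalid box: need top < bottom and left < right")
  fg <- cbind(floor((box$top + box$bottom) / 2),
              floor((box$left + box$right) / 2))
  bg <- rbind(c(box$top, box$left), c(box$top, box$right),
              c(box$bottom, box$left), c(box$bottom, box$right))
  click_set(fg, bg)
}

#' Serialize / deserialize clicks and boxes as JSON
#'
#' @param x a `usj_clicks` or `usj_bbox`.
#' @param path file path.
#' @return `read_clicks` returns a `usj_clicks`; `read_bbox` a `usj_bbox`.
#' @export
write_clicks <- function(x, path) {
  stopifnot(inherits(x, "usj_clicks"))
  rows <- function(m) lapply(seq_len(nrow(m)), function(i)
    as.integer(m[i, ]))
  jsonlite::write_json(list(foreground = rows(x$foreground),
                            background = rows(x$background)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_clicks
#' @export
read_clicks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) {
    if (length(v) == 0) return(matrix(integer(), 0, 2))
    if (is.matrix(v)) matrix(as.integer(v), ncol = 2)
    else matrix(as.integer(do.call(rbind, v)), ncol = 2)
  }
  click_set(as_mat(j$foreground), as_mat(j$background))
}

#' @rdname write_clicks
#' @export
write_bbox <- function(x, path) {
  jsonlite::write_json(list(top = x$top, left = x$left, bottom = x$bottom,
                            right = x$right), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_clicks
#' @export
read_bbox <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(top = as.integer(j$top), left = as.integer(j$left),
                 bottom = as.integer(j$bottom),
                 right = as.integer(j$right)), class = "usj_bbox")
}
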