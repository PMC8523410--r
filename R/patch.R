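#' Extract the lesion-centered patch used by the classification-only
#' network
#'
#' Crops a square patch centered on the lesion's tight-box center with a
#' side equal to twice the larger tight-box dimension (clamped to at
#' least 8 px), replicating edge pixels where the patch exceeds the image
#' border, and resamples it bilinearly to the classifier input size.
#'
#' @param record a `usj_record`, or any list with `image` and `mask`.
#' @param box optional bounding box (0-based `top`/`left`/`bottom`/
#'   `right`) used instead of the mask's tight box.
#' @param size output side in pixels.
#' @return `size` x `size` numeric matrix on the 0--255 scale, with the
#'   pre-resampling side stored in attribute `"side_px"`.
#' @export
extract_patch <- function(record, box = NULL, size = 64) {
  tb <- if (is.null(box)) tight_box(record$mask) else box
  h <- tb$bottom - tb$top + 1
  w <- tb$right - tb$left + 1
  side <- max(2 * max(h, w), 8)
  cr <- floor((tb$top + tb$bottom) / 2)
  cc <- floor((tb$left + tb$right) / 2)
  r0 <- cr - floor(side / 2)
  c0 <- cc - floor(side / 2)
  H <- nrow(record$image); W <- ncol(record$image)
  ri <- pmin(pmax(r0 + seq_len(side) - 1, 0), H - 1) + 1  # edge replication
  ci <- pmin(pmax(c0 + seq_len(side) - 1, 0), W - 1) + 1
  patch <- record$image[ri, ci, drop = FALSE]
  out <- as.matrix(EBImage::resize(patch + 0, w = size, h = size))
  attr(out, "side_px") <- side
  out
}
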