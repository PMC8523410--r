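#' Pixelwise focal loss for segmentation
#'
#' Mean over pixels of \eqn{-(1-p_t)^\gamma \log p_t}, where \eqn{p_t}
#' is the predicted probability of the true pixel class (\eqn{p} on
#' lesion pixels, \eqn{1-p} on background). \eqn{\gamma = 0} reduces to
#' plain binary cross-entropy; larger \eqn{\gamma} down-weights easy
#' pixels. Probabilities are clamped to \eqn{[\epsilon, 1-\epsilon]}
#' with \eqn{\epsilon = 10^{-7}} to keep the loss finite.
#'
#' @param seg_prob predicted foreground probabilities (any array shape).
#' @param mask binary reference mask of the same shape.
#' @param gamma focusing exponent (>= 0).
#' @return scalar loss (>= 0).
#' @export
focal_loss_pixelwise <- function(seg_prob, mask, gamma = 2) {
  if (!identical(dim(seg_prob), dim(mask)) &&
        length(seg_prob) != length(mask))
    stopf("seg_prob and mask shapes differ")
  p <- pmin(pmax(seg_prob, 1e-7), 1 - 1e-7)
  m <- (mask > 0) + 0
  pt <- m * p + (1 - m) * (1 - p)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Alpha-balanced focal loss for classification
#'
#' \eqn{-\alpha_y (1-p_y)^\gamma \log p_y} for true class \eqn{y}, where
#' \eqn{\alpha} is a per-class weight (e.g. normalized inverse class
#' frequency). With \eqn{\alpha = 1, \gamma = 0} this is the standard
#' cross-entropy of the true class.
#'
#' @param cls_prob probability vector over classes (sums to 1), or an
#'   N x K matrix for a batch.
#' @param label 1-based true class index (vector of length N for a
#'   batch).
#' @param alpha_per_class per-class weights, recycled to K.
#' @param gamma focusing exponent.
#' @return scalar loss (mean over the batch).
#' @export
focal_loss_classification <- function(cls_prob, label, alpha_per_class = 1,
                                      gamma = 2) {
  if (is.null(dim(cls_prob))) cls_prob <- matrix(cls_prob, 1)
  K <- ncol(cls_prob)
  if (any(label < 1 | label > K)) stopf("label out of range 1..%d", K)
  alpha <- rep_len(alpha_per_class, K)
  p <- pmin(pmax(cls_prob[cbind(seq_len(nrow(cls_prob)), label)], 1e-7),
            1 - 1e-7)
  mean(-alpha[label] * (1 - p)^gamma * log(p))
}

#' Joint training loss
#'
#' The unweighted sum of the segmentation and classification components.
#'
#' @param seg_loss,cls_loss finite scalars.
#' @return their sum.
#' @export
joint_loss <- function(seg_loss, cls_loss) {
  stopifnot(is.finite(seg_loss), is.finite(cls_loss))
  seg_loss + cls_loss
}

# Gradient of the pixelwise focal loss with respect to the *logit* map,
# with p = sigmoid(z). Derived by the chain rule through the clamped
# probability; returns an array shaped like the logits.
focal_seg_logit_grad <- function(seg_logit, mask, gamma) {
  p <- sigmoid(seg_logit)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  m <- (mask > 0) + 0
  pt <- m * pc + (1 - m) * (1 - pc)
  # dL/dpt, then dpt/dz = +/- p(1-p)
  dL_dpt <- gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
    (1 - pt)^gamma / pt
  if (gamma == 0) dL_dpt <- -1 / pt
  sgn <- 2 * m - 1
  inside <- (p > 1e-7 & p < 1 - 1e-7)
  g <- dL_dpt * sgn * p * (1 - p) * inside
  g / length(p)
}

# Gradient of the alpha-balanced focal loss with respect to the class
# *logits* (softmax inputs). cls_prob: (N, K); label: length N.
focal_cls_logit_grad <- function(cls_prob, label, alpha_per_class, gamma) {
  N <- nrow(cls_prob)
  K <- ncol(cls_prob)
  alpha <- rep_len(alpha_per_class, K)
  py <- pmin(pmax(cls_prob[cbind(seq_len(N), label)], 1e-7), 1 - 1e-7)
  # dL/dpy for each sample
  dL_dpy <- alpha[label] *
    (gamma * (1 - py)^(pmax(gamma - 1, 0)) * log(py) - (1 - py)^gamma / py)
  if (gamma == 0) dL_dpy <- -alpha[label] / py
  # softmax jacobian: dpy/dz_k = py (delta_yk - p_k)
  onehot <- matrix(0, N, K)
  onehot[cbind(seq_len(N), label)] <- 1
  g <- dL_dpy * py * (onehot - cls_prob)
  g / N
}
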