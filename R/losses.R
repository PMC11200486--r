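# Segmentation loss functions.
#
# Notation: y_ij is the one-hot ground truth of pixel i on class j,
# yhat_ij the predicted probability, m the class count, N the pixel
# count, d the boundary-band half-width in pixels.  Global losses (CE,
# WCE) score every pixel; local losses (soft IoU, Dice) score per-class
# overlap; the boundary loss is the soft-IoU form restricted to pixels
# within distance d of a class boundary in either the ground truth or
# the hard prediction.

LOG_EPS <- 1e-7   # probability clip inside logarithms

#' Cross-entropy loss
#'
#' Mean per-pixel negative log predicted probability of the true class:
#' `-(1/N) sum_i sum_j y_ij log(yhat_ij)`.  Probabilities are clipped to
#' `[1e-7, 1]` before the log.  Zero exactly when `pred` is the one-hot
#' encoding of `gt`.
#'
#' @param pred probability array, height x width x m.
#' @param gt integer label matrix, ids `< m`.
#' @return non-negative scalar.
#' @export
ce_loss <- function(pred, gt) {
  validate_probmap(pred); validate_mask(gt, m = dim(pred)[3], arg = "gt")
  check_same_shape(pred, gt)
  pv <- pred[cbind(c(row(gt)), c(col(gt)), c(gt) + 1L)]
  0 - mean(log(pmin(pmax(pv, LOG_EPS), 1))) + 0   # + 0 avoids IEEE -0
}

#' Weighted cross-entropy loss
#'
#' Cross-entropy with a per-class weight `w_j` multiplying each pixel's
#' contribution: `-(1/N) sum_i sum_j w_j y_ij log(yhat_ij)`.  Reduces to
#' [ce_loss()] when all weights are 1.
#'
#' @inheritParams ce_loss
#' @param weights numeric vector of m non-negative class weights, not
#'   all zero; default [inverse_freq_weights()] of `gt`.
#' @return non-negative scalar.
#' @export
wce_loss <- function(pred, gt, weights = inverse_freq_weights(gt, dim(pred)[3])) {
  validate_probmap(pred); validate_mask(gt, m = dim(pred)[3], arg = "gt")
  check_same_shape(pred, gt)
  m <- dim(pred)[3]
  if (length(weights) != m)
    stop(sprintf("`weights` must have length m = %d, got %d", m, length(weights)))
  if (any(weights < 0) || all(weights == 0))
    stop("`weights` must be non-negative and not all zero")
  pv <- pred[cbind(c(row(gt)), c(col(gt)), c(gt) + 1L)]
  0 - mean(weights[c(gt) + 1L] * log(pmin(pmax(pv, LOG_EPS), 1))) + 0
}

#' Inverse-frequency class weights
#'
#' Default weighting for [wce_loss()]: each class present in `gt` gets a
#' weight proportional to the inverse of its pixel frequency; classes
#' absent from `gt` get weight 0; weights are scaled to mean 1 over all
#' m classes.
#'
#' @param gt integer label matrix.
#' @param m number of classes.
#' @return numeric vector of length m.
#' @export
inverse_freq_weights <- function(gt, m) {
  validate_mask(gt, m = m, arg = "gt")
  cnt <- tabulate(c(gt) + 1L, nbins = m)
  w <- ifelse(cnt > 0, 1 / cnt, 0)
  w * m / sum(w)
}

## shared soft-overlap machinery: per-class ratio with the 0/0 -> 1
## convention (a class absent from both gt and pred incurs no loss)
soft_ratios <- function(pred, gt, class_set, kind, keep = NULL) {
  vapply(class_set, function(cls) {
    y <- as.numeric(gt == cls)
    p <- c(pred[, , cls + 1L])
    if (!is.null(keep)) { y <- y[keep]; p <- p[keep] }
    inter <- sum(y * p); sy <- sum(y); sp <- sum(p)
    denom <- if (kind == "iou") sy + sp - inter else sy + sp
    num   <- if (kind == "iou") inter else 2 * inter
    if (denom <= 0) 1 else num / denom
  }, numeric(1))
}

#' Soft IoU loss
#'
#' One minus the mean over classes of the soft intersection-over-union
#' ratio `sum(y*yhat) / (sum(y) + sum(yhat) - sum(y*yhat))`.  A class
#' with an empty denominator (absent from both ground truth and
#' prediction) counts as ratio 1, i.e. contributes no loss.
#'
#' @inheritParams ce_loss
#' @param class_set integer vector of class ids to average over;
#'   default all m classes.
#' @return scalar in `[0, 1]`.
#' @export
iou_loss <- function(pred, gt, class_set = NULL) {
  validate_probmap(pred); validate_mask(gt, m = dim(pred)[3], arg = "gt")
  check_same_shape(pred, gt)
  if (is.null(class_set)) class_set <- seq_len(dim(pred)[3]) - 1L
  1 - mean(soft_ratios(pred, gt, class_set, "iou"))
}

#' Soft Dice loss
#'
#' One minus the mean over classes of the soft Dice ratio
#' `2 sum(y*yhat) / (sum(y) + sum(yhat))`; same empty-class convention
#' as [iou_loss()].  Always `<=` [iou_loss()] on the same input.
#'
#' @inheritParams iou_loss
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, gt, class_set = NULL) {
  validate_probmap(pred); validate_mask(gt, m = dim(pred)[3], arg = "gt")
  check_same_shape(pred, gt)
  if (is.null(class_set)) class_set <- seq_len(dim(pred)[3]) - 1L
  1 - mean(soft_ratios(pred, gt, class_set, "dice"))
}

## ---- boundary band --------------------------------------------------------

#' Boundary band of a label mask
#'
#' Boundary pixels are pixels with at least one 4-neighbor of a
#' different class id; the image frame itself is not a boundary.  The
#' band is every pixel whose Euclidean distance to the nearest boundary
#' pixel is at most `d` (exact distance-transform semantics).
#'
#' @param mask integer label matrix.
#' @param d band half-width in pixels, integer `>= 1`.
#' @return logical matrix, `TRUE` inside the band; all-`FALSE` for a
#'   uniform single-class mask.
#' @export
boundary_band <- function(mask, d) {
  validate_mask(mask)
  if (d < 1) stop("`d` must be >= 1")
  h <- nrow(mask); w <- ncol(mask)
  bnd <- matrix(FALSE, h, w)
  if (h > 1) {
    dv <- mask[-1, , drop = FALSE] != mask[-h, , drop = FALSE]
    bnd[-h, ] <- bnd[-h, ] | dv
    bnd[-1, ] <- bnd[-1, ] | dv
  }
  if (w > 1) {
    dh <- mask[, -1, drop = FALSE] != mask[, -w, drop = FALSE]
    bnd[, -w] <- bnd[, -w] | dh
    bnd[, -1] <- bnd[, -1] | dh
  }
  if (!any(bnd)) return(bnd)
  dist <- EBImage::distmap(matrix(as.numeric(!bnd), h, w), metric = "euclidean")
  matrix(as.numeric(dist) <= d, h, w)
}

#' Boundary loss
#'
#' Soft-IoU loss evaluated only on boundary-band pixels: the pixel set
#' is the union of the ground-truth band and the band of the hard
#' (argmax) prediction, each of half-width `d`, and the per-class ratios
#' are averaged over the ocular structure classes (pupil, iris, sclera,
#' caruncle by default — skin is excluded).  Symmetric in the sense that
#' swapping hard labels and prediction leaves the value unchanged.
#' Empty band (uniform masks) gives loss 0.
#'
#' @inheritParams ce_loss
#' @param d band half-width in pixels.
#' @param class_set class ids averaged over; default all non-skin ids
#'   `1:(m-1)`.
#' @return scalar in `[0, 1]`.
#' @export
boundary_loss <- function(pred, gt, d, class_set = NULL) {
  validate_probmap(pred); validate_mask(gt, m = dim(pred)[3], arg = "gt")
  check_same_shape(pred, gt)
  if (d < 1) stop("`d` must be >= 1")
  m <- dim(pred)[3]
  if (is.null(class_set)) class_set <- seq_len(m)[-1] - 1L
  band <- boundary_band(gt, d) | boundary_band(argmax_mask(pred), d)
  if (!any(band)) return(0)
  1 - mean(soft_ratios(pred, gt, class_set, "iou", keep = c(band)))
}

## ---- hybrid loss ----------------------------------------------------------

#' Boundary-weight schedule
#'
#' Linear ramp of the boundary-loss weight over training:
#' `gamma(e) = gamma_max * e / (total_epochs - 1)` for 0-based epoch
#' `e`, so the first epoch has weight 0 and the last `gamma_max`.  With
#' a single epoch the weight is `gamma_max` immediately.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs total number of epochs, `>= 1`.
#' @param gamma_max terminal boundary weight (default 1).
#' @return scalar weight.
#' @export
gamma_schedule <- function(epoch, total_epochs, gamma_max = 1) {
  if (total_epochs < 1) stop("`total_epochs` must be >= 1")
  if (epoch < 0 || epoch >= total_epochs)
    stop(sprintf("`epoch` must be in [0, %d)", total_epochs))
  if (total_epochs == 1) return(gamma_max)
  gamma_max * epoch / (total_epochs - 1)
}

#' Hybrid loss configuration
#'
#' Bundles the weights and term choices of the scheduled hybrid loss
#' `alpha * L_global + beta * L_local + gamma(epoch) * L_boundary`.
#' The three named training modes are global + boundary ("G+B": local
#' term `"none"`, `beta = 0`), local + boundary ("L+B": `alpha = 0`),
#' and global + local + boundary ("G+L+B").
#'
#' @param alpha weight of the global term (default 1).
#' @param beta weight of the local term (default 1).
#' @param gamma_max terminal boundary weight (default 1).
#' @param global_term `"ce"` or `"wce"`.
#' @param local_term `"iou"`, `"dice"`, or `"none"` (requires
#'   `beta = 0`).
#' @param total_epochs schedule length, `>= 1`.
#' @param d_fraction boundary band width as a fraction of the image
#'   diagonal (default 0.02); ignored when `d` is given.
#' @param d explicit band half-width in pixels, or `NULL` to derive it
#'   from `d_fraction` and the mask size.
#' @return object of class `"hybrid_loss_config"`.
#' @export
hybrid_config <- function(alpha = 1, beta = 1, gamma_max = 1,
                          global_term = c("ce", "wce"),
                          local_term = c("iou", "dice", "none"),
                          total_epochs = 150L, d_fraction = 0.02, d = NULL) {
  global_term <- match.arg(global_term)
  local_term <- match.arg(local_term)
  if (alpha < 0 || beta < 0 || gamma_max < 0)
    stop("`alpha`, `beta`, `gamma_max` must be >= 0")
  if (total_epochs < 1) stop("`total_epochs` must be >= 1")
  if (local_term == "none" && beta > 0)
    stop("`local_term = \"none\"` requires `beta = 0`")
  structure(list(alpha = alpha, beta = beta, gamma_max = gamma_max,
                 global_term = global_term, local_term = local_term,
                 schedule = "linear", total_epochs = as.integer(total_epochs),
                 d_fraction = d_fraction, d = d),
            class = "hybrid_loss_config")
}

#' @export
print.hybrid_loss_config <- function(x, ...) {
  terms <- c(
    if (x$alpha > 0) sprintf("%g*%s", x$alpha, toupper(x$global_term)),
    if (x$beta > 0 && x$local_term != "none")
      sprintf("%g*%s", x$beta, toupper(x$local_term)),
    if (x$gamma_max > 0) sprintf("gamma(e)*Boundary [gamma_max=%g]", x$gamma_max))
  cat("Hybrid segmentation loss: ", paste(terms, collapse = " + "),
      "\n  linear gamma ramp over ", x$total_epochs, " epochs; d = ",
      if (is.null(x$d)) sprintf("%g * image diagonal", x$d_fraction)
      else sprintf("%d px", x$d), "\n", sep = "")
  invisible(x)
}

#' Scheduled hybrid loss
#'
#' Evaluates `alpha * L_global + beta * L_local + gamma(epoch) *
#' L_boundary` for a configuration built by [hybrid_config()].  Terms
#' with weight 0 (or local term `"none"`) are skipped entirely.
#'
#' @inheritParams ce_loss
#' @param cfg a `"hybrid_loss_config"`.
#' @param epoch 0-based epoch index for the gamma schedule.
#' @param weights optional class weights for a `"wce"` global term.
#' @return non-negative scalar.
#' @export
hybrid_loss <- function(pred, gt, cfg, epoch = 0L, weights = NULL) {
  if (!inherits(cfg, "hybrid_loss_config"))
    stop("`cfg` must be built by hybrid_config()")
  gam <- gamma_schedule(epoch, cfg$total_epochs, cfg$gamma_max)
  total <- 0
  if (cfg$alpha > 0) {
    g <- if (cfg$global_term == "ce") ce_loss(pred, gt)
         else if (is.null(weights)) wce_loss(pred, gt)
         else wce_loss(pred, gt, weights)
    total <- total + cfg$alpha * g
  }
  if (cfg$beta > 0 && cfg$local_term != "none") {
    l <- if (cfg$local_term == "iou") iou_loss(pred, gt) else dice_loss(pred, gt)
    total <- total + cfg$beta * l
  }
  if (gam > 0) {
    d <- if (!is.null(cfg$d)) cfg$d
         else d_from_fraction(nrow(gt), ncol(gt), cfg$d_fraction)
    total <- total + gam * boundary_loss(pred, gt, d)
  }
  total
}
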