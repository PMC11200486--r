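# Evaluation metrics for hard segmentation masks.

#' Per-class and mean segmentation metrics
#'
#' Computes per-class IoU, Dice, precision, recall and F1 from confusion
#' counts, plus their arithmetic means over `class_set`.  The empty-class
#' convention is 0/0 -> 1 throughout (a class absent from both masks
#' scores perfectly), consistent with the loss functions.  F1 equals
#' Dice per class algebraically; both are reported for table parity.
#'
#' @param pred,gt integer label matrices of the same shape.
#' @param class_set class ids to average over (default all 5 eye
#'   classes, `0:4`).
#' @param m number of classes (default `max(class_set) + 1`).
#' @return list of class `"metric_report"` with elements `per_class`
#'   (data frame) and `means` (named vector `miou`, `mdice`,
#'   `mprecision`, `mrecall`, `mf1`).
#' @export
segmentation_metrics <- function(pred, gt, class_set = 0:4,
                                 m = max(class_set) + 1L) {
  cc <- confusion_counts(pred, gt, m = m)
  cc <- cc[cc$class %in% class_set, , drop = FALSE]
  safe <- function(num, den) ifelse(den == 0, 1, num / den)
  per <- data.frame(
    class     = cc$class,
    iou       = safe(cc$tp, cc$tp + cc$fp + cc$fn),
    dice      = safe(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn),
    precision = safe(cc$tp, cc$tp + cc$fp),
    recall    = safe(cc$tp, cc$tp + cc$fn)
  )
  per$f1 <- ifelse(per$precision + per$recall == 0, 0,
                   2 * per$precision * per$recall / (per$precision + per$recall))
  # precision = recall = 1 under the 0/0 convention gives f1 = 1 as well
  means <- c(miou = mean(per$iou), mdice = mean(per$dice),
             mprecision = mean(per$precision), mrecall = mean(per$recall),
             mf1 = mean(per$f1))
  structure(list(per_class = per, means = means), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics (", nrow(x$per_class), " classes)\n", sep = "")
  print(round(x$per_class, 4), row.names = FALSE)
  cat("means: ", paste(sprintf("%s=%.4f", names(x$means), x$means),
                       collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Mean boundary IoU (MBIOU)
#'
#' Boundary-restricted IoU: for each class, the ground-truth and
#' predicted masks are binarized for that class, the boundary bands of
#' half-width `d` are extracted from each ([boundary_band()] on the
#' binary masks), and the hard IoU of the class is computed over pixels
#' in the union of the two bands.  The mean is over `class_set`, by
#' default the four ocular structures (skin excluded).  0/0 -> 1 as
#' elsewhere.
#'
#' @param pred,gt integer label matrices.
#' @param d band half-width in pixels, `>= 1`.
#' @param class_set class ids (default `1:4`).
#' @return scalar in `[0, 1]`.
#' @export
mbiou <- function(pred, gt, d, class_set = 1:4) {
  validate_mask(pred, arg = "pred"); validate_mask(gt, arg = "gt")
  check_same_shape(pred, gt)
  if (d < 1) stop("`d` must be >= 1")
  vals <- vapply(class_set, function(cls) {
    gb <- matrix(as.integer(gt == cls), nrow(gt), ncol(gt))
    pb <- matrix(as.integer(pred == cls), nrow(pred), ncol(pred))
    band <- boundary_band(gb, d) | boundary_band(pb, d)
    y <- (gt == cls)[band]; p <- (pred == cls)[band]
    inter <- sum(y & p); union <- sum(y | p)
    if (union == 0) 1 else inter / union
  }, numeric(1))
  mean(vals)
}

#' Mean wall-clock time of a function over a list of inputs
#'
#' Applies `fn` to each element of `inputs` and reports results together
#' with the mean elapsed wall-clock time per call, the `avg_time`
#' companion figure of a metric report.  Hardware-dependent; never used
#' for correctness checks.
#'
#' @param fn function of one argument.
#' @param inputs non-empty list of inputs.
#' @return list with elements `results` (list) and `avg_time_s`.
#' @export
timed <- function(fn, inputs) {
  if (length(inputs) == 0L) stop("`inputs` must be non-empty")
  times <- numeric(length(inputs))
  results <- vector("list", length(inputs))
  for (k in seq_along(inputs)) {
    t0 <- proc.time()[["elapsed"]]
    results[[k]] <- fn(inputs[[k]])
    times[k] <- proc.time()[["elapsed"]] - t0
  }
  list(results = results, avg_time_s = mean(times))
}
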