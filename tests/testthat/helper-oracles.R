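# Independent brute-force oracles: plain per-pixel loops, no shared code
# with the implementation.

random_mask <- function(h, w, m) {
  matrix(sample(0:(m - 1), h * w, replace = TRUE), h, w)
}

# random probability map via normalized uniforms
random_probmap <- function(h, w, m) {
  p <- array(stats::runif(h * w * m), dim = c(h, w, m))
  s <- apply(p, c(1, 2), sum)
  for (k in seq_len(m)) p[, , k] <- p[, , k] / s
  p
}

oracle_ce <- function(pred, gt) {
  h <- nrow(gt); w <- ncol(gt); total <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    pv <- pred[i, j, gt[i, j] + 1]
    total <- total - log(min(max(pv, 1e-7), 1))
  }
  total / (h * w)
}

oracle_wce <- function(pred, gt, wts) {
  h <- nrow(gt); w <- ncol(gt); total <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    pv <- pred[i, j, gt[i, j] + 1]
    total <- total - wts[gt[i, j] + 1] * log(min(max(pv, 1e-7), 1))
  }
  total / (h * w)
}

oracle_overlap <- function(pred, gt, kind, class_set = NULL,
                           keep = NULL) {
  m <- dim(pred)[3]
  if (is.null(class_set)) class_set <- 0:(m - 1)
  h <- nrow(gt); w <- ncol(gt)
  ratios <- numeric(0)
  for (cls in class_set) {
    inter <- 0; sy <- 0; sp <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!is.null(keep) && !keep[i, j]) next
      y <- as.numeric(gt[i, j] == cls)
      p <- pred[i, j, cls + 1]
      inter <- inter + y * p; sy <- sy + y; sp <- sp + p
    }
    den <- if (kind == "iou") sy + sp - inter else sy + sp
    num <- if (kind == "iou") inter else 2 * inter
    ratios <- c(ratios, if (den <= 0) 1 else num / den)
  }
  1 - mean(ratios)
}

# exhaustive boundary band: all pairwise distances to differing-neighbour
# pixels
oracle_band <- function(mask, d) {
  h <- nrow(mask); w <- ncol(mask)
  bpix <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, ,
             drop = FALSE]
    if (any(mask[nb] != mask[i, j])) bpix <- rbind(bpix, c(i, j))
  }
  band <- matrix(FALSE, h, w)
  if (is.null(bpix)) return(band)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dmin <- min(sqrt((bpix[, 1] - i)^2 + (bpix[, 2] - j)^2))
    band[i, j] <- dmin <= d
  }
  band
}

oracle_boundary_loss <- function(pred, gt, d, class_set = NULL) {
  m <- dim(pred)[3]
  if (is.null(class_set)) class_set <- 1:(m - 1)
  hard <- matrix(0L, nrow(gt), ncol(gt))
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt)))
    hard[i, j] <- which.max(pred[i, j, ]) - 1L
  band <- oracle_band(gt, d) | oracle_band(hard, d)
  if (!any(band)) return(0)
  oracle_overlap(pred, gt, "iou", class_set, keep = band)
}

oracle_confusion <- function(pred, gt, m) {
  out <- NULL
  for (cls in 0:(m - 1)) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
      pv <- pred[i, j] == cls; gv <- gt[i, j] == cls
      if (pv && gv) tp <- tp + 1L
      else if (pv && !gv) fp <- fp + 1L
      else if (!pv && gv) fn <- fn + 1L
      else tn <- tn + 1L
    }
    out <- rbind(out, data.frame(class = cls, tp = tp, fp = fp, fn = fn, tn = tn))
  }
  out
}

# sample points on an ellipse, exact
ellipse_points <- function(cx, cy, a, b, ang, n = 36) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th) * cos(ang) - b * sin(th) * sin(ang),
        cy + a * cos(th) * sin(ang) + b * sin(th) * cos(ang))
}

# the standard random-geometry family used for closure sweeps
random_eye_geometry <- function() {
  r_i <- stats::runif(1, 26, 36)
  curv <- stats::runif(1, 2.0, 2.5)
  W <- curv * r_i
  off <- stats::runif(1, -0.6, 0.6) * (W - r_i)
  eye_geometry(width = 200L, height = 150L,
               iris_center = c(100 + off, 75), iris_radius = r_i,
               pupil_radius = stats::runif(1, 0.32, 0.45) * r_i,
               aperture = stats::runif(1, 0.5, 1.7) * r_i,
               lid_curvature = curv, gaze_offset = off)
}
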