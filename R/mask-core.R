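# Core mask containers and I/O.
#
# A label mask is an integer matrix (rows x columns) of class ids; the
# five-class ocular code is 0 = skin, 1 = pupil, 2 = iris, 3 = sclera,
# 4 = lacrimal caruncle.  A probability map is a numeric array
# height x width x m whose per-pixel slices sum to 1.
#
# Coordinate conventions used throughout the package: row-major, 0-based
# pixel indices with the origin at the top-left corner; the centre of
# pixel (i, j) (0-based) sits at continuous coordinates (x, y) =
# (j + 0.5, i + 0.5).  Rectangles are half-open: [x0, x1) x [y0, y1).

#' Class ids and palette for five-class eye masks
#'
#' The canonical label code for ocular segmentation masks: 0 = skin,
#' 1 = pupil, 2 = iris, 3 = sclera, 4 = lacrimal caruncle, with the
#' conventional display palette black, green, red, blue, yellow.
#'
#' @return `eye_classes()` returns a named integer vector of class ids;
#'   `eye_palette()` a 5 x 3 integer matrix of 8-bit RGB rows, one per
#'   class id (row 1 = class 0).
#' @export
eye_classes <- function() {
  c(skin = 0L, pupil = 1L, iris = 2L, sclera = 3L, caruncle = 4L)
}

#' @rdname eye_classes
#' @export
eye_palette <- function() {
  pal <- rbind(
    skin     = c(0L,   0L,   0L),
    pupil    = c(0L,   255L, 0L),
    iris     = c(255L, 0L,   0L),
    sclera   = c(0L,   0L,   255L),
    caruncle = c(255L, 255L, 0L)
  )
  colnames(pal) <- c("r", "g", "b")
  pal
}

## ---- validators -----------------------------------------------------------

validate_mask <- function(mask, m = NULL, arg = "mask") {
  if (!is.matrix(mask) || length(mask) == 0L)
    stop(sprintf("`%s` must be a non-empty integer matrix of class ids", arg))
  if (anyNA(mask) || any(mask < 0) || any(mask != floor(mask)))
    stop(sprintf("`%s` must contain non-negative integer class ids", arg))
  if (!is.null(m) && any(mask >= m))
    stop(sprintf("`%s` contains class id %d but only m = %d classes are declared",
                 arg, max(mask), m))
  invisible(storage.mode(mask) <- "integer")
}

validate_probmap <- function(p, arg = "pred") {
  if (!is.array(p) || length(dim(p)) != 3L)
    stop(sprintf("`%s` must be a height x width x m probability array", arg))
  if (dim(p)[3] < 2L)
    stop(sprintf("`%s` must have m >= 2 class planes", arg))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("`%s` must hold probabilities in [0, 1]", arg))
  sums <- apply(p, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop(sprintf("per-pixel probabilities in `%s` must sum to 1 (max deviation %.3g)",
                 arg, max(abs(sums - 1))))
  invisible(TRUE)
}

check_same_shape <- function(a, b, what = "masks") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(da, db))
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]))
  invisible(TRUE)
}

## run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- palette PNG I/O ------------------------------------------------------

#' Read a five-class eye mask from a palette-coded PNG
#'
#' Decodes a PNG whose pixels use the exact display palette of
#' [eye_palette()] (black, green, red, blue, yellow) into an integer
#' label matrix.  Decoding is exact-match: any pixel whose 8-bit RGB
#' triple is not one of the five palette colors is an error, so label
#' noise in upstream files fails loudly instead of being silently
#' snapped to the nearest class.
#'
#' @param path path to a PNG file.
#' @return integer matrix of class ids (0-4).
#' @seealso [write_mask_png()]
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)            # greyscale: promote to RGB
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  rgb <- round(img[, , 1:3, drop = FALSE] * 255)
  pal <- eye_palette()
  code <- rgb[, , 1] * 65536L + rgb[, , 2] * 256L + rgb[, , 3]
  palcode <- pal[, 1] * 65536L + pal[, 2] * 256L + pal[, 3]
  idx <- match(c(code), palcode)
  if (anyNA(idx)) {
    h <- dim(img)[1]
    lin <- which(is.na(idx))[1]
    bi <- (lin - 1L) %% h + 1L
    bj <- (lin - 1L) %/% h + 1L
    stop(sprintf(
      "unknown palette color RGB(%d,%d,%d) at pixel row %d, column %d (0-based %d,%d)",
      rgb[bi, bj, 1], rgb[bi, bj, 2], rgb[bi, bj, 3],
      bi, bj, bi - 1L, bj - 1L))
  }
  mask <- matrix(as.integer(idx - 1L), nrow = dim(img)[1], ncol = dim(img)[2])
  mask
}

#' Write a five-class eye mask as a palette-coded PNG
#'
#' Inverse of [read_mask_png()]: emits an RGB PNG using the bit-exact
#' palette of [eye_palette()], so `read_mask_png(write_mask_png(x))` is
#' the identity.
#'
#' @param mask integer label matrix with ids in 0-4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask, m = 5L)
  pal <- eye_palette() / 255
  img <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (k in 1:3) img[, , k] <- matrix(pal[mask + 1L, k], nrow(mask), ncol(mask))
  png::writePNG(img, target = path)
  invisible(path)
}

## ---- probability-map container -------------------------------------------

#' Read or write a probability map container
#'
#' A probability map (height x width x m array of per-pixel class
#' probabilities) is stored as a single file holding the named arrays
#' `probs` and `classes` in R's native serialization, the portable
#' numeric-array container used across the package's command-line
#' surface.
#'
#' @param p probability array, height x width x m.
#' @param path file path.
#' @param classes optional integer vector of class ids corresponding to
#'   the third dimension; defaults to `0:(m-1)`.
#' @return `read_probmap()` returns a list with elements `probs` and
#'   `classes`; `write_probmap()` returns `path` invisibly.
#' @export
write_probmap <- function(p, path, classes = NULL) {
  validate_probmap(p)
  if (is.null(classes)) classes <- seq_len(dim(p)[3]) - 1L
  if (length(classes) != dim(p)[3])
    stop("`classes` must have one id per probability plane")
  saveRDS(list(probs = p, classes = as.integer(classes)), file = path)
  invisible(path)
}

#' @rdname write_probmap
#' @export
read_probmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$probs) || is.null(obj$classes))
    stop("not a probability-map container (missing `probs`/`classes`): ", path)
  validate_probmap(obj$probs)
  obj
}

## ---- encoding -------------------------------------------------------------

#' One-hot encode a label mask
#'
#' @param mask integer label matrix.
#' @param m number of classes; every id in `mask` must be `< m`.
#' @return height x width x m probability array with 1 at each pixel's
#'   own class and 0 elsewhere.
#' @export
one_hot <- function(mask, m) {
  validate_mask(mask, m = m)
  h <- nrow(mask); w <- ncol(mask)
  p <- array(0, dim = c(h, w, m))
  idx <- cbind(c(row(mask)), c(col(mask)), c(mask) + 1L)
  p[idx] <- 1
  p
}

#' Hard labels from a probability map
#'
#' Per-pixel argmax over class planes.  Ties are broken deterministically
#' to the lowest class id.
#'
#' @param p probability array, height x width x m.
#' @return integer label matrix.
#' @export
argmax_mask <- function(p) {
  validate_probmap(p)
  h <- dim(p)[1]; w <- dim(p)[2]; m <- dim(p)[3]
  flat <- matrix(p, nrow = h * w, ncol = m)
  matrix(max.col(flat, ties.method = "first") - 1L, nrow = h, ncol = w)
}

## ---- confusion counting ---------------------------------------------------

#' Per-class confusion counts between two label masks
#'
#' @param pred,gt integer label matrices of the same shape.
#' @param m number of classes (default: enough for the largest id seen).
#' @return data frame with one row per class and columns `class`, `tp`,
#'   `fp`, `fn`, `tn`; each row sums to the pixel count.
#' @export
confusion_counts <- function(pred, gt, m = NULL) {
  validate_mask(pred, arg = "pred"); validate_mask(gt, arg = "gt")
  check_same_shape(pred, gt)
  if (is.null(m)) m <- max(pred, gt) + 1L
  validate_mask(pred, m = m, arg = "pred"); validate_mask(gt, m = m, arg = "gt")
  n <- length(gt)
  tab <- table(factor(gt, levels = 0:(m - 1)), factor(pred, levels = 0:(m - 1)))
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  tn <- n - tp - fn - fp
  data.frame(class = 0:(m - 1), tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), tn = as.integer(tn), row.names = NULL)
}

## ---- preprocessing --------------------------------------------------------

#' Expand an eye bounding box by a padding fraction
#'
#' Landmark-derived eye boxes are tight; downstream segmentation wants
#' context, so the box is grown on all four sides by `pad_frac` times the
#' corresponding box side length, then clipped to the image.  Boxes are
#' 0-based half-open rectangles `c(x0, y0, x1, y1)`.
#'
#' @param image_dims `c(width, height)` of the image in pixels.
#' @param box numeric `c(x0, y0, x1, y1)`, half-open, inside the image.
#' @param pad_frac non-negative padding fraction per side (default 0.25).
#' @return expanded, clipped box `c(x0, y0, x1, y1)`.
#' @export
crop_eye <- function(image_dims, box, pad_frac = 0.25) {
  if (length(image_dims) != 2L || any(image_dims <= 0))
    stop("`image_dims` must be positive c(width, height)")
  if (length(box) != 4L) stop("`box` must be c(x0, y0, x1, y1)")
  if (box[3] <= box[1] || box[4] <= box[2]) stop("empty box")
  if (pad_frac < 0) stop("`pad_frac` must be >= 0")
  if (box[1] < 0 || box[2] < 0 || box[3] > image_dims[1] || box[4] > image_dims[2])
    stop("box must lie inside the image")
  wpad <- pad_frac * (box[3] - box[1])
  hpad <- pad_frac * (box[4] - box[2])
  c(max(0, box[1] - wpad), max(0, box[2] - hpad),
    min(image_dims[1], box[3] + wpad), min(image_dims[2], box[4] + hpad))
}

#' Horizontally flip a label mask, swapping the eye-side tag
#'
#' Mirrors the mask left-right (column order reversed) and swaps a
#' `"left"`/`"right"` eye tag, the augmentation used to pool both eyes
#' into one training set.  Involutive: flipping twice is the identity.
#'
#' @param mask integer label matrix.
#' @param side `"left"` or `"right"`.
#' @return list with elements `mask` (flipped) and `side` (swapped).
#' @export
hflip_mask <- function(mask, side = c("left", "right")) {
  validate_mask(mask)
  side <- match.arg(side)
  list(mask = mask[, rev(seq_len(ncol(mask))), drop = FALSE],
       side = if (side == "left") "right" else "left")
}

#' Deterministic train/test split
#'
#' Splits items at a fixed ratio under a seed.  When `group_key` is
#' supplied (e.g. a subject id per item), all items sharing a key land on
#' the same side, preventing subject-level leakage; the default splits by
#' item.
#'
#' @param items vector or list of items.
#' @param ratio train fraction in (0, 1); default 0.8 (a 4:1 split).
#' @param seed integer RNG seed.
#' @param group_key optional vector, one key per item.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(items, ratio = 0.8, seed = 1L, group_key = NULL) {
  n <- length(items)
  if (n == 0L) stop("`items` must be non-empty")
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)")
  if (is.null(group_key)) {
    idx <- with_seed(seed, sample.int(n))
    ntrain <- round(ratio * n)
    train_idx <- sort(idx[seq_len(ntrain)])
  } else {
    if (length(group_key) != n) stop("`group_key` must have one key per item")
    keys <- unique(group_key)
    kidx <- with_seed(seed, sample.int(length(keys)))
    ntrain_k <- round(ratio * length(keys))
    train_keys <- keys[kidx[seq_len(ntrain_k)]]
    train_idx <- which(group_key %in% train_keys)
  }
  list(train = items[train_idx],
       test  = items[setdiff(seq_len(n), train_idx)])
}
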