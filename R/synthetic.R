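# Parametric synthetic eye-mask generator.
#
# The generator draws a five-class eye mask from explicit geometry: the
# palpebral fissure is bounded by two parabolic lid arcs whose maximal
# separation is the aperture; inside it sit a pupil disk concentric
# within an iris disk (shifted horizontally from the fissure centre by
# the gaze offset), a small caruncle wedge at the nasal corner, and
# sclera elsewhere; everything outside the fissure is skin.  Every
# indicator the analysis pipeline measures is also computed here in
# closed form from the same pixel-centre rasterization rules, giving
# analytically known ground truth for closure testing.

#' Synthetic eye geometry
#'
#' Validated parameter bundle for [generate_eye()].  The fissure centre
#' is the iris centre shifted back by `gaze_offset`; the fissure
#' half-width is `lid_curvature * iris_radius` (a dimensionless shape
#' factor: typical adult fissures are 2-2.5 iris radii wide).
#'
#' @param width,height image size in pixels.
#' @param iris_center numeric (x, y) of the iris centre in pixels.
#' @param iris_radius,pupil_radius disk radii in pixels,
#'   `pupil_radius < iris_radius`.
#' @param aperture lid opening at the fissure centre, pixels, `>= 0`.
#' @param lid_curvature fissure half-width as a multiple of the iris
#'   radius.
#' @param gaze_offset signed horizontal shift (px) of the iris from the
#'   fissure centre; negative = shifted toward image left.
#' @param caruncle_side nasal corner holding the caruncle wedge.
#' @param seed integer recorded with the geometry.
#' @return object of class `"eye_geometry"`.
#' @export
eye_geometry <- function(width = 200L, height = 150L,
                         iris_center = c(width / 2, height / 2),
                         iris_radius = 32, pupil_radius = 13,
                         aperture = 48, lid_curvature = 2.2,
                         gaze_offset = 0,
                         caruncle_side = c("left", "right"), seed = 1L) {
  caruncle_side <- match.arg(caruncle_side)
  if (width < 1 || height < 1) stop("image must be at least 1x1")
  if (pupil_radius >= iris_radius) stop("`pupil_radius` must be < `iris_radius`")
  if (pupil_radius <= 0) stop("`pupil_radius` must be > 0")
  if (aperture < 0) stop("`aperture` must be >= 0")
  if (lid_curvature <= 0) stop("`lid_curvature` must be > 0")
  if (iris_center[1] - iris_radius < 0 || iris_center[1] + iris_radius > width ||
      iris_center[2] - iris_radius < 0 || iris_center[2] + iris_radius > height)
    stop("iris disk must lie inside the image")
  structure(list(width = as.integer(width), height = as.integer(height),
                 iris_center = as.numeric(iris_center),
                 iris_radius = iris_radius, pupil_radius = pupil_radius,
                 aperture = aperture, lid_curvature = lid_curvature,
                 gaze_offset = gaze_offset, caruncle_side = caruncle_side,
                 seed = as.integer(seed)),
            class = "eye_geometry")
}

## caruncle wedge width as a fraction of the fissure half-width
CARUNCLE_FRAC <- 0.12

## lid separation at horizontal pixel-centre x; 0 outside the fissure
lid_separation <- function(geom, x) {
  xc <- geom$iris_center[1] - geom$gaze_offset
  W <- geom$lid_curvature * geom$iris_radius
  u <- (x - xc) / W
  ifelse(abs(u) < 1, (geom$aperture / 2) * (1 - u^2), 0)
}

## count of pixel rows with centre strictly inside (ylo, yhi)
rows_inside <- function(ylo, yhi) {
  i_min <- floor(ylo - 0.5 + 1e-9) + 1
  i_max <- ceiling(yhi - 0.5 - 1e-9) - 1
  pmax(0, i_max - i_min + 1)
}

#' Generate a synthetic eye mask with analytic ground truth
#'
#' Rasterizes the geometry at pixel centres (pixel (i, j), 0-based, has
#' centre x = j + 0.5, y = i + 0.5) with label priority
#' pupil > iris > caruncle > sclera inside the fissure and skin outside.
#' The returned ground truth is computed in closed form from the same
#' rasterization rules (pixel counting on the generator's own label
#' functions), so it is consistent with the emitted mask by
#' construction; rasterization leaves at most sub-pixel slack against
#' the continuous geometry.
#'
#' The ground-truth gaze direction is the sign of `gaze_offset`
#' (zero -> `"front"`), and `sclera_gaze_px` counts the gaze-side
#' sclera, split at the iris centre as in [scleral_area()].
#'
#' @param geom an [eye_geometry()].
#' @return list with `mask` (integer label matrix), `truth` (list of
#'   ground-truth indicators: `eyelid_distance_px`, `sclera_left_px`,
#'   `sclera_right_px`, `sclera_gaze_px`, `eye_area_px`,
#'   `sclera_proportion`, `clock_point`, `clock_grade`, `lid_drop_t`,
#'   `gaze`), and `geometry`.
#' @export
generate_eye <- function(geom) {
  if (!inherits(geom, "eye_geometry")) stop("`geom` must be an eye_geometry()")
  h <- geom$height; w <- geom$width
  cls <- eye_classes()
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # pixel-centre coords
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  xc <- geom$iris_center[1] - geom$gaze_offset
  yc <- geom$iris_center[2]
  W <- geom$lid_curvature * geom$iris_radius
  sep <- matrix(lid_separation(geom, x[1, ])[col(x)], h, w)
  fissure <- sep > 0 & y > yc - sep & y < yc + sep
  r2 <- (x - geom$iris_center[1])^2 + (y - yc)^2
  iris <- fissure & r2 <= geom$iris_radius^2
  pupil <- fissure & r2 <= geom$pupil_radius^2
  cw <- CARUNCLE_FRAC * W
  caruncle <- fissure & !iris &
    (if (geom$caruncle_side == "left") x < xc - W + cw else x > xc + W - cw)
  mask <- matrix(cls[["skin"]], h, w)
  mask[fissure] <- cls[["sclera"]]
  mask[caruncle] <- cls[["caruncle"]]
  mask[iris] <- cls[["iris"]]
  mask[pupil] <- cls[["pupil"]]
  storage.mode(mask) <- "integer"

  ## ---- analytic ground truth (mirrors the rasterization rules) ----
  # eyelid distance: max column extent of fissure-minus-caruncle columns
  xs <- seq_len(w) - 0.5
  seps <- lid_separation(geom, xs)
  in_car_band <- if (geom$caruncle_side == "left") xs < xc - W + cw
                 else xs > xc + W - cw
  ext <- rows_inside(yc - seps, yc + seps)
  ext[seps <= 0 | in_car_band] <- 0
  lid_px <- max(ext)

  # sclera split at the iris centre (pixel centre <= cx counts left)
  sclera <- mask == cls[["sclera"]]
  sl <- sum(sclera & x <= geom$iris_center[1])
  sr <- sum(sclera & x > geom$iris_center[1])
  gaze <- if (geom$gaze_offset < 0) "left" else if (geom$gaze_offset > 0) "right"
          else "front"
  sg <- switch(gaze, left = sl, right = sr, front = max(sl, sr))
  eye_area <- sum(mask != cls[["skin"]])
  prop <- if (eye_area == 0) 0 else sg / eye_area

  # clock point: top fissure pixel in the column nearest the iris centre
  if (lid_px == 0 || all(ext == 0)) {
    tt <- 1
  } else {
    open_cols <- which(ext > 0)
    jn <- open_cols[which.min(abs(xs[open_cols] - geom$iris_center[1]))]
    ylo <- yc - seps[jn]
    h_top <- (floor(ylo - 0.5 + 1e-9) + 1) + 0.5     # centre y of top row
    tt <- (h_top - (yc - geom$iris_radius)) / (2 * geom$iris_radius)
    tt <- min(max(tt, 0), 1)
  }
  ck <- clock_from_drop(tt)

  list(mask = mask,
       truth = list(eyelid_distance_px = as.integer(lid_px),
                    sclera_left_px = sl, sclera_right_px = sr,
                    sclera_gaze_px = sg, eye_area_px = eye_area,
                    sclera_proportion = prop,
                    clock_point = ck$clock_point, clock_grade = ck$clock_grade,
                    lid_drop_t = tt, gaze = gaze),
       geometry = geom)
}

#' Corrupt a mask into an imperfect probability map
#'
#' Emulates imperfect network output: pixels on class boundaries are
#' replaced by the label of a uniformly random pixel within `jitter_px`
#' (Chebyshev) of their location, then the one-hot encoding is blended
#' with the uniform distribution: `p = (1 - softness) * onehot +
#' softness / m`.  With `jitter_px = 0` and `softness = 0` the result is
#' the exact one-hot of the input.
#'
#' @param mask integer label matrix.
#' @param jitter_px maximum boundary displacement in pixels, `>= 0`.
#' @param softness uniform-blend weight in `[0, 1)`.
#' @param seed RNG seed.
#' @param m number of classes (default 5).
#' @return probability array height x width x m.
#' @export
corrupt_prediction <- function(mask, jitter_px = 0, softness = 0, seed = 1L,
                               m = 5L) {
  validate_mask(mask, m = m)
  if (jitter_px < 0) stop("`jitter_px` must be >= 0")
  if (softness < 0 || softness >= 1) stop("`softness` must be in [0, 1)")
  lab <- mask
  if (jitter_px > 0) {
    bnd <- which(region_boundary_multi(mask), arr.ind = TRUE)
    if (nrow(bnd) > 0) {
      off <- with_seed(seed, matrix(sample(seq(-jitter_px, jitter_px),
                                           2L * nrow(bnd), replace = TRUE),
                                    ncol = 2))
      ri <- pmin(pmax(bnd[, 1] + off[, 1], 1L), nrow(mask))
      ci <- pmin(pmax(bnd[, 2] + off[, 2], 1L), ncol(mask))
      lab[bnd] <- mask[cbind(ri, ci)]
    }
  }
  p <- one_hot(lab, m)
  (1 - softness) * p + softness / m
}

## pixels with a 4-neighbour of a different class (shared with
## boundary_band, but returning the logical matrix for index use)
region_boundary_multi <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bnd <- matrix(FALSE, h, w)
  if (h > 1) {
    dv <- mask[-1, , drop = FALSE] != mask[-h, , drop = FALSE]
    bnd[-h, ] <- bnd[-h, ] | dv; bnd[-1, ] <- bnd[-1, ] | dv
  }
  if (w > 1) {
    dh <- mask[, -1, drop = FALSE] != mask[, -w, drop = FALSE]
    bnd[, -w] <- bnd[, -w] | dh; bnd[, -1] <- bnd[, -1] | dh
  }
  bnd
}

## draw one random eye geometry; `offset_frac_range` positions the iris
## between the fissure centre (0) and the fissure end (1) on the gaze side
sample_geometry <- function(gaze_side, offset_frac_range, caruncle_side) {
  r_i <- stats::runif(1, 26, 36)
  geom_try <- function() {
    curv <- stats::runif(1, 2.0, 2.5)
    W <- curv * r_i
    frac <- stats::runif(1, offset_frac_range[1], offset_frac_range[2])
    off <- frac * (W - r_i) * (if (gaze_side == "left") -1 else 1)
    eye_geometry(
      width = 200L, height = 150L,
      iris_center = c(100 + off, 75),
      iris_radius = r_i,
      pupil_radius = stats::runif(1, 0.32, 0.45) * r_i,
      aperture = stats::runif(1, 1.1, 1.6) * r_i,
      lid_curvature = curv,
      gaze_offset = off,
      caruncle_side = caruncle_side,
      seed = sample.int(.Machine$integer.max %/% 2L, 1L))
  }
  geom_try()
}

#' Generate a synthetic two-eye cohort with known phenotype
#'
#' Each subject contributes a left-eye and a right-eye mask captured at
#' left gaze.  Normal subjects have the iris shifted far toward the gaze
#' side (the eye adducts fully), leaving a gaze-side scleral proportion
#' below 0.025 in both eyes; OMG subjects have the iris near the fissure
#' centre (impaired movement), leaving a proportion of at least 0.035.
#' Both phenotypes keep a 0.005 margin off the 0.03 decision threshold
#' so that pixel-level measurement noise cannot flip a noise-free call.
#' Geometries are rejection-sampled against the analytic ground truth
#' until the phenotype constraint holds, so labels are correct by
#' construction.  Deterministic per seed.
#'
#' @param n number of subjects, `>= 1`.
#' @param phenotype `"normal"` or `"omg"`.
#' @param seed RNG seed.
#' @return list of `n` subjects, each a list with `left`, `right`
#'   (outputs of [generate_eye()]), `label` and `gaze`.
#' @export
generate_cohort <- function(n, phenotype = c("normal", "omg"), seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (n < 1) stop("`n` must be >= 1")
  target <- if (phenotype == "normal") c(0, 0.025) else c(0.035, 1)
  range0 <- if (phenotype == "normal") c(0.80, 0.98) else c(0.0, 0.25)
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      draw_eye <- function(caruncle_side) {
        for (try in 1:500) {
          g <- sample_geometry("left", range0, caruncle_side)
          eye <- generate_eye(g)
          pr <- eye$truth$sclera_proportion
          if (pr >= target[1] && pr < target[2]) return(eye)
        }
        stop("could not sample a ", phenotype, "-phenotype eye in 500 tries")
      }
      # caruncle on the nasal side: image-right for the left eye,
      # image-left for the right eye
      list(left = draw_eye("right"), right = draw_eye("left"),
           label = if (phenotype == "normal") "normal" else "OMG",
           gaze = "left")
    })
  })
}
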