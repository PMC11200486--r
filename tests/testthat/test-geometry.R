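test_that("fit_ellipse recovers exact conic samples to 1e-6", {
  pts <- ellipse_points(50, 40, 10, 10, 0)
  e <- fit_ellipse(pts)
  expect_equal(unname(e$center), c(50, 40), tolerance = 1e-6)
  expect_equal(unname(e$semi_axes), c(10, 10), tolerance = 1e-6)

  e2 <- fit_ellipse(ellipse_points(30, 20, 12, 7, 0.5))
  expect_equal(unname(e2$center), c(30, 20), tolerance = 1e-6)
  expect_equal(unname(e2$semi_axes), c(12, 7), tolerance = 1e-6)
  expect_equal(e2$angle, 0.5, tolerance = 1e-6)

  expect_error(fit_ellipse(ellipse_points(0, 0, 5, 3, 0, n = 4)), "at least 5")
  colin <- cbind(1:6, 2 * (1:6) + 1)
  expect_error(fit_ellipse(colin), "degenerate|no ellipse")
})

test_that("regularize_mask is near-idempotent on elliptical regions and robust to rim noise", {
  eye <- generate_eye(eye_geometry())
  reg <- regularize_mask(eye$mask)
  # already-elliptical pupil/iris: re-rasterization moves only rim pixels
  expect_lt(mean(reg != eye$mask), 0.02)
  for (cls in 1:2)
    expect_lt(abs(sum(reg == cls) - sum(eye$mask == cls)) /
                sum(eye$mask == cls), 0.02)

  # salt noise on 10% of the pupil rim: recovered area within 5%
  set.seed(301)
  msk <- matrix(2L, 80, 80)
  cx <- 40; cy <- 40
  xs <- col(msk) - 0.5; ys <- row(msk) - 0.5
  inside <- ((xs - cx) / 15)^2 + ((ys - cy) / 10)^2 <= 1
  msk[inside] <- 1L
  area0 <- sum(inside)
  noisy <- msk
  rim <- which(inside &
                 (((xs - cx) / 15)^2 + ((ys - cy) / 10)^2 > 0.8))
  flip <- sample(rim, round(0.1 * length(rim)))
  noisy[flip] <- 2L
  regn <- regularize_mask(noisy)
  expect_lt(abs(sum(regn == 1L) - area0) / area0, 0.05)

  # masks without pupil or iris pass through unchanged
  skin <- matrix(0L, 10, 10)
  expect_identical(regularize_mask(skin), skin)
})

test_that("eyelid_distance measures the tallest fissure column", {
  expect_equal(eyelid_distance(matrix(0L, 12, 12))$distance_px, 0L)

  rect <- matrix(0L, 20, 20)
  rect[6:15, 4:16] <- 3L               # 10-row sclera rectangle
  ld <- eyelid_distance(rect)
  expect_equal(ld$distance_px, 10L)

  # caruncle does not count toward the fissure
  rect2 <- rect; rect2[2:17, 10] <- 4L
  expect_equal(eyelid_distance(rect2)$distance_px, 10L)

  set.seed(302)
  for (k in 1:10) {
    eye <- generate_eye(random_eye_geometry())
    got <- eyelid_distance(eye$mask)$distance_px
    expect_lte(abs(got - eye$truth$eyelid_distance_px), 1)
  }
})

test_that("clock_from_drop maps hour-line thresholds with less-severe ties", {
  expect_equal(clock_from_drop(0), list(clock_point = "12", clock_grade = 0L))
  expect_equal(clock_from_drop(1), list(clock_point = "6", clock_grade = 4L))
  # exact centre coverage is the less severe band
  expect_equal(clock_from_drop(0.5),
               list(clock_point = "10-2", clock_grade = 1L))
  expect_equal(clock_from_drop(0.5 + 1e-9),
               list(clock_point = "9-3", clock_grade = 2L))
  th1 <- (1 - cos(pi / 6)) / 2
  expect_equal(clock_from_drop(th1)$clock_point, "12")
  expect_equal(clock_from_drop(th1 + 1e-9)$clock_point, "11-1")
  # grade is monotone non-decreasing in t
  ts <- seq(0, 1, by = 0.001)
  gr <- vapply(ts, function(t) clock_from_drop(t)$clock_grade, integer(1))
  expect_true(all(diff(gr) >= 0))
})

test_that("clock_point handles empty fissures as complete ptosis", {
  ck <- clock_point(matrix(0L, 8, 8), NULL)
  expect_equal(ck$clock_point, "6")
  expect_equal(ck$clock_grade, 4L)
})

test_that("scleral_area splits at the iris centre and normalizes by eye area", {
  none <- matrix(0L, 10, 10)
  expect_equal(scleral_area(none, NULL)$sclera_proportion, 0)

  # 50 sclera px left of centre, 950 iris px, eye area 1000
  msk <- matrix(0L, 20, 50)
  msk[, ] <- 0L
  msk[1:20, 1:50] <- 2L                      # 1000 iris
  msk[1:10, 1:5] <- 3L                       # 50 sclera, all left of x = 25
  iris <- structure(list(center = c(x = 25, y = 10),
                         semi_axes = c(a = 10, b = 10), angle = 0),
                    class = "ellipse_params")
  sa <- scleral_area(msk, iris, gaze = "left")
  expect_equal(sa$sclera_left_px, 50)
  expect_equal(sa$sclera_right_px, 0)
  expect_equal(sa$eye_area_px, 1000)
  expect_equal(sa$sclera_proportion, 0.05)

  # gaze-side proportion grows with the residual offset from full gaze
  # (flat at zero while the iris still hides the whole gaze-side sclera)
  props <- sapply(seq(0, 40, by = 10), function(g) {
    geom <- eye_geometry(iris_center = c(100 - 40 + g, 75), gaze_offset = -(40 - g))
    eye <- generate_eye(geom)
    compute_indicators(eye$mask, gaze = "left")$sclera_proportion
  })
  expect_true(all(diff(props) >= 0))
  expect_gt(props[5], props[1])
})

test_that("compute_indicators degrades gracefully and is flip-equivariant", {
  closed <- compute_indicators(matrix(0L, 30, 30))
  expect_equal(closed$eyelid_distance_px, 0L)
  expect_equal(closed$clock_point, "6")
  expect_equal(closed$clock_grade, 4L)
  expect_equal(closed$sclera_proportion, 0)

  set.seed(304)
  for (k in 1:5) {
    eye <- generate_eye(random_eye_geometry())
    a <- compute_indicators(eye$mask, gaze = "left")
    b <- compute_indicators(hflip_mask(eye$mask, "left")$mask, gaze = "right")
    expect_equal(a$eyelid_distance_px, b$eyelid_distance_px)
    expect_equal(a$clock_grade, b$clock_grade)
    expect_equal(a$sclera_left_px, b$sclera_right_px)
    expect_equal(a$sclera_right_px, b$sclera_left_px)
    expect_equal(a$sclera_proportion, b$sclera_proportion, tolerance = 1e-12)
  }
})
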