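test_that("generate_eye rasterizes all five classes with containment", {
  eye <- generate_eye(eye_geometry())
  expect_setequal(sort(unique(c(eye$mask))), 0:4)
  cls <- eye_classes()
  # pupil inside iris disk inside fissure: no pupil pixel touches sclera
  pup <- eye$mask == cls[["pupil"]]
  iri <- eye$mask == cls[["iris"]]
  fis <- pup | iri | eye$mask == cls[["sclera"]]
  expect_true(all(fis[pup]))
  # every pupil pixel's 4-neighbours are pupil or iris
  idx <- which(pup, arr.ind = TRUE)
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- cbind(idx[, 1] + s[1], idx[, 2] + s[2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(pup) & nb[, 2] >= 1 & nb[, 2] <= ncol(pup)
    expect_true(all(pup[nb[ok, , drop = FALSE]] | iri[nb[ok, , drop = FALSE]]))
  }

  # closed eye: all skin, degenerate indicators
  shut <- generate_eye(eye_geometry(aperture = 0))
  expect_true(all(shut$mask == 0L))
  expect_equal(shut$truth$eyelid_distance_px, 0L)
  expect_equal(shut$truth$clock_grade, 4L)
  expect_equal(shut$truth$sclera_proportion, 0)

  # deterministic
  expect_identical(generate_eye(eye_geometry())$mask, eye$mask)
  expect_error(eye_geometry(pupil_radius = 40, iris_radius = 30), "pupil_radius")
})

test_that("corrupt_prediction blends and jitters as specified", {
  eye <- generate_eye(eye_geometry())
  p0 <- corrupt_prediction(eye$mask, 0, 0)
  expect_identical(argmax_mask(p0), eye$mask)
  expect_equal(range(p0), c(0, 1))

  p5 <- corrupt_prediction(eye$mask, 0, 0.5)
  expect_equal(max(p5), 0.5 + 0.5 / 5, tolerance = 1e-12)
  expect_equal(min(p5), 0.1, tolerance = 1e-12)

  # same seed -> same corruption; jitter degrades boundary quality monotonically
  expect_identical(corrupt_prediction(eye$mask, 2, 0.2, seed = 9),
                   corrupt_prediction(eye$mask, 2, 0.2, seed = 9))
  mb <- sapply(c(0, 1, 2, 4), function(j)
    mbiou(argmax_mask(corrupt_prediction(eye$mask, j, 0, seed = 5)),
          eye$mask, d = 4))
  expect_true(all(diff(mb) <= 1e-12))
})

test_that("generator closure: analyzer recovers analytic ground truth", {
  set.seed(401)
  n <- 40
  ok_lid <- ok_prop <- ok_clock <- 0
  for (k in seq_len(n)) {
    eye <- generate_eye(random_eye_geometry())
    ind <- compute_indicators(eye$mask, gaze = eye$truth$gaze)
    ok_lid <- ok_lid +
      (abs(ind$eyelid_distance_px - eye$truth$eyelid_distance_px) <= 1)
    ok_prop <- ok_prop +
      (abs(ind$sclera_proportion - eye$truth$sclera_proportion) <= 0.01)
    ok_clock <- ok_clock + (ind$clock_grade == eye$truth$clock_grade)
  }
  expect_gte(ok_lid / n, 0.95)
  expect_gte(ok_prop / n, 0.95)
  expect_gte(ok_clock / n, 0.95)
})

test_that("cohorts respect their phenotype margins and are seed-stable", {
  co_n <- generate_cohort(4, "normal", seed = 11)
  co_o <- generate_cohort(4, "omg", seed = 12)
  for (s in co_n) for (side in c("left", "right"))
    expect_lt(s[[side]]$truth$sclera_proportion, 0.03)
  for (s in co_o) for (side in c("left", "right"))
    expect_gte(s[[side]]$truth$sclera_proportion, 0.035)
  expect_equal(unique(sapply(co_n, `[[`, "label")), "normal")
  expect_equal(unique(sapply(co_o, `[[`, "label")), "OMG")
  again <- generate_cohort(4, "normal", seed = 11)
  expect_identical(lapply(again, function(s) s$left$mask),
                   lapply(co_n, function(s) s$left$mask))
})
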