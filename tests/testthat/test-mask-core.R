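test_that("palette PNG round-trip is the identity and the palette is exact", {
  tf <- withr::local_tempfile(fileext = ".png")

  mask <- matrix(1L, 2, 2)            # all pupil -> all green
  write_mask_png(mask, tf)
  img <- png::readPNG(tf)
  expect_equal(unique(round(c(img[, , 1]) * 255)), 0)
  expect_equal(unique(round(c(img[, , 2]) * 255)), 255)
  expect_identical(read_mask_png(tf), mask)

  mask5 <- matrix(0:4, 5, 4)          # every class present
  write_mask_png(mask5, tf)
  img <- png::readPNG(tf)
  cols <- unique(apply(round(img * 255), c(1, 2), paste, collapse = ","))
  expect_length(unique(c(cols)), 5)

  set.seed(11)
  for (k in 1:100) {
    msk <- random_mask(sample(1:9, 1), sample(1:9, 1), 5)
    write_mask_png(msk, tf)
    expect_identical(read_mask_png(tf), msk)
  }
})

test_that("unknown palette colors are rejected with pixel location", {
  tf <- withr::local_tempfile(fileext = ".png")
  img <- array(0, dim = c(2, 2, 3))
  img[1, 2, ] <- 128 / 255            # grey pixel
  png::writePNG(img, tf)
  expect_error(read_mask_png(tf), "RGB\\(128,128,128\\).*row 1, column 2")
})

test_that("one_hot and argmax_mask are mutually inverse with low-id ties", {
  set.seed(21)
  for (m in c(2L, 3L, 5L)) {
    msk <- random_mask(6, 7, m)
    p <- one_hot(msk, m)
    expect_equal(apply(p, c(1, 2), sum), matrix(1, 6, 7))
    expect_identical(argmax_mask(p), msk)
  }
  expect_equal(one_hot(matrix(3L, 1, 1), 5)[1, 1, ], c(0, 0, 0, 1, 0))
  expect_error(one_hot(matrix(4L, 1, 1), 2), "class id 4")
  # exact tie resolves to the lowest class id
  tie <- array(0.5, dim = c(1, 1, 2))
  expect_identical(argmax_mask(tie)[1, 1], 0L)
  pix <- array(c(0.1, 0.7, 0.2, 0, 0), dim = c(1, 1, 5))
  expect_identical(argmax_mask(pix)[1, 1], 1L)
})

test_that("confusion_counts matches the exhaustive loop oracle", {
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "mismatched shapes")
  gt <- matrix(0L, 4, 4); pr <- matrix(1L, 4, 4)
  cc <- confusion_counts(pr, gt, m = 2)
  expect_equal(cc$tp, c(0L, 0L)); expect_equal(cc$fn[1], 16L)
  expect_equal(cc$fp[2], 16L)

  set.seed(31)
  for (k in 1:10) {
    gt <- random_mask(8, 8, 5); pr <- random_mask(8, 8, 5)
    got <- confusion_counts(pr, gt, m = 5)
    expect_equal(got, oracle_confusion(pr, gt, 5))
    expect_equal(sum(got$tp + got$fn), 64L)
    expect_equal(sum(got$tp + got$fp), 64L)
    expect_true(all(got$tp + got$fp + got$fn + got$tn == 64L))
  }
  gt <- random_mask(4, 4, 3)
  expect_true(all(confusion_counts(gt, gt, m = 3)[, c("fp", "fn")] == 0L))
})

test_that("crop_eye pads per side and clips to the image", {
  expect_equal(crop_eye(c(100, 100), c(10, 10, 20, 20), 0),
               c(10, 10, 20, 20))
  expect_equal(crop_eye(c(100, 100), c(10, 10, 20, 20), 0.5),
               c(5, 5, 25, 25))
  expect_equal(crop_eye(c(30, 30), c(0, 0, 10, 10), 0.5),
               c(0, 0, 15, 15))
  expect_error(crop_eye(c(100, 100), c(10, 10, 10, 20)), "empty box")
})

test_that("hflip_mask mirrors columns, swaps the side tag, and is involutive", {
  msk <- matrix(c(0L, 1L, 2L, 3L, 4L, 0L), 2, 3)
  f <- hflip_mask(msk, "left")
  expect_equal(f$side, "right")
  for (i in 1:2) for (j in 1:3)
    expect_identical(f$mask[i, j], msk[i, 4 - j])
  back <- hflip_mask(f$mask, f$side)
  expect_identical(back$mask, msk)
  expect_equal(back$side, "left")
})

test_that("split_dataset is seeded, ratio-correct and group-aware", {
  sp <- split_dataset(1:10, ratio = 0.8, seed = 5)
  expect_length(sp$train, 8); expect_length(sp$test, 2)
  expect_identical(sp, split_dataset(1:10, ratio = 0.8, seed = 5))
  expect_setequal(c(sp$train, sp$test), 1:10)

  subj <- rep(1:5, each = 4)
  for (s in 1:5) {
    gsp <- split_dataset(seq_along(subj), ratio = 0.6, seed = s,
                         group_key = subj)
    straddle <- intersect(unique(subj[gsp$train]), unique(subj[gsp$test]))
    expect_length(straddle, 0)
  }
})

test_that("probability-map container round-trips", {
  tf <- withr::local_tempfile(fileext = ".rds")
  set.seed(41)
  p <- random_probmap(4, 5, 3)
  write_probmap(p, tf)
  got <- read_probmap(tf)
  expect_equal(got$probs, p)
  expect_identical(got$classes, 0:2)
})
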