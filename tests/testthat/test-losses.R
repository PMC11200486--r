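test_that("ce_loss: perfect prediction, uniform closed form, loop oracle", {
  set.seed(101)
  gt <- random_mask(4, 4, 5)
  expect_equal(ce_loss(one_hot(gt, 5), gt), 0)
  unif <- array(0.2, dim = c(4, 4, 5))
  expect_equal(ce_loss(unif, gt), log(5), tolerance = 1e-12)
  for (k in 1:5) {
    gt <- random_mask(2, 2, 3); p <- random_probmap(2, 2, 3)
    expect_equal(ce_loss(p, gt), oracle_ce(p, gt), tolerance = 1e-6)
  }
  expect_error(ce_loss(random_probmap(2, 2, 3), random_mask(3, 3, 3)),
               "mismatched shapes")
})

test_that("wce_loss reduces to ce_loss at unit weights and matches the oracle", {
  set.seed(102)
  gt <- random_mask(3, 3, 4); p <- random_probmap(3, 3, 4)
  expect_equal(wce_loss(p, gt, rep(1, 4)), ce_loss(p, gt))
  # zero weight silences a class
  w0 <- c(0, 1, 1, 1)
  gt0 <- matrix(0L, 3, 3)
  expect_equal(wce_loss(random_probmap(3, 3, 4), gt0, w0), 0)
  for (k in 1:5) {
    gt <- random_mask(2, 2, 2); p <- random_probmap(2, 2, 2); w <- c(1, 2)
    expect_equal(wce_loss(p, gt, w), oracle_wce(p, gt, w), tolerance = 1e-6)
  }
  expect_error(wce_loss(random_probmap(3, 3, 4), random_mask(3, 3, 4), c(1, 2)),
               "length")
})

test_that("inverse-frequency weights have mean 1 and zero absent classes", {
  gt <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  w <- inverse_freq_weights(gt, 3)
  expect_equal(mean(w), 1)
  expect_equal(w[3], 0)
  expect_gt(w[2], w[1])
})

test_that("iou and dice losses: identities, complement case, oracle, ordering", {
  set.seed(103)
  gt <- random_mask(4, 4, 5)
  expect_equal(iou_loss(one_hot(gt, 5), gt), 0)
  expect_equal(dice_loss(one_hot(gt, 5), gt), 0)
  # exact complement with both classes present
  gt2 <- matrix(c(0L, 1L), 4, 4)
  expect_equal(iou_loss(one_hot(1L - gt2, 2), gt2), 1)
  expect_equal(dice_loss(one_hot(1L - gt2, 2), gt2), 1)
  for (k in 1:10) {
    gt <- random_mask(4, 4, 3); p <- random_probmap(4, 4, 3)
    li <- iou_loss(p, gt); ld <- dice_loss(p, gt)
    expect_equal(li, oracle_overlap(p, gt, "iou"), tolerance = 1e-6)
    expect_equal(ld, oracle_overlap(p, gt, "dice"), tolerance = 1e-6)
    expect_lte(ld, li + 1e-12)
  }
})

test_that("empty classes incur no loss", {
  # m = 5 but only classes 0/1 occur anywhere
  gt <- matrix(c(0L, 1L), 2, 2)
  p <- one_hot(gt, 5)
  expect_equal(iou_loss(p, gt), 0)
  expect_equal(dice_loss(p, gt), 0)
})

test_that("boundary_band matches the exhaustive distance oracle", {
  expect_false(any(boundary_band(matrix(2L, 6, 6), 3)))
  # two-class 8x8 split saturates at large d
  split8 <- cbind(matrix(0L, 8, 4), matrix(1L, 8, 4))
  expect_true(all(boundary_band(split8, 12)))
  expect_equal(boundary_band(split8, 1), oracle_band(split8, 1))
  set.seed(104)
  for (k in 1:8) {
    msk <- random_mask(8, 8, 3)
    for (d in c(1, 2)) expect_equal(boundary_band(msk, d), oracle_band(msk, d))
  }
})

test_that("boundary_loss: zero at perfect prediction, oracle, swap symmetry", {
  set.seed(105)
  gt <- random_mask(8, 8, 5)
  expect_equal(boundary_loss(one_hot(gt, 5), gt, 2), 0)
  for (k in 1:5) {
    gt <- random_mask(8, 8, 3); p <- random_probmap(8, 8, 3)
    expect_equal(boundary_loss(p, gt, 2), oracle_boundary_loss(p, gt, 2),
                 tolerance = 1e-6)
  }
  for (k in 1:10) {
    a <- random_mask(8, 8, 4); b <- random_mask(8, 8, 4)
    expect_equal(boundary_loss(one_hot(a, 4), b, 2),
                 boundary_loss(one_hot(b, 4), a, 2), tolerance = 1e-12)
  }
})

test_that("boundary_loss with saturated band equals iou_loss on that class set", {
  set.seed(106)
  for (k in 1:5) {
    gt <- random_mask(8, 8, 5); p <- random_probmap(8, 8, 5)
    expect_equal(boundary_loss(p, gt, 12), iou_loss(p, gt, class_set = 1:4),
                 tolerance = 1e-12)
  }
})

test_that("gamma_schedule ramps linearly from 0 to gamma_max", {
  expect_equal(gamma_schedule(0, 150), 0)
  expect_equal(gamma_schedule(149, 150), 1)
  expect_equal(gamma_schedule(75, 150), 75 / 149)
  expect_equal(gamma_schedule(0, 1, gamma_max = 0.7), 0.7)
  expect_error(gamma_schedule(150, 150), "epoch")
})

test_that("hybrid_loss assembles its terms additively", {
  set.seed(107)
  gt <- random_mask(8, 8, 5); p <- random_probmap(8, 8, 5)
  # gamma 0, no local term: pure CE
  cfg0 <- hybrid_config(beta = 0, gamma_max = 0, local_term = "none",
                        total_epochs = 10)
  expect_equal(hybrid_loss(p, gt, cfg0, 0), ce_loss(p, gt))
  # all three at the final epoch
  cfg <- hybrid_config(local_term = "dice", total_epochs = 10, d = 2)
  expect_equal(hybrid_loss(p, gt, cfg, 9),
               ce_loss(p, gt) + dice_loss(p, gt) + boundary_loss(p, gt, 2))
  # the CE + IoU + Boundary composition is constructible
  cfg2 <- hybrid_config(global_term = "ce", local_term = "iou",
                        total_epochs = 80)
  expect_s3_class(cfg2, "hybrid_loss_config")
  expect_equal(cfg2$alpha, 1); expect_equal(cfg2$beta, 1)
  expect_error(hybrid_config(beta = 1, local_term = "none"), "beta")
})

test_that("losses are finite, non-negative and zero only on agreement", {
  set.seed(108)
  for (k in 1:20) {
    m <- sample(c(2, 3, 5), 1)
    gt <- random_mask(8, 8, m); p <- random_probmap(8, 8, m)
    vals <- c(ce_loss(p, gt), wce_loss(p, gt), iou_loss(p, gt),
              dice_loss(p, gt), boundary_loss(p, gt, 2))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})
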