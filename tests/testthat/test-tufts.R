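test_that("consensus is a per-pixel majority vote", {
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  expect_identical(consensus_mask(rep(list(m), 6), quorum = 4), m)

  # boundary of "at least four": 3 votes out, 4 votes in
  votes3 <- c(rep(list(m), 3), rep(list(matrix(FALSE, 10, 10)), 3))
  votes4 <- c(rep(list(m), 4), rep(list(matrix(FALSE, 10, 10)), 2))
  expect_false(any(consensus_mask(votes3, 4)))
  expect_identical(consensus_mask(votes4, 4), m)

  # random masks against a per-pixel counting oracle
  masks <- withr::with_seed(4, lapply(1:6, function(i)
    matrix(runif(100) > 0.5, 10, 10)))
  cons <- consensus_mask(masks, quorum = 4)
  counts <- Reduce(`+`, lapply(masks, `*`, 1L))
  expect_identical(cons, counts >= 4L)

  # raising the quorum never adds pixels
  for (q in 2:6)
    expect_true(all(consensus_mask(masks, q) <= consensus_mask(masks, q - 1)))

  expect_error(consensus_mask(list(m, matrix(FALSE, 9, 10))), "shape")
  expect_error(consensus_mask(list(m), quorum = 2), "quorum")
})

test_that("training labels follow the strict 25% consensus rule", {
  dims <- c(20, 20)
  tiles <- manual_tiles(row0 = c(0, 0, 8), col0 = c(0, 8, 0), side = 8,
                        label = NA, image_dim = dims)
  cons <- matrix(FALSE, 20, 20)
  cons[1:8, 1:8] <- TRUE                   # tile 1 fully inside
  cons[1:2, 9:16] <- TRUE                  # tile 2: exactly 25% of 64 px
  cons[9:16, 1:8] <- matrix(c(TRUE, FALSE), 8, 8)  # tile 3: checkerboard 50%
  lab <- label_training_tiles(tiles, cons, min_frac = 0.25)
  expect_equal(as.character(lab$label), c("tuft", "normal", "tuft"))
})

test_that("prediction applies the classifier inside the ROI only", {
  dims <- c(30, 30)
  tiles <- manual_tiles(row0 = c(0, 10, 20), col0 = c(0, 0, 0), side = 10,
                        label = NA, inside_roi = c(TRUE, TRUE, FALSE),
                        image_dim = dims)
  # make tile features coincide with a separable training design
  tiles[1, c("I_loc", "I_g", "I_LoG", "LBP0", "LBP9")] <- c(2, 0.9, 0.8, 0.1, 0.6)
  tiles[2, c("I_loc", "I_g", "I_LoG", "LBP0", "LBP9")] <- c(1, 0.2, 0.05, 0.9, 0.02)
  tiles[3, c("I_loc", "I_g", "I_LoG", "LBP0", "LBP9")] <- c(2, 0.9, 0.8, 0.1, 0.6)
  withr::with_seed(2, {
    xt <- matrix(rnorm(5 * 30, mean = rep(c(2, 0.9, 0.8, 0.1, 0.6), each = 30),
                       sd = 0.05), 30, 5)
    xn <- matrix(rnorm(5 * 30, mean = rep(c(1, 0.2, 0.05, 0.9, 0.02), each = 30),
                       sd = 0.05), 30, 5)
  })
  model <- qda_fit(rbind(xt, xn), rep(c("tuft", "normal"), each = 30),
                   cov_mode = "per_class")
  pred <- predict_tuft_tiles(model, tiles)
  expect_equal(as.character(pred$label), c("tuft", "normal", "normal"))
})

test_that("thickness validation keeps solid tufts and drops thin vessels", {
  n <- 40
  img <- matrix(0.1, n, n)
  img[1:20, ] <- 0.9                        # solid bright block (tuft-like)
  img[31, ] <- 0.9                          # thin bright line (vessel-like)
  bg <- flat_background(c(n, n), I_b = 0.3, sigma_b = 0)
  g <- geom_from_mask(matrix(TRUE, n, n), phi = 1000)  # neighbourhood 10 px
  tiles <- manual_tiles(row0 = c(5, 25), col0 = c(10, 10), side = 10,
                        label = "tuft", image_dim = c(n, n))
  res <- validate_tufts(tiles, img, bg, g)
  # tuft tile interior: neighbourhood fraction 1 > 0.8, kept
  expect_true(all(res$validated_mask[8:14, 12:18]))
  # vessel tile: the line covers ~10% of each neighbourhood, removed
  expect_equal(sum(res$validated_mask[26:35, 11:20]), 0)
  expect_equal(res$tuft_area_px, sum(res$validated_mask))
  expect_true(all(res$validated_mask <= res$qda_mask))
})

test_that("validation is strict at the 80% boundary and monotone", {
  n <- 20
  g <- geom_from_mask(matrix(TRUE, n, n), phi = 500)  # neighbourhood 5 px
  bg <- flat_background(c(n, n), I_b = 0.5)
  img <- matrix(0, n, n)
  img[, 1:16] <- 1                     # columns 1..16 above threshold
  tiles <- manual_tiles(row0 = 5, col0 = 10, side = 10, label = "tuft",
                        image_dim = c(n, n))
  res <- validate_tufts(tiles, img, bg, g, min_above_frac = 0.80)
  # at column 15 the 5x5 neighbourhood holds exactly 20/25 above pixels:
  # fraction 0.80 does not strictly exceed 0.80 -> removed
  expect_false(res$validated_mask[8, 15])
  # at column 13 the whole neighbourhood is above -> kept
  expect_true(res$validated_mask[8, 13])
  # raising the threshold never adds pixels
  lo <- validate_tufts(tiles, img, bg, g, min_above_frac = 0.5)
  hi <- validate_tufts(tiles, img, bg, g, min_above_frac = 0.9)
  expect_true(all(hi$validated_mask <= lo$validated_mask))
})

test_that("segmentation error counts false pixels relative to truth", {
  truth <- matrix(FALSE, 30, 30); truth[11:20, 11:20] <- TRUE
  same <- segmentation_error(truth, truth)
  expect_equal(c(same$false_pos_px, same$false_neg_px,
                 same$relative_error_pct), c(0, 0, 0))
  none <- segmentation_error(matrix(FALSE, 30, 30), truth)
  expect_equal(none$false_neg_px, 100)
  expect_equal(none$relative_error_pct, 100)
  # predicted = truth plus 50 extra pixels -> FP/T = 50%
  pred <- truth; pred[1:5, 1:10] <- TRUE
  expect_equal(segmentation_error(pred, truth)$relative_error_pct, 50)
  empty <- segmentation_error(pred, matrix(FALSE, 30, 30))
  expect_true(empty$empty_truth)
  expect_true(is.na(empty$relative_error_pct))
  expect_error(segmentation_error(truth, matrix(FALSE, 2, 2)), "shape")
})
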