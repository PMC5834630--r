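test_that("Bradley thresholding matches the naive oracle bit for bit", {
  for (seed in 1:3) {
    img <- seeded_image(64, seed)
    for (w in c(3L, 5L, 8L, 15L)) {
      expect_identical(bradley_threshold(img, w, 1),
                       naive_bradley(img, w, 1))
      expect_identical(bradley_threshold(img, w, 1.15),
                       naive_bradley(img, w, 1.15))
    }
  }
})

test_that("Bradley picks out a bright line and rejects flat input", {
  expect_false(any(bradley_threshold(matrix(0.7, 30, 30), 5, 1)))
  img <- matrix(0, 21, 21); img[11, ] <- 1
  fg <- bradley_threshold(img, 5, 1)
  # interior line pixels exceed the 5x5 window mean of 0.2
  expect_true(all(fg[11, 3:19]))
  expect_false(any(fg[c(1:8, 14:21), ]))
})

test_that("lower sensitivity never shrinks the foreground", {
  img <- seeded_image(50, 4)
  f1 <- bradley_threshold(img, 7, 1.2)
  f2 <- bradley_threshold(img, 7, 1.0)
  f3 <- bradley_threshold(img, 7, 0.8)
  expect_true(all(f1 <= f2) && all(f2 <= f3))
})

test_that("vessel segmentation recovers a noise-free synthetic tree", {
  p <- synth_params(n_tufts = 0, noise_sd = 0, illumination_amp = 0, mottle_amp = 0)
  syn <- generate_retina(p, seed = 2)
  geom <- delineate_flat_mount(syn$image)
  v <- segment_vessels(syn$image, geom)
  iou <- sum(v$mask & syn$truth_vessels) / sum(v$mask | syn$truth_vessels)
  expect_gt(iou, 0.8)

  # a smooth 2x illumination gradient must not break adaptivity
  n <- nrow(syn$image)
  gradient <- matrix(rep(seq(1, 2, length.out = n), each = n), n, n)
  v2 <- segment_vessels(syn$image * gradient, geom)
  iou2 <- sum(v2$mask & syn$truth_vessels) / sum(v2$mask | syn$truth_vessels)
  expect_gt(iou2, 0.8)
})

test_that("an avascular retina with flat noise yields almost no vessels", {
  p <- synth_params(n_tufts = 0, n_trunks = 0L, depth = 0L, noise_sd = 0.02,
                    mottle_amp = 0)
  syn <- generate_retina(p, seed = 5)
  geom <- delineate_flat_mount(syn$image)
  v <- segment_vessels(syn$image, geom)
  expect_lt(sum(v$mask) / sum(geom$mask), 0.01)
})

test_that("skeletons of canonical shapes have the expected topology", {
  g <- geom_from_mask(matrix(TRUE, 120, 120), phi = 120)
  bar <- matrix(FALSE, 120, 120); bar[58:62, 11:110] <- TRUE
  sk <- skeletonize_vessels(bar, g)
  expect_equal(nrow(sk$branch_points), 0)
  # thinning trims about half the stroke width at each end of the bar
  expect_gte(sk$total_length_px, 99 - 5)
  expect_lte(sk$total_length_px, 99 + 1)
  expect_true(all(sk$skeleton <= bar))

  # Y: three arms meeting at one point
  ymask <- matrix(FALSE, 120, 120)
  for (t in 0:49) {
    ymask[60 - t + (-2:2), 60 + (-2:2)] <- TRUE       # vertical arm up
    ymask[60 + round(t * 0.7) + (-2:2), 60 - round(t * 0.7) + (-2:2)] <- TRUE
    ymask[60 + round(t * 0.7) + (-2:2), 60 + round(t * 0.7) + (-2:2)] <- TRUE
  }
  sky <- skeletonize_vessels(ymask, g, prune_frac = 0.05)
  expect_equal(nrow(sky$branch_points), 1)

  # plus: four arms, still a single merged branch point
  pl <- matrix(FALSE, 120, 120)
  pl[58:62, 11:110] <- TRUE
  pl[11:110, 58:62] <- TRUE
  skp <- skeletonize_vessels(pl, g, prune_frac = 0.05)
  expect_equal(nrow(skp$branch_points), 1)

  # one-pixel-wide invariant: no 2x2 block survives thinning
  s <- sky$skeleton
  expect_false(any(s[-1, -1] & s[-nrow(s), -1] & s[-1, -ncol(s)] &
                     s[-nrow(s), -ncol(s)]))

  empty <- skeletonize_vessels(matrix(FALSE, 120, 120), g)
  expect_equal(sum(empty$skeleton), 0)
  expect_equal(empty$total_length_px, 0)
})

test_that("branch counts are invariant to rotation and mirroring", {
  p <- synth_params(n_tufts = 0, noise_sd = 0, illumination_amp = 0, mottle_amp = 0)
  syn <- generate_retina(p, seed = 4)
  geom <- delineate_flat_mount(syn$image)
  v <- segment_vessels(syn$image, geom)$mask
  g <- geom_from_mask(geom$mask, phi = geom$phi)
  n0 <- nrow(skeletonize_vessels(v, g)$branch_points)
  rot <- t(v)[ncol(v):1, ]
  grot <- geom_from_mask(t(geom$mask)[ncol(geom$mask):1, ], phi = geom$phi)
  expect_equal(nrow(skeletonize_vessels(rot, grot)$branch_points), n0)
  mir <- v[, ncol(v):1]
  gmir <- geom_from_mask(geom$mask[, ncol(geom$mask):1], phi = geom$phi)
  expect_equal(nrow(skeletonize_vessels(mir, gmir)$branch_points), n0)
})

test_that("planted branch counts and lengths drive the skeleton metrics", {
  p <- synth_params(n_tufts = 0, noise_sd = 0, illumination_amp = 0, mottle_amp = 0)
  syn <- generate_retina(p, seed = 6)
  geom <- delineate_flat_mount(syn$image)
  sk <- skeletonize_vessels(segment_vessels(syn$image, geom), geom)
  expect_equal(nrow(sk$branch_points), syn$n_branch_points)
  m <- vascular_metrics(sk, geom)
  expect_equal(m$n_branch_points, nrow(sk$branch_points))
  expect_equal(m$skeleton_frac, sum(sk$skeleton) / sum(geom$mask))

  # skeleton length scales linearly with the drawn length
  p2 <- synth_params(n_tufts = 0, noise_sd = 0, illumination_amp = 0, mottle_amp = 0,
                     n_trunks = 3L)
  syn2 <- generate_retina(p2, seed = 6)
  geom2 <- delineate_flat_mount(syn2$image)
  sk2 <- skeletonize_vessels(segment_vessels(syn2$image, geom2), geom2)
  ratio_drawn <- syn$total_drawn_length_px / syn2$total_drawn_length_px
  ratio_skel <- sk$total_length_px / sk2$total_length_px
  expect_equal(ratio_skel, ratio_drawn, tolerance = 0.05)

  zero <- vascular_metrics(
    skeletonize_vessels(matrix(FALSE, 10, 10),
                        geom_from_mask(matrix(TRUE, 10, 10))),
    geom_from_mask(matrix(TRUE, 10, 10)))
  expect_equal(unlist(zero), c(n_branch_points = 0, total_length_px = 0,
                               skeleton_frac = 0, branch_density = 0))
})

test_that("lowering Bradley sensitivity raises skeleton density", {
  p <- synth_params(n_tufts = 0)
  syn <- generate_retina(p, seed = 7)
  geom <- delineate_flat_mount(syn$image)
  fr <- vapply(c(1.3, 1.15, 1.05), function(s) {
    skeletonize_vessels(segment_vessels(syn$image, geom, sensitivity = s),
                        geom)$skeleton_frac
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("tile branch counts partition the total and are reproducible", {
  g <- geom_from_mask(matrix(TRUE, 200, 200), phi = 200)
  skel <- structure(list(skeleton = matrix(FALSE, 200, 200),
                         branch_points = cbind(row = c(5, 25, 25, 199),
                                               col = c(5, 25, 26, 199)),
                         endpoints = matrix(numeric(), 0, 2),
                         total_length_px = 0, skeleton_frac = 0),
                    class = "skeleton_graph")
  # full tiling: counts sum to the total without double counting
  expect_warning(
    all_tiles <- count_branchpoints_in_tiles(skel, g, tile_frac = 0.1,
                                             n_tiles = 1000L, seed = 1),
    "using all")
  expect_equal(sum(all_tiles$n_branch_points), 4)
  one <- all_tiles[all_tiles$row0 == 20 & all_tiles$col0 == 20, ]
  expect_equal(one$n_branch_points, 2)
  # fixed seed reproduces the same random tile selection
  s1 <- count_branchpoints_in_tiles(skel, g, n_tiles = 5L, seed = 9)
  s2 <- count_branchpoints_in_tiles(skel, g, n_tiles = 5L, seed = 9)
  expect_identical(s1, s2)
})
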