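test_that("Gaussian smoothing has unit gain and the right impulse response", {
  expect_equal(smooth_image(matrix(3.2, 20, 20)), matrix(3.2, 20, 20),
               tolerance = 1e-10)
  n <- 21
  imp <- matrix(0, n, n); imp[11, 11] <- 1
  sm <- smooth_image(imp, sigma = 0.5)
  k <- oirquant:::gaussian_kernel(0.5)
  r <- (nrow(k) - 1) / 2
  expect_equal(sm[11 + (-r:r), 11 + (-r:r)], k, tolerance = 1e-8)
  expect_equal(sum(sm), 1, tolerance = 1e-8)
})

test_that("smoothing a step edge matches direct correlation", {
  img <- matrix(0, 11, 11); img[, 6:11] <- 1
  sm <- smooth_image(img, sigma = 1)
  k <- oirquant:::gaussian_kernel(1)
  for (pt in list(c(6, 5), c(6, 6), c(3, 8), c(1, 1)))
    expect_equal(sm[pt[1], pt[2]], direct_corr_at(img, k, pt[1], pt[2]),
                 tolerance = 1e-8)
  expect_true(all(diff(sm[6, ]) >= -1e-12))  # monotone sigmoid profile
})

test_that("local normalization is a windowed contrast ratio", {
  expect_equal(local_norm_intensity(matrix(5, 30, 30), phi = 64),
               matrix(1, 30, 30), tolerance = 1e-10)
  # multiplicative gain invariance
  img <- seeded_image(40, 5) + 0.2
  expect_equal(local_norm_intensity(img * 7.3, phi = 160),
               local_norm_intensity(img, phi = 160), tolerance = 1e-10)
  # 33-px toy: bright plateau of width 5 on background 1, window 8
  img2 <- matrix(1, 33, 33); img2[, 15:19] <- 2
  out <- local_norm_intensity(img2, phi = 64)  # round(64/8) = 8 px window
  # brute-force moving average at the centre pixel (window rows 14..21)
  expect_equal(out[17, 17], 2 / mean(img2[14:21, 14:21]), tolerance = 1e-10)
})

test_that("global normalization is the affine map onto [0, 1]", {
  img <- matrix(c(3, 7, 7, 3), 2, 2)
  expect_equal(global_norm_intensity(img), matrix(c(0, 1, 1, 0), 2, 2))
  img2 <- matrix(c(2, 4, 6, 8), 2, 2)
  expect_equal(global_norm_intensity(img2), matrix(c(0, 1, 2, 3) / 3, 2, 2))
  r <- seeded_image(10, 2)
  r[1] <- 0; r[100] <- 1
  expect_equal(global_norm_intensity(r), r)
  expect_error(global_norm_intensity(matrix(4, 5, 5)), "constant")
})

test_that("LoG response prefers blobs at its scale over thin lines", {
  phi <- 300  # sigma = 5
  expect_equal(log_response(matrix(2, 64, 64), phi), matrix(0, 64, 64),
               tolerance = 1e-8)
  n <- 101; sigma <- phi / 60
  dr <- outer(seq_len(n) - 51, rep(1, n)); dc <- t(dr)
  blob <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
  resp <- log_response(blob, phi)
  expect_equal(which(resp == max(resp)), which.max(blob))
  # direct correlation oracle at the blob centre (up to the global max
  # normalization, checked as a ratio against an off-centre pixel)
  k <- oirquant:::log_kernel(sigma)
  direct_c <- -direct_corr_at(blob, k, 51, 51)
  direct_o <- max(0, -direct_corr_at(blob, k, 51, 61))
  expect_equal(resp[51, 61] / resp[51, 51], direct_o / direct_c,
               tolerance = 1e-6)
  # thin line vs 4-sigma disk of equal peak brightness
  line <- matrix(0, n, n); line[, 50:51] <- 1
  disk <- (dr^2 + dc^2 <= (2 * sigma)^2) * 1
  both <- pmax(line, 0)
  r_line <- log_response(line, phi)[51, 50]
  r_disk <- log_response(disk, phi)[51, 51]
  # same image scale-free comparison via unnormalized responses
  k <- oirquant:::log_kernel(sigma)
  u_line <- -direct_corr_at(line, k, 51, 50)
  u_disk <- -direct_corr_at(disk, k, 51, 51)
  expect_gt(u_disk, u_line)
})

test_that("raw and mapped LBP codes follow the uniform-rotation scheme", {
  # the worked example: exceedance bits (0,1,0,0,1,0,1,1) -> code 210,
  # non-uniform, mapped to the catch-all 9
  bits <- c(0, 1, 0, 0, 1, 0, 1, 1)
  nb <- 0.5 + bits            # center + U = 0.75 separates the two levels
  code <- lbp_code(nb, center = 0.5, U = 0.25)
  expect_equal(code$raw, 210)
  expect_equal(code$mapped, 9)
  # homogeneous neighbourhood
  expect_equal(lbp_code(rep(0.5, 8), 0.5, U = 0.01),
               list(raw = 0, mapped = 0L))
  # half-circle pattern: raw 15, two transitions, four set bits
  code2 <- lbp_code(0.5 + c(1, 1, 1, 1, 0, 0, 0, 0), 0.5, U = 0.25)
  expect_equal(code2$raw, 15)
  expect_equal(code2$mapped, 4L)
  expect_error(lbp_code(rep(1, 7), 0, 0))
})

test_that("LBP images are constant-0 on flat input and partition codes", {
  img <- matrix(0.3, 20, 20)
  codes <- lbp_image(img, lbp_config(U = 0.01))
  valid <- !is.na(codes)
  expect_true(all(codes[valid] == 0L))
  rimg <- seeded_image(40, 9)
  codes2 <- lbp_image(rimg, lbp_config(U = 0))
  fr <- table(factor(codes2[!is.na(codes2)], levels = 0:9)) /
    sum(!is.na(codes2))
  expect_equal(sum(fr), 1)
})

test_that("mapped-code histogram is invariant to 90-degree rotation and
           transposition at R = 1", {
  img <- seeded_image(36, 21)
  h0 <- table(factor(lbp_image(img, lbp_config(U = 0)), levels = 0:9))
  rot <- t(img)[ncol(img):1, ]
  h90 <- table(factor(lbp_image(rot, lbp_config(U = 0)), levels = 0:9))
  expect_equal(as.numeric(h0), as.numeric(h90))
  htr <- table(factor(lbp_image(t(img), lbp_config(U = 0)), levels = 0:9))
  expect_equal(as.numeric(h0), as.numeric(htr))
})

test_that("LBP codes are gain-invariant when U = 0", {
  img <- seeded_image(30, 13)
  c1 <- lbp_image(img, lbp_config(U = 0))
  c2 <- lbp_image(img * 9.7, lbp_config(U = 0))
  expect_identical(c1, c2)
})

test_that("tile features match a brute-force per-tile computation", {
  n <- 64
  img <- seeded_image(n, 17) * 0.5
  img[20:40, 20:40] <- img[20:40, 20:40] + 0.4
  mask <- matrix(TRUE, n, n)
  g <- geom_from_mask(mask, center = c(32.5, 32.5), phi = 600)
  roi <- structure(list(mask = mask, kind = "custom"), class = "oir_roi")
  tiles <- tile_features(img, g, roi, cfg = lbp_config(U = 0), tile_frac = 0.01)
  expect_equal(unique(tiles$side), 6)  # round(0.01 * 600)
  ism <- smooth_image(img)
  floc <- local_norm_intensity(ism, g$phi)
  fg <- global_norm_intensity(ism)
  flog <- log_response(ism, g$phi)
  codes <- lbp_image(img, lbp_config(U = 0))
  for (t in c(1L, 14L, nrow(tiles))) {
    rs <- (tiles$row0[t] + 1):min(tiles$row0[t] + 6, n)
    cs <- (tiles$col0[t] + 1):min(tiles$col0[t] + 6, n)
    expect_equal(tiles$I_loc[t], mean(floc[rs, cs]))
    expect_equal(tiles$I_g[t], mean(fg[rs, cs]))
    expect_equal(tiles$I_LoG[t], mean(flog[rs, cs]))
    cd <- codes[rs, cs]; cd <- cd[!is.na(cd)]
    expect_equal(tiles$LBP0[t], mean(cd == 0))
    expect_equal(tiles$LBP9[t], mean(cd == 9))
    expect_equal(tiles$LBP0[t] + tiles$LBP9[t] <= 1 + 1e-12, TRUE)
  }
})

test_that("tiles mostly outside the ROI are excluded from analysis", {
  n <- 60
  mask <- matrix(FALSE, n, n)
  mask[1:30, ] <- TRUE
  g <- geom_from_mask(matrix(TRUE, n, n), phi = 500)
  roi <- structure(list(mask = mask, kind = "custom"), class = "oir_roi")
  tiles <- tile_features(seeded_image(n, 1), g, roi, tile_frac = 0.01)
  side <- unique(tiles$side)
  fully_out <- tiles$row0 >= 30
  expect_true(all(!tiles$inside_roi[fully_out]))
  fully_in <- tiles$row0 + side <= 30
  expect_true(all(tiles$inside_roi[fully_in]))
})
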