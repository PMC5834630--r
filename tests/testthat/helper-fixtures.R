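# Shared fixtures and independent oracles used across the suite.

# Filled disk mask/image helpers -------------------------------------------

disk_mask <- function(n, center = c((n + 1) / 2, (n + 1) / 2), radius) {
  dr <- outer(seq_len(n) - center[1L], rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - center[2L])
  sqrt(dr^2 + dc^2) <= radius
}

disk_image <- function(n, radius, fg = 200, bg = 10,
                       center = c((n + 1) / 2, (n + 1) / 2)) {
  img <- matrix(bg, n, n)
  img[disk_mask(n, center, radius)] <- fg
  img
}

# A retina_geometry built directly from a known mask (bypasses delineation).
geom_from_mask <- function(mask, center = NULL, phi = NULL) {
  if (is.null(center)) {
    rc <- which(mask, arr.ind = TRUE)
    center <- c(mean(rc[, 1L]), mean(rc[, 2L]))
  }
  if (is.null(phi)) phi <- retina_diameter(mask)
  structure(list(mask = mask, center = center, phi = phi,
                 threshold = NA_real_),
            class = "retina_geometry")
}

# A background model with constant fields (for validation-rule tests).
flat_background <- function(dim, I_b, sigma_b = 0, k_sigma = 3) {
  structure(list(I_b = matrix(I_b, dim[1L], dim[2L]),
                 sigma_b = matrix(sigma_b, dim[1L], dim[2L]),
                 threshold = matrix(I_b + k_sigma * sigma_b, dim[1L], dim[2L]),
                 window_frac = 0.07, k_sigma = k_sigma, rescaled = FALSE,
                 decimate = 1L),
            class = "background_model")
}

# A minimal feature_tiles table with given tile origins (0-based) and labels.
manual_tiles <- function(row0, col0, side, label, inside_roi = TRUE,
                         image_dim) {
  n <- length(row0)
  structure(
    data.frame(row0 = row0, col0 = col0, side = side,
               inside_roi = rep_len(inside_roi, n),
               I_loc = 1, I_g = 0.5, I_LoG = 0, LBP0 = 1, LBP9 = 0,
               label = factor(rep_len(label, n),
                              levels = c("normal", "tuft"))),
    class = c("feature_tiles", "data.frame"),
    tile_side = side, image_dim = image_dim)
}

# Independent oracles --------------------------------------------------------

# Naive windowed mean comparison (the Bradley definition, O(N w^2)).
naive_bradley <- function(image, w, sensitivity) {
  nr <- nrow(image); nc <- ncol(image)
  h1 <- (w - 1L) %/% 2L; h2 <- w %/% 2L
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1L, r - h1):min(nr, r + h2)
    cs <- max(1L, c - h1):min(nc, c + h2)
    out[r, c] <- image[r, c] > mean(image[rs, cs]) * sensitivity
  }
  out
}

# Direct dense-arithmetic evaluation of the Gaussian class-conditional
# classifier: densities via solve()/det(), posterior by normalization,
# decision by expected-cost argmin with ties toward "normal".
brute_qda <- function(model, x) {
  K <- length(model$levels)
  d <- ncol(model$means)
  dens <- vapply(seq_len(K), function(k) {
    S <- model$covs[[k]]
    cen <- x - model$means[k, ]
    (2 * pi)^(-d / 2) * det(S)^(-0.5) *
      exp(-0.5 * as.numeric(t(cen) %*% solve(S) %*% cen))
  }, numeric(1))
  post <- dens * model$prior
  post <- post / sum(post)
  ec <- as.numeric(model$cost %*% post)   # expected cost of predicting y
  cand <- which(ec == min(ec))
  if (length(cand) > 1L && any(model$levels[cand] == "normal"))
    cand <- cand[model$levels[cand] == "normal"]
  list(post = post, class = model$levels[cand[1L]])
}

# Direct correlation at one pixel with reflected borders.
direct_corr_at <- function(image, kern, r, c) {
  hr <- (nrow(kern) - 1L) %/% 2L
  hc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  acc <- 0
  for (dr in -hr:hr) for (dc in -hc:hc) {
    acc <- acc + kern[dr + hr + 1L, dc + hc + 1L] *
      image[reflect(r + dr, nr), reflect(c + dc, nc)]
  }
  acc
}

# Cheap deterministic pseudo-image.
seeded_image <- function(n, seed) {
  withr::with_seed(seed, matrix(stats::runif(n * n), n, n))
}
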