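# Per-tile descriptors for tuft classification. The retina is tiled with
# squares of side 1% of the flat-mount diameter and five features are
# computed per tile: local and global normalized intensity, a
# Laplacian-of-Gaussian (blob) response, and the fractions of LBP codes 0
# (homogeneous texture) and 9 (irregular, non-edge texture).

#' Gaussian pre-smoothing
#'
#' Correlation with a unit-sum Gaussian kernel (default standard deviation
#' half a pixel); borders are handled by reflection. All intensity features
#' are computed from this smoothed image.
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels (default 0.5).
#' @return smoothed matrix.
#' @export
smooth_image <- function(image, sigma = 0.5) {
  stopifnot_image(image)
  if (sigma <= 0) stop("sigma must be positive")
  filter2_reflect(image, gaussian_kernel(sigma))
}

#' Locally normalized intensity
#'
#' Ratio of the smoothed image to its moving average over a square window of
#' side `round(phi * window_frac)` (default one eighth of the flat-mount
#' diameter). Invariant to global multiplicative gain. Where the local mean is
#' at or below `eps` (dark windows) the ratio is set to 1 (neutral contrast).
#' @param i_smooth smoothed image ([smooth_image()]).
#' @param phi flat-mount diameter in pixels.
#' @param window_frac window side as fraction of `phi` (default 1/8).
#' @param eps denominator guard.
#' @return matrix of local contrast values.
#' @export
local_norm_intensity <- function(i_smooth, phi, window_frac = 1 / 8,
                                 eps = 1e-8) {
  stopifnot_image(i_smooth)
  if (phi <= 0) stop("phi must be positive")
  w <- max(1L, round(phi * window_frac))
  den <- box_mean(i_smooth, w)
  out <- i_smooth / pmax(den, eps)
  out[den <= eps] <- 1
  out
}

#' Globally normalized intensity
#'
#' Affine map of the smoothed image onto `[0, 1]` using its global minimum
#' and maximum.
#' @param i_smooth smoothed image.
#' @return matrix in `[0, 1]`.
#' @export
global_norm_intensity <- function(i_smooth) {
  stopifnot_image(i_smooth)
  rng <- range(i_smooth)
  if (diff(rng) <= 0)
    stop("global normalization undefined: image is constant", call. = FALSE)
  (i_smooth - rng[1L]) / diff(rng)
}

# LoG kernel as printed in the method: ((x^2+y^2-2 sigma^2) k_g) /
# (2 pi sigma^6 sum(k_g)); response uses the negated kernel so bright
# blob-like structures of scale ~sigma respond positively.
log_kernel <- function(sigma) {
  r <- max(2L, ceiling(3.5 * sigma))
  x <- -r:r
  kg <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k <- ((outer(x^2, x^2, `+`) - 2 * sigma^2) * kg) / (2 * pi * sigma^6 * sum(kg))
  k - mean(k)   # exact zero sum on the truncated discrete support
}

#' Laplacian-of-Gaussian blob response
#'
#' Band-pass response that enhances thick, globular structures at scale
#' `sigma = phi * sigma_frac` (default one sixtieth of the flat-mount
#' diameter). The image is correlated with the negated LoG kernel so bright
#' blobs give positive response; negative values are clipped to zero and the
#' result normalized globally to `[0, 1]` (all-zero response stays zero).
#' @param i_smooth smoothed image.
#' @param phi flat-mount diameter in pixels.
#' @param sigma_frac kernel scale as a fraction of `phi` (default 1/60).
#' @return matrix in `[0, 1]`.
#' @export
log_response <- function(i_smooth, phi, sigma_frac = 1 / 60) {
  stopifnot_image(i_smooth)
  if (phi <= 0) stop("phi must be positive")
  sigma <- phi * sigma_frac
  resp <- -filter2_reflect(i_smooth, log_kernel(sigma))
  resp[resp < 0] <- 0
  # FFT round-off on structure-free images must not be amplified by the
  # global normalization
  eps <- 1e-9 * max(mean(abs(i_smooth)), .Machine$double.xmin)
  mx <- max(resp)
  if (mx > eps) resp / mx else matrix(0, nrow(resp), ncol(resp))
}

#' LBP configuration
#'
#' @param P number of circle samples (the 10-code mapping requires 8).
#' @param R circle radius in pixels (default 1; not fixed by the method
#'   description).
#' @param U intensity difference threshold; differences of at most `U` are
#'   ignored. Default 0.01 (1% of the rescaled intensity range); `U = 0`
#'   reproduces the textbook LBP.
#' @return list of class `lbp_config`.
#' @export
lbp_config <- function(P = 8L, R = 1, U = 0.01) {
  if (P != 8L) stop("the 10-code mapping is defined for P = 8")
  if (R <= 0) stop("R must be positive")
  if (U < 0) stop("U must be non-negative")
  structure(list(P = 8L, R = R, U = U), class = "lbp_config")
}

#' Raw and mapped LBP code of one neighbourhood
#'
#' The raw code is `sum(H(P_i - P_c - U) * 2^i)` over the 8 circle samples
#' (`H` the Heaviside step). The rotation-invariant uniform mapping assigns
#' the number of set bits when the circular bit pattern has at most two
#' 0/1 transitions, and the catch-all code 9 otherwise.
#' @param neighbors numeric vector of 8 interpolated sample intensities.
#' @param center centre pixel intensity.
#' @param U difference threshold.
#' @return list with `raw` (0..255) and `mapped` (0..9).
#' @export
lbp_code <- function(neighbors, center, U = 0) {
  if (length(neighbors) != 8L) stop("exactly 8 neighbour samples required")
  bits <- as.integer(neighbors - center - U > 0)
  raw <- sum(bits * 2^(0:7))
  trans <- sum(abs(bits - bits[c(2:8, 1L)]))
  mapped <- if (trans <= 2L) sum(bits) else 9L
  list(raw = raw, mapped = mapped)
}

# Bilinear sample of the image at a fixed fractional offset (dr, dc),
# returned as a full matrix (borders invalid, handled by caller).
sample_offset <- function(image, dr, dc) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  # weights for the 4 integer shifts
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  out <- w00 * shift_mat(image, -r0, -c0) +
    w01 * shift_mat(image, -r0, -(c0 + 1L)) +
    w10 * shift_mat(image, -(r0 + 1L), -c0) +
    w11 * shift_mat(image, -(r0 + 1L), -(c0 + 1L))
  out
}

#' Per-pixel mapped LBP codes
#'
#' Samples the 8 neighbours on the radius-`R` circle at angles `2*pi*i/8` by
#' bilinear interpolation and maps each pixel's raw code through the
#' rotation-invariant uniform scheme (codes 0..8 for uniform patterns, 9 for
#' the rest). A border band of width `ceiling(R)` is marked invalid (`NA`).
#' @param image numeric matrix.
#' @param cfg an [lbp_config()].
#' @return integer matrix of mapped codes with `NA` in the border band.
#' @export
lbp_image <- function(image, cfg = lbp_config()) {
  stopifnot_image(image)
  stopifnot(inherits(cfg, "lbp_config"))
  nr <- nrow(image); nc <- ncol(image)
  b <- ceiling(cfg$R)
  if (nr <= 2 * b || nc <= 2 * b)
    stop("image too small for LBP radius", call. = FALSE)
  bits <- vector("list", 8L)
  ang <- 2 * pi * (0:7) / 8
  snap <- function(x) round(x, 9)        # kill trig noise on axis samples
  for (i in 1:8) {
    dr <- snap(cfg$R * sin(ang[i]))
    dc <- snap(cfg$R * cos(ang[i]))
    bits[[i]] <- (sample_offset(image, dr, dc) - image - cfg$U > 0) * 1L
  }
  nset <- Reduce(`+`, bits)
  trans <- matrix(0L, nr, nc)
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    trans <- trans + abs(bits[[i]] - bits[[j]])
  }
  mapped <- ifelse(trans <= 2L, nset, 9L)
  mapped[c(seq_len(b), nr - seq_len(b) + 1L), ] <- NA_integer_
  mapped[, c(seq_len(b), nc - seq_len(b) + 1L)] <- NA_integer_
  matrix(as.integer(mapped), nr, nc)
}

#' Tile-level feature table
#'
#' Tiles the bounding box of the ROI with squares of side
#' `round(phi * tile_frac)` (anchored at the box's top-left corner; edge
#' tiles are clipped to the image) and computes per tile the means of the
#' three intensity features plus the fractions of valid pixels with mapped
#' LBP code 0 and 9. Tiles with fewer than half their pixels inside the ROI
#' are flagged `inside_roi = FALSE` and are excluded from training and
#' prediction.
#'
#' @param image numeric matrix (intensities; rescale beforehand if desired).
#' @param geom a `retina_geometry`.
#' @param roi an `oir_roi` (or logical matrix).
#' @param cfg an [lbp_config()].
#' @param tile_frac tile side as a fraction of `phi` (default 0.01).
#' @param min_inside_frac minimum in-ROI pixel fraction (default 0.5).
#' @return data.frame of class `feature_tiles` with columns `row0`, `col0`
#'   (0-based tile origin), `side`, `inside_roi`, `I_loc`, `I_g`, `I_LoG`,
#'   `LBP0`, `LBP9`, `label` (factor, `NA` until labelled). The tile side and
#'   image dimensions are kept as attributes.
#' @export
tile_features <- function(image, geom, roi, cfg = lbp_config(),
                          tile_frac = 0.01, min_inside_frac = 0.5) {
  stopifnot_image(image)
  stopifnot(inherits(geom, "retina_geometry"))
  rmask <- roi_mask(roi)
  side <- round(geom$phi * tile_frac)
  if (side < 3L) stop("tile side below 3 px; phi too small", call. = FALSE)
  if (!any(rmask)) {
    warning("empty ROI: no tiles")
    return(empty_tiles(side, dim(image)))
  }
  ism <- smooth_image(image)
  f_loc <- local_norm_intensity(ism, geom$phi)
  f_g <- global_norm_intensity(ism)
  f_log <- log_response(ism, geom$phi)
  codes <- lbp_image(image, cfg)
  rc <- which(rmask, arr.ind = TRUE)
  r0 <- min(rc[, 1L]); c0 <- min(rc[, 2L])
  r1 <- max(rc[, 1L]); c1 <- max(rc[, 2L])
  rows0 <- seq(r0, r1, by = side)
  cols0 <- seq(c0, c1, by = side)
  grid <- expand.grid(row = rows0, col = cols0)
  n <- nrow(grid)
  out <- data.frame(row0 = grid$row - 1L, col0 = grid$col - 1L,
                    side = side, inside_roi = FALSE,
                    I_loc = NA_real_, I_g = NA_real_, I_LoG = NA_real_,
                    LBP0 = NA_real_, LBP9 = NA_real_,
                    label = factor(rep(NA_character_, n),
                                   levels = c("normal", "tuft")))
  nr <- nrow(image); nc <- ncol(image)
  for (t in seq_len(n)) {
    rs <- grid$row[t]:min(grid$row[t] + side - 1L, nr)
    cs <- grid$col[t]:min(grid$col[t] + side - 1L, nc)
    inroi <- rmask[rs, cs, drop = FALSE]
    out$inside_roi[t] <- mean(inroi) >= min_inside_frac
    out$I_loc[t] <- mean(f_loc[rs, cs])
    out$I_g[t] <- mean(f_g[rs, cs])
    out$I_LoG[t] <- mean(f_log[rs, cs])
    cd <- codes[rs, cs]
    cd <- cd[!is.na(cd)]
    if (length(cd)) {
      out$LBP0[t] <- mean(cd == 0L)
      out$LBP9[t] <- mean(cd == 9L)
    } else {
      out$LBP0[t] <- 0
      out$LBP9[t] <- 0
    }
  }
  structure(out, class = c("feature_tiles", "data.frame"),
            tile_side = side, image_dim = dim(image))
}

empty_tiles <- function(side, image_dim) {
  structure(
    data.frame(row0 = integer(), col0 = integer(), side = integer(),
               inside_roi = logical(), I_loc = numeric(), I_g = numeric(),
               I_LoG = numeric(), LBP0 = numeric(), LBP9 = numeric(),
               label = factor(character(), levels = c("normal", "tuft"))),
    class = c("feature_tiles", "data.frame"),
    tile_side = side, image_dim = image_dim)
}

feature_columns <- c("I_loc", "I_g", "I_LoG", "LBP0", "LBP9")

# Pixel mask covered by a subset of tiles.
tiles_to_mask <- function(tiles, which_tiles, image_dim) {
  mask <- matrix(FALSE, image_dim[1L], image_dim[2L])
  for (t in which_tiles) {
    rs <- (tiles$row0[t] + 1L):min(tiles$row0[t] + tiles$side[t], image_dim[1L])
    cs <- (tiles$col0[t] + 1L):min(tiles$col0[t] + tiles$side[t], image_dim[2L])
    mask[rs, cs] <- TRUE
  }
  mask
}
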