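# Low-level raster helpers shared by all pipeline stages.
#
# Images are plain numeric matrices indexed [row, col], 0-based pixel-centre
# coordinates are used only at the I/O boundary; internally everything is
# 1-based R indexing. Masks are logical matrices of the same shape.

#' @importFrom stats median rnorm runif sd
NULL

stopifnot_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(image)
}

#' Shift a matrix by whole pixels
#'
#' Returns a matrix of the same shape with contents moved by (`dr`, `dc`);
#' vacated cells are filled with `fill`.
#' @param m matrix.
#' @param dr,dc integer shift in rows / columns (positive moves content down /
#'   right).
#' @param fill fill value for vacated cells.
#' @return shifted matrix.
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# Summed-area table with a zero top row / left column so that
# sums over [r1..r2, c1..c2] are S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1].
integral_image <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  S
}

#' Local box mean via an integral image
#'
#' Mean over a `w` x `w` window centred at each pixel, with the window clipped
#' at the image border (the divisor is the number of in-image pixels).
#' @param m numeric matrix.
#' @param w odd or even window side in pixels (>= 1).
#' @return matrix of local means, same shape as `m`.
#' @keywords internal
box_mean <- function(m, w) {
  w <- as.integer(w)
  if (w < 1L) stop("window side must be >= 1")
  nr <- nrow(m); nc <- ncol(m)
  h1 <- (w - 1L) %/% 2L          # extent above/left
  h2 <- w %/% 2L                 # extent below/right (handles even w)
  # centring keeps cumulative sums exact on constant images, so strict
  # comparisons against the local mean cannot flip on round-off dust
  m0 <- mean(m)
  S <- integral_image(m - m0)
  r1 <- pmax(seq_len(nr) - h1, 1L); r2 <- pmin(seq_len(nr) + h2, nr)
  c1 <- pmax(seq_len(nc) - h1, 1L); c2 <- pmin(seq_len(nc) + h2, nc)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / cnt + m0
}

# Reflect-pad a matrix by (pr, pc) pixels on each side.
pad_reflect <- function(m, pr, pc = pr) {
  nr <- nrow(m); nc <- ncol(m)
  pr <- min(pr, nr - 1L); pc <- min(pc, nc - 1L)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

#' Correlate an image with a kernel, reflected borders
#'
#' Thin wrapper around [EBImage::filter2()] (FFT-based correlation) that
#' reflect-pads the image first so border artefacts stay within the kernel
#' support. Symmetric kernels make correlation and convolution coincide.
#' @param m numeric matrix.
#' @param kern odd-sided kernel matrix.
#' @return filtered matrix, same shape as `m`.
#' @keywords internal
filter2_reflect <- function(m, kern) {
  pr <- (nrow(kern) - 1L) %/% 2L
  pc <- (ncol(kern) - 1L) %/% 2L
  mp <- pad_reflect(m, pr, pc)
  # repeated reflect padding when the kernel outgrows the image
  while (nrow(mp) < nrow(kern) || ncol(mp) < ncol(kern))
    mp <- pad_reflect(mp, nrow(mp) - 1L, ncol(mp) - 1L)
  fp <- EBImage::filter2(mp, kern, boundary = "circular")
  ro <- (nrow(mp) - nrow(m)) %/% 2L
  co <- (ncol(mp) - ncol(m)) %/% 2L
  fp[ro + seq_len(nrow(m)), co + seq_len(ncol(m)), drop = FALSE]
}

# Unit-sum isotropic Gaussian kernel sampled at pixel centres,
# truncated at ceiling(3.5 sigma).
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- -r:r
  k <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' Label 8-connected foreground components
#'
#' EBImage's `bwlabel()` is 4-connected, so diagonal-only contacts would split
#' objects; this uses the 8-neighbour pixel graph instead.
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pix <- match(idx, idx)                 # 1..n ids of foreground pixels
  id_of <- matrix(NA_integer_, nr, nc)
  id_of[idx] <- pix
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(id_of, off[1L], off[2L], fill = NA_integer_)
    both <- which(!is.na(id_of) & !is.na(nb))
    if (length(both))
      edges <- c(edges, rbind(id_of[both], nb[both]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::make_graph(edges = as.integer(edges), n = length(idx),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(comp)
  lab
}

# Fill interior holes of a binary mask (EBImage fillHull).
fill_holes <- function(mask) {
  f <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.numeric(f) > 0.5, nrow(mask), ncol(mask))
}

# Logical disk structuring element of radius r (pixels).
disk_kernel <- function(r) {
  r <- max(1L, as.integer(round(r)))
  x <- -r:r
  outer(x^2, x^2, `+`) <= r^2
}

# Count of 8-neighbours that are TRUE, per pixel.
neighbor_count8 <- function(mask) {
  m <- mask * 1L
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + shift_mat(m, dr, dc, fill = 0L)
  }
  s
}

#' Catmull-Rom bicubic upsampling of a decimated grid
#'
#' Interpolates values sampled on the regular grid
#' `rows = 1 + (i-1)*step`, `cols = 1 + (j-1)*step` back to full resolution.
#' Separable; grid indices are clamped at the borders.
#' @param G matrix of samples (no NAs).
#' @param step decimation step used when sampling.
#' @param nr,nc output size.
#' @return `nr` x `nc` matrix.
#' @keywords internal
bicubic_upsample <- function(G, step, nr, nc) {
  cr_w <- function(t) {
    # Catmull-Rom weights for the 4 support points at offsets -1,0,1,2
    t2 <- t * t; t3 <- t2 * t
    cbind(-0.5 * t3 + t2 - 0.5 * t,
          1.5 * t3 - 2.5 * t2 + 1,
          -1.5 * t3 + 2 * t2 + 0.5 * t,
          0.5 * t3 - 0.5 * t2)
  }
  wmat <- function(n_out, n_grid) {
    pos <- (seq_len(n_out) - 1) / step        # fractional grid coordinate
    i0 <- floor(pos)
    t <- pos - i0
    W <- matrix(0, n_out, n_grid)
    wts <- cr_w(t)
    for (k in -1:2) {
      ik <- pmin(pmax(i0 + k, 0), n_grid - 1L) + 1L
      W[cbind(seq_len(n_out), ik)] <- W[cbind(seq_len(n_out), ik)] + wts[, k + 2L]
    }
    W
  }
  Wr <- wmat(nr, nrow(G))
  Wc <- wmat(nc, ncol(G))
  Wr %*% G %*% t(Wc)
}

# Replace NAs by iterated 3x3 neighbour means (nearest-estimate fill).
fill_na_nearest <- function(m, max_iter = 10000L) {
  it <- 0L
  while (anyNA(m) && it < max_iter) {
    it <- it + 1L
    na <- is.na(m)
    v <- m; v[na] <- 0
    w <- (!na) * 1
    sv <- matrix(0, nrow(m), ncol(m)); sw <- sv
    for (dr in -1:1) for (dc in -1:1) {
      sv <- sv + shift_mat(v, dr, dc)
      sw <- sw + shift_mat(w, dr, dc)
    }
    upd <- na & sw > 0
    m[upd] <- sv[upd] / sw[upd]
  }
  if (anyNA(m)) m[is.na(m)] <- mean(m, na.rm = TRUE)
  m
}
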