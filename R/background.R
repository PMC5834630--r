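# Local background model: the flat-mount mosaics show strong background
# fluctuations (sample thickness, staining, photobleaching, stitching seams),
# so tuft validation compares intensities against a spatially varying
# threshold I_b + k * sigma_b estimated from inter-vessel background pockets.

#' Saturating linear rescale
#'
#' Rescales intensities linearly onto `[0, 1]` so that the bottom `low_frac`
#' and top `high_frac` of all pixel values saturate at 0 and 1. A constant
#' image maps to 0.5 everywhere (documented convention, no error).
#'
#' @param image numeric matrix.
#' @param low_frac,high_frac saturated tails (defaults 0.01 each).
#' @return matrix in `[0, 1]`.
#' @export
rescale_saturate <- function(image, low_frac = 0.01, high_frac = 0.01) {
  stopifnot_image(image)
  if (low_frac + high_frac >= 1) stop("low_frac + high_frac must be < 1")
  s <- sort(as.vector(image))
  n <- length(s)
  lo <- s[max(1L, ceiling(n * low_frac))]
  hi <- s[min(n, n - ceiling(n * high_frac) + 1L)]
  if (hi <= lo) return(matrix(0.5, nrow(image), ncol(image)))
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

#' Weighted regional minima of a quantized image
#'
#' Bins the image into `n_levels` equally spaced levels and identifies
#' 8-connected constant-level plateaus all of whose neighbours have a higher
#' level (regional minima). Each minima pixel is weighted by its plateau area,
#' so large uniform background pockets dominate small dips. Pixels outside
#' `mask` are ignored entirely; plateaus touching the image border are
#' discarded (their surround is ambiguous).
#'
#' @param image numeric matrix (typically rescaled to `[0, 1]`).
#' @param n_levels number of quantization levels (default 10).
#' @param mask optional logical matrix restricting the analysis.
#' @return list with `minima` (logical matrix), `weight` (numeric matrix,
#'   plateau area at minima pixels, 0 elsewhere) and `n_objects`.
#' @export
find_weighted_minima <- function(image, n_levels = 10L, mask = NULL) {
  stopifnot_image(image)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  rng <- range(image[mask])
  if (diff(rng) <= 0) {
    lev <- matrix(0L, nr, nc)
  } else {
    lev <- matrix(pmin(floor((image - rng[1L]) / diff(rng) * n_levels),
                       n_levels - 1L), nr, nc)
  }
  lev[!mask] <- NA_integer_
  minima <- matrix(FALSE, nr, nc)
  weight <- matrix(0, nr, nc)
  n_obj <- 0L
  # a plateau is a regional minimum iff none of its pixels has an in-mask
  # neighbour with a lower level
  lower_nb <- matrix(FALSE, nr, nc)
  border_nb <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- shift_mat(lev, dr, dc, fill = NA_integer_)
    cmp <- !is.na(lev) & !is.na(nb) & nb < lev
    lower_nb <- lower_nb | cmp
  }
  border_px <- matrix(FALSE, nr, nc)
  border_px[c(1L, nr), ] <- TRUE
  border_px[, c(1L, nc)] <- TRUE
  for (l in sort(unique(lev[!is.na(lev)]))) {
    lab <- label8(!is.na(lev) & lev == l)
    if (!any(lab > 0L)) next
    nlab <- max(lab)
    bad <- rep(FALSE, nlab)
    bad[unique(lab[lab > 0L & lower_nb])] <- TRUE
    bad[unique(lab[lab > 0L & border_px])] <- TRUE
    keep <- which(!bad)
    if (!length(keep)) next
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    sel <- lab > 0L & !bad[pmax(lab, 1L)]
    minima[sel] <- TRUE
    weight[sel] <- sizes[lab[sel]]
    n_obj <- n_obj + length(keep)
  }
  list(minima = minima, weight = weight, n_objects = n_obj)
}

#' Estimate the spatially varying local background
#'
#' At each pixel, the weighted mean `I_b` and spread `sigma_b` of the image
#' values at regional-minima pixels (see [find_weighted_minima()]) are
#' computed inside a circular window of diameter `window_frac * phi`. One
#' refinement pass excludes values beyond `k_sigma * sigma_b` of `I_b`. Pixels
#' whose window contains no minima are filled by bicubic interpolation from
#' pixels that have direct estimates. The validation threshold is
#' `I_b + k_sigma * sigma_b`.
#'
#' For efficiency the windowed statistics are evaluated on a decimated grid
#' (every `decimate`-th pixel) and upsampled; `decimate = 1` gives the exact
#' per-pixel computation.
#'
#' @param image numeric matrix.
#' @param geom a `retina_geometry`.
#' @param window_frac circular window diameter as a fraction of `phi`
#'   (default 0.07).
#' @param k_sigma spread multiplier for both the outlier exclusion and the
#'   final threshold (default 3).
#' @param n_levels quantization levels for minima detection.
#' @param rescale apply [rescale_saturate()] before minima detection and
#'   statistics (the model is then on the rescaled scale). Set `FALSE` when
#'   the image has already been rescaled, or to work on raw intensities.
#' @param decimate grid step for the windowed statistics (default 8).
#' @return object of class `background_model`: list with matrices `I_b`,
#'   `sigma_b`, `threshold` and the parameters used.
#' @export
estimate_background <- function(image, geom, window_frac = 0.07, k_sigma = 3,
                                n_levels = 10L, rescale = TRUE, decimate = 8L) {
  stopifnot_image(image)
  stopifnot(inherits(geom, "retina_geometry"))
  work <- if (rescale) rescale_saturate(image) else image
  mn <- find_weighted_minima(work, n_levels = n_levels, mask = geom$mask)
  nr <- nrow(work); nc <- ncol(work)
  radius <- window_frac * geom$phi / 2
  if (!any(mn$minima)) {
    warning("no regional minima found; falling back to global statistics")
    v <- work[geom$mask]
    m0 <- mean(v); s0 <- stats::sd(v); if (!is.finite(s0)) s0 <- 0
    keep <- abs(v - m0) <= k_sigma * s0
    if (any(keep) && !all(keep)) {
      m0 <- mean(v[keep])
      s0 <- stats::sd(v[keep]); if (!is.finite(s0)) s0 <- 0
    }
    I_b <- matrix(m0, nr, nc); sigma_b <- matrix(s0, nr, nc)
  } else {
    rc <- which(mn$minima, arr.ind = TRUE)
    vals <- work[mn$minima]
    wts <- mn$weight[mn$minima]
    gr <- seq(1L, nr, by = decimate)
    gc <- seq(1L, nc, by = decimate)
    st <- window_stats_grid(rc, vals, wts, gr, gc, radius, k_sigma)
    Gm <- fill_na_nearest(st$mean)
    Gs <- fill_na_nearest(st$sd)
    if (decimate == 1L) {
      I_b <- Gm; sigma_b <- Gs
    } else {
      I_b <- bicubic_upsample(Gm, decimate, nr, nc)
      sigma_b <- pmax(bicubic_upsample(Gs, decimate, nr, nc), 0)
    }
  }
  structure(list(I_b = I_b, sigma_b = sigma_b,
                 threshold = I_b + k_sigma * sigma_b,
                 window_frac = window_frac, k_sigma = k_sigma,
                 rescaled = rescale, decimate = decimate),
            class = "background_model")
}

# Weighted mean/sd of (vals, wts) at minima coordinates rc within a circular
# window around each (gr x gc) grid point, with one outlier-exclusion pass.
window_stats_grid <- function(rc, vals, wts, gr, gc, radius, k_sigma) {
  cell <- max(1, ceiling(radius))
  cr <- (rc[, 1L] - 1L) %/% cell
  cc <- (rc[, 2L] - 1L) %/% cell
  key <- paste(cr, cc)
  buckets <- split(seq_along(vals), key)
  Gm <- matrix(NA_real_, length(gr), length(gc))
  Gs <- matrix(NA_real_, length(gr), length(gc))
  r2 <- radius^2
  for (i in seq_along(gr)) {
    pr <- gr[i]
    bcr <- (pr - 1L) %/% cell
    for (j in seq_along(gc)) {
      pc <- gc[j]
      bcc <- (pc - 1L) %/% cell
      cand <- NULL
      for (a in (bcr - 1L):(bcr + 1L)) for (b in (bcc - 1L):(bcc + 1L)) {
        bk <- buckets[[paste(a, b)]]
        if (!is.null(bk)) cand <- c(cand, bk)
      }
      if (is.null(cand)) next
      d2 <- (rc[cand, 1L] - pr)^2 + (rc[cand, 2L] - pc)^2
      sel <- cand[d2 <= r2]
      if (!length(sel)) next
      v <- vals[sel]; w <- wts[sel]
      m <- sum(w * v) / sum(w)
      s <- sqrt(sum(w * (v - m)^2) / sum(w))
      keep <- abs(v - m) <= k_sigma * s
      if (any(keep) && !all(keep)) {
        v <- v[keep]; w <- w[keep]
        m <- sum(w * v) / sum(w)
        s <- sqrt(sum(w * (v - m)^2) / sum(w))
      }
      Gm[i, j] <- m
      Gs[i, j] <- s
    }
  }
  list(mean = Gm, sd = Gs)
}

#' @export
print.background_model <- function(x, ...) {
  cat("Local background model\n")
  cat(sprintf("  I_b range: [%.4g, %.4g]\n", min(x$I_b), max(x$I_b)))
  cat(sprintf("  sigma_b range: [%.4g, %.4g]\n", min(x$sigma_b), max(x$sigma_b)))
  cat(sprintf("  threshold = I_b + %g * sigma_b\n", x$k_sigma))
  invisible(x)
}
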