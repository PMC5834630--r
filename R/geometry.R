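#' Delineate the flat-mounted retina
#'
#' Finds the retinal region of a flat-mount mosaic: the image is smoothed with
#' a Gaussian whose standard deviation is a fraction of the image size, a
#' global threshold is placed at the histogram valley between the two highest
#' intensity peaks, holes are filled and the largest 8-connected object is
#' kept. The characteristic flat-mount diameter `phi` (the scale unit for
#' every downstream size parameter) is the equivalent-circle diameter of the
#' resulting mask.
#'
#' @param image numeric matrix of intensities (rows x cols).
#' @param smooth_frac Gaussian standard deviation as a fraction of
#'   `max(nrow, ncol)`. Default 0.025.
#' @param threshold optional intensity override; when given, the histogram
#'   valley search is skipped.
#' @param center optional `(row, col)` optic-nerve position. Defaults to the
#'   mask centroid (automatic nerve-head detection is out of scope).
#' @param n_bins histogram bins for the valley search.
#' @return an object of class `retina_geometry`: list with `mask` (logical
#'   matrix), `center` (numeric length-2, row/col), `phi` (pixels), and
#'   `threshold` (the intensity cut used).
#' @examples
#' img <- matrix(10, 128, 128)
#' img[as.matrix(expand.grid(30:100, 30:100))] <- 200
#' g <- delineate_flat_mount(img)
#' g$phi
#' @export
delineate_flat_mount <- function(image, smooth_frac = 0.025, threshold = NULL,
                                 center = NULL, n_bins = 256L) {
  stopifnot_image(image)
  if (diff(range(image)) <= 0)
    stop("no histogram valley: image is constant", call. = FALSE)
  sigma <- smooth_frac * max(dim(image))
  sm <- if (sigma > 0) filter2_reflect(image, gaussian_kernel(sigma)) else image
  if (is.null(threshold)) {
    threshold <- histogram_valley(sm, n_bins = n_bins)
  }
  fg <- sm > threshold
  if (!any(fg)) stop("flat-mount delineation failed: empty foreground", call. = FALSE)
  fg <- fill_holes(fg)
  lab <- label8(fg)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  phi <- retina_diameter(mask)
  if (is.null(center)) {
    rc <- which(mask, arr.ind = TRUE)
    center <- c(mean(rc[, 1L]), mean(rc[, 2L]))
  }
  center <- as.numeric(center)
  structure(list(mask = mask, center = center, phi = phi,
                 threshold = threshold),
            class = "retina_geometry")
}

# Valley (minimum-count bin) strictly between the two highest histogram
# peaks of the smoothed image. Peaks are local maxima of the bin counts;
# ties in the valley go to the lower intensity.
histogram_valley <- function(sm, n_bins = 256L) {
  rng <- range(sm)
  if (diff(rng) <= 0)
    stop("no histogram valley: image is constant", call. = FALSE)
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  cnt <- tabulate(pmin(pmax(findInterval(sm, br, rightmost.closed = TRUE), 1L),
                       n_bins), nbins = n_bins)
  # local maxima (plateau-tolerant): count >= both neighbours, > at least one
  left <- c(-1, cnt[-n_bins]); right <- c(cnt[-1L], -1)
  is_peak <- cnt >= left & cnt >= right & (cnt > left | cnt > right)
  peaks <- which(is_peak)
  if (length(peaks) < 2L)
    stop("no histogram valley: fewer than two peaks", call. = FALSE)
  top2 <- peaks[order(cnt[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  if (hi - lo < 2L)
    stop("no histogram valley: peaks are adjacent", call. = FALSE)
  between <- (lo + 1L):(hi - 1L)
  valley <- between[which.min(cnt[between])]   # which.min takes first = lower
  (br[valley] + br[valley + 1L]) / 2
}

#' Equivalent-circle diameter of a mask
#'
#' The flat-mount diameter is defined as the diameter of the circle with the
#' same area as the mask, `2 * sqrt(area / pi)`; this is robust to the
#' petal-lobed outline of cut flat mounts.
#' @param mask logical matrix (or a `retina_geometry`).
#' @return diameter in pixels.
#' @examples
#' retina_diameter(matrix(TRUE, 1, 1))  # 2 / sqrt(pi)
#' @export
retina_diameter <- function(mask) {
  if (inherits(mask, "retina_geometry")) mask <- mask$mask
  a <- sum(mask)
  if (a == 0L) stop("empty mask", call. = FALSE)
  2 * sqrt(a / pi)
}

dist_to_center <- function(dim, center) {
  dr <- seq_len(dim[1L]) - center[1L]
  dc <- seq_len(dim[2L]) - center[2L]
  sqrt(outer(dr^2, dc^2, `+`))
}

#' Annular analysis region
#'
#' Pixels whose distance to the optic-nerve centre lies in
#' `[inner_frac * phi/2, outer_frac * phi/2)`, intersected with the retina
#' mask. Tuft analysis is restricted to the 0.2-0.8 phi annulus to avoid the
#' central zone and the cut sample edges.
#' @param geom a `retina_geometry`.
#' @param inner_frac,outer_frac inner/outer diameters as fractions of `phi`.
#' @return an `oir_roi` object: list with `mask`, `kind`, `inner_frac`,
#'   `outer_frac`.
#' @export
make_annulus <- function(geom, inner_frac = 0.2, outer_frac = 0.8) {
  stopifnot(inherits(geom, "retina_geometry"))
  if (!(inner_frac >= 0 && inner_frac < outer_frac))
    stop("need 0 <= inner_frac < outer_frac", call. = FALSE)
  d <- dist_to_center(dim(geom$mask), geom$center)
  mask <- d >= inner_frac * geom$phi / 2 & d < outer_frac * geom$phi / 2 &
    geom$mask
  structure(list(mask = mask, kind = "annulus",
                 inner_frac = inner_frac, outer_frac = outer_frac),
            class = "oir_roi")
}

#' Central disk region for avascular analysis
#'
#' Pixels closer to the optic-nerve centre than `diam_frac * phi / 2`,
#' intersected with the retina mask.
#' @param geom a `retina_geometry`.
#' @param diam_frac disk diameter as a fraction of `phi` (default 0.6).
#' @return an `oir_roi` object.
#' @export
make_central_disk <- function(geom, diam_frac = 0.6) {
  stopifnot(inherits(geom, "retina_geometry"))
  if (diam_frac <= 0) stop("diam_frac must be positive", call. = FALSE)
  d <- dist_to_center(dim(geom$mask), geom$center)
  mask <- d < diam_frac * geom$phi / 2 & geom$mask
  structure(list(mask = mask, kind = "central_disk", diam_frac = diam_frac),
            class = "oir_roi")
}

roi_mask <- function(roi) {
  if (inherits(roi, "oir_roi")) roi$mask else roi
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat("Flat-mount geometry\n")
  cat(sprintf("  image: %d x %d px, mask area %d px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  cat(sprintf("  phi (equivalent diameter): %.1f px\n", x$phi))
  cat(sprintf("  center (row, col): %.1f, %.1f\n", x$center[1L], x$center[2L]))
  invisible(x)
}

#' @export
print.oir_roi <- function(x, ...) {
  cat(sprintf("ROI (%s): %d px\n", x$kind, sum(x$mask)))
  invisible(x)
}
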