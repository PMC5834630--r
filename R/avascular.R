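# Avascular (vaso-obliterated) zones: vessel-free regions whose farthest
# point from the vessel skeleton exceeds 1% of the flat-mount diameter,
# measured inside a central circular region of interest.

#' Delineate avascular zones
#'
#' The skeleton indicator is blurred with a Gaussian of standard deviation
#' `sigma_frac * phi` (discarding small details), binarized with a Bradley
#' threshold (window `round(phi / 50)`, sensitivity 1), and the 8-connected
#' background objects inside the ROI become candidates. For each candidate
#' the maximum Euclidean distance to the nearest *original* skeleton pixel
#' is computed; objects whose maximum strictly exceeds `dist_frac * phi` are
#' kept. The union is smoothed by a morphological closing (disk radius
#' `round(close_frac * phi)`) then opening (`round(open_frac * phi)`).
#'
#' An empty skeleton means the whole ROI is avascular (infinite distance
#' convention); a warning is emitted.
#'
#' @param skel a `skeleton_graph` (or logical skeleton matrix).
#' @param geom a `retina_geometry`.
#' @param roi an `oir_roi`; default: central disk of diameter `0.6 * phi`.
#' @param sigma_frac skeleton smoothing scale (default 1/250 of `phi`).
#' @param dist_frac distance criterion (default 0.01 of `phi`, strict).
#' @param close_frac,open_frac cleanup disk radii as fractions of `phi`.
#' @return object of class `avascular_map`: list with `final_mask`,
#'   `area_px`, `area_frac_of_retina`, `objects` (data.frame `label`,
#'   `area_px`, `max_dist_px`, `kept`), `candidate_labels` (matrix).
#' @export
avascular_zones <- function(skel, geom, roi = NULL, sigma_frac = 1 / 250,
                            dist_frac = 0.01, close_frac = 0.005,
                            open_frac = 0.0025) {
  skmask <- if (inherits(skel, "skeleton_graph")) skel$skeleton else skel
  stopifnot(inherits(geom, "retina_geometry"))
  if (is.null(roi)) roi <- make_central_disk(geom, 0.6)
  rmask <- roi_mask(roi)
  phi <- geom$phi
  if (!any(skmask)) {
    warning("empty skeleton: entire ROI reported avascular")
    return(structure(list(final_mask = rmask, area_px = sum(rmask),
                          area_frac_of_retina = sum(rmask) / sum(geom$mask),
                          objects = data.frame(label = integer(),
                                               area_px = integer(),
                                               max_dist_px = numeric(),
                                               kept = logical()),
                          candidate_labels = matrix(0L, nrow(rmask),
                                                    ncol(rmask))),
                     class = "avascular_map"))
  }
  blur <- filter2_reflect(skmask * 1, gaussian_kernel(sigma_frac * phi))
  # far from any skeleton pixel the blurred field is pure FFT round-off;
  # floor it to exact zero so the strict Bradley comparison cannot speckle
  blur[blur < 1e-9 * max(blur)] <- 0
  veins <- bradley_threshold(blur, max(3L, round(phi / 50)), sensitivity = 1)
  bg <- rmask & !veins
  lab <- label8(bg)
  # exact EDT to the original skeleton
  dist <- matrix(as.numeric(EBImage::distmap(EBImage::Image((!skmask) * 1),
                                             metric = "euclidean")),
                 nrow(skmask), ncol(skmask))
  nlab <- max(lab)
  objects <- data.frame(label = integer(), area_px = integer(),
                        max_dist_px = numeric(), kept = logical())
  final <- matrix(FALSE, nrow(rmask), ncol(rmask))
  if (nlab > 0L) {
    l <- lab[lab > 0L]
    dmax <- tapply(dist[lab > 0L], l, max)
    areas <- tabulate(l, nbins = nlab)
    kept <- as.numeric(dmax) > dist_frac * phi
    objects <- data.frame(label = as.integer(names(dmax)),
                          area_px = areas[as.integer(names(dmax))],
                          max_dist_px = as.numeric(dmax), kept = kept)
    keep_ids <- objects$label[objects$kept]
    if (length(keep_ids))
      final <- matrix(lab %in% keep_ids, nrow(lab), ncol(lab))
  }
  if (any(final)) {
    cr <- round(close_frac * phi)
    or <- round(open_frac * phi)
    f <- final * 1
    if (cr >= 1) f <- EBImage::closing(f, disk_kernel(cr) * 1)
    if (or >= 1) f <- EBImage::opening(f, disk_kernel(or) * 1)
    final <- matrix(as.numeric(f) > 0.5, nrow(final), ncol(final)) & rmask
  }
  structure(list(final_mask = final, area_px = sum(final),
                 area_frac_of_retina = sum(final) / sum(geom$mask),
                 objects = objects, candidate_labels = lab),
            class = "avascular_map")
}

#' @export
print.avascular_map <- function(x, ...) {
  cat("Avascular zones\n")
  cat(sprintf("  candidate objects: %d, kept: %d\n",
              nrow(x$objects), sum(x$objects$kept)))
  cat(sprintf("  final area: %d px (%.3f%% of retina)\n",
              x$area_px, 100 * x$area_frac_of_retina))
  invisible(x)
}
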