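# Seeded generator of flat-mount-like images with exact ground truth.
#
# The goal is not photorealism: every planted structure (vessel tree with
# known branch points and drawn length, capillary mesh, bright textured tuft
# blobs, vessel-free discs) is recorded exactly so each pipeline stage can be
# validated without real data. Vessel trees grow outward from a ring around
# the optic-nerve centre by recursive branching with midpoint-displaced
# segments; children colliding with already-drawn vessels are redrawn or
# dropped so the drawn topology always equals the recorded one.

#' Parameters for the synthetic flat-mount generator
#'
#' Defaults emulate a typical severity mid-range OIR flat mount at reduced
#' scale: a lobed circular retina, six first-order vessels branching
#' recursively, a handful of bright speckled tufts, smooth uneven
#' illumination and mild additive noise.
#'
#' @param phi target flat-mount diameter in pixels (>= 256).
#' @param margin_frac image padding around the retina.
#' @param lobe_amp,n_lobes amplitude / count of the petal-like boundary lobes.
#' @param background,outside_level base intensities inside / outside the
#'   retina (arbitrary units in `[0, 1]`).
#' @param vessel_value added intensity of vessels.
#' @param vessel_width trunk stroke width in pixels (>= 3; tapers with
#'   branching level).
#' @param n_trunks first-order vessels leaving the optic-nerve ring.
#' @param depth branching generations per trunk (each split is a recorded
#'   branch point).
#' @param seg_len_frac first-segment length as a fraction of `phi`.
#' @param n_tufts number of tuft clusters (0 disables).
#' @param tuft_value peak added intensity of tufts.
#' @param tuft_r_frac length-2 range of tuft blob radii as fractions of `phi`.
#' @param avascular list of vessel-free discs, each `c(dr, dc, r)` in
#'   fractions of `phi` (offset from centre, radius). `NULL` for none.
#' @param capillary_spacing_frac spacing of the fine capillary mesh as a
#'   fraction of `phi`; `NULL` disables the mesh.
#' @param capillary_width mesh stroke width in pixels.
#' @param illumination_amp relative amplitude of the smooth gradient +
#'   vignette field (0 disables).
#' @param mottle_amp relative amplitude of the fine-scale background mottle
#'   (tissue autofluorescence texture; correlation length ~2% of `phi`;
#'   0 disables). Without it the background is implausibly flat and the
#'   minima-based local background model sits at a degenerate margin.
#' @param noise_sd additive Gaussian noise standard deviation (0 disables).
#' @param saturate clip intensities at 1 (stress option).
#' @param bleach_patches number of photobleached (dimmed) discs (stress
#'   option).
#' @return list of class `synth_params`.
#' @export
synth_params <- function(phi = 512, margin_frac = 0.08, lobe_amp = 0.05,
                         n_lobes = 4L, background = 0.15,
                         outside_level = 0.02, vessel_value = 0.55,
                         vessel_width = 5L, n_trunks = 6L, depth = 3L,
                         seg_len_frac = 0.16, n_tufts = 6L,
                         tuft_value = 0.75, tuft_r_frac = c(0.012, 0.022),
                         avascular = NULL, capillary_spacing_frac = NULL,
                         capillary_width = 3L, illumination_amp = 0.15,
                         mottle_amp = 0.12, noise_sd = 0.02, saturate = FALSE,
                         bleach_patches = 0L) {
  if (phi < 256) stop("phi must be >= 256 for meaningful size fractions")
  if (vessel_width < 3L) stop("vessel width must be >= 3 px")
  structure(as.list(environment()), class = "synth_params")
}

#' Generate a synthetic flat mount with ground truth
#'
#' @param params a [synth_params()] list.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return object of class `synthetic_retina`: list with `image`,
#'   `truth_vessels`, `truth_tufts`, `truth_avascular` (logical matrices),
#'   `geometry` (a `retina_geometry` built from the planted mask),
#'   `branch_points` (matrix), `n_branch_points`, `total_drawn_length_px`,
#'   `params`, `seed`.
#' @export
generate_retina <- function(params = synth_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(as.integer(seed), build_retina(params, as.integer(seed)))
}

build_retina <- function(p, seed) {
  phi <- p$phi
  n <- ceiling(phi * (1 + 2 * p$margin_frac))
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  # lobed boundary with area matched to a phi-diameter disk
  dr <- outer(seq_len(n) - ctr[1L], rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - ctr[2L])
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  phase <- stats::runif(1L, 0, 2 * pi)
  r0 <- (phi / 2) / sqrt(1 + p$lobe_amp^2 / 2)
  mask <- rad <= r0 * (1 + p$lobe_amp * cos(p$n_lobes * theta + phase))
  if (sum(mask) < 100) stop("degenerate retina mask")

  # vessel-free discs (clearance keeps strokes out; a rim vessel bounds them)
  av_discs <- NULL
  truth_av <- matrix(FALSE, n, n)
  if (!is.null(p$avascular)) {
    av_discs <- do.call(rbind, lapply(p$avascular, function(a)
      c(ctr[1L] + a[1L] * phi, ctr[2L] + a[2L] * phi, a[3L] * phi)))
    for (i in seq_len(nrow(av_discs)))
      truth_av <- truth_av |
        (sqrt((dr - (av_discs[i, 1L] - ctr[1L]))^2 +
                (dc - (av_discs[i, 2L] - ctr[2L]))^2) <
           av_discs[i, 3L] - p$capillary_width / 2)
    truth_av <- truth_av & mask
  }

  tree <- grow_tree(p, n, ctr, mask, av_discs)
  vessels <- tree$mask

  if (!is.null(p$capillary_spacing_frac)) {
    vessels <- vessels | draw_mesh(p, n, ctr, mask, av_discs)
  }
  if (!is.null(av_discs)) {
    # vessel-free zones are bounded by a dense vascular front (as in the
    # regrowing OIR plexus): several tightly spaced rings at the rim
    ring_gap <- max(2 * p$capillary_width, round(0.006 * phi))
    for (i in seq_len(nrow(av_discs))) {
      for (k in 0:2)
        vessels <- vessels |
          draw_ring(n, av_discs[i, 1:2], av_discs[i, 3L] + k * ring_gap,
                    p$capillary_width)
    }
  }
  vessels <- vessels & mask

  # tufts: clusters of overlapping bright discs with speckle texture
  truth_tufts <- matrix(FALSE, n, n)
  tuft_field <- matrix(0, n, n)
  if (p$n_tufts > 0L) {
    tf <- place_tufts(p, n, ctr, phi, truth_av)
    truth_tufts <- tf$mask & mask
    tuft_field <- tf$field
  }

  illum <- matrix(1, n, n)
  if (p$illumination_amp > 0) {
    ramp_dir <- stats::runif(1L, 0, 2 * pi)
    ramp <- (cos(ramp_dir) * dc + sin(ramp_dir) * dr) / phi
    vignette <- -0.5 * (rad / (phi / 2))^2
    illum <- 1 + p$illumination_amp * (ramp + vignette)
  }
  if (p$mottle_amp > 0) {
    # fine-scale background texture (autofluorescence mottle); unit-sd
    # Gaussian random field with correlation length ~2% of phi
    fld <- matrix(stats::runif(n * n, -1, 1), n, n)
    fld <- filter2_reflect(fld, gaussian_kernel(0.02 * phi))
    fld <- fld / stats::sd(fld)
    illum <- illum * (1 + p$mottle_amp * pmax(pmin(fld, 2.5), -2.5) / 2.5)
  }

  img <- matrix(p$outside_level, n, n)
  signal <- p$background + p$vessel_value * (vessels * 1) + tuft_field
  img[mask] <- (signal * illum)[mask]
  if (p$bleach_patches > 0L) {
    for (b in seq_len(p$bleach_patches)) {
      bc <- ctr + stats::runif(2L, -0.3, 0.3) * phi
      br <- stats::runif(1L, 0.04, 0.08) * phi
      patch <- sqrt((dr - (bc[1L] - ctr[1L]))^2 +
                      (dc - (bc[2L] - ctr[2L]))^2) < br
      img[patch] <- img[patch] * 0.6
    }
  }
  if (p$noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
  img <- pmax(img, 0)
  if (p$saturate) img <- pmin(img, 1)

  geometry <- structure(list(mask = mask, center = ctr,
                             phi = retina_diameter(mask), threshold = NA_real_),
                        class = "retina_geometry")
  structure(list(image = img, truth_vessels = vessels,
                 truth_tufts = truth_tufts, truth_avascular = truth_av,
                 geometry = geometry,
                 branch_points = tree$branch_points,
                 n_branch_points = nrow(tree$branch_points),
                 total_drawn_length_px = tree$total_length,
                 params = p, seed = seed),
            class = "synthetic_retina")
}

# --- vessel tree ------------------------------------------------------------

# Stamp a thick stroke along p0 -> p1 into mask; returns pixels drawn.
stroke_pixels <- function(n, p0, p1, width) {
  len <- sqrt(sum((p1 - p0)^2))
  steps <- max(2L, ceiling(len / 0.5))
  t <- seq(0, 1, length.out = steps)
  cr <- p0[1L] + t * (p1[1L] - p0[1L])
  cc <- p0[2L] + t * (p1[2L] - p0[2L])
  r <- width / 2
  ir <- floor(-r):ceiling(r)
  offs <- as.matrix(expand.grid(dr = ir, dc = ir))
  offs <- offs[offs[, 1L]^2 + offs[, 2L]^2 <= r^2, , drop = FALSE]
  rr <- rep(round(cr), each = nrow(offs)) + offs[, 1L]
  cc2 <- rep(round(cc), each = nrow(offs)) + offs[, 2L]
  ok <- rr >= 1L & rr <= n & cc2 >= 1L & cc2 <= n
  cbind(rr[ok], cc2[ok])
}

# Midpoint-displaced polyline between a and b (two subdivision levels).
wiggle_polyline <- function(a, b, amp) {
  subdivide <- function(pts, amp) {
    out <- pts[1L, , drop = FALSE]
    for (i in seq_len(nrow(pts) - 1L)) {
      p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
      mid <- (p0 + p1) / 2
      d <- p1 - p0
      nrm <- c(-d[2L], d[1L]) / max(sqrt(sum(d^2)), 1e-9)
      mid <- mid + nrm * stats::runif(1L, -amp, amp)
      out <- rbind(out, mid, p1)
    }
    out
  }
  pts <- rbind(a, b)
  pts <- subdivide(pts, amp)
  subdivide(pts, amp / 2)
}

angle_wrap <- function(a) atan2(sin(a), cos(a))

grow_tree <- function(p, n, ctr, retina, av_discs) {
  phi <- p$phi
  mask <- matrix(FALSE, n, n)
  branch_points <- NULL
  total_length <- 0
  base_r <- 0.04 * phi
  trunk_angles <- seq(0, 2 * pi, length.out = p$n_trunks + 1L)[-(p$n_trunks + 1L)] +
    stats::runif(p$n_trunks, -0.15, 0.15)
  # strokes are kept clear of the retina boundary so no stroke is ever cut
  # by the outline (clipping would create fragments the recorded topology
  # does not know about)
  safe <- matrix(as.numeric(EBImage::erode(retina * 1,
                                           disk_kernel(p$vessel_width + 2L) * 1)) > 0.5,
                 n, n)

  blocked <- function(b) {
    if (is.null(av_discs)) return(FALSE)
    any(sqrt((b[1L] - av_discs[, 1L])^2 + (b[2L] - av_discs[, 2L])^2) <
          av_discs[, 3L] + p$capillary_width + p$vessel_width)
  }
  # a straight sub-stroke can cross a vessel-free disc even when its
  # endpoints are clear, so the path is sampled every few pixels
  path_blocked <- function(a, b) {
    if (is.null(av_discs)) return(FALSE)
    len <- sqrt(sum((b - a)^2))
    for (t in seq(0, 1, length.out = max(2L, ceiling(len / 3)))) {
      if (blocked(a + t * (b - a))) return(TRUE)
    }
    FALSE
  }

  # Draw one midpoint-displaced segment with collision staging: sub-strokes
  # are accepted only while they stay inside the safe region and clear of
  # previously drawn vessels (beyond a start exclusion where merging with
  # the parent and siblings is legitimate). A collision in the first half
  # drops the segment entirely, so the drawn tree topology always equals
  # the recorded one.
  draw_segment <- function(start, ang, len, width) {
    end <- start + len * c(sin(ang), cos(ang))
    poly <- wiggle_polyline(start, end, amp = 0.03 * len)
    excl_r2 <- (3 * width)^2
    staged <- list()
    drawn_len <- 0
    last <- start
    complete <- TRUE
    n_sub <- nrow(poly) - 1L
    for (i in seq_len(n_sub)) {
      a <- poly[i, ]; b <- poly[i + 1L, ]
      inb <- b[1L] >= 1 && b[1L] <= n && b[2L] >= 1 && b[2L] <= n &&
        safe[round(b[1L]), round(b[2L])]
      if (!inb || path_blocked(a, b)) { complete <- FALSE; break }
      wide <- stroke_pixels(n, a, b, width + 3)
      far <- (wide[, 1L] - start[1L])^2 + (wide[, 2L] - start[2L])^2 > excl_r2
      if (any(mask[wide[far, , drop = FALSE]])) {
        if (i <= ceiling(n_sub / 2)) return(list(len = 0))
        complete <- FALSE
        break
      }
      staged[[i]] <- stroke_pixels(n, a, b, width)
      drawn_len <- drawn_len + sqrt(sum((b - a)^2))
      last <- b
    }
    if (drawn_len < 3) return(list(len = 0))
    for (px in staged) if (!is.null(px)) mask[px] <<- TRUE
    list(end = last, len = drawn_len, complete = complete)
  }

  # returns TRUE if the branch drew a substantial stroke
  grow <- function(start, ang, level) {
    len <- p$seg_len_frac * phi * 0.78^level
    width <- max(3L, p$vessel_width - level)
    seg <- draw_segment(start, ang, len, width)
    if (seg$len == 0) return(FALSE)
    total_length <<- total_length + seg$len
    if (!seg$complete || level >= p$depth) return(TRUE)
    # radially outward reference direction at the node
    radial <- atan2(seg$end[1L] - ctr[1L], seg$end[2L] - ctr[2L])
    offs <- stats::runif(2L, 0.30, 0.62)   # ~17-36 degrees each side
    kids <- 0L
    for (s in c(-1, 1)) {
      ca <- angle_wrap(ang + s * offs[if (s < 0) 1L else 2L])
      # keep growth outward: clamp to +-0.9 rad of the radial direction
      dlt <- angle_wrap(ca - radial)
      if (abs(dlt) > 0.9) ca <- angle_wrap(radial + sign(dlt) * 0.9)
      kids <- kids + grow(seg$end, ca, level + 1L)
    }
    if (kids >= 2L)
      branch_points <<- rbind(branch_points, round(seg$end))
    TRUE
  }

  for (i in seq_len(p$n_trunks)) {
    a0 <- trunk_angles[i]
    start <- ctr + base_r * c(sin(a0), cos(a0))
    # when a vessel-free zone covers the centre, first-order vessels
    # radiate from just outside it
    tries <- 0L
    while (blocked(start) && tries < 200L) {
      start <- start + 3 * c(sin(a0), cos(a0))
      tries <- tries + 1L
    }
    grow(start, a0, 0L)
  }
  if (is.null(branch_points)) branch_points <- matrix(numeric(), 0L, 2L)
  colnames(branch_points) <- c("row", "col")
  list(mask = mask, branch_points = branch_points, total_length = total_length)
}

# Square capillary lattice clipped to the retina and outside vessel-free
# discs; drawn with thin strokes so its skeleton is a fine mesh.
draw_mesh <- function(p, n, ctr, retina, av_discs) {
  s <- max(4L, round(p$capillary_spacing_frac * p$phi))
  off <- stats::runif(2L, 0, s)
  mesh <- matrix(FALSE, n, n)
  w <- p$capillary_width
  h <- floor(w / 2)
  for (r in seq(1 + off[1L], n, by = s)) {
    rr <- max(1L, round(r) - h):min(n, round(r) + h)
    mesh[rr, ] <- TRUE
  }
  for (c in seq(1 + off[2L], n, by = s)) {
    cc <- max(1L, round(c) - h):min(n, round(c) + h)
    mesh[, cc] <- TRUE
  }
  mesh <- mesh & retina
  if (!is.null(av_discs)) {
    dr <- outer(seq_len(n), rep(1, n)) ; dc <- t(dr)
    for (i in seq_len(nrow(av_discs))) {
      d <- sqrt((dr - av_discs[i, 1L])^2 + (dc - av_discs[i, 2L])^2)
      # clip the mesh only inside the rim band so mesh and rim vessels meet
      # without a vessel-free channel around the disc
      mesh[d < av_discs[i, 3L] - w / 2] <- FALSE
    }
  }
  mesh
}

draw_ring <- function(n, center, radius, width) {
  dr <- outer(seq_len(n), rep(1, n)); dc <- t(dr)
  d <- sqrt((dr - center[1L])^2 + (dc - center[2L])^2)
  abs(d - radius) <= width / 2
}

place_tufts <- function(p, n, ctr, phi, truth_av) {
  mask <- matrix(FALSE, n, n)
  field <- matrix(0, n, n)
  dr <- outer(seq_len(n), rep(1, n)); dc <- t(dr)
  rmax <- p$tuft_r_frac[2L] * phi
  centers <- NULL
  attempts <- 0L
  while ((is.null(centers) || nrow(centers) < p$n_tufts) && attempts < 200L) {
    attempts <- attempts + 1L
    ang <- stats::runif(1L, 0, 2 * pi)
    rad <- stats::runif(1L, 0.25, 0.70) * phi / 2
    cand <- ctr + rad * c(sin(ang), cos(ang))
    if (any(truth_av[max(1, round(cand[1L])), max(1, round(cand[2L]))]))
      next
    if (!is.null(centers) &&
        any(sqrt((centers[, 1L] - cand[1L])^2 +
                   (centers[, 2L] - cand[2L])^2) < 5 * rmax))
      next
    centers <- rbind(centers, cand)
  }
  if (is.null(centers)) return(list(mask = mask, field = field))
  for (i in seq_len(nrow(centers))) {
    nb <- sample(2:4, 1L)
    for (b in seq_len(nb)) {
      r <- stats::runif(1L, p$tuft_r_frac[1L], p$tuft_r_frac[2L]) * phi
      cc <- centers[i, ] + stats::runif(2L, -0.7, 0.7) * r
      d <- sqrt((dr - cc[1L])^2 + (dc - cc[2L])^2)
      mask <- mask | (d < r)
    }
  }
  # speckle texture: smoothed uniform noise, zero mean, scale ~2 px
  spk <- matrix(stats::runif(n * n, -1, 1), n, n)
  spk <- filter2_reflect(spk, gaussian_kernel(1))
  spk <- spk / max(abs(spk))
  field[mask] <- p$tuft_value * (1 + 0.4 * spk[mask])
  field <- pmax(field, 0)
  list(mask = mask, field = field)
}

#' Perturbed annotator masks from a ground truth
#'
#' Emulates inter-evaluator variability for testing consensus and error
#' metrics: each evaluator's mask is the truth with a random boundary
#' dilation or erosion (up to `boundary_px`, disk element) and random
#' whole-object dropout.
#' @param truth logical matrix.
#' @param n_evaluators number of annotators (default 6).
#' @param error_model list with `boundary_px` (max |dilation|, 0 disables),
#'   `dropout_prob` (per-object omission probability) and optionally
#'   `dilate_px` (a fixed signed dilation applied to every evaluator instead
#'   of a random one).
#' @param seed integer seed.
#' @return list of logical matrices of length `n_evaluators`.
#' @export
generate_annotations <- function(truth, n_evaluators = 6L,
                                 error_model = list(boundary_px = 2L,
                                                    dropout_prob = 0.1),
                                 seed = 1L) {
  if (n_evaluators < 1L) stop("need at least one evaluator")
  bp <- error_model$boundary_px %||% 0L
  dp <- error_model$dropout_prob %||% 0
  withr::with_seed(as.integer(seed), {
    lab <- label8(truth)
    nlab <- max(lab)
    lapply(seq_len(n_evaluators), function(e) {
      m <- truth
      if (nlab > 0L && dp > 0) {
        drop <- which(stats::runif(nlab) < dp)
        if (length(drop)) m <- m & !(matrix(lab %in% drop, nrow(m), ncol(m)))
      }
      fixed <- error_model$dilate_px
      if (!is.null(fixed) || bp > 0L) {
        amt <- if (!is.null(fixed)) as.integer(fixed)
               else sample(seq(-bp, bp), 1L)
        if (amt > 0L) {
          m <- matrix(as.numeric(EBImage::dilate(m * 1, disk_kernel(amt) * 1)) > 0.5,
                      nrow(m), ncol(m))
        } else if (amt < 0L) {
          m <- matrix(as.numeric(EBImage::erode(m * 1, disk_kernel(-amt) * 1)) > 0.5,
                      nrow(m), ncol(m))
        }
      }
      m
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_retina <- function(x, ...) {
  cat("Synthetic flat mount\n")
  cat(sprintf("  image: %d x %d px, phi = %.1f px, seed = %d\n",
              nrow(x$image), ncol(x$image), x$geometry$phi, x$seed))
  cat(sprintf("  vessels: %d px, branch points: %d, drawn length: %.0f px\n",
              sum(x$truth_vessels), x$n_branch_points,
              x$total_drawn_length_px))
  cat(sprintf("  tufts: %d px, avascular: %d px\n",
              sum(x$truth_tufts), sum(x$truth_avascular)))
  invisible(x)
}
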