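# Tuft segmentation: consensus ground truth from several annotators, tile
# labelling, QDA prediction, and a local-background thickness validation that
# removes bright-vessel false positives.

#' Majority-vote consensus of annotator masks
#'
#' A pixel belongs to the consensus iff at least `quorum` of the masks mark
#' it (default: at least 4 of 6 evaluators).
#' @param masks list of logical matrices, one per evaluator.
#' @param quorum minimum number of votes.
#' @return logical matrix.
#' @export
consensus_mask <- function(masks, quorum = 4L) {
  if (!length(masks)) stop("no annotation masks", call. = FALSE)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("annotation masks have mismatched shapes", call. = FALSE)
  if (quorum < 1L || quorum > length(masks))
    stop("quorum must be between 1 and the number of masks", call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  votes >= quorum
}

#' Label training tiles from a consensus mask
#'
#' A tile is labelled `"tuft"` iff strictly more than `min_frac` of its
#' pixels lie in the consensus ("more than 25%"); only tiles inside the
#' analysis ROI receive a label.
#' @param tiles a `feature_tiles` table ([tile_features()]).
#' @param consensus logical matrix.
#' @param min_frac consensus fraction threshold (default 0.25, strict).
#' @return the tile table with `label` filled for `inside_roi` tiles.
#' @export
label_training_tiles <- function(tiles, consensus, min_frac = 0.25) {
  dims <- attr(tiles, "image_dim")
  if (!is.null(dims) && any(dim(consensus) != dims))
    stop("consensus mask shape does not match the tiled image", call. = FALSE)
  lab <- tiles$label
  for (t in which(tiles$inside_roi)) {
    rs <- (tiles$row0[t] + 1L):min(tiles$row0[t] + tiles$side[t],
                                   nrow(consensus))
    cs <- (tiles$col0[t] + 1L):min(tiles$col0[t] + tiles$side[t],
                                   ncol(consensus))
    frac <- mean(consensus[rs, cs])
    lab[t] <- if (frac > min_frac) "tuft" else "normal"
  }
  tiles$label <- lab
  tiles
}

#' Predict tuft tiles with a trained QDA model
#'
#' Applies the classifier to every tile inside the ROI; tiles outside are
#' labelled `"normal"`.
#' @param model an `oir_qda` model trained on the five tile features.
#' @param tiles a `feature_tiles` table.
#' @return the tile table with predicted labels.
#' @export
predict_tuft_tiles <- function(model, tiles) {
  stopifnot(inherits(model, "oir_qda"))
  if (ncol(model$means) != length(feature_columns))
    stop("feature dimension mismatch", call. = FALSE)
  tiles$label <- factor(rep("normal", nrow(tiles)),
                        levels = levels(tiles$label))
  ins <- which(tiles$inside_roi)
  if (length(ins)) {
    x <- as.matrix(tiles[ins, feature_columns])
    tiles$label[ins] <- qda_classify(model, x)
  }
  tiles
}

#' Validate predicted tufts against the local background
#'
#' Tufts are thicker than vessels: within each QDA-positive tile, a pixel is
#' kept only when the fraction of pixels above the local background
#' threshold (`I_b + k * sigma_b`) in a square neighbourhood around it
#' strictly exceeds `min_above_frac`. A thin bright vessel fills only a small
#' part of any neighbourhood and is discarded; a tuft fills most of it.
#'
#' @param tiles a `feature_tiles` table with predicted labels.
#' @param image the intensity image the background model was estimated from
#'   (same scale).
#' @param background a `background_model`.
#' @param geom a `retina_geometry`.
#' @param neighborhood_frac square neighbourhood side as a fraction of `phi`
#'   (default 0.01, the tile scale).
#' @param min_above_frac minimum above-background fraction (default 0.80,
#'   strict).
#' @return object of class `tuft_result`: list with `validated_mask`,
#'   `qda_mask` (pre-validation tile mask), `tuft_area_px`,
#'   `tuft_area_frac_of_retina`, `tiles`.
#' @export
validate_tufts <- function(tiles, image, background, geom,
                           neighborhood_frac = 0.01, min_above_frac = 0.80) {
  stopifnot_image(image)
  stopifnot(inherits(background, "background_model"),
            inherits(geom, "retina_geometry"))
  dims <- dim(image)
  qda_mask <- tiles_to_mask(tiles, which(tiles$label == "tuft" &
                                           tiles$inside_roi), dims)
  w <- max(1L, round(neighborhood_frac * geom$phi))
  above <- (image > background$threshold) * 1
  frac_above <- box_mean(above, w)
  validated <- qda_mask & frac_above > min_above_frac
  area <- sum(validated)
  structure(list(validated_mask = validated, qda_mask = qda_mask,
                 tuft_area_px = area,
                 tuft_area_frac_of_retina = area / sum(geom$mask),
                 tiles = tiles,
                 neighborhood_px = w, min_above_frac = min_above_frac),
            class = "tuft_result")
}

#' @export
print.tuft_result <- function(x, ...) {
  cat("Tuft segmentation\n")
  cat(sprintf("  QDA-positive area: %d px\n", sum(x$qda_mask)))
  cat(sprintf("  validated tuft area: %d px (%.3f%% of retina)\n",
              x$tuft_area_px, 100 * x$tuft_area_frac_of_retina))
  invisible(x)
}

#' Pixel-level segmentation error against a ground truth
#'
#' False positives plus false negatives, reported absolutely and as a
#' percentage of the ground-truth pixel count (the relative-error statistic
#' used to benchmark manual and automatic segmentations).
#' @param predicted,truth logical matrices of equal shape.
#' @return object of class `error_report`: list with `false_pos_px`,
#'   `false_neg_px`, `relative_error_pct` (`NA` with `empty_truth = TRUE`
#'   when the truth mask is empty).
#' @export
segmentation_error <- function(predicted, truth) {
  if (any(dim(predicted) != dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tp <- sum(truth)
  structure(list(false_pos_px = fp, false_neg_px = fn,
                 relative_error_pct = if (tp > 0) 100 * (fp + fn) / tp else NA_real_,
                 empty_truth = tp == 0L),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Segmentation error: FP %d px, FN %d px, relative %s\n",
              x$false_pos_px, x$false_neg_px,
              if (is.na(x$relative_error_pct)) "undefined (empty truth)"
              else sprintf("%.1f%%", x$relative_error_pct)))
  invisible(x)
}
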