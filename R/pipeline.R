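# End-to-end orchestration: geometry -> background -> features -> tufts
# (when a classifier is supplied) -> vessels -> avascular, with a flat JSON
# configuration whose size parameters are all fractions of the flat-mount
# diameter.

#' Default pipeline configuration
#'
#' Every size parameter is a fraction of the flat-mount diameter `phi`, so a
#' single configuration applies across magnifications. Values are the
#' method's defaults; any entry can be overridden via `...`.
#' @param ... named overrides.
#' @return list of class `oir_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    smooth_frac = 0.025,          # geometry: Gaussian sd / image size
    annulus_inner_frac = 0.2,     # tuft analysis annulus
    annulus_outer_frac = 0.8,
    central_roi_frac = 0.6,       # avascular region of interest
    tile_frac = 0.01,             # feature tile side
    square_kernel_frac = 1 / 8,   # local-intensity normalization window
    log_sigma_frac = 1 / 60,      # LoG scale
    lbp_R = 1,                    # LBP circle radius (px)
    lbp_U = 0.01,                 # LBP difference threshold
    rescale_low_frac = 0.01,      # saturating rescale tails
    rescale_high_frac = 0.01,
    background_window_frac = 0.07,
    background_k_sigma = 3,
    background_levels = 10L,
    background_decimate = 8L,
    bradley_window_frac = 1 / 50,
    bradley_sensitivity = 1.15,
    min_object_px = 25L,
    prune_frac = 0.005,
    skeleton_smooth_frac = 1 / 250,
    avascular_dist_frac = 0.01,
    avascular_close_frac = 0.005,
    avascular_open_frac = 0.0025,
    validate_window_frac = 0.01,
    validate_min_above_frac = 0.80,
    train_label_min_frac = 0.25,
    consensus_quorum = 4L,
    cov_mode = "per_class",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("oir_config", "list"))
}

#' Read / write a pipeline configuration as flat JSON
#'
#' @param cfg an `oir_config`.
#' @param path file path.
#' @return `read_config` returns the configuration; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}

#' Run the full analysis pipeline
#'
#' Runs geometry delineation, local-background estimation, vessel
#' segmentation, skeleton metrics and avascular-zone detection; when a
#' trained classifier is given, also tile-feature extraction, tuft
#' prediction and thickness validation. Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param image numeric matrix, or a path readable by [read_gray_image()],
#'   or a `synthetic_retina`.
#' @param model optional `oir_qda` model (or path to a JSON model file); the
#'   tuft stage is skipped when absent.
#' @param config an [default_config()] list.
#' @param out_dir optional directory for artifact files (masks as PNG,
#'   summary and effective configuration as JSON).
#' @return object of class `oir_report`: list with `geometry`, `background`,
#'   `vessels`, `skeleton`, `avascular`, `tufts` (or `NULL`), and `summary`
#'   (named list: `tuft_frac`, `skeleton_frac`, `n_branch_points`,
#'   `total_length_px`, `avascular_frac`).
#' @export
run_pipeline <- function(image, model = NULL, config = default_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "oir_config"))
  if (inherits(image, "synthetic_retina")) image <- image$image
  if (is.character(image)) image <- read_gray_image(image)
  if (is.character(model)) model <- qda_load(model)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  img <- stage("rescale", rescale_saturate(image, config$rescale_low_frac,
                                           config$rescale_high_frac))
  geom <- stage("geometry", delineate_flat_mount(image,
                                                 smooth_frac = config$smooth_frac))
  bg <- stage("background",
              estimate_background(img, geom,
                                  window_frac = config$background_window_frac,
                                  k_sigma = config$background_k_sigma,
                                  n_levels = config$background_levels,
                                  rescale = FALSE,
                                  decimate = config$background_decimate))
  tufts <- NULL
  if (!is.null(model)) {
    annulus <- stage("roi", make_annulus(geom, config$annulus_inner_frac,
                                         config$annulus_outer_frac))
    tiles <- stage("features",
                   tile_features(img, geom, annulus,
                                 cfg = lbp_config(R = config$lbp_R,
                                                  U = config$lbp_U),
                                 tile_frac = config$tile_frac))
    tiles <- stage("tufts", predict_tuft_tiles(model, tiles))
    tufts <- stage("tufts",
                   validate_tufts(tiles, img, bg, geom,
                                  neighborhood_frac = config$validate_window_frac,
                                  min_above_frac = config$validate_min_above_frac))
  }
  vessels <- stage("vessels",
                   segment_vessels(img, geom,
                                   sensitivity = config$bradley_sensitivity,
                                   min_object_px = config$min_object_px))
  skel <- stage("skeleton",
                skeletonize_vessels(vessels, geom,
                                    prune_frac = config$prune_frac))
  central <- stage("roi", make_central_disk(geom, config$central_roi_frac))
  av <- stage("avascular",
              avascular_zones(skel, geom, central,
                              sigma_frac = config$skeleton_smooth_frac,
                              dist_frac = config$avascular_dist_frac,
                              close_frac = config$avascular_close_frac,
                              open_frac = config$avascular_open_frac))
  vm <- vascular_metrics(skel, geom)
  summary <- list(
    tuft_frac = if (is.null(tufts)) NA_real_ else tufts$tuft_area_frac_of_retina,
    skeleton_frac = vm$skeleton_frac,
    n_branch_points = vm$n_branch_points,
    total_length_px = vm$total_length_px,
    avascular_frac = av$area_frac_of_retina)
  report <- structure(list(geometry = geom, background = bg,
                           vessels = vessels, skeleton = skel,
                           avascular = av, tufts = tufts, summary = summary,
                           config = config),
                      class = "oir_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_geometry(report$geometry, out_dir)
  write_mask_png(report$vessels$mask, file.path(out_dir, "vessels.png"))
  write_mask_png(report$skeleton$skeleton, file.path(out_dir, "skeleton.png"))
  write_mask_png(report$avascular$final_mask,
                 file.path(out_dir, "avascular.png"))
  if (!is.null(report$tufts))
    write_mask_png(report$tufts$validated_mask,
                   file.path(out_dir, "tufts.png"))
  utils::write.csv(data.frame(report$skeleton$branch_points),
                   file.path(out_dir, "branch_points.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  write_config(report$config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}

#' @export
print.oir_report <- function(x, ...) {
  cat("Flat-mount analysis report\n")
  s <- x$summary
  cat(sprintf("  skeleton fraction: %.4f, branch points: %d, length: %.0f px\n",
              s$skeleton_frac, s$n_branch_points, s$total_length_px))
  cat(sprintf("  avascular fraction of retina: %.4f\n", s$avascular_frac))
  if (!is.na(s$tuft_frac))
    cat(sprintf("  tuft fraction of retina: %.4f\n", s$tuft_frac))
  invisible(x)
}

#' Two-fold split evaluation of the tuft classifier
#'
#' Splits the images in two halves (first vs second, as in a
#' seven-versus-seven protocol), trains a classifier on the consensus labels
#' of each half and predicts the other, and reports per-image relative
#' segmentation errors against the consensus plus their median.
#'
#' @param images list of numeric matrices (or `synthetic_retina` objects).
#' @param annotations list (one element per image) of lists of annotator
#'   masks.
#' @param config an [default_config()] list.
#' @return list with `per_image` (data.frame: `image`, `fold`,
#'   `relative_error_pct`, `false_pos_px`, `false_neg_px`) and
#'   `median_relative_error_pct`.
#' @export
evaluate_split <- function(images, annotations, config = default_config()) {
  n <- length(images)
  if (n < 2L) stop("need at least 2 images", call. = FALSE)
  if (length(annotations) != n) stop("one annotation set per image required",
                                     call. = FALSE)
  half1 <- seq_len(ceiling(n / 2))
  half2 <- setdiff(seq_len(n), half1)
  prep <- lapply(seq_len(n), function(i) {
    im <- images[[i]]
    if (inherits(im, "synthetic_retina")) im <- im$image
    img <- rescale_saturate(im, config$rescale_low_frac,
                            config$rescale_high_frac)
    geom <- delineate_flat_mount(im, smooth_frac = config$smooth_frac)
    roi <- make_annulus(geom, config$annulus_inner_frac,
                        config$annulus_outer_frac)
    tiles <- tile_features(img, geom, roi,
                           cfg = lbp_config(R = config$lbp_R,
                                            U = config$lbp_U),
                           tile_frac = config$tile_frac)
    cons <- consensus_mask(annotations[[i]], config$consensus_quorum)
    list(img = img, geom = geom, tiles = tiles, consensus = cons)
  })
  train_on <- function(idx) {
    labelled <- lapply(idx, function(i)
      label_training_tiles(prep[[i]]$tiles, prep[[i]]$consensus,
                           config$train_label_min_frac))
    x <- do.call(rbind, lapply(labelled, function(tl)
      as.matrix(tl[tl$inside_roi, feature_columns])))
    y <- unlist(lapply(labelled, function(tl)
      as.character(tl$label[tl$inside_roi])))
    qda_fit(x, y, cov_mode = config$cov_mode)
  }
  res <- vector("list", n)
  for (fold in 1:2) {
    tr <- if (fold == 1L) half2 else half1
    te <- if (fold == 1L) half1 else half2
    model <- train_on(tr)
    for (i in te) {
      pr <- prep[[i]]
      tiles <- predict_tuft_tiles(model, pr$tiles)
      bg <- estimate_background(pr$img, pr$geom,
                                window_frac = config$background_window_frac,
                                k_sigma = config$background_k_sigma,
                                rescale = FALSE,
                                decimate = config$background_decimate)
      tres <- validate_tufts(tiles, pr$img, bg, pr$geom,
                             neighborhood_frac = config$validate_window_frac,
                             min_above_frac = config$validate_min_above_frac)
      err <- segmentation_error(tres$validated_mask, pr$consensus)
      res[[i]] <- data.frame(image = i, fold = fold,
                             relative_error_pct = err$relative_error_pct,
                             false_pos_px = err$false_pos_px,
                             false_neg_px = err$false_neg_px,
                             tuft_frac = tres$tuft_area_frac_of_retina)
    }
  }
  per_image <- do.call(rbind, res)
  list(per_image = per_image,
       median_relative_error_pct = stats::median(per_image$relative_error_pct,
                                                 na.rm = TRUE))
}
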