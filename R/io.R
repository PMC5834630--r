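# Image I/O. Images are grayscale numeric matrices; 8/16-bit PNG and TIFF
# inputs are supported, multi-channel inputs are reduced by a channel index.

#' Read a grayscale image
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package) into a
#' numeric matrix scaled to `[0, 1]`. Multi-channel images are reduced to
#' the requested channel.
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param channel channel index for multi-channel inputs (default 1).
#' @return numeric matrix (rows x cols).
#' @export
read_gray_image <- function(path, channel = 1L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("the 'tiff' package is required for TIFF input")
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , channel]
  m <- as.matrix(arr)
  if (any(!is.finite(m)) || any(m < 0))
    stop("image must be finite and non-negative after loading")
  m
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask * 1), path)
  invisible(path)
}

#' Write geometry as mask PNG plus JSON sidecar
#'
#' @param geom a `retina_geometry`.
#' @param dir output directory.
#' @param stem file stem (default `"geometry"`).
#' @return invisibly, the two paths written.
#' @export
write_geometry <- function(geom, dir, stem = "geometry") {
  stopifnot(inherits(geom, "retina_geometry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, paste0(stem, "_mask.png"))
  json_path <- file.path(dir, paste0(stem, ".json"))
  write_mask_png(geom$mask, mask_path)
  jsonlite::write_json(list(center = as.numeric(geom$center) - 1,
                            phi_px = geom$phi),
                       json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(mask = mask_path, json = json_path))
}
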