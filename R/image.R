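#' Calibrated RGB image
#'
#' The spatial substrate of the pipeline: an H x W x 3 intensity array in
#' \[0, 255\] together with its physical pixel size in microns per pixel
#' (mpp).  All physical coordinates used by the package are in microns,
#' with the origin at the centre of the top-left pixel, x increasing to
#' the right and y increasing downwards; rasters are row-major and
#' 1-based on the pixel grid.
#'
#' @param pixels Numeric H x W x 3 array, intensities in \[0, 255\].
#' @param mpp Microns per pixel (> 0).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, mpp) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop2("'pixels' must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop2("image must have at least one pixel")
  assert_scalar_number(mpp, "mpp", lower = 0, strict_lower = TRUE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop2("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, mpp = mpp), class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$mpp,
              d[1] * x$mpp / 1000, d[2] * x$mpp / 1000))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)[1:2]

#' Binary tumor/stroma mask
#'
#' @param values Integer/logical H x W matrix; 1 = tumor, 0 = stroma.
#' @param mpp Microns per pixel, inherited from the source image.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(values, mpp) {
  if (!is.matrix(values)) stop2("'values' must be a matrix")
  assert_scalar_number(mpp, "mpp", lower = 0, strict_lower = TRUE)
  v <- values
  storage.mode(v) <- "integer"
  if (!all(v %in% c(0L, 1L))) stop2("mask values must be 0 or 1")
  structure(list(values = v, mpp = mpp), class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d x %d px, %.4g um/px, tumor fraction %.3f\n",
              nrow(x$values), ncol(x$values), x$mpp, mean(x$values)))
  invisible(x)
}

#' @export
dim.tumor_mask <- function(x) dim(x$values)

# physical frame of a raster (pixel-centre coordinate extent), in microns
frame_extent_um <- function(obj) {
  d <- dim(obj)
  c(x = (d[2] - 1) * obj$mpp, y = (d[1] - 1) * obj$mpp)
}

## ---- plain-text raster I/O (portable NetPBM) --------------------------
## TIFF/PNG codecs are not part of the supported dependency set, so
## rasters travel as ASCII PGM (masks) / PPM (images) with a JSON sidecar
## ("<path>.json") carrying the microns-per-pixel calibration.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, mpp) {
  jsonlite::write_json(list(mpp = mpp), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
}

read_sidecar_mpp <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- jsonlite::read_json(sp)
  if (is.null(meta$mpp)) NULL else as.numeric(meta$mpp)
}

#' Write a calibrated image as plain-text PPM with a calibration sidecar
#'
#' Intensities are rounded to integers on write; the physical pixel size
#' is stored in `<path>.json`.
#'
#' @param image A [calibrated_image].
#' @param path Output file path (conventionally `.ppm`).
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- round(image$pixels)
  d <- dim(px)
  # interleave channels row-major: R G B per pixel
  flat <- aperm(px, c(3, 2, 1))  # channel, col, row
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  writeLines(paste(as.integer(flat), collapse = " "), con)
  write_sidecar(path, image$mpp)
  invisible(path)
}

#' Read a calibrated image written by [write_calibrated_image()]
#'
#' Calibration is taken from the JSON sidecar unless `mpp_override` is
#' given, which always wins.  Missing calibration with no override is an
#' error: every downstream stage needs physical units.
#'
#' @param path PPM file path.
#' @param mpp_override Optional microns-per-pixel override.
#' @return A [calibrated_image].
#' @export
read_calibrated_image <- function(path, mpp_override = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1] != "P3")
    stop2("not a plain-text PPM (P3) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h * 3L) stop2("corrupt PPM payload in ", path)
  px <- aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
  mpp <- if (!is.null(mpp_override)) mpp_override else read_sidecar_mpp(path)
  if (is.null(mpp))
    stop2("no calibration: ", path, " has no '", basename(sidecar_path(path)),
          "' sidecar and no 'mpp_override' was given")
  calibrated_image(px, mpp)
}

#' Write a tumor mask as plain-text PGM (0/1) with a calibration sidecar
#'
#' @param mask A [tumor_mask].
#' @param path Output file path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  d <- dim(mask$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(d[2], d[1]), "1"), con)
  writeLines(paste(as.integer(t(mask$values)), collapse = " "), con)
  write_sidecar(path, mask$mpp)
  invisible(path)
}

#' Read a tumor mask written by [write_mask()]
#'
#' @param path PGM file path.
#' @param mpp_override Optional microns-per-pixel override.
#' @return A [tumor_mask].
#' @export
read_mask <- function(path, mpp_override = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1] != "P2")
    stop2("not a plain-text PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop2("corrupt PGM payload in ", path)
  # stored values may be 0/1 or 0/255
  vals <- as.integer(vals > 0L)
  mpp <- if (!is.null(mpp_override)) mpp_override else read_sidecar_mpp(path)
  if (is.null(mpp))
    stop2("no calibration for mask ", path, " and no 'mpp_override'")
  tumor_mask(matrix(vals, nrow = h, ncol = w, byrow = TRUE), mpp)
}
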