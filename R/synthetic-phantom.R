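## Ground-truthed pseudo-IHC slide phantoms: a tissue block spanning the
## raster, an epithelial-origin line near the top edge, an invasive edge
## near the bottom, and elliptical tumor nests placed by rejection until
## each 1-mm band reaches its target tumor area fraction.  Tumor renders
## in a DAB-like brown, stroma in a haematoxylin-like blue-grey.

#' Phantom generator configuration
#'
#' Defaults describe a scaled-down slide: 4 um/px (a WSI downsampled
#' ~28x from scanner resolution) over a 2.56 x 2.0 mm frame, dense inner
#' tumor (0.9) and stroma-rich invasive front (0.3), 40-um mean nest
#' radius, mild sensor noise.
#'
#' @param image_size_px Integer (height, width) in pixels.
#' @param mpp Microns per pixel (> 0).
#' @param inner_target_fraction,front_target_fraction Target tumor area
#'   fractions in the inner-tumor and ITF bands, each in \[0, 1\].
#' @param nest_radius_um Mean tumor-nest radius in microns (lognormal).
#' @param noise_sd Additive Gaussian colour noise SD in intensity units.
#' @param seed Integer RNG seed.
#' @param curve_margin_um Distance of the two boundary curves from the
#'   top/bottom of the frame.
#' @param band_width_um Band width used for the ground-truth zones.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size_px = c(640, 500), mpp = 4,
                           inner_target_fraction = 0.9,
                           front_target_fraction = 0.3,
                           nest_radius_um = 40, noise_sd = 4, seed = 1L,
                           curve_margin_um = 80, band_width_um = 1000) {
  if (length(image_size_px) != 2L || any(image_size_px < 1))
    stop2("'image_size_px' must be (height, width) positive integers")
  assert_scalar_number(mpp, "mpp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(inner_target_fraction, "inner_target_fraction", 0, 1)
  assert_scalar_number(front_target_fraction, "front_target_fraction", 0, 1)
  assert_scalar_number(nest_radius_um, "nest_radius_um", 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  ext_y <- (image_size_px[1] - 1) * mpp
  if (ext_y < 2 * band_width_um + 2 * curve_margin_um)
    stop2("image too small for two ", band_width_um, "-um bands: ",
          "physical height ", ext_y, " um < ",
          2 * band_width_um + 2 * curve_margin_um, " um")
  structure(list(image_size_px = as.integer(image_size_px), mpp = mpp,
                 inner_target_fraction = inner_target_fraction,
                 front_target_fraction = front_target_fraction,
                 nest_radius_um = nest_radius_um, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 curve_margin_um = curve_margin_um,
                 band_width_um = band_width_um),
            class = "phantom_config")
}

# set the pixels of one ellipse within a row window; returns updated mask
rasterize_ellipse <- function(mask, cx, cy, a, b, theta, mpp,
                              row_lo, row_hi) {
  r <- max(a, b)
  rows <- max(row_lo, ceiling((cy - r) / mpp) + 1):
    min(row_hi, floor((cy + r) / mpp) + 1)
  cols <- max(1, ceiling((cx - r) / mpp) + 1):
    min(ncol(mask), floor((cx + r) / mpp) + 1)
  if (length(rows) < 1L || length(cols) < 1L || rows[1] > rows[length(rows)] ||
      cols[1] > cols[length(cols)]) return(mask)
  dx <- outer(rep(1, length(rows)), (cols - 1) * mpp - cx)
  dy <- outer((rows - 1) * mpp - cy, rep(1, length(cols)))
  u <- dx * cos(theta) + dy * sin(theta)
  w <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (w / b)^2 <= 1
  sub <- mask[rows, cols, drop = FALSE]
  sub[inside] <- 1L
  mask[rows, cols] <- sub
  mask
}

# fill one horizontal region of the mask up to a target fraction
fill_region <- function(mask, target, y_lo, y_hi, row_lo, row_hi, ext_x,
                        nest_radius_um, mpp, max_tries = 50000L) {
  if (target <= 0 || row_hi < row_lo) return(mask)
  region_n <- (row_hi - row_lo + 1L) * ncol(mask)
  filled <- sum(mask[row_lo:row_hi, ])
  tries <- 0L
  while (filled / region_n < target && tries < max_tries) {
    tries <- tries + 1L
    cx <- stats::runif(1, 0, ext_x)
    cy <- stats::runif(1, y_lo, y_hi)
    ab <- stats::rlnorm(2, meanlog = log(nest_radius_um), sdlog = 0.3)
    theta <- stats::runif(1, 0, pi)
    mask <- rasterize_ellipse(mask, cx, cy, ab[1], ab[2], theta, mpp,
                              row_lo, row_hi)
    filled <- sum(mask[row_lo:row_hi, ])
  }
  mask
}

#' Generate a ground-truthed pseudo-IHC phantom
#'
#' Builds the tumor mask first (elliptical nests clipped to each
#' horizontal region so per-band fractions are controlled independently),
#' then renders it through the H-DAB optical-density model plus Gaussian
#' noise.  Deterministic for a given seed.
#'
#' The tissue is organised top-to-bottom: surface stroma, the epithelial
#' origin line, the 1-mm inner-tumor band, a transition region (tumor
#' fraction midway between the two targets), the 1-mm ITF band ending at
#' the invasive edge line, then stroma-only normal tissue.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `image` ([calibrated_image]) and `truth`
#'   (class `phantom_truth`: `tumor_mask`, `epithelial_origin`,
#'   `invasive_edge`, `true_inner_fraction`, `true_front_fraction`,
#'   `bands` with exact inner/ITF [zone_band] rasters).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    h <- config$image_size_px[1]; w <- config$image_size_px[2]
    mpp <- config$mpp
    ext_x <- (w - 1) * mpp
    ext_y <- (h - 1) * mpp
    bw <- config$band_width_um
    y_origin <- config$curve_margin_um
    y_edge <- ext_y - config$curve_margin_um

    # closed-interval row windows by pixel-centre coordinate
    rows_in <- function(a, b) {
      lo <- max(1L, as.integer(ceiling(a / mpp - 1e-9)) + 1L)
      hi <- min(h, as.integer(floor(b / mpp + 1e-9)) + 1L)
      c(lo, hi)
    }
    inner_rw <- rows_in(y_origin, y_origin + bw)
    itf_rw <- rows_in(y_edge - bw, y_edge)
    mid_rw <- c(inner_rw[2] + 1L, itf_rw[1] - 1L)

    mask <- matrix(0L, h, w)
    mask <- fill_region(mask, config$inner_target_fraction,
                        y_origin, y_origin + bw,
                        inner_rw[1], inner_rw[2], ext_x,
                        config$nest_radius_um, mpp)
    mid_target <- mean(c(config$inner_target_fraction,
                         config$front_target_fraction))
    if (mid_rw[2] >= mid_rw[1])
      mask <- fill_region(mask, mid_target, y_origin + bw, y_edge - bw,
                          mid_rw[1], mid_rw[2], ext_x,
                          config$nest_radius_um, mpp)
    mask <- fill_region(mask, config$front_target_fraction,
                        y_edge - bw, y_edge,
                        itf_rw[1], itf_rw[2], ext_x,
                        config$nest_radius_um, mpp)

    band_fraction <- function(rw) {
      if (rw[2] < rw[1]) return(NA_real_)
      sum(mask[rw[1]:rw[2], ]) / ((rw[2] - rw[1] + 1L) * w)
    }
    true_inner <- band_fraction(inner_rw)
    true_front <- band_fraction(itf_rw)
    check_target <- function(achieved, target, label) {
      if (is.na(achieved) || abs(achieved - target) > 0.05)
        warning(sprintf(
          "%s band fraction %.3f misses target %.3f (nest geometry limit)",
          label, achieved, target), call. = FALSE)
    }
    check_target(true_inner, config$inner_target_fraction, "inner")
    check_target(true_front, config$front_target_fraction, "front")

    # render: stroma = haematoxylin-like, tumor = DAB-dominant
    v <- hdab_stain_vectors()
    od <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      base <- 0.55 * v["hematoxylin", ch]
      tum <- 0.25 * v["hematoxylin", ch] + 1.0 * v["dab", ch]
      od[, , ch] <- base + (tum - base) * mask
    }
    px <- optical_density_to_rgb(od)
    if (config$noise_sd > 0)
      px <- px + stats::rnorm(length(px), sd = config$noise_sd)
    px <- clamp(px, 0, 255)

    band_raster <- function(rw) {
      m <- matrix(0L, h, w)
      if (rw[2] >= rw[1]) m[rw[1]:rw[2], ] <- 1L
      m
    }
    origin_curve <- boundary_curve(rbind(c(0, y_origin), c(ext_x, y_origin)),
                                   role = "epithelial_origin",
                                   tumor_side = c(0, 1))
    edge_curve <- boundary_curve(rbind(c(0, y_edge), c(ext_x, y_edge)),
                                 role = "invasive_edge",
                                 tumor_side = c(0, -1))
    truth <- structure(list(
      tumor_mask = tumor_mask(mask, mpp),
      epithelial_origin = origin_curve,
      invasive_edge = edge_curve,
      true_inner_fraction = true_inner,
      true_front_fraction = true_front,
      bands = list(
        inner = zone_band(band_raster(inner_rw), "inner_tumor", bw, mpp),
        itf = zone_band(band_raster(itf_rw), "itf", bw, mpp))),
      class = "phantom_truth")
    list(image = calibrated_image(px, mpp), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> inner fraction %.3f, front fraction %.3f\n",
              x$true_inner_fraction, x$true_front_fraction))
  invisible(x)
}

#' Write phantom artifacts to a directory
#'
#' Writes `image.ppm` (+ sidecar), `mask.pgm` (+ sidecar),
#' `curves.geojson` and `truth.json` under `dir`.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calibrated_image(phantom$image, file.path(dir, "image.ppm"))
  write_mask(phantom$truth$tumor_mask, file.path(dir, "mask.pgm"))
  write_curves(list(phantom$truth$epithelial_origin,
                    phantom$truth$invasive_edge),
               file.path(dir, "curves.geojson"))
  jsonlite::write_json(
    list(true_inner_fraction = phantom$truth$true_inner_fraction,
         true_front_fraction = phantom$truth$true_front_fraction),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
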