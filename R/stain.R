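#' Convert RGB intensities to optical density
#'
#' Beer-Lambert preprocessing for stain separation:
#' `OD = -log10((I + 1) / 256)` per channel, so a blank (255) pixel has
#' OD ~ 0 and OD increases monotonically as intensity falls.
#'
#' @param image A [calibrated_image], or a bare numeric array in
#'   \[0, 255\].
#' @return An H x W x 3 array of optical densities (>= 0).
#' @export
rgb_to_optical_density <- function(image) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (min(px) < 0 || max(px) > 255)
    stop2("intensities must lie in [0, 255]")
  -log10((px + 1) / 256)
}

# inverse of rgb_to_optical_density, used by the phantom renderer
optical_density_to_rgb <- function(od) {
  256 * 10^(-od) - 1
}

#' Default H-DAB stain basis
#'
#' Conventional haematoxylin / DAB optical-density unit vectors (the
#' widely used published basis for brown/blue separation), completed to
#' an invertible 3 x 3 matrix by their normalized cross product as the
#' residual channel.  Rows are stains, columns are R, G, B.
#'
#' @return A 3 x 3 numeric matrix with unit-norm rows, rownames
#'   `hematoxylin`, `dab`, `residual`.
#' @export
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  v <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab         = d / sqrt(sum(d^2)),
             residual    = r / sqrt(sum(r^2)))
  colnames(v) <- c("R", "G", "B")
  v
}

#' Deconvolve an optical-density raster into per-stain concentrations
#'
#' Solves `OD = C %*% V` per pixel for the concentration row `C`, where
#' `V` is the stain basis (rows = stain OD unit vectors).  The round trip
#' `concentrations %*% V` reproduces the input OD to machine precision.
#'
#' @param od H x W x 3 optical-density array (from
#'   [rgb_to_optical_density()]).
#' @param stain_vectors Invertible 3 x 3 stain basis; defaults to
#'   [hdab_stain_vectors()].
#' @return H x W x 3 array of stain concentrations; third-dimension
#'   names follow the basis rownames.
#' @export
deconvolve_hdab <- function(od, stain_vectors = hdab_stain_vectors()) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop2("'od' must be an H x W x 3 array")
  if (!is.matrix(stain_vectors) || any(dim(stain_vectors) != 3L))
    stop2("'stain_vectors' must be a 3 x 3 matrix")
  inv <- tryCatch(solve(stain_vectors),
                  error = function(e) stop2("singular stain basis: ",
                                            conditionMessage(e)))
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)         # pixels x channels
  conc <- flat %*% inv                   # pixels x stains
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stain_vectors))
  out
}

#' Threshold the DAB channel into a tumor mask
#'
#' The deterministic fast path for phantom images, where the brown (DAB)
#' concentration separates tumor from stroma cleanly.
#'
#' @param dab H x W matrix of DAB concentrations (or an H x W x 3
#'   concentration array, from which the `dab` slice is taken).
#' @param threshold Finite scalar; pixels with concentration >=
#'   `threshold` are tumor.
#' @param mpp Microns per pixel for the resulting mask.
#' @return A [tumor_mask].
#' @export
threshold_classify <- function(dab, threshold = 0.5, mpp) {
  if (is.array(dab) && length(dim(dab)) == 3L) dab <- dab[, , "dab"]
  if (!is.matrix(dab)) stop2("'dab' must be a matrix or H x W x 3 array")
  if (!is_scalar_number(threshold)) stop2("'threshold' must be finite")
  tumor_mask((dab >= threshold) * 1L, mpp)
}

#' One-call threshold segmentation of a calibrated image
#'
#' Convenience wrapper: OD transform, H-DAB deconvolution, DAB threshold.
#'
#' @inheritParams rgb_to_optical_density
#' @inheritParams threshold_classify
#' @param stain_vectors Stain basis passed to [deconvolve_hdab()].
#' @return A [tumor_mask].
#' @export
segment_image <- function(image, threshold = 0.5,
                          stain_vectors = hdab_stain_vectors()) {
  stopifnot(inherits(image, "calibrated_image"))
  conc <- deconvolve_hdab(rgb_to_optical_density(image), stain_vectors)
  threshold_classify(conc[, , "dab"], threshold, mpp = image$mpp)
}
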