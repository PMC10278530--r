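#' Rectangular image field
#'
#' An axis-aligned analysis field, by default the 20x-objective-equivalent
#' 1.15 x 0.68 mm (0.782 mm^2) rectangle, addressed by its top-left
#' corner in physical microns.
#'
#' @param x,y Top-left corner in microns.
#' @param width_um,height_um Field dimensions in microns.
#' @param zone Zone the field was selected for.
#' @return An object of class `field_box`.
#' @export
field_box <- function(x, y, width_um = 1150, height_um = 680,
                      zone = c("inner_tumor", "itf")) {
  zone <- match.arg(zone)
  assert_scalar_number(x, "x"); assert_scalar_number(y, "y")
  assert_scalar_number(width_um, "width_um", lower = 0, strict_lower = TRUE)
  assert_scalar_number(height_um, "height_um", lower = 0, strict_lower = TRUE)
  structure(list(x = x, y = y, width_um = width_um, height_um = height_um,
                 zone = zone), class = "field_box")
}

#' @export
print.field_box <- function(x, ...) {
  cat(sprintf("<field_box> %s at (%g, %g) um, %g x %g um\n",
              x$zone, x$x, x$y, x$width_um, x$height_um))
  invisible(x)
}

# closed-interval pixel index range [a, b] um -> 1-based indices
px_range <- function(a, b, mpp, n) {
  lo <- ceiling(a / mpp - 1e-9) + 1
  hi <- floor(b / mpp + 1e-9) + 1
  c(max(1, lo), min(n, hi))
}

# summed-area table with a zero border row/column
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

rect_sum <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

#' Enumerate candidate field positions over a zone band
#'
#' All axis-aligned boxes on a regular stride grid whose centre pixel
#' lies inside the band and whose extent stays inside the raster frame.
#' Both field orientations (w x h and h x w) are generated; enumeration
#' order is row-major (y outer, x inner) within the first orientation,
#' then the second, which also defines the tie-break order downstream.
#'
#' @param band A [zone_band].
#' @param field_dims_um Length-2 vector (width, height) in microns.
#' @param stride_um Grid stride in microns (> 0).
#' @return A data.frame with columns `x`, `y`, `w`, `h` (microns) and
#'   `orientation` (1 or 2), one row per candidate box.
#' @export
enumerate_windows <- function(band, field_dims_um = c(1150, 680),
                              stride_um = 50) {
  stopifnot(inherits(band, "zone_band"))
  assert_scalar_number(stride_um, "stride_um", lower = 0, strict_lower = TRUE)
  if (sum(band$values) == 0L) stop2("band is empty")
  ext <- frame_extent_um(band)
  dims <- list(field_dims_um, rev(field_dims_um))
  if (field_dims_um[1] == field_dims_um[2]) dims <- dims[1]
  out <- list()
  for (o in seq_along(dims)) {
    w <- dims[[o]][1]; h <- dims[[o]][2]
    if (w > ext["x"] || h > ext["y"]) next
    xs <- seq(0, ext["x"] - w, by = stride_um)
    ys <- seq(0, ext["y"] - h, by = stride_um)
    g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # x varies fastest
    cr <- round((g$y + h / 2) / band$mpp) + 1
    cc <- round((g$x + w / 2) / band$mpp) + 1
    cr <- clamp(cr, 1, nrow(band$values))
    cc <- clamp(cc, 1, ncol(band$values))
    keep <- band$values[cbind(cr, cc)] == 1L
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(x = g$x[keep], y = g$y[keep],
                                            w = w, h = h, orientation = o)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), orientation = integer()))
  do.call(rbind, out)
}

# pixel index ranges for a window table; returns matrix of r1,r2,c1,c2
window_px_ranges <- function(win, mpp, dims) {
  r1 <- pmax(1, ceiling(win$y / mpp - 1e-9) + 1)
  r2 <- pmin(dims[1], floor((win$y + win$h) / mpp + 1e-9) + 1)
  c1 <- pmax(1, ceiling(win$x / mpp - 1e-9) + 1)
  c2 <- pmin(dims[2], floor((win$x + win$w) / mpp + 1e-9) + 1)
  cbind(r1 = r1, r2 = r2, c1 = c1, c2 = c2)
}

#' Does tumor reach all four borders of a field?
#'
#' Checks that each border strip of depth `margin_um` just inside the box
#' contains at least one tumor pixel, operationalising the requirement
#' that tumor cells be present at all borders of a selected field.
#'
#' @param mask A [tumor_mask].
#' @param box A [field_box] (inside the mask frame).
#' @param margin_um Strip depth in microns; must not exceed half the
#'   smaller box dimension.
#' @return Logical flag.
#' @export
border_has_tumor <- function(mask, box, margin_um = 20) {
  stopifnot(inherits(mask, "tumor_mask"), inherits(box, "field_box"))
  if (margin_um > min(box$width_um, box$height_um) / 2)
    stop2("margin_um exceeds half the box dimensions")
  S <- integral_image(mask$values)
  win <- data.frame(x = box$x, y = box$y, w = box$width_um, h = box$height_um)
  all(border_flags(S, win, margin_um, mask$mpp, dim(mask$values)))
}

# vectorised border check for a table of windows
border_flags <- function(S, win, margin_um, mpp, dims) {
  rg <- window_px_ranges(win, mpp, dims)
  # strip pixel depth (at least one pixel line)
  mrow <- pmax(0, floor(margin_um / mpp + 1e-9))
  top    <- rect_sum(S, rg[, 1], pmin(rg[, 2], rg[, 1] + mrow), rg[, 3], rg[, 4])
  bottom <- rect_sum(S, pmax(rg[, 1], rg[, 2] - mrow), rg[, 2], rg[, 3], rg[, 4])
  left   <- rect_sum(S, rg[, 1], rg[, 2], rg[, 3], pmin(rg[, 4], rg[, 3] + mrow))
  right  <- rect_sum(S, rg[, 1], rg[, 2], pmax(rg[, 3], rg[, 4] - mrow), rg[, 4])
  top > 0 & bottom > 0 & left > 0 & right > 0
}

boxes_overlap <- function(a, b) {
  a$x < b$x + b$width_um && b$x < a$x + a$width_um &&
    a$y < b$y + b$height_um && b$y < a$y + a$height_um
}

#' Select the k stroma-richest valid fields in a band
#'
#' Enumerates candidate windows ([enumerate_windows()]), keeps those with
#' tumor at all four borders ([border_has_tumor()] logic), and returns
#' the `k` windows of smallest tumor area fraction, ties broken by
#' enumeration (scan) order.  Overlapping fields are allowed by default,
#' matching the acquisition protocol.
#'
#' @param mask A [tumor_mask].
#' @param band A [zone_band] aligned with the mask.
#' @param k Number of fields (default 3).
#' @param field_dims_um,stride_um Passed to [enumerate_windows()].
#' @param margin_um Border strip depth for the tumor-at-borders check.
#' @param allow_overlap If `FALSE`, fields are chosen greedily in
#'   ascending fraction order skipping any that overlap an earlier pick.
#' @return A list of `field_measurement` objects (fields `box`,
#'   `tumor_fraction`, `border_ok`), sorted ascending by fraction.  If
#'   fewer than `k` valid windows exist, all are returned with a warning
#'   and attribute `incomplete = TRUE`.
#' @export
select_fields <- function(mask, band, k = 3, field_dims_um = c(1150, 680),
                          stride_um = 50, margin_um = 20,
                          allow_overlap = TRUE) {
  stopifnot(inherits(mask, "tumor_mask"), inherits(band, "zone_band"))
  if (!all(dim(mask$values) == dim(band$values)))
    stop2("mask and band rasters disagree in shape")
  win <- enumerate_windows(band, field_dims_um, stride_um)
  if (nrow(win) == 0L)
    stop2("no candidate window fits the band/raster geometry")
  S <- integral_image(mask$values)
  dims <- dim(mask$values)
  rg <- window_px_ranges(win, mask$mpp, dims)
  npix <- (rg[, 2] - rg[, 1] + 1) * (rg[, 4] - rg[, 3] + 1)
  frac <- rect_sum(S, rg[, 1], rg[, 2], rg[, 3], rg[, 4]) / npix
  ok <- border_flags(S, win, margin_um, mask$mpp, dims)
  if (!any(ok))
    stop2("no candidate window has tumor at all four borders")
  cand <- win[ok, , drop = FALSE]
  cand$fraction <- frac[ok]
  cand <- cand[order(cand$fraction), , drop = FALSE]  # stable: keeps scan order

  picked <- list()
  for (i in seq_len(nrow(cand))) {
    bx <- field_box(cand$x[i], cand$y[i], cand$w[i], cand$h[i],
                    zone = band$zone)
    if (!allow_overlap &&
        any(vapply(picked, function(p) boxes_overlap(p$box, bx), logical(1))))
      next
    picked[[length(picked) + 1L]] <-
      structure(list(box = bx, tumor_fraction = cand$fraction[i],
                     border_ok = TRUE), class = "field_measurement")
    if (length(picked) == k) break
  }
  if (length(picked) < k) {
    warning("only ", length(picked), " valid field(s) found (requested ",
            k, ")", call. = FALSE)
    attr(picked, "incomplete") <- TRUE
  }
  picked
}

#' @export
print.field_measurement <- function(x, ...) {
  cat(sprintf("<field_measurement> %s (%g, %g) %gx%g um: tumor %.4f\n",
              x$box$zone, x$box$x, x$box$y, x$box$width_um, x$box$height_um,
              x$tumor_fraction))
  invisible(x)
}

#' Tabulate selected fields
#'
#' @param fields List of `field_measurement` objects.
#' @return data.frame with columns zone, x, y, w, h, fraction, border_ok.
#' @export
fields_to_df <- function(fields) {
  data.frame(zone = vapply(fields, function(f) f$box$zone, character(1)),
             x = vapply(fields, function(f) f$box$x, numeric(1)),
             y = vapply(fields, function(f) f$box$y, numeric(1)),
             w = vapply(fields, function(f) f$box$width_um, numeric(1)),
             h = vapply(fields, function(f) f$box$height_um, numeric(1)),
             fraction = vapply(fields, function(f) f$tumor_fraction,
                               numeric(1)),
             border_ok = vapply(fields, function(f) f$border_ok, logical(1)))
}
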