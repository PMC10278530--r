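#' Boundary curve annotation
#'
#' A polyline in physical coordinates (microns, origin at the top-left
#' pixel centre, y downward) marking either the invasive edge of the
#' tumor or the origin of the epithelial tumor tissue.  `tumor_side` is a
#' 2-vector pointing from the curve towards the tumor; only its
#' orientation relative to the curve matters, so the raster of distances
#' is invariant to reversing the vertex order.
#'
#' @param vertices n x 2 numeric matrix of (x, y) in microns, n >= 2,
#'   consecutive vertices distinct.
#' @param role `"invasive_edge"` or `"epithelial_origin"`.
#' @param tumor_side Length-2 numeric vector pointing towards the tumor
#'   side of the curve (need not be unit length).
#' @return An object of class `boundary_curve`.
#' @export
boundary_curve <- function(vertices, role = c("invasive_edge",
                                              "epithelial_origin"),
                           tumor_side) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop2("'vertices' must be an n x 2 matrix with n >= 2")
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0))
    stop2("consecutive curve vertices must be distinct")
  if (length(tumor_side) != 2L || all(tumor_side == 0) ||
      any(!is.finite(tumor_side)))
    stop2("'tumor_side' must be a nonzero 2-vector")
  structure(list(vertices = vertices, role = role,
                 tumor_side = tumor_side / sqrt(sum(tumor_side^2))),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %s, %d vertices, tumor side (%.2f, %.2f)\n",
              x$role, nrow(x$vertices), x$tumor_side[1], x$tumor_side[2]))
  invisible(x)
}

# zone label implied by a curve's role
zone_for_role <- function(role) {
  switch(role, invasive_edge = "itf", epithelial_origin = "inner_tumor")
}

#' Per-pixel distance to a boundary curve, restricted to the tumor side
#'
#' Euclidean distance in microns from each pixel centre to the polyline.
#' A pixel belongs to the tumor side when, relative to its nearest
#' segment, it lies on the same side as the `tumor_side` direction;
#' pixels on the opposite side are `NA`.  Pixels exactly on the curve (or
#' on its collinear extension) have sign zero and are kept.
#'
#' @param grid A [calibrated_image] or [tumor_mask] supplying the raster
#'   dimensions and microns-per-pixel.
#' @param curve A [boundary_curve].
#' @return H x W numeric matrix of distances in microns, `NA` outside
#'   the tumor side.
#' @export
distance_to_curve <- function(grid, curve) {
  stopifnot(inherits(curve, "boundary_curve"))
  d <- dim(grid)
  mpp <- grid$mpp
  v <- curve$vertices
  if (nrow(unique(v)) < 2L) stop2("degenerate curve: all vertices identical")

  px <- rep((seq_len(d[2]) - 1) * mpp, each = d[1])   # x, column-major
  py <- rep((seq_len(d[1]) - 1) * mpp, times = d[2])  # y

  best <- rep(Inf, d[1] * d[2])
  side <- rep(0, d[1] * d[2])
  for (i in seq_len(nrow(v) - 1L)) {
    p1 <- v[i, ]; p2 <- v[i + 1L, ]
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx * dx + dy * dy
    t <- clamp(((px - p1[1]) * dx + (py - p1[2]) * dy) / len2, 0, 1)
    ex <- px - (p1[1] + t * dx)
    ey <- py - (p1[2] + t * dy)
    dist <- sqrt(ex * ex + ey * ey)
    upd <- dist < best
    if (any(upd)) {
      best[upd] <- dist[upd]
      # side of the nearest segment: sign of the perpendicular component,
      # compared against the sign the tumor_side direction has for this
      # segment (invariant to vertex-order reversal)
      perp_pix <- dx * (py[upd] - p1[2]) - dy * (px[upd] - p1[1])
      perp_tum <- dx * curve$tumor_side[2] - dy * curve$tumor_side[1]
      side[upd] <- sign(perp_pix) * sign(perp_tum)
    }
  }
  best[side < 0] <- NA_real_
  matrix(best, nrow = d[1], ncol = d[2])
}

#' Labelled 1-mm band raster
#'
#' @param values H x W binary matrix (1 = pixel in band).
#' @param zone `"inner_tumor"` or `"itf"`.
#' @param width_um Band width in microns.
#' @param mpp Microns per pixel.
#' @return An object of class `zone_band`.
#' @export
zone_band <- function(values, zone = c("inner_tumor", "itf"),
                      width_um = 1000, mpp) {
  zone <- match.arg(zone)
  v <- values
  storage.mode(v) <- "integer"
  if (!all(v %in% c(0L, 1L))) stop2("band values must be 0 or 1")
  assert_scalar_number(width_um, "width_um", lower = 0)
  assert_scalar_number(mpp, "mpp", lower = 0, strict_lower = TRUE)
  structure(list(values = v, zone = zone, width_um = width_um, mpp = mpp),
            class = "zone_band")
}

#' @export
print.zone_band <- function(x, ...) {
  cat(sprintf("<zone_band> %s, %g um wide, %d px (%.2f mm^2)\n",
              x$zone, x$width_um, sum(x$values),
              sum(x$values) * (x$mpp / 1000)^2))
  invisible(x)
}

#' @export
dim.zone_band <- function(x) dim(x$values)

#' Extract the 1-mm band on the tumor side of a boundary curve
#'
#' Band membership is by pixel centre: a pixel is in the band when its
#' tumor-side distance to the curve lies in the closed interval
#' `[0, width_um]`.  The band is intersected with the raster frame (the
#' tissue extent of the analysed region).
#'
#' @param context A [tumor_mask] or [calibrated_image] giving dimensions,
#'   calibration and tissue extent.
#' @param curve A [boundary_curve]; its role determines the zone label.
#' @param width_um Band width in microns (default 1000 = 1 mm).
#' @return A [zone_band].
#' @export
extract_band <- function(context, curve, width_um = 1000) {
  assert_scalar_number(width_um, "width_um", lower = 0)
  dist <- distance_to_curve(context, curve)
  vals <- (!is.na(dist) & dist <= width_um) * 1L
  if (sum(vals) == 0L)
    stop2("empty band: curve '", curve$role,
          "' does not border the raster on its tumor side")
  zone_band(vals, zone = zone_for_role(curve$role),
            width_um = width_um, mpp = context$mpp)
}
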