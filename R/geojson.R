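#' Write boundary curves to GeoJSON
#'
#' Each curve becomes a LineString feature with `role` and `tumor_side`
#' properties; coordinates are physical microns in the package's image
#' coordinate convention (origin at the top-left pixel centre, y down).
#'
#' @param curves List of [boundary_curve] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  features <- lapply(curves, function(cv) {
    stopifnot(inherits(cv, "boundary_curve"))
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(cv$vertices)),
                                              function(i) cv$vertices[i, ])),
         properties = list(role = cv$role, tumor_side = cv$tumor_side))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read boundary curves from GeoJSON
#'
#' @param path GeoJSON file with LineString features carrying `role` and
#'   `tumor_side` properties.
#' @return List of [boundary_curve] objects.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop2("not a GeoJSON FeatureCollection: ", path)
  lapply(gj$features, function(f) {
    if (f$geometry$type != "LineString")
      stop2("unsupported geometry type: ", f$geometry$type)
    verts <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    boundary_curve(verts, role = f$properties$role,
                   tumor_side = unlist(f$properties$tumor_side))
  })
}

#' Write / read selected fields as CSV
#'
#' @param fields List of `field_measurement` objects (write) or a path
#'   (read).
#' @param path CSV path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_fields <- function(fields, path) {
  df <- fields_to_df(fields)
  # full-precision text so the round trip is bit-exact
  for (nm in c("x", "y", "w", "h", "fraction"))
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields
#' @export
read_fields <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(zone = "character", x = "numeric",
                                 y = "numeric", w = "numeric", h = "numeric",
                                 fraction = "numeric",
                                 border_ok = "logical"))
}
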