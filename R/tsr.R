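#' Tumor-stroma ratio of a single field
#'
#' TSR = tumor area / field area x 100 (percent).
#'
#' @param measurement A `field_measurement` (from [select_fields()]) or a
#'   bare fraction in \[0, 1\].
#' @return TSR in percent.
#' @export
field_tsr <- function(measurement) {
  frac <- if (inherits(measurement, "field_measurement"))
    measurement$tumor_fraction else measurement
  if (any(frac < 0 | frac > 1)) stop2("tumor fraction must lie in [0, 1]")
  frac * 100
}

#' Region-level TSR: average of the field TSRs, dichotomized at 50%
#'
#' The arithmetic mean of the (nominally three) field TSRs is the
#' region's TSR; the region is `tumor_high` when the mean is >= 50
#' percent (the threshold itself counts as high) and `tumor_low` below.
#'
#' @param field_tsrs Numeric vector of field TSRs in percent; nominally
#'   length 3, shorter vectors are accepted with `incomplete = TRUE`.
#' @param zone `"inner_tumor"` or `"itf"`.
#' @param threshold Dichotomization threshold in percent (default 50).
#' @return An object of class `region_tsr` with fields `zone`,
#'   `field_tsrs`, `mean_tsr`, `group`, `incomplete`.
#' @export
region_tsr <- function(field_tsrs, zone = c("inner_tumor", "itf"),
                       threshold = 50) {
  zone <- match.arg(zone)
  if (length(field_tsrs) == 0L) stop2("no field TSR values supplied")
  if (any(!is.finite(field_tsrs)) || any(field_tsrs < 0 | field_tsrs > 100))
    stop2("field TSRs must lie in [0, 100]")
  m <- mean(field_tsrs)
  structure(list(zone = zone, field_tsrs = field_tsrs, mean_tsr = m,
                 group = if (m >= threshold) "tumor_high" else "tumor_low",
                 incomplete = length(field_tsrs) != 3L),
            class = "region_tsr")
}

#' @export
print.region_tsr <- function(x, ...) {
  cat(sprintf("<region_tsr> %s: fields {%s} -> mean %.2f%% (%s)\n",
              x$zone, paste(sprintf("%.2f", x$field_tsrs), collapse = ", "),
              x$mean_tsr, x$group))
  invisible(x)
}

#' Joint inner-tumor / ITF slide pattern
#'
#' Combines the two dichotomized regions into the four-way pattern
#' `high_high`, `high_low`, `low_low` or `low_high` (inner first).  Three
#' of the four occur commonly in practice; `low_high` is emitted for
#' completeness.
#'
#' @param inner,itf [region_tsr()] results for the inner tumor and ITF.
#' @return An object of class `slide_pattern`.
#' @export
slide_pattern <- function(inner, itf) {
  stopifnot(inherits(inner, "region_tsr"), inherits(itf, "region_tsr"))
  if (inner$zone != "inner_tumor" || itf$zone != "itf")
    stop2("arguments must be the inner_tumor and itf region TSRs, in order")
  short <- function(g) if (g == "tumor_high") "high" else "low"
  structure(list(inner = inner, itf = itf,
                 pattern = paste(short(inner$group), short(itf$group),
                                 sep = "_")),
            class = "slide_pattern")
}

#' @export
print.slide_pattern <- function(x, ...) {
  cat(sprintf("<slide_pattern> %s (inner %.2f%%, ITF %.2f%%)\n",
              x$pattern, x$inner$mean_tsr, x$itf$mean_tsr))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the physical and algorithmic parameters of the slide pipeline.
#' Defaults encode the acquisition protocol: 1-mm bands, 1.15 x 0.68 mm
#' fields, three fields per band, 50% dichotomization.
#'
#' @param mpp_override Optional microns-per-pixel override for image
#'   reading.
#' @param band_width_um Band width (default 1000).
#' @param field_dims_um Field width and height in microns.
#' @param n_fields Fields per band (default 3).
#' @param tsr_threshold Dichotomization threshold in percent, in (0,100).
#' @param stride_um Candidate-window stride.
#' @param border_margin_um Border strip depth for the tumor-at-borders
#'   constraint.
#' @param seed Seed for any stochastic stage (trained segmentation).
#' @param segmentation_mode `"threshold"` (deterministic stain-deconvolution
#'   path) or `"trained"` (scribble-trained ensemble).
#' @param dab_threshold DAB concentration cut for the threshold path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mpp_override = NULL, band_width_um = 1000,
                            field_dims_um = c(1150, 680), n_fields = 3,
                            tsr_threshold = 50, stride_um = 50,
                            border_margin_um = 20, seed = 0L,
                            segmentation_mode = c("threshold", "trained"),
                            dab_threshold = 0.5) {
  segmentation_mode <- match.arg(segmentation_mode)
  assert_scalar_number(band_width_um, "band_width_um", 0, strict_lower = TRUE)
  assert_scalar_number(n_fields, "n_fields", 1)
  assert_scalar_number(tsr_threshold, "tsr_threshold", 0, 100)
  if (tsr_threshold <= 0 || tsr_threshold >= 100)
    stop2("'tsr_threshold' must lie strictly inside (0, 100)")
  assert_scalar_number(stride_um, "stride_um", 0, strict_lower = TRUE)
  assert_scalar_number(border_margin_um, "border_margin_um", 0)
  if (length(field_dims_um) != 2L || any(field_dims_um <= 0))
    stop2("'field_dims_um' must be two positive numbers")
  structure(list(mpp_override = mpp_override, band_width_um = band_width_um,
                 field_dims_um = field_dims_um, n_fields = n_fields,
                 tsr_threshold = tsr_threshold, stride_um = stride_um,
                 border_margin_um = border_margin_um, seed = seed,
                 segmentation_mode = segmentation_mode,
                 dab_threshold = dab_threshold),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop2("stage '", stage, "': ", conditionMessage(e)))
}

#' Run the full per-slide pipeline
#'
#' Segmentation -> band construction -> field selection -> TSR, for both
#' the inner tumor and the ITF.  Returns the slide-level result with the
#' full provenance (configuration, chosen fields, per-field TSRs) so a
#' run can be reproduced bit-for-bit.
#'
#' @param image A [calibrated_image].
#' @param curves List of two [boundary_curve] objects, one with role
#'   `epithelial_origin` and one with role `invasive_edge` (any order).
#' @param clinical_row Optional one-row data.frame of clinical covariates
#'   to carry through into the returned record.
#' @param config A [pipeline_config()].
#' @param classifier Optional trained [train_pixel_classifier()] model,
#'   required when `config$segmentation_mode == "trained"`.
#' @return A list of class `slide_report` with elements `inner`, `itf`
#'   ([region_tsr()]), `pattern`, `fields` (per-zone
#'   [fields_to_df()] tables), `record` (one-row data.frame merging the
#'   clinical row with TSR results) and `provenance`.
#' @export
run_pipeline <- function(image, curves, clinical_row = NULL,
                         config = pipeline_config(), classifier = NULL) {
  run_stage("calibration", {
    stopifnot(inherits(image, "calibrated_image"))
    if (!is.null(config$mpp_override))
      image <- calibrated_image(image$pixels, config$mpp_override)
    assert_scalar_number(image$mpp, "mpp", lower = 0, strict_lower = TRUE)
  })
  roles <- vapply(curves, function(cv) cv$role, character(1))
  if (!setequal(roles, c("epithelial_origin", "invasive_edge")))
    stop2("stage 'zonation': need one epithelial_origin and one ",
          "invasive_edge curve")
  origin <- curves[[which(roles == "epithelial_origin")]]
  edge <- curves[[which(roles == "invasive_edge")]]

  mask <- run_stage("segmentation", {
    if (config$segmentation_mode == "threshold")
      segment_image(image, threshold = config$dab_threshold)
    else {
      if (is.null(classifier)) stop2("trained mode requires a classifier")
      predict_mask(classifier, image)
    }
  })
  bands <- run_stage("zonation", list(
    inner = extract_band(mask, origin, config$band_width_um),
    itf = extract_band(mask, edge, config$band_width_um)))
  fields <- run_stage("field_selection", lapply(bands, function(b)
    select_fields(mask, b, k = config$n_fields,
                  field_dims_um = config$field_dims_um,
                  stride_um = config$stride_um,
                  margin_um = config$border_margin_um)))
  regions <- run_stage("tsr", {
    mk <- function(fl, zone) region_tsr(vapply(fl, field_tsr, numeric(1)),
                                        zone = zone,
                                        threshold = config$tsr_threshold)
    list(inner = mk(fields$inner, "inner_tumor"),
         itf = mk(fields$itf, "itf"))
  })
  pat <- slide_pattern(regions$inner, regions$itf)

  rec <- data.frame(tsr_inner = regions$inner$mean_tsr,
                    tsr_itf = regions$itf$mean_tsr,
                    group_inner = regions$inner$group,
                    group_itf = regions$itf$group,
                    pattern = pat$pattern)
  if (!is.null(clinical_row)) rec <- cbind(clinical_row, rec)

  structure(list(inner = regions$inner, itf = regions$itf, pattern = pat,
                 mask = mask,
                 fields = lapply(fields, fields_to_df),
                 record = rec,
                 provenance = list(config = unclass(config),
                                   mpp = image$mpp,
                                   image_dim = dim(image),
                                   segmentation_mode = config$segmentation_mode,
                                   seed = config$seed)),
            class = "slide_report")
}

#' @export
print.slide_report <- function(x, ...) {
  cat(sprintf("<slide_report> pattern %s | inner %.2f%% (%s) | ITF %.2f%% (%s)\n",
              x$pattern$pattern, x$inner$mean_tsr, x$inner$group,
              x$itf$mean_tsr, x$itf$group))
  invisible(x)
}

#' Write a per-slide JSON report
#'
#' @param report A `slide_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_slide_report <- function(report, path) {
  out <- list(pattern = report$pattern$pattern,
              inner = list(field_tsrs = report$inner$field_tsrs,
                           mean_tsr = report$inner$mean_tsr,
                           group = report$inner$group),
              itf = list(field_tsrs = report$itf$field_tsrs,
                         mean_tsr = report$itf$mean_tsr,
                         group = report$itf$group),
              fields = report$fields,
              provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
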