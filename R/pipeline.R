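#' Run the full plate-analysis pipeline
#'
#' Orchestrates register -> flat-field -> well readout -> optical density
#' -> standard-curve fit -> concentration prediction. The camera is fixed
#' relative to the device, so the transform fitted on the test image's
#' fiducials is applied to the white calibration image as well.
#'
#' @param test a [plate_image()] or PNG path: the plate photograph.
#' @param white a [plate_image()] or PNG path: the white-block calibration
#'   image from the same device. Required.
#' @param layout a [plate_layout()] or layout CSV path.
#' @param assay an [assay_config()] or assay YAML path.
#' @param fiducials_mm canonical fiducial positions (4 x 2 mm matrix,
#'   TL/TR/BL/BR), see [default_fiducials()].
#' @param scale working resolution of the registered images, px/mm.
#' @param conventional_od use conventional absorbance sign, see
#'   [optical_density()].
#' @param roi_fraction well ROI radius as a fraction of the well radius.
#' @return a `plate_assay` object: list with `readings`, `od`, `curve`,
#'   `results` (per sample well: `Cd`, `dilution_factor`, `C`, flags,
#'   replicate mean/SD), `transform`, `qc`.
#' @export
plate_analyze <- function(test, white, layout, assay,
                          fiducials_mm = default_fiducials()$centers,
                          scale = 5, conventional_od = FALSE,
                          roi_fraction = 0.7) {
  if (missing(white) || is.null(white)) stop("calibration image required")
  if (is.character(test)) test <- read_plate_image(test, provenance = "test")
  if (is.character(white)) white <- read_plate_image(white, provenance = "white-calibration")
  if (is.character(layout)) layout <- read_layout(layout)
  if (is.character(assay)) assay <- read_assay(assay)

  fids <- detect_fiducials(test)
  transform <- fit_transform(fids, canonical = fiducials_mm)
  test_al <- align(test, transform, scale = scale)
  white_al <- align(white, transform, scale = scale)
  ff <- build_flatfield(white_al)
  corrected <- apply_flatfield(test_al, ff)

  readings <- read_wells(corrected, layout, assay$weights, roi_fraction = roi_fraction)
  od <- od_table(readings, conventional = conventional_od)

  std <- layout$role == "standard"
  curve <- fit_standard_curve(layout$concentration[std],
                              od$od[match(layout$well_id[std], od$well_id)],
                              assay = assay, conventional = conventional_od)

  smp <- which(layout$role == "sample")
  results <- NULL
  if (length(smp)) {
    ids <- layout$well_id[smp]
    dfs <- layout$dilution_factor[smp]
    dfs[is.na(dfs)] <- 1
    pred <- predict(curve, od$od[match(ids, od$well_id)], dilution_factor = dfs)
    results <- cbind(data.frame(well_id = ids,
                                replicate_group = layout$replicate_group[smp],
                                stringsAsFactors = FALSE),
                     pred)
    results$group_mean <- NA_real_
    results$group_sd <- NA_real_
    for (grp in unique(results$replicate_group[!is.na(results$replicate_group)])) {
      sel <- which(results$replicate_group == grp)
      st <- replicate_stats(results$C[sel])
      results$group_mean[sel] <- st$mean
      results$group_sd[sel] <- st$sd
    }
  }

  qc <- list(fiducial_residual_mm = transform$residual_mm,
             fallback_incident = sum(od$fallback_incident),
             saturated_wells = sum(od$saturated),
             r_squared = curve$r_squared,
             zero_standard_od = curve$zero_od,
             flagged_wells = if (!is.null(results))
               results$well_id[results$above_range | results$below_range]
             else character())
  structure(list(readings = readings, od = od, curve = curve,
                 results = results, transform = transform, assay = assay,
                 layout = layout, qc = qc),
            class = "plate_assay")
}

#' @export
print.plate_assay <- function(x, ...) {
  cat(sprintf("Plate assay: %s, %d standards, %d samples\n",
              x$assay$analyte, sum(x$layout$role == "standard"),
              sum(x$layout$role == "sample")))
  cat(sprintf("  fit: x = %.4f, z = %.4f, R^2 = %.6f\n",
              x$curve$x, x$curve$z, x$curve$r_squared))
  cat(sprintf("  QC: fiducial residual %.3g mm, %d fallback incident, %d saturated\n",
              x$qc$fiducial_residual_mm, x$qc$fallback_incident, x$qc$saturated_wells))
  if (!is.null(x$results)) {
    cat("  sample results:\n")
    print(utils::head(x$results[, c("well_id", "replicate_group", "od", "Cd",
                                    "dilution_factor", "C", "group_mean", "group_sd")],
                      20L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.plate_assay <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$curve)
  invisible(object)
}

fmt6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.6f", x) else x
}

write_csv6 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a result bundle to a directory
#'
#' Emits `well_readings.csv`, `od.csv`, `curve.json`, `results.csv` and a
#' plain-text `qc_report.txt`. Numeric columns are written with 6 decimal
#' places so reruns with identical inputs produce byte-identical files.
#'
#' @param x a `plate_assay` from [plate_analyze()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_assay <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv6(x$readings, file.path(dir, "well_readings.csv"))
  write_csv6(x$od, file.path(dir, "od.csv"))
  jsonlite::write_json(list(x = x$curve$x, z = x$curve$z,
                            r_squared = x$curve$r_squared,
                            od_range = x$curve$od_range,
                            conc_range = x$curve$conc_range,
                            units = x$curve$units,
                            conventional = x$curve$conventional),
                       file.path(dir, "curve.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(x$results))
    write_csv6(x$results, file.path(dir, "results.csv"))
  writeLines(qc_report(x), file.path(dir, "qc_report.txt"))
  invisible(dir)
}

qc_report <- function(x) {
  q <- x$qc
  c(sprintf("analyte: %s (%s)", x$assay$analyte, x$assay$units),
    sprintf("fiducial max reprojection error: %.6f mm", q$fiducial_residual_mm),
    sprintf("standard curve: x = %.6f, z = %.6f, R^2 = %.6f",
            x$curve$x, x$curve$z, q$r_squared),
    sprintf("zero-standard OD (QC): %s",
            paste(sprintf("%.6f", q$zero_standard_od), collapse = ", ")),
    sprintf("fallback incident estimates: %d", q$fallback_incident),
    sprintf("saturated wells: %d", q$saturated_wells),
    sprintf("range-flagged wells: %s",
            if (length(q$flagged_wells)) paste(q$flagged_wells, collapse = ", ") else "none"))
}
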