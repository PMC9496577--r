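#' Well identifiers of an 8 x 12 plate
#'
#' Row-major: `"A1" ... "A12", "B1", ..., "H12"`.
#' @return character vector of length 96.
#' @export
well_ids <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' ANSI/SLAS 96-well plate geometry defaults
#'
#' 9 mm well pitch with the A1 centre at (14.38, 11.24) mm from the plate's
#' top-left corner (x right, y down), drawn well radius 3.4 mm on a
#' 127.76 x 85.48 mm footprint.
#' @return named list of geometry constants (mm).
#' @export
slas_geometry <- function() {
  list(plate_width_mm = 127.76, plate_height_mm = 85.48,
       pitch_mm = 9, a1_x_mm = 14.38, a1_y_mm = 11.24, well_radius_mm = 3.4)
}

#' Canonical fiducial positions
#'
#' Centres (mm, plate frame) of the four dark reference squares around the
#' well area, labelled TL/TR/BL/BR, plus the square side length. These are
#' configuration, not constants of the standard: the physical marker
#' placement varies per device.
#' @param inset_mm distance of each fiducial centre from the nearest plate
#'   corner, along both axes.
#' @param size_mm fiducial square side length.
#' @return list with `centers` (4 x 2 matrix, rownames TL/TR/BL/BR) and `size_mm`.
#' @export
default_fiducials <- function(inset_mm = 5.5, size_mm = 5) {
  g <- slas_geometry()
  W <- g$plate_width_mm; H <- g$plate_height_mm
  centers <- rbind(TL = c(inset_mm, inset_mm),
                   TR = c(W - inset_mm, inset_mm),
                   BL = c(inset_mm, H - inset_mm),
                   BR = c(W - inset_mm, H - inset_mm))
  colnames(centers) <- c("x_mm", "y_mm")
  list(centers = centers, size_mm = size_mm)
}

#' Plate layout: geometry plus per-well annotations
#'
#' @param role character vector of 96 roles (`"standard"`, `"sample"`,
#'   `"empty"`), named by well ID or in [well_ids()] order.
#' @param concentration known concentrations for standards (assay units),
#'   `NA` otherwise; named or in order.
#' @param dilution_factor fold-dilution (`>= 1`) for samples, `NA` otherwise.
#' @param replicate_group replicate group labels for samples.
#' @param geometry list as from [slas_geometry()].
#' @return a `plate_layout`: data frame with columns `well_id`, `row`,
#'   `col`, `x_mm`, `y_mm`, `radius_mm`, `role`, `concentration`,
#'   `dilution_factor`, `replicate_group`.
#' @export
plate_layout <- function(role = rep("empty", 96), concentration = rep(NA_real_, 96),
                         dilution_factor = rep(NA_real_, 96),
                         replicate_group = rep(NA_character_, 96),
                         geometry = slas_geometry()) {
  ids <- well_ids()
  expand <- function(x, default) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      bad <- setdiff(names(x), ids)
      if (length(bad)) stop("unknown well IDs: ", paste(bad, collapse = ", "))
      out <- rep(default, 96); names(out) <- ids
      out[names(x)] <- x
      unname(out)
    } else {
      if (length(x) != 96L) stop("per-well fields must have 96 entries or be named by well ID")
      x
    }
  }
  role <- expand(role, "empty")
  concentration <- expand(concentration, NA_real_)
  dilution_factor <- expand(dilution_factor, NA_real_)
  replicate_group <- expand(replicate_group, NA_character_)
  if (!all(role %in% c("standard", "sample", "empty")))
    stop("roles must be standard, sample or empty")
  if (any(!is.na(concentration) & concentration < 0))
    stop("standard concentrations must be non-negative")
  if (any(role == "standard" & is.na(concentration)))
    stop("standards need a known concentration")
  if (any(!is.na(dilution_factor) & dilution_factor < 1))
    stop("dilution factors must be >= 1")
  g <- geometry
  if (2 * g$well_radius_mm > g$pitch_mm)
    stop("well ROIs overlap: 2 * radius exceeds the well pitch")
  row <- rep(1:8, each = 12); col <- rep(1:12, times = 8)
  out <- data.frame(well_id = ids, row = row, col = col,
                    x_mm = g$a1_x_mm + (col - 1) * g$pitch_mm,
                    y_mm = g$a1_y_mm + (row - 1) * g$pitch_mm,
                    radius_mm = g$well_radius_mm,
                    role = role, concentration = concentration,
                    dilution_factor = dilution_factor,
                    replicate_group = replicate_group,
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Layout with the standard series across row A
#'
#' The conventional arrangement: standards in wells A1..A7 (ascending, the
#' zero standard first), samples where requested, everything else empty.
#'
#' @param assay an [assay_config()] supplying the standard series.
#' @param samples optional data frame with columns `well_id`,
#'   `dilution_factor`, `replicate_group` describing sample wells.
#' @param geometry list as from [slas_geometry()].
#' @return a [plate_layout()].
#' @export
layout_standard_row <- function(assay, samples = NULL, geometry = slas_geometry()) {
  std_wells <- paste0("A", seq_along(assay$standards))
  role <- setNames(rep("standard", length(std_wells)), std_wells)
  conc <- setNames(assay$standards, std_wells)
  df <- NULL; grp <- NULL
  if (!is.null(samples)) {
    role <- c(role, setNames(rep("sample", nrow(samples)), samples$well_id))
    df <- setNames(samples$dilution_factor, samples$well_id)
    grp <- setNames(as.character(samples$replicate_group), samples$well_id)
  }
  plate_layout(role = role, concentration = conc,
               dilution_factor = df %||% rep(NA_real_, 96),
               replicate_group = grp %||% rep(NA_character_, 96),
               geometry = geometry)
}

#' Read and write plate layouts as CSV
#'
#' @param layout a [plate_layout()].
#' @param path file path.
#' @return `read_layout()` returns a [plate_layout()].
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @param geometry geometry to rebuild ROI positions from when the CSV
#'   carries only annotations.
#' @export
read_layout <- function(path, geometry = slas_geometry()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "role")
  if (!all(need %in% names(x))) stop("layout CSV needs columns ", paste(need, collapse = ", "))
  plate_layout(role = setNames(x$role, x$well_id),
               concentration = setNames(x$concentration %||% rep(NA_real_, nrow(x)), x$well_id),
               dilution_factor = setNames(x$dilution_factor %||% rep(NA_real_, nrow(x)), x$well_id),
               replicate_group = setNames(as.character(x$replicate_group %||% rep(NA, nrow(x))), x$well_id),
               geometry = geometry)
}
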