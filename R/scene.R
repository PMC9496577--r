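#' Camera model for the synthetic renderer
#'
#' Builds the homography mapping plate millimetres to image pixels. The
#' default is a fronto-parallel view at `scale` px/mm with a pixel margin;
#' `tilt` adds a small projective component (units 1/mm) emulating an
#' off-axis camera.
#'
#' @param scale pixels per millimetre.
#' @param margin_px margin around the plate in the image, pixels.
#' @param tilt length-2 projective row `c(h31, h32)` of the homography.
#' @param plate_dims plate width/height in mm.
#' @return list with `H` (mm to px), `Hinv`, `width_px`, `height_px`.
#' @export
camera_model <- function(scale = 5, margin_px = 15, tilt = c(0, 0),
                         plate_dims = c(127.76, 85.48)) {
  H <- matrix(c(scale, 0, margin_px,
                0, scale, margin_px,
                tilt[1], tilt[2], 1), 3, 3, byrow = TRUE)
  corners <- rbind(c(0, 0), c(plate_dims[1], 0), c(0, plate_dims[2]), plate_dims)
  proj <- apply_homography(H, corners)
  list(H = H, Hinv = solve(H),
       width_px = ceiling(max(proj[, 1])) + margin_px,
       height_px = ceiling(max(proj[, 2])) + margin_px)
}

#' Scene specification for synthetic plate photographs
#'
#' Everything needed to render a plate photograph with exact ground truth:
#' plate and well-grid geometry, fiducial placement, the per-well true
#' concentration map, a four-corner LED illumination model, a sensor noise
#' and artifact model, the camera homography, and an RNG seed.
#'
#' The illumination at plate position p is
#' `sum_i s_i * (h^2 / (h^2 + r_i^2))^(falloff/2)` over the four corner
#' sources (distance `r_i` in-plane, LED height `h`); `falloff = 3` is the
#' physical Lambertian-times-inverse-square law for a downward-pointing
#' LED. The field is normalised to peak 1 over the image, then scaled by
#' `white_rgb`.
#'
#' @param concentrations named numeric of true per-well concentrations
#'   (assay units); `NA` = empty well. Missing wells default to empty.
#' @param assay an [assay_config()] defining the dye response.
#' @param geometry plate/grid geometry, see [slas_geometry()].
#' @param fiducials fiducial placement, see [default_fiducials()].
#' @param illumination list: `rel_intensity` (4 per-source factors,
#'   TL/TR/BL/BR), `height_mm`, `falloff`. `falloff = 0` gives uniform
#'   illumination.
#' @param noise list: `sigma` (per-channel Gaussian SD, intensity units),
#'   `glare_n`/`glare_r_mm` (count and radius range of saturated glare
#'   discs), `bubble_n`/`bubble_r_mm` (dark bubble discs).
#' @param camera a [camera_model()].
#' @param white_rgb RGB of the brightest plate surface point.
#' @param well_base_rgb RGB of an empty well's bottom (near-white).
#' @param fiducial_rgb RGB of the dark reference squares.
#' @param supersample subpixel samples per axis used to anti-alias the
#'   fiducial marker edges (emulating
#'   optical blur; 1 disables).
#' @param seed integer RNG seed; renders are bit-identical given the spec.
#' @return object of class `plate_scene`.
#' @export
plate_scene <- function(concentrations = NULL,
                        assay = creatinine_assay(),
                        geometry = slas_geometry(),
                        fiducials = default_fiducials(),
                        illumination = list(rel_intensity = c(1, 0.95, 1.05, 0.9),
                                            height_mm = 70, falloff = 3),
                        noise = list(sigma = 2, glare_n = 3, glare_r_mm = c(0.5, 1.2),
                                     bubble_n = 2, bubble_r_mm = c(0.3, 0.7)),
                        camera = camera_model(),
                        white_rgb = c(250, 249, 247),
                        well_base_rgb = c(247, 246, 244),
                        fiducial_rgb = c(25, 25, 25),
                        supersample = 16L,
                        seed = 1L) {
  if (supersample < 1L || supersample != round(supersample))
    stop("supersample must be a positive integer")
  ids <- well_ids()
  conc <- setNames(rep(NA_real_, 96L), ids)
  if (!is.null(concentrations)) {
    if (is.null(names(concentrations)) && length(concentrations) == 96L)
      names(concentrations) <- ids
    bad <- setdiff(names(concentrations), ids)
    if (length(bad)) stop("unknown well IDs in concentration map: ", paste(bad, collapse = ", "))
    conc[names(concentrations)] <- concentrations
  }
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  g <- geometry
  geo <- unlist(g)
  if (any(!is.finite(geo)) || any(geo <= 0)) stop("geometric fields must be strictly positive")
  if (g$a1_x_mm + 11 * g$pitch_mm + g$well_radius_mm > g$plate_width_mm ||
      g$a1_y_mm + 7 * g$pitch_mm + g$well_radius_mm > g$plate_height_mm ||
      g$a1_x_mm - g$well_radius_mm < 0 || g$a1_y_mm - g$well_radius_mm < 0)
    stop("well grid does not fit inside the plate bounds")
  if (abs(det(camera$H)) < .Machine$double.eps * 100)
    stop("camera homography is not invertible")
  if (length(illumination$rel_intensity) != 4L || any(illumination$rel_intensity <= 0))
    stop("illumination needs 4 positive per-source intensities")
  structure(list(concentrations = conc, assay = assay, geometry = g,
                 fiducials = fiducials, illumination = illumination,
                 noise = noise, camera = camera, white_rgb = white_rgb,
                 well_base_rgb = well_base_rgb, fiducial_rgb = fiducial_rgb,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "plate_scene")
}

#' @export
print.plate_scene <- function(x, ...) {
  cat(sprintf("<plate_scene %d filled / %d wells, %s assay, %dx%d px, seed %d>\n",
              sum(!is.na(x$concentrations)), 96L, x$assay$analyte,
              x$camera$width_px, x$camera$height_px, x$seed))
  invisible(x)
}

#' Scene from a plate layout
#'
#' Fills standards at their known concentrations and sample wells at the
#' supplied true concentrations (diluted scale, i.e. what is physically in
#' the well).
#'
#' @param layout a [plate_layout()].
#' @param assay an [assay_config()].
#' @param sample_conc named numeric: true in-well concentration per sample
#'   well ID.
#' @param ... passed to [plate_scene()].
#' @return a `plate_scene`.
#' @export
scene_from_layout <- function(layout, assay, sample_conc = NULL, ...) {
  conc <- setNames(rep(NA_real_, 96L), layout$well_id)
  std <- layout$role == "standard"
  conc[layout$well_id[std]] <- layout$concentration[std]
  if (!is.null(sample_conc)) conc[names(sample_conc)] <- sample_conc
  plate_scene(concentrations = conc[!is.na(conc)], assay = assay,
              geometry = c(slas_geometry()[c("plate_width_mm", "plate_height_mm")],
                           list(pitch_mm = layout$x_mm[2] - layout$x_mm[1],
                                a1_x_mm = layout$x_mm[1], a1_y_mm = layout$y_mm[1],
                                well_radius_mm = layout$radius_mm[1])), ...)
}

#' Read and write scene specifications as YAML
#'
#' @param scene a [plate_scene()].
#' @param path file path.
#' @return `read_scene()` returns a [plate_scene()].
#' @export
write_scene <- function(scene, path) {
  x <- list(
    concentrations = as.list(scene$concentrations[!is.na(scene$concentrations)]),
    assay = assay_to_list(scene$assay),
    geometry = scene$geometry,
    fiducials = list(centers = apply(scene$fiducials$centers, 1, as.list),
                     size_mm = scene$fiducials$size_mm),
    illumination = scene$illumination, noise = scene$noise,
    camera = list(H = as.vector(t(scene$camera$H)),
                  width_px = scene$camera$width_px, height_px = scene$camera$height_px),
    white_rgb = scene$white_rgb, well_base_rgb = scene$well_base_rgb,
    fiducial_rgb = scene$fiducial_rgb, supersample = scene$supersample,
    seed = scene$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

assay_to_list <- function(assay) {
  w <- assay$weights
  x <- unclass(assay)
  x$weights <- list(wavelength_nm = w$wavelength_nm, RS = w$RS, GS = w$GS, BS = w$BS)
  x
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- yaml::read_yaml(path)
  a <- x$assay
  assay <- assay_config(analyte = a$analyte, wavelength_nm = a$wavelength_nm,
                        weights = spectral_weights(a$weights$RS, a$weights$GS, a$weights$BS,
                                                   wavelength_nm = a$weights$wavelength_nm %||% a$wavelength_nm),
                        standards = as.numeric(a$standards), units = a$units,
                        range = as.numeric(a$range),
                        response = lapply(a$response, function(v) if (length(v) > 1) as.numeric(v) else v),
                        blank_rgb = as.numeric(a$blank_rgb))
  Hm <- matrix(as.numeric(x$camera$H), 3, 3, byrow = TRUE)
  centers <- do.call(rbind, lapply(x$fiducials$centers, function(p) as.numeric(unlist(p))))
  rownames(centers) <- c("TL", "TR", "BL", "BR")
  colnames(centers) <- c("x_mm", "y_mm")
  plate_scene(concentrations = unlist(x$concentrations),
              assay = assay, geometry = x$geometry,
              fiducials = list(centers = centers, size_mm = x$fiducials$size_mm),
              illumination = lapply(x$illumination, function(v) as.numeric(unlist(v))),
              noise = lapply(x$noise, function(v) as.numeric(unlist(v))),
              camera = list(H = Hm, Hinv = solve(Hm),
                            width_px = x$camera$width_px, height_px = x$camera$height_px),
              white_rgb = as.numeric(x$white_rgb),
              well_base_rgb = as.numeric(x$well_base_rgb),
              fiducial_rgb = as.numeric(x$fiducial_rgb),
              supersample = x$supersample %||% 16L,
              seed = x$seed)
}
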