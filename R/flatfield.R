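#' Build a flat-field gain map from an aligned white image
#'
#' The white-block image records the product of the illumination field and
#' the sensor's spatial response. The correction is a per-pixel,
#' per-channel multiplicative gain,
#' `gain(p, ch) = median_ch / white_smoothed(p, ch)`,
#' where the white image is first Gaussian-smoothed (default sigma 2% of
#' the image width) to suppress target texture and sensor noise without
#' blurring the illumination field, and the per-channel median is the
#' reference level (robust to specular highlights, unlike the maximum).
#' By construction the per-channel median gain is 1.
#' No dark-frame term: a single white image supports a multiplicative
#' model only, and dark offset is negligible for a well-exposed camera.
#'
#' @param white an aligned [plate_image()] of the white block.
#' @param smooth_sigma Gaussian sigma in px; default `0.02 * width`;
#'   `0` disables smoothing.
#' @return a `flatfield`: list with `gain` (array like the input),
#'   `medians` (per-channel reference levels), `smooth_sigma`.
#' @export
build_flatfield <- function(white, smooth_sigma = NULL) {
  d <- dim(white)
  if (is.null(smooth_sigma)) smooth_sigma <- 0.02 * d[2]
  gain <- array(NA_real_, d)
  medians <- numeric(3L)
  for (ch in 1:3) {
    plane <- white[, , ch]
    na <- is.na(plane)
    frac_sat <- mean(plane[!na] >= 255)
    if (is.nan(frac_sat) || frac_sat > 0.01)
      stop("white image saturated in channel ", ch)
    if (smooth_sigma > 0) {
      filled <- plane
      filled[na] <- median(plane[!na])
      sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(filled / 255),
                                              sigma = smooth_sigma)) * 255
      sm[na] <- NA_real_
    } else {
      sm <- plane
    }
    if (any(sm[!na] <= 0))
      stop("white image has zero-valued pixels after smoothing in channel ", ch)
    med <- median(sm[!na])        # reference level: median of the smoothed white
    g <- med / sm
    medians[ch] <- med
    gain[, , ch] <- g
  }
  ratio <- max(gain, na.rm = TRUE) / min(gain, na.rm = TRUE)
  if (!is.finite(ratio) || ratio >= 10)
    stop(sprintf("flat-field gain spread too large (max/min = %.2f >= 10); bad white image", ratio))
  structure(list(gain = gain, medians = medians, smooth_sigma = smooth_sigma,
                 pixels_per_mm = attr(white, "pixels_per_mm")),
            class = "flatfield")
}

#' @export
print.flatfield <- function(x, ...) {
  cat(sprintf("<flatfield %d x %d px, gain range [%.3f, %.3f], reference levels %s>\n",
              dim(x$gain)[2], dim(x$gain)[1],
              min(x$gain, na.rm = TRUE), max(x$gain, na.rm = TRUE),
              paste(sprintf("%.1f", x$medians), collapse = "/")))
  invisible(x)
}

#' Apply a flat-field correction
#'
#' Per-pixel multiplication by the gain map, clipped to `[0, 255]`.
#' `NA` sentinel pixels pass through.
#'
#' @param test an aligned [plate_image()] with the same dimensions as the
#'   gain map.
#' @param ff a `flatfield` from [build_flatfield()].
#' @return the corrected [plate_image()].
#' @export
apply_flatfield <- function(test, ff) {
  if (!all(dim(test) == dim(ff$gain)))
    stop("image and flat-field dimensions differ")
  out <- clip255(unclass(test) * ff$gain)
  plate_image(out, provenance = attr(test, "provenance") %||% "test",
              pixels_per_mm = attr(test, "pixels_per_mm"))
}

#' Write and read a flat-field as a gain TIFF-free text bundle
#'
#' The gain map is stored as a plain matrix CSV per channel plus JSON
#' metadata, keeping fixtures text-only and portable.
#'
#' @param ff a `flatfield`.
#' @param path base path (without extension).
#' @return `read_flatfield()` returns a `flatfield`.
#' @export
write_flatfield <- function(ff, path) {
  d <- dim(ff$gain)
  jsonlite::write_json(list(dim = d, medians = ff$medians,
                            smooth_sigma = ff$smooth_sigma,
                            pixels_per_mm = ff$pixels_per_mm),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  m <- matrix(ff$gain, d[1], d[2] * 3L)
  utils::write.csv(m, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_flatfield
#' @export
read_flatfield <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  structure(list(gain = array(m, meta$dim), medians = meta$medians,
                 smooth_sigma = meta$smooth_sigma,
                 pixels_per_mm = meta$pixels_per_mm),
            class = "flatfield")
}
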