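#' Plate image container
#'
#' A plate image is a numeric `height x width x 3` array of 8-bit RGB
#' intensities on the 0--255 scale. Pixels that fall outside the source
#' image after registration are carried as `NA` sentinels and are excluded
#' from every downstream histogram. Pixel centres sit at half-integer
#' coordinates: pixel `(row r, col c)` has centre `(x, y) = (c - 0.5, r - 0.5)`.
#'
#' @param data numeric array with dimensions `c(height, width, 3)`,
#'   values in `[0, 255]` or `NA`.
#' @param provenance one of `"test"`, `"white-calibration"`, `"synthetic"`.
#' @param pixels_per_mm optional scale of a registered image (px per mm).
#' @return object of class `plate_image` (a numeric array with attributes).
#' @export
plate_image <- function(data, provenance = "test", pixels_per_mm = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("plate image must be a height x width x 3 array")
  storage.mode(data) <- "double"
  rng <- suppressWarnings(range(data, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255))
    stop("plate image intensities must lie in [0, 255]")
  structure(data,
            provenance = provenance,
            pixels_per_mm = pixels_per_mm,
            class = c("plate_image", "array"))
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<plate_image %d x %d px, provenance: %s%s, %d NA px>\n",
              d[2], d[1], attr(x, "provenance") %||% "unknown",
              if (!is.null(attr(x, "pixels_per_mm")))
                sprintf(", %.3g px/mm", attr(x, "pixels_per_mm")) else "",
              sum(is.na(x[, , 1]))))
  invisible(x)
}

img_dim <- function(img) dim(img)[1:2]

# Clip to [0, 255] and quantize to 8-bit integers. base::round() rounds
# half to even, matching commodity camera ADC conventions used here.
quantize8 <- function(x) round(pmin(pmax(x, 0), 255))

clip255 <- function(x) pmin(pmax(x, 0), 255)

as_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

#' Read and write plate images as 8-bit PNG
#'
#' @param path file path.
#' @param provenance provenance tag to attach on read.
#' @return `read_plate_image()` returns a [plate_image()]; `write_plate_image()`
#'   returns `path` invisibly.
#' @export
read_plate_image <- function(path, provenance = "test") {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  plate_image(raw * 255, provenance = provenance)
}

#' @rdname read_plate_image
#' @param img a [plate_image()]; `NA` pixels are written as black.
#' @export
write_plate_image <- function(img, path) {
  x <- unclass(img)
  x[is.na(x)] <- 0
  png::writePNG(quantize8(x) / 255, path)
  invisible(path)
}
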