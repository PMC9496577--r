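#' Detect the four dark fiducial squares
#'
#' Otsu-thresholds the grayscale image, labels connected dark components,
#' and keeps components that look like solid squares: area within
#' `[0.25, 4]` times the expected fiducial area (when known), solidity
#' > 0.8, and a 99th-percentile/mean radial-distance ratio above 1.62.
#' The radial ratio (about 1.72 for a square, 1.49 for a disc; invariant
#' to rotation and robust to boundary noise) separates the square markers
#' from circular dye wells, which are equally dark and solid on a loaded
#' plate; a channel-neutrality cut (mean RGB spread <= 40) additionally
#' rejects chromatic dye spots whose shape was distorted by glare or
#' bubbles -- the markers are gray, dye is coloured.
#' Exactly one candidate must remain in each image quadrant;
#' centroids are computed by normalized coverage for sub-pixel precision.
#'
#' @param image a [plate_image()] (raw, unregistered).
#' @param expected_area_px expected fiducial area in pixels, or `NULL` to
#'   skip the absolute area band.
#' @param min_area_px discard components smaller than this before scoring.
#' @return a `fiducial_set`: data frame with columns `label`
#'   (TL/TR/BL/BR), `x_px`, `y_px`, `area_px`.
#' @export
detect_fiducials <- function(image, expected_area_px = NULL, min_area_px = 64) {
  gray <- as_gray(image)
  gray[is.na(gray)] <- 255      # sentinels count as background
  d <- dim(gray); Hpx <- d[1]; Wpx <- d[2]
  th <- EBImage::otsu(EBImage::Image(gray / 255))
  mask <- gray / 255 < th
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  cand <- which(counts >= min_area_px & counts <= 0.05 * Hpx * Wpx)
  if (!is.null(expected_area_px))
    cand <- cand[counts[cand] >= 0.25 * expected_area_px &
                 counts[cand] <= 4 * expected_area_px]
  feats <- list()
  for (k in cand) {
    idx <- which(lab == k, arr.ind = TRUE)
    r <- idx[, 1]; cc <- idx[, 2]
    n <- length(r)
    d <- sqrt((r - mean(r))^2 + (cc - mean(cc))^2)
    radial_ratio <- stats::quantile(d, 0.99, names = FALSE) / mean(d)
    if (radial_ratio < 1.62) next   # disc-like (a dye well), not a square
    chans <- c(mean(image[, , 1][idx]), mean(image[, , 2][idx]),
               mean(image[, , 3][idx]))
    if (max(chans) - min(chans) > 40) next  # chromatic: dye, not a gray marker
    hull <- grDevices::chull(cc, r)
    hx <- cc[hull]; hy <- r[hull]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    solidity <- if (hull_area > 0) n / hull_area else 1
    if (solidity < 0.8) next
    ctr <- coverage_centroid(gray, lab, k, r, cc, Hpx, Wpx)
    feats[[length(feats) + 1L]] <- data.frame(
      x_px = ctr[1], y_px = ctr[2], area_px = n)
  }
  found <- if (length(feats)) do.call(rbind, feats) else
    data.frame(x_px = numeric(), y_px = numeric(), area_px = numeric())
  quadrant <- function(x, y) {
    paste0(ifelse(y < Hpx / 2, "T", "B"), ifelse(x < Wpx / 2, "L", "R"))
  }
  q <- quadrant(found$x_px, found$y_px)
  dup <- names(which(table(q) > 1))
  if (length(dup))
    stop("multiple fiducial candidates in quadrant ", paste(dup, collapse = ", "))
  if (nrow(found) != 4L)
    stop(sprintf("expected 4 fiducials, found %d", nrow(found)))
  out <- found[match(c("TL", "TR", "BL", "BR"), q), ]
  if (max(out$area_px) > 3 * min(out$area_px))
    stop("fiducial candidate areas are inconsistent (> 3x spread)")
  out <- cbind(label = c("TL", "TR", "BL", "BR"), out)
  rownames(out) <- NULL
  class(out) <- c("fiducial_set", "data.frame")
  out
}

dilate3 <- function(m) {
  EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1),
                                     EBImage::makeBrush(3, "box"))) > 0
}

erode3 <- function(m) !dilate3(!m)

# Sub-pixel centroid of a dark marker by normalized coverage: local
# background and dark levels are fitted as planes (cancelling the
# illumination gradient), each pixel's marker coverage is
# (bg - I) / (bg - dark), and the centroid is coverage-weighted. Interior
# pixels weigh exactly 1; anti-aliased edge pixels weigh by their true
# coverage fraction.
coverage_centroid <- function(gray, lab, k, r, cc, Hpx, Wpx) {
  r0 <- max(1L, min(r) - 3L); r1 <- min(Hpx, max(r) + 3L)
  c0 <- max(1L, min(cc) - 3L); c1 <- min(Wpx, max(cc) + 3L)
  sub <- gray[r0:r1, c0:c1]
  mask <- lab[r0:r1, c0:c1] == k
  xs <- rep(c0:c1, each = nrow(sub)) - 0.5
  ys <- rep(r0:r1, times = ncol(sub)) - 0.5
  near <- dilate3(mask)
  bg_px <- !dilate3(near)                 # >= 2 px away from the marker
  core <- erode3(erode3(mask))            # >= 2 px inside the marker
  plane <- function(sel) {
    if (sum(sel) < 6L) return(function(x, y) rep(mean(sub[sel]), length(x)))
    fit <- stats::lm.fit(cbind(1, xs[sel], ys[sel]), as.vector(sub)[sel])
    function(x, y) fit$coefficients[1] + fit$coefficients[2] * x +
      fit$coefficients[3] * y
  }
  bgp <- plane(bg_px); dkp <- plane(core)
  x <- xs[near]; y <- ys[near]
  b <- bgp(x, y); d <- dkp(x, y)
  cov <- pmin(pmax((b - as.vector(sub)[near]) / pmax(b - d, 1), 0), 1)
  c(sum(x * cov) / sum(cov), sum(y * cov) / sum(cov))
}

#' Fit the pixel-to-plate transform from fiducials
#'
#' Exact projective homography through the four fiducial correspondences
#' (4 points, 8 constraints, 8 degrees of freedom).
#'
#' @param fiducials a `fiducial_set` from [detect_fiducials()].
#' @param canonical 4 x 2 matrix of the fiducials' plate-frame positions
#'   (mm), rows ordered TL, TR, BL, BR as in [default_fiducials()].
#' @return a `plate_transform`: list with `H` (px to mm), `Hinv` (mm to
#'   px), and `residual_mm` (max reprojection error over the four points).
#' @export
fit_transform <- function(fiducials, canonical = default_fiducials()$centers) {
  src <- as.matrix(fiducials[, c("x_px", "y_px")])
  dst <- as.matrix(canonical)
  H <- fit_homography(src, dst)
  proj <- apply_homography(H, src)
  residual <- max(sqrt(rowSums((proj - dst)^2)))
  structure(list(H = H, Hinv = solve(H), residual_mm = residual),
            class = "plate_transform")
}

#' @export
print.plate_transform <- function(x, ...) {
  cat(sprintf("<plate_transform, max fiducial reprojection %.3g mm>\n", x$residual_mm))
  invisible(x)
}

#' Write and read a plate transform as JSON
#' @param transform a `plate_transform`.
#' @param path file path.
#' @return `read_transform()` returns a `plate_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(H = transform$H, residual_mm = transform$residual_mm),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(unlist(x$H), 3, 3)
  structure(list(H = H, Hinv = solve(H), residual_mm = x$residual_mm),
            class = "plate_transform")
}

#' Rectify an image into the canonical plate frame
#'
#' Resamples the image onto a millimetre grid (bilinear interpolation) so
#' that plate position `(x, y)` mm lands at pixel
#' `(row, col) = (y * scale, x * scale)`. Pixels that map outside the
#' source image become `NA` sentinels, excluded from all downstream
#' histograms.
#'
#' @param image a [plate_image()].
#' @param transform a `plate_transform` from [fit_transform()].
#' @param scale output resolution, px per mm (> 0).
#' @param plate_dims plate width/height in mm.
#' @return a registered [plate_image()] with `pixels_per_mm` set.
#' @export
align <- function(image, transform, scale = 5, plate_dims = c(127.76, 85.48)) {
  if (!is.numeric(scale) || scale <= 0) stop("output scale must be positive")
  Wout <- ceiling(plate_dims[1] * scale)
  Hout <- ceiling(plate_dims[2] * scale)
  x_mm <- (rep((1:Wout) - 0.5, each = Hout)) / scale
  y_mm <- (rep((1:Hout) - 0.5, times = Wout)) / scale
  src <- apply_homography(transform$Hinv, cbind(x_mm, y_mm))
  vals <- sample_bilinear(unclass(image), src[, 1], src[, 2])
  arr <- array(vals, c(Hout, Wout, 3L))
  plate_image(arr, provenance = attr(image, "provenance") %||% "test",
              pixels_per_mm = scale)
}
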