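#' Segment the 96 well ROIs of an aligned image
#'
#' Each well's region of interest is the circle of the layout centre and
#' `roi_fraction` times the layout radius (default 0.7, which keeps the
#' ROI clear of the well wall and rim shadow). Sentinel (`NA`) pixels are
#' excluded.
#'
#' @param image an aligned, flat-fielded [plate_image()] (needs a
#'   `pixels_per_mm` attribute).
#' @param layout a [plate_layout()].
#' @param roi_fraction fraction of the well radius used for the ROI.
#' @param min_pixels minimum usable pixels per ROI before erroring.
#' @return named list (by well ID) of integer vectors of linear indices
#'   into one image plane.
#' @export
segment_wells <- function(image, layout, roi_fraction = 0.7, min_pixels = 50) {
  scale <- attr(image, "pixels_per_mm")
  if (is.null(scale)) stop("image lacks a pixels_per_mm attribute; align it first")
  d <- dim(image); Hpx <- d[1]; Wpx <- d[2]
  usable <- !is.na(image[, , 1])
  out <- vector("list", nrow(layout))
  names(out) <- layout$well_id
  for (k in seq_len(nrow(layout))) {
    cx <- layout$x_mm[k] * scale          # px coords, centres at half-integers
    cy <- layout$y_mm[k] * scale
    r <- layout$radius_mm[k] * roi_fraction * scale
    cols <- max(1L, floor(cx - r)):min(Wpx, ceiling(cx + r) + 1L)
    rows <- max(1L, floor(cy - r)):min(Hpx, ceiling(cy + r) + 1L)
    px <- expand.grid(row = rows, col = cols)
    keep <- (px$col - 0.5 - cx)^2 + (px$row - 0.5 - cy)^2 <= r^2
    idx <- (px$col[keep] - 1L) * Hpx + px$row[keep]
    idx <- idx[usable[idx]]
    if (length(idx) < min_pixels)
      stop("well ", layout$well_id[k], " has fewer than ", min_pixels, " usable pixels")
    out[[k]] <- idx
  }
  out
}

#' Histogram-mode intensity of a pixel set
#'
#' The 8-bit intensity bin (256 integer bins) with the highest count; ties
#' break toward the lower intensity. The mode is what makes the readout
#' robust to glare, bubbles and reflections: artifacts move pixels out of
#' the majority bin but rarely form a larger one.
#'
#' @param values numeric vector of one channel's ROI intensities (0--255;
#'   non-integers are binned by rounding).
#' @return the mode intensity as an integer value.
#' @export
mode_intensity <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty pixel set")
  bins <- pmin(pmax(round(values), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  which.max(counts) - 1L        # first max = lowest bin on ties
}

#' Spectrally weighted scalar intensity
#'
#' `y = a I_R + b I_G + c I_B` with the normalized camera-sensitivity
#' weights.
#'
#' @param modes numeric length-3 vector of RGB mode intensities.
#' @param weights a [spectral_weights()].
#' @return the scalar intensity `y`.
#' @export
weighted_intensity <- function(modes, weights) {
  stopifnot(inherits(weights, "spectral_weights"), length(modes) == 3L)
  weights$a * modes[1] + weights$b * modes[2] + weights$c * modes[3]
}

#' Reduce every well to RGB modes and a weighted intensity
#'
#' Channel modes are computed first, then combined by [weighted_intensity()]
#' -- mode before weighting, so artifact robustness acts per channel.
#'
#' @inheritParams segment_wells
#' @param weights a [spectral_weights()].
#' @return a `well_readings` data frame: `well_id`, `role`, `I_R`, `I_G`,
#'   `I_B`, `y`, `n_px`, `mode_share` (fraction of ROI pixels within one
#'   bin of the mode, averaged over channels).
#' @export
read_wells <- function(image, layout, weights, roi_fraction = 0.7) {
  rois <- segment_wells(image, layout, roi_fraction = roi_fraction)
  n <- nrow(layout)
  IR <- IG <- IB <- share <- numeric(n)
  npx <- integer(n)
  planes <- list(image[, , 1], image[, , 2], image[, , 3])
  for (k in seq_len(n)) {
    idx <- rois[[k]]
    m <- s <- numeric(3L)
    for (ch in 1:3) {
      v <- planes[[ch]][idx]
      m[ch] <- mode_intensity(v)
      s[ch] <- mean(abs(round(v) - m[ch]) <= 1)
    }
    IR[k] <- m[1]; IG[k] <- m[2]; IB[k] <- m[3]
    share[k] <- mean(s)
    npx[k] <- length(idx)
  }
  out <- data.frame(well_id = layout$well_id, role = layout$role,
                    row = layout$row, col = layout$col,
                    I_R = IR, I_G = IG, I_B = IB,
                    y = weights$a * IR + weights$b * IG + weights$c * IB,
                    n_px = npx, mode_share = share,
                    stringsAsFactors = FALSE)
  class(out) <- c("well_readings", "data.frame")
  out
}
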