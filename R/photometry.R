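#' Most frequent empty-well intensity across the plate
#'
#' Histograms the 96 weighted intensities over 256 integer levels and
#' returns the most frequent one. Wells holding solution take varying
#' values while empty wells cluster tightly, so the argmax bin is the
#' empty-well level; ties break toward the higher intensity (empty wells
#' are the brightest repeated value).
#'
#' @param y numeric vector of per-well weighted intensities.
#' @return the modal intensity level `w` (integer value).
#' @export
global_empty_mode <- function(y) {
  bins <- pmin(pmax(round(y), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  max(which(counts == max(counts))) - 1L   # tie -> higher intensity
}

#' Local incident-light estimate for one well
#'
#' Collects the weighted intensities of all wells in the 5 x 5 grid window
#' centred on the well (truncated at the plate edges, centre included),
#' keeps those at or above 95% of the plate-wide empty-well level `w`, and
#' returns their mean. If no neighbour passes the cut the estimate falls
#' back to `w` and the fallback flag is set.
#'
#' @param well_id well identifier, e.g. `"C7"`.
#' @param readings a `well_readings` data frame from [read_wells()].
#' @param w plate-wide empty-well level from [global_empty_mode()].
#' @param window odd window size in wells (5 = the 5 x 5 neighbourhood).
#' @return list with `wL` (incident estimate), `P` (window cardinality),
#'   `Q` (empty wells found), `fallback` (logical).
#' @export
local_incident <- function(well_id, readings, w, window = 5L) {
  k <- match(well_id, readings$well_id)
  if (is.na(k)) stop("unknown well ", well_id)
  half <- (window - 1L) %/% 2L
  inwin <- abs(readings$row - readings$row[k]) <= half &
           abs(readings$col - readings$col[k]) <= half
  S_y <- readings$y[inwin]
  S_w <- S_y[S_y >= 0.95 * w]
  if (length(S_w)) {
    list(wL = mean(S_w), P = length(S_y), Q = length(S_w), fallback = FALSE)
  } else {
    list(wL = w, P = length(S_y), Q = 0L, fallback = TRUE)
  }
}

#' Optical density of a well
#'
#' `OD = -log10(wL / y)`: the logarithmic ratio of the incident-light
#' estimate to the transmitted (measured) intensity. Under this printed
#' sign convention an absorbing solution has OD <= 0 -- the negative of
#' conventional absorbance; the standard-curve slope absorbs the sign.
#' Set `conventional = TRUE` to flip to absorbance (`log10(wL / y)`).
#'
#' @param y weighted well intensity (transmitted light), > 0.
#' @param wL local incident-light estimate, > 0.
#' @param conventional flip the sign to conventional absorbance.
#' @return the optical density (NA where `y <= 0`, i.e. fully dark).
#' @export
optical_density <- function(y, wL, conventional = FALSE) {
  if (any(wL <= 0)) stop("incident estimate must be positive")
  od <- ifelse(y > 0, -log10(wL / y), NA_real_)
  if (conventional) -od else od
}

#' Per-well optical densities with incident-light estimation
#'
#' Runs [global_empty_mode()], [local_incident()] and [optical_density()]
#' across the plate.
#'
#' @param readings a `well_readings` data frame from [read_wells()].
#' @param conventional sign convention flag, see [optical_density()].
#' @param window neighbourhood size in wells.
#' @return an `od_table` data frame: `well_id`, `role`, `y`, `w`, `wL`,
#'   `P`, `Q`, `od`, `fallback_incident`, `saturated`.
#' @export
od_table <- function(readings, conventional = FALSE, window = 5L) {
  w <- global_empty_mode(readings$y)
  n <- nrow(readings)
  wL <- numeric(n); P <- Q <- integer(n); fb <- logical(n)
  for (k in seq_len(n)) {
    li <- local_incident(readings$well_id[k], readings, w, window = window)
    wL[k] <- li$wL; P[k] <- li$P; Q[k] <- li$Q; fb[k] <- li$fallback
  }
  od <- optical_density(readings$y, wL, conventional = conventional)
  out <- data.frame(well_id = readings$well_id, role = readings$role,
                    y = readings$y, w = w, wL = wL, P = P, Q = Q, od = od,
                    fallback_incident = fb, saturated = readings$y <= 0,
                    stringsAsFactors = FALSE)
  attr(out, "conventional") <- conventional
  class(out) <- c("od_table", "data.frame")
  out
}
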