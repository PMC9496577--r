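#' Spectral channel weights
#'
#' The camera reduces a well to three RGB intensities; a single scalar
#' intensity is their weighted average, with weights proportional to the
#' camera's channel sensitivities at the assay's peak absorbance
#' wavelength:
#' \deqn{a = RS / (RS + GS + BS), \quad b = GS / (RS + GS + BS), \quad
#'       c = BS / (RS + GS + BS)}
#'
#' @param RS,GS,BS camera red/green/blue sensitivities (unitless, > 0) at
#'   the absorbance wavelength.
#' @param wavelength_nm the absorbance wavelength the sensitivities were
#'   read at (informational).
#' @return object of class `spectral_weights` with fields `RS`, `GS`, `BS`,
#'   `a`, `b`, `c`, `wavelength_nm`.
#' @examples
#' spectral_weights(0.07, 0.82, 0.66, wavelength_nm = 490)
#' @export
spectral_weights <- function(RS, GS, BS, wavelength_nm = NA_real_) {
  if (any(!is.finite(c(RS, GS, BS))) || any(c(RS, GS, BS) <= 0))
    stop("channel sensitivities must be positive and finite")
  s <- RS + GS + BS
  structure(list(wavelength_nm = wavelength_nm, RS = RS, GS = GS, BS = BS,
                 a = RS / s, b = GS / s, c = BS / s),
            class = "spectral_weights")
}

#' @export
print.spectral_weights <- function(x, ...) {
  cat(sprintf("Spectral weights @ %s nm: a=%.5f b=%.5f c=%.5f (RS=%.3g GS=%.3g BS=%.3g)\n",
              format(x$wavelength_nm), x$a, x$b, x$c, x$RS, x$GS, x$BS))
  invisible(x)
}

#' Interpolate channel sensitivities from a camera sensitivity curve
#'
#' @param curve data frame with columns `wavelength_nm`, `RS`, `GS`, `BS`
#'   (e.g. digitised from the sensor datasheet).
#' @param wavelength_nm wavelength to interpolate at (must lie within the
#'   curve's range).
#' @return a [spectral_weights()] object.
#' @export
weights_from_curve <- function(curve, wavelength_nm) {
  need <- c("wavelength_nm", "RS", "GS", "BS")
  if (!all(need %in% names(curve))) stop("curve needs columns ", paste(need, collapse = ", "))
  if (wavelength_nm < min(curve$wavelength_nm) || wavelength_nm > max(curve$wavelength_nm))
    stop("wavelength outside the sensitivity curve range")
  ip <- function(col) stats::approx(curve$wavelength_nm, curve[[col]], xout = wavelength_nm)$y
  spectral_weights(ip("RS"), ip("GS"), ip("BS"), wavelength_nm = wavelength_nm)
}

#' Assay configuration
#'
#' Bundles everything analyte-specific: the absorbance wavelength and the
#' camera sensitivities there, the standard concentration series, the
#' detection range, and the dye response model used by the synthetic plate
#' generator.
#'
#' The dye response model gives the weighted transmittance
#' `T(c) = y(c) / y_blank` of a well at analyte concentration `c`:
#' \describe{
#'   \item{`"log_linear"` (default)}{`T(c) = (c / c_ref)^(-gamma)` for
#'     `c >= c_lo`, with a linear ramp from `T(0) = 1` down to the power
#'     law at `c_lo` (`c_lo` below the lowest nonzero standard). Saturating
#'     response: optical density is proportional to `log(c)` over the
#'     standards, the regime in which an exponential standard curve
#'     `Cd = exp(x OD + z)` is exact. This emulates the empirically
#'     log-linear response of camera-based white-plate readouts.}
#'   \item{`"beer_lambert"`}{`T(c) = 10^(-k c)`: ideal Beer--Lambert
#'     attenuation of the weighted intensity, so OD is proportional to
#'     `c`.}
#' }
#' In both models the attenuation is distributed across RGB channels with
#' relative absorptivities `alpha` (absorbance channel = 1, attenuates
#' most), scaled per concentration so the weighted intensity matches
#' `T(c)` exactly.
#'
#' @param analyte analyte name.
#' @param wavelength_nm peak absorbance wavelength (nm).
#' @param weights a [spectral_weights()] object.
#' @param standards ascending standard concentrations, including the zero
#'   standard, in `units`.
#' @param units concentration units (e.g. `"mmol/L"`, `"mg/dL"`).
#' @param range detection range `c(low, high)` in `units`.
#' @param response list describing the dye response model (see Details).
#' @param blank_rgb RGB colour of the zero-analyte (blank) well.
#' @param incubation_min informational incubation time (not computed on).
#' @return object of class `assay_config`.
#' @export
assay_config <- function(analyte, wavelength_nm, weights, standards, units,
                         range = base::range(standards),
                         response = list(model = "log_linear", gamma = 0.64,
                                         c_ref = standards[standards > 0][1] / 1.34,
                                         c_lo = standards[standards > 0][1] * 0.8,
                                         alpha = c(0.12, 1, 0.85)),
                         blank_rgb = c(247, 246, 244),
                         incubation_min = 30) {
  if (is.unsorted(standards, strictly = TRUE)) stop("standards must be strictly ascending")
  if (any(standards < 0)) stop("standard concentrations must be non-negative")
  if (sum(standards > 0) < 3L) stop("need at least 3 nonzero standards")
  if (range[1] >= range[2]) stop("detection range must have low < high")
  stopifnot(inherits(weights, "spectral_weights"))
  response$model <- match.arg(response$model, c("log_linear", "beer_lambert"))
  if (response$model == "log_linear") {
    if (is.null(response$gamma) || response$gamma <= 0) stop("log_linear model needs gamma > 0")
    if (is.null(response$c_ref) || is.null(response$c_lo) || response$c_lo < response$c_ref)
      stop("log_linear model needs c_lo >= c_ref > 0")
    if (response$c_lo >= min(standards[standards > 0]))
      stop("c_lo must lie below the lowest nonzero standard")
  } else {
    if (is.null(response$k) || response$k <= 0) stop("beer_lambert model needs extinction factor k > 0")
  }
  if (is.null(response$alpha)) response$alpha <- c(0.12, 1, 0.85)
  if (length(response$alpha) != 3L || any(response$alpha <= 0))
    stop("alpha must be 3 positive channel absorptivities")
  structure(list(analyte = analyte, wavelength_nm = wavelength_nm,
                 weights = weights, standards = standards, units = units,
                 range = range, response = response,
                 blank_rgb = blank_rgb, incubation_min = incubation_min),
            class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("Assay: %s @ %g nm [%s], %d standards %g-%g %s, response: %s\n",
              x$analyte, x$wavelength_nm, x$units, length(x$standards),
              min(x$standards), max(x$standards), x$units, x$response$model))
  invisible(x)
}

#' Built-in assay presets
#'
#' Jaffe creatinine (red complex, peak absorbance 490 nm, detection range
#' 0--1.77 mmol/L i.e. 0--20 mg/dL, doubling standard series) and glucose
#' oxidase/peroxidase (pink product, 560 nm, 0--32 mg/dL). Camera channel
#' sensitivities are the Sony IMX219 values at the respective wavelengths.
#'
#' @return an [assay_config()].
#' @export
creatinine_assay <- function() {
  assay_config(
    analyte = "creatinine", wavelength_nm = 490,
    weights = spectral_weights(0.07, 0.82, 0.66, wavelength_nm = 490),
    standards = c(0, 0.0553, 0.1105, 0.221, 0.442, 0.884, 1.77),
    units = "mmol/L", range = c(0, 1.77),
    response = list(model = "log_linear", gamma = 0.64, c_ref = 0.0413,
                    c_lo = 0.045, alpha = c(0.12, 1, 0.85)))
}

#' @rdname creatinine_assay
#' @export
glucose_assay <- function() {
  assay_config(
    analyte = "glucose", wavelength_nm = 560,
    weights = spectral_weights(0.13, 0.83, 0.11, wavelength_nm = 560),
    standards = c(0, 1, 2, 4, 8, 16, 32),
    units = "mg/dL", range = c(0, 32),
    response = list(model = "log_linear", gamma = 0.64, c_ref = 0.747,
                    c_lo = 0.8, alpha = c(0.15, 1, 0.35)))
}

#' Read and write assay configurations as YAML
#'
#' @param assay an [assay_config()].
#' @param path file path.
#' @return `read_assay()` returns an [assay_config()].
#' @export
write_assay <- function(assay, path) {
  x <- unclass(assay)
  w <- x$weights
  x$weights <- list(wavelength_nm = w$wavelength_nm, RS = w$RS, GS = w$GS, BS = w$BS)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  x <- yaml::read_yaml(path)
  assay_config(analyte = x$analyte, wavelength_nm = x$wavelength_nm,
               weights = spectral_weights(x$weights$RS, x$weights$GS, x$weights$BS,
                                          wavelength_nm = x$weights$wavelength_nm %||% x$wavelength_nm),
               standards = as.numeric(x$standards), units = x$units,
               range = as.numeric(x$range),
               response = lapply(x$response, function(v) if (is.list(v)) unlist(v) else v),
               blank_rgb = as.numeric(x$blank_rgb),
               incubation_min = x$incubation_min %||% 30)
}
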