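#' Fit the log-linear standard curve
#'
#' Ordinary least squares of log concentration on optical density:
#' \deqn{\ln C_d = x \cdot OD + z}
#' so that \eqn{C_d = e^{x \cdot OD + z}}. The zero standard cannot enter
#' the log fit (ln 0 undefined); it is retained as a quality-control point
#' whose OD should be near 0, reported in the fit summary.
#'
#' @param concentration standard concentrations (assay units), may include
#'   the zero standard.
#' @param od matching optical densities.
#' @param assay optional [assay_config()]; records units and detection
#'   range on the fit.
#' @param conventional sign convention the ODs were computed under
#'   (recorded, not acted on: the slope absorbs the sign).
#' @return a `standard_curve` object with components `x` (slope), `z`
#'   (intercept), `r_squared`, `residuals`, `od_range`, `conc_range`,
#'   `zero_od`, `n`, `data`, and the underlying `lm` fit. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' od <- c(-1, -0.5, -0.2)
#' fit <- fit_standard_curve(exp(2 * od + 1), od)
#' coef(fit)   # x = 2, z = 1
#' @export
fit_standard_curve <- function(concentration, od, assay = NULL,
                               conventional = FALSE) {
  if (length(concentration) != length(od)) stop("concentration and od lengths differ")
  ok <- !is.na(concentration) & !is.na(od)
  zero_od <- od[ok & concentration == 0]
  use <- ok & concentration > 0
  if (sum(use) < 3L) stop("need at least 3 nonzero standards to fit")
  if (var(od[use]) == 0) stop("degenerate standards: zero variance in OD")
  fit <- lm(log(concentration[use]) ~ od[use])
  co <- unname(coef(fit))
  structure(list(
    x = co[2], z = co[1],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    residuals = unname(residuals(fit)),
    od_range = range(od[use]),
    conc_range = range(concentration[use]),
    zero_od = if (length(zero_od)) zero_od else NA_real_,
    n = sum(use),
    conventional = conventional,
    units = if (!is.null(assay)) assay$units else NA_character_,
    detection_range = if (!is.null(assay)) assay$range else NULL,
    data = data.frame(concentration = concentration[use], od = od[use]),
    lm = fit), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, digits = 5, ...) {
  cat("Log-linear standard curve: ln(Cd) = x*OD + z\n")
  cat(sprintf("  x = %.*g, z = %.*g  (n = %d standards, R^2 = %.6f)\n",
              digits, x$x, digits, x$z, x$n, x$r_squared))
  cat(sprintf("  OD range [%.4g, %.4g], concentrations [%.4g, %.4g] %s\n",
              x$od_range[1], x$od_range[2], x$conc_range[1], x$conc_range[2],
              if (is.na(x$units)) "" else x$units))
  if (!all(is.na(x$zero_od)))
    cat(sprintf("  zero-standard OD (QC): %s\n",
                paste(sprintf("%.4g", x$zero_od), collapse = ", ")))
  cat(sprintf("  OD sign convention: %s\n",
              if (x$conventional) "conventional absorbance" else "as printed (absorbing => OD <= 0)"))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) c(x = object$x, z = object$z)

#' @export
residuals.standard_curve <- function(object, ...) object$residuals

#' @export
summary.standard_curve <- function(object, ...) {
  print(object)
  cat("\nPer-standard fit:\n")
  d <- object$data
  d$fitted <- exp(object$x * d$od + object$z)
  d$rel_error <- d$fitted / d$concentration - 1
  print(d, row.names = FALSE)
  invisible(object)
}

#' @export
plot.standard_curve <- function(x, ...) {
  d <- x$data
  graphics::plot(d$od, d$concentration, log = "y", xlab = "OD",
                 ylab = paste0("concentration", if (!is.na(x$units)) paste0(" (", x$units, ")")),
                 pch = 19, main = "Standard curve", ...)
  ods <- seq(min(d$od), max(d$od), length.out = 200)
  graphics::lines(ods, exp(x$x * ods + x$z), col = "firebrick")
  invisible(x)
}

#' Predict concentrations from a fitted standard curve
#'
#' `Cd = exp(x * OD + z)`, then the dilution correction `C = Cd * df`.
#' Flags are advisory, never failures: `above_range`/`below_range` when
#' the diluted concentration falls outside the standards' span (the
#' quantity actually on the curve), `extrapolated` when the OD is outside
#' the standards' OD span. An above-range result means the sample should
#' be diluted further and re-tested.
#'
#' @param object a `standard_curve`.
#' @param od optical densities to convert.
#' @param dilution_factor fold-dilution(s) applied before assay (>= 1).
#' @param ... unused.
#' @return data frame with columns `od`, `Cd`, `dilution_factor`, `C`,
#'   `above_range`, `below_range`, `extrapolated`.
#' @export
predict.standard_curve <- function(object, od, dilution_factor = 1, ...) {
  if (any(dilution_factor < 1, na.rm = TRUE)) stop("dilution factors must be >= 1")
  Cd <- exp(object$x * od + object$z)
  data.frame(od = od, Cd = Cd, dilution_factor = dilution_factor,
             C = Cd * dilution_factor,
             above_range = Cd > object$conc_range[2],
             below_range = Cd < object$conc_range[1],
             extrapolated = od < object$od_range[1] | od > object$od_range[2])
}

#' @rdname predict.standard_curve
#' @param curve a `standard_curve`.
#' @export
predict_concentration <- function(curve, od, dilution_factor = 1) {
  predict(curve, od = od, dilution_factor = dilution_factor)
}

#' Replicate mean and sample standard deviation
#'
#' Arithmetic mean and the n-1 denominator SD; for duplicate measurements
#' this is `|x1 - x2| / sqrt(2)`.
#'
#' @param x replicate concentrations of one group.
#' @return list with `mean`, `sd` (`NA` with `sd_undefined = TRUE` when
#'   fewer than 2 replicates), `n`.
#' @export
replicate_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no replicate values")
  list(mean = mean(x), sd = if (length(x) >= 2L) sd(x) else NA_real_,
       n = length(x), sd_undefined = length(x) < 2L)
}

#' Dilution-series advisory
#'
#' For a sample assayed at several dilution factors with replicates,
#' tabulates per-level mean and SD of the final concentrations and
#' recommends the dilution minimising the replicate SD among levels whose
#' diluted concentration stayed within the usable range (levels that fell
#' out of range -- e.g. over-diluted below the lowest standard -- are
#' excluded). Ties go to the lowest dilution factor.
#'
#' @param df vector of dilution factors (one entry per measurement).
#' @param concentration matching final (dilution-corrected) concentrations.
#' @param conc_range usable diluted-concentration range `c(low, high)`
#'   (e.g. the standards' span), or `NULL` to skip the range screen.
#' @return a `dilution_report` data frame (`dilution_factor`, `mean`, `sd`,
#'   `n`, `Cd_mean`, `in_range`) with attribute `recommended_df`.
#' @export
dilution_series_report <- function(df, concentration, conc_range = NULL) {
  stopifnot(length(df) == length(concentration))
  levels_df <- sort(unique(df))
  if (length(levels_df) < 2L) stop("need at least 2 dilution levels")
  rows <- lapply(levels_df, function(d) {
    st <- replicate_stats(concentration[df == d])
    cd <- st$mean / d
    data.frame(dilution_factor = d, mean = st$mean, sd = st$sd, n = st$n,
               Cd_mean = cd,
               in_range = if (is.null(conc_range)) TRUE
                          else cd >= conc_range[1] & cd <= conc_range[2])
  })
  out <- do.call(rbind, rows)
  eligible <- out$in_range & !is.na(out$sd)
  rec <- if (any(eligible)) {
    e <- out[eligible, ]
    e$dilution_factor[which.min(e$sd)]   # first min = lowest df on ties
  } else NA_real_
  attr(out, "recommended_df") <- rec
  class(out) <- c("dilution_report", "data.frame")
  out
}

#' @export
print.dilution_report <- function(x, ...) {
  cat("Dilution series:\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("Recommended dilution factor: %s\n",
              format(attr(x, "recommended_df"))))
  invisible(x)
}
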