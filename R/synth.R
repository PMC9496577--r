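#' Dye colour of a well at a given concentration
#'
#' Forward colour model of the synthetic renderer. The assay's response
#' model fixes the weighted transmittance `T(c) = y(c) / y_blank` (see
#' [assay_config()]); the attenuation is then distributed over the RGB
#' channels with the assay's relative channel absorptivities `alpha`
#' (absorbance-wavelength channel = 1, attenuates most): per channel,
#' `I_ch = blank_ch * 10^(-alpha_ch * t)` with the scalar `t >= 0` solved
#' per concentration so that the spectrally weighted intensity matches
#' `T(c)` exactly. The zero-analyte colour is the blank, unchanged, and
#' the weighted intensity is strictly decreasing in concentration.
#'
#' @param concentration non-negative concentration(s), assay units.
#' @param assay an [assay_config()].
#' @return `n x 3` matrix of RGB values in `[0, 255]` (continuous; the
#'   renderer quantizes).
#' @export
dye_color <- function(concentration, assay) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be non-negative and finite")
  Ty <- dye_transmittance(concentration, assay)
  w <- with(assay$weights, c(a, b, c))
  blank <- assay$blank_rgb
  alpha <- assay$response$alpha
  y_blank <- sum(w * blank)
  out <- matrix(NA_real_, length(concentration), 3L)
  for (i in seq_along(concentration)) {
    target <- Ty[i] * y_blank
    if (Ty[i] >= 1) { out[i, ] <- blank; next }
    f <- function(t) sum(w * blank * 10^(-alpha * t)) - target
    hi <- 1
    while (f(hi) > 0) hi <- hi * 2
    t <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    out[i, ] <- blank * 10^(-alpha * t)
  }
  clip255(out)
}

# Weighted transmittance T(c) in (0, 1] under the assay's response model.
dye_transmittance <- function(concentration, assay) {
  r <- assay$response
  if (r$model == "beer_lambert") {
    10^(-r$k * concentration)
  } else {
    T_pl <- function(c) (c / r$c_ref)^(-r$gamma)
    ifelse(concentration >= r$c_lo,
           T_pl(pmax(concentration, r$c_lo)),
           1 - (1 - T_pl(r$c_lo)) * concentration / r$c_lo)
  }
}

# Illumination field (unnormalized) at plate coordinates.
illum_raw <- function(scene, x_mm, y_mm) {
  il <- scene$illumination
  if (il$falloff == 0) return(rep(sum(il$rel_intensity), length(x_mm)))
  W <- scene$geometry$plate_width_mm; H <- scene$geometry$plate_height_mm
  src <- rbind(c(0, 0), c(W, 0), c(0, H), c(W, H))
  h2 <- il$height_mm^2
  v <- 0
  for (i in 1:4) {
    r2 <- (x_mm - src[i, 1])^2 + (y_mm - src[i, 2])^2
    v <- v + il$rel_intensity[i] * (h2 / (h2 + r2))^(il$falloff / 2)
  }
  v
}

# Pixel-centre grid of a scene's camera, column-major plane order, mapped
# to plate mm. `illum` is normalised to peak 1; `illum_max` is the
# normalisation constant (shared by the fiducial anti-aliasing pass).
scene_grid <- function(scene) {
  W <- scene$camera$width_px; H <- scene$camera$height_px
  x_px <- rep((1:W) - 0.5, each = H)
  y_px <- rep((1:H) - 0.5, times = W)
  mm <- apply_homography(scene$camera$Hinv, cbind(x_px, y_px))
  il <- illum_raw(scene, mm[, 1], mm[, 2])
  norm <- max(il)
  list(x_px = x_px, y_px = y_px, x_mm = mm[, 1], y_mm = mm[, 2],
       illum = il / norm, illum_max = norm)
}

# Anti-alias the fiducial squares with analytic edge coverage: each pixel
# near a marker is re-rendered as a blend of marker and plate colour
# weighted by the exact overlap of the pixel's plate-frame footprint with
# the marker square (separable in x and y; exact for the near-axis-aligned
# views of a fixed plate camera). This is the sub-pixel edge information a
# real camera's optical blur provides, and what makes sub-pixel fiducial
# localisation meaningful. Disabled when scene$supersample == 1.
aa_fiducials <- function(img, scene, grid) {
  if ((scene$supersample %||% 16L) <= 1L) return(img)
  H <- scene$camera$height_px; W <- scene$camera$width_px
  fc <- scene$fiducials$centers
  half <- scene$fiducials$size_mm / 2
  overlap1 <- function(lo, hi, a, b) pmax(0, pmin(hi, b) - pmax(lo, a))
  for (i in seq_len(nrow(fc))) {
    corners <- cbind(fc[i, 1] + c(-half, half, -half, half),
                     fc[i, 2] + c(-half, -half, half, half))
    pr <- apply_homography(scene$camera$H, corners)
    cols <- max(1L, floor(min(pr[, 1]) - 1)):min(W, ceiling(max(pr[, 1]) + 2))
    rows <- max(1L, floor(min(pr[, 2]) - 1)):min(H, ceiling(max(pr[, 2]) + 2))
    px <- expand.grid(row = rows, col = cols)
    x <- px$col - 0.5; y <- px$row - 0.5
    ctr <- apply_homography(scene$camera$Hinv, cbind(x, y))
    xl <- apply_homography(scene$camera$Hinv, cbind(x - 0.5, y))[, 1]
    xr <- apply_homography(scene$camera$Hinv, cbind(x + 0.5, y))[, 1]
    yt <- apply_homography(scene$camera$Hinv, cbind(x, y - 0.5))[, 2]
    yb <- apply_homography(scene$camera$Hinv, cbind(x, y + 0.5))[, 2]
    cx <- overlap1(pmin(xl, xr), pmax(xl, xr), fc[i, 1] - half, fc[i, 1] + half) /
      abs(xr - xl)
    cy <- overlap1(pmin(yt, yb), pmax(yt, yb), fc[i, 2] - half, fc[i, 2] + half) /
      abs(yb - yt)
    cover <- cx * cy
    illum <- illum_raw(scene, ctr[, 1], ctr[, 2]) / grid$illum_max
    idx <- (px$col - 1L) * H + px$row
    for (ch in 1:3) {
      img[idx, ch] <- (cover * scene$fiducial_rgb[ch] +
                       (1 - cover) * scene$white_rgb[ch]) * illum
    }
  }
  img
}

#' Render a synthetic plate photograph with ground truth
#'
#' Draws the white plate, four dark fiducial squares, the 8 x 12 well grid
#' (empty wells near-white, filled wells at their [dye_color()]), modulates
#' by the corner-LED illumination field, adds seeded Gaussian sensor noise
#' and glare/bubble artifacts, and quantizes to 8-bit (round half to even).
#' Renders are bit-identical for identical scenes (same seed).
#'
#' @param scene a [plate_scene()].
#' @return list with `image` (a [plate_image()]) and `truth`, a list with
#'   `wells` (data frame: `well_id`, `concentration`, `R`, `G`, `B` -- the
#'   quantized noiseless dye colour at unit illumination), `fiducials`
#'   (data frame: `label`, `x_px`, `y_px` -- analytic projections of the
#'   fiducial centres), and `homography` (the mm-to-px matrix used).
#' @export
render_plate <- function(scene) {
  g <- scene$geometry
  grid <- scene_grid(scene)
  npx <- length(grid$x_px)
  H <- scene$camera$height_px; W <- scene$camera$width_px

  # validate: every well disc projects inside the image
  ids <- well_ids()
  wx <- g$a1_x_mm + (rep(1:12, times = 8) - 1) * g$pitch_mm
  wy <- g$a1_y_mm + (rep(1:8, each = 12) - 1) * g$pitch_mm
  for (k in seq_len(96)) {
    pts <- rbind(c(wx[k] - g$well_radius_mm, wy[k]), c(wx[k] + g$well_radius_mm, wy[k]),
                 c(wx[k], wy[k] - g$well_radius_mm), c(wx[k], wy[k] + g$well_radius_mm))
    pr <- apply_homography(scene$camera$H, pts)
    if (any(pr[, 1] < 0 | pr[, 1] > W | pr[, 2] < 0 | pr[, 2] > H))
      stop("well ", ids[k], " projects outside the image")
  }

  # base reflectance per pixel
  base <- matrix(rep(scene$white_rgb, each = npx), npx, 3L)

  # fiducial squares
  fc <- scene$fiducials$centers
  half <- scene$fiducials$size_mm / 2
  for (i in seq_len(nrow(fc))) {
    m <- abs(grid$x_mm - fc[i, 1]) <= half & abs(grid$y_mm - fc[i, 2]) <= half
    base[m, ] <- matrix(rep(scene$fiducial_rgb, each = sum(m)), ncol = 3L)
  }

  # wells: nearest grid node, then radius test
  jj <- round((grid$x_mm - g$a1_x_mm) / g$pitch_mm)
  ii <- round((grid$y_mm - g$a1_y_mm) / g$pitch_mm)
  cx <- g$a1_x_mm + jj * g$pitch_mm
  cy <- g$a1_y_mm + ii * g$pitch_mm
  inwell <- ii >= 0 & ii <= 7 & jj >= 0 & jj <= 11 &
    (grid$x_mm - cx)^2 + (grid$y_mm - cy)^2 <= g$well_radius_mm^2
  widx <- ii * 12L + jj + 1L  # index into well_ids() order

  conc <- scene$concentrations
  well_rgb <- matrix(rep(scene$well_base_rgb, each = 96L), 96L, 3L)
  filled <- which(!is.na(conc))
  if (length(filled))
    well_rgb[filled, ] <- dye_color(conc[filled], scene$assay)
  base[inwell, ] <- well_rgb[widx[inwell], , drop = FALSE]

  img <- base * grid$illum
  img <- aa_fiducials(img, scene, grid)

  # seeded artifacts and sensor noise
  ns <- scene$noise
  img <- with_seed(scene$seed, {
    if ((ns$glare_n %||% 0) > 0) {
      for (k in seq_len(ns$glare_n)) {
        w <- sample.int(96L, 1L)
        r <- runif(1, ns$glare_r_mm[1], ns$glare_r_mm[2])
        th <- runif(1, 0, 2 * pi); d <- runif(1, 0, 0.5 * g$well_radius_mm)
        gx <- wx[w] + d * cos(th); gy <- wy[w] + d * sin(th)
        m <- (grid$x_mm - gx)^2 + (grid$y_mm - gy)^2 <= r^2
        img[m, ] <- 255
      }
    }
    if ((ns$bubble_n %||% 0) > 0) {
      for (k in seq_len(ns$bubble_n)) {
        w <- sample.int(96L, 1L)
        r <- runif(1, ns$bubble_r_mm[1], ns$bubble_r_mm[2])
        th <- runif(1, 0, 2 * pi); d <- runif(1, 0, 0.6 * g$well_radius_mm)
        bx <- wx[w] + d * cos(th); by <- wy[w] + d * sin(th)
        m <- (grid$x_mm - bx)^2 + (grid$y_mm - by)^2 <= r^2
        img[m, ] <- img[m, ] * 0.45
      }
    }
    if ((ns$sigma %||% 0) > 0)
      img <- img + rnorm(length(img), 0, ns$sigma)
    img
  })

  arr <- array(quantize8(img), c(H, W, 3L))
  truth_rgb <- quantize8(well_rgb)
  fid_px <- apply_homography(scene$camera$H, fc)
  if (any(fid_px[, 1] < 0 | fid_px[, 1] > W | fid_px[, 2] < 0 | fid_px[, 2] > H))
    stop("fiducial projects outside the image")
  list(image = plate_image(arr, provenance = "synthetic"),
       truth = list(
         wells = data.frame(well_id = ids, concentration = unname(conc),
                            R = truth_rgb[, 1], G = truth_rgb[, 2], B = truth_rgb[, 3]),
         fiducials = data.frame(label = rownames(fc),
                                x_px = fid_px[, 1], y_px = fid_px[, 2]),
         homography = scene$camera$H))
}

#' Render the white calibration image
#'
#' Same illumination, camera and sensor-noise model as [render_plate()],
#' but the target is a featureless white block covering the field of view.
#' The companion of a test image for flat-field calibration.
#'
#' @param scene a [plate_scene()].
#' @return a [plate_image()] with provenance `"white-calibration"`.
#' @export
render_white_block <- function(scene) {
  grid <- scene_grid(scene)
  npx <- length(grid$x_px)
  H <- scene$camera$height_px; W <- scene$camera$width_px
  base <- matrix(rep(scene$white_rgb, each = npx), npx, 3L)
  img <- base * grid$illum
  sigma <- scene$noise$sigma %||% 0
  if (sigma > 0)
    img <- with_seed(scene$seed + 1L, img + rnorm(length(img), 0, sigma))
  arr <- array(quantize8(img), c(H, W, 3L))
  plate_image(arr, provenance = "white-calibration")
}

#' Write a synthetic fixture bundle
#'
#' Renders a scene and writes `plate.png`, `white.png`,
#' `ground_truth.csv` (well ID, concentration, noiseless RGB) and
#' `ground_truth.json` (homography, fiducial projections) to a directory.
#'
#' @param scene a [plate_scene()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synth_bundle <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- render_plate(scene)
  write_plate_image(r$image, file.path(dir, "plate.png"))
  write_plate_image(render_white_block(scene), file.path(dir, "white.png"))
  utils::write.csv(r$truth$wells, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(homography = r$truth$homography, fiducials = r$truth$fiducials),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
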