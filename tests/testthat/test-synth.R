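test_that("zero analyte leaves the blank colour unchanged in both response models", {
  a_log <- creatinine_assay()
  a_bl <- assay_config("creatinine", 490, spectral_weights(0.07, 0.82, 0.66, 490),
                       standards = c(0, 0.0553, 0.1105, 0.221, 0.442, 0.884, 1.77),
                       units = "mmol/L",
                       response = list(model = "beer_lambert",
                                       k = -log10(0.1) / 1.77, alpha = c(0.12, 1, 0.85)))
  expect_equal(as.vector(dye_color(0, a_log)), a_log$blank_rgb)
  expect_equal(as.vector(dye_color(0, a_bl)), a_bl$blank_rgb)
  expect_error(dye_color(-1, a_log), "non-negative")
})

test_that("Beer-Lambert response: weighted y of a rendered well hits y_blank * 10^(-k c)", {
  # k chosen so 10^(-k c) = 0.1 at c_max
  cmax <- 1.77
  k <- -log10(0.1) / cmax
  assay <- assay_config("creatinine", 490, spectral_weights(0.07, 0.82, 0.66, 490),
                        standards = c(0, 0.0553, 0.1105, 0.221, 0.442, 0.884, 1.77),
                        units = "mmol/L",
                        response = list(model = "beer_lambert", k = k,
                                        alpha = c(0.12, 1, 0.85)))
  w <- assay$weights
  y_blank <- w$a * assay$blank_rgb[1] + w$b * assay$blank_rgb[2] + w$c * assay$blank_rgb[3]
  # direct forward formula
  rgb <- dye_color(cmax, assay)
  expect_equal(w$a * rgb[1] + w$b * rgb[2] + w$c * rgb[3], 0.1 * y_blank,
               tolerance = 1e-9)
  # pipeline readout on a noiseless uniformly lit render
  layout <- plate_layout(role = setNames("standard", "D6"),
                         concentration = setNames(cmax, "D6"))
  scene <- scene_from_layout(layout, assay, illumination = uniform_illum(),
                             noise = no_noise(), camera = fast_camera(), seed = 1)
  r <- render_plate(scene)
  tr <- fit_transform(detect_fiducials(r$image))
  aligned <- align(r$image, tr, scale = 3)
  reading <- read_wells(aligned, layout, assay$weights)
  y_well <- reading$y[reading$well_id == "D6"]
  expect_lt(abs(y_well - 0.1 * y_blank), 1)   # within 8-bit quantization
})

test_that("weighted intensity strictly decreases with concentration in both models", {
  a_log <- creatinine_assay()
  a_bl <- assay_config("glucose", 560, spectral_weights(0.13, 0.83, 0.11, 560),
                       standards = c(0, 1, 2, 4, 8, 16, 32), units = "mg/dL",
                       response = list(model = "beer_lambert", k = 0.05,
                                       alpha = c(0.15, 1, 0.35)))
  for (assay in list(a_log, a_bl)) {
    cs <- c(0, 0.01, 0.02, 0.03, seq(0.05, 1.7, length.out = 30)) *
      max(assay$standards) / 1.77
    rgb <- dye_color(cs, assay)
    w <- assay$weights
    y <- rgb %*% c(w$a, w$b, w$c)
    expect_true(all(diff(y) < 0))
  }
})

test_that("identical scene specs render bit-identical images", {
  layout <- holdout_layout()
  build <- function() scene_from_layout(layout, creatinine_assay(),
                                        sample_conc = c(B1 = 0.221, B2 = 0.221),
                                        camera = fast_camera(), seed = 42)
  r1 <- render_plate(build()); r2 <- render_plate(build())
  expect_identical(unclass(r1$image), unclass(r2$image))
  expect_identical(unclass(render_white_block(build())),
                   unclass(render_white_block(build())))
  expect_identical(r1$truth, r2$truth)
})

test_that("ground-truth fiducial centroids are the analytic projections", {
  s <- shared_noiseless()
  H <- s$truth$homography
  fc <- s$scene$fiducials$centers
  proj <- apply_homography(H, fc)
  expect_equal(s$truth$fiducials$x_px, unname(proj[, 1]), tolerance = 1e-12)
  expect_equal(s$truth$fiducials$y_px, unname(proj[, 2]), tolerance = 1e-12)
})

test_that("an all-empty plate reads near-zero OD in every well", {
  scene <- plate_scene(noise = no_noise(), camera = fast_camera(), seed = 5)
  r <- render_plate(scene)
  white <- render_white_block(scene)
  tr <- fit_transform(detect_fiducials(r$image))
  corrected <- apply_flatfield(align(r$image, tr, scale = 3),
                               build_flatfield(align(white, tr, scale = 3)))
  odt <- od_table(read_wells(corrected, plate_layout(), creatinine_assay()$weights))
  expect_true(all(abs(odt$od) < 0.02))
})

test_that("wells that project outside the image are rejected by name", {
  cam <- fast_camera()
  cam$width_px <- 250   # clips the right edge of the plate
  expect_error(render_plate(plate_scene(camera = cam, noise = no_noise())),
               "well A[0-9]+ projects outside")
})

test_that("white block under uniform illumination is constant; corner falloff matches the analytic model", {
  scene_u <- plate_scene(illumination = uniform_illum(), noise = no_noise(),
                         camera = fast_camera(), seed = 1)
  wb <- render_white_block(scene_u)
  for (ch in 1:3) expect_length(unique(as.vector(wb[, , ch])), 1L)

  il <- corner_illum(rel = c(1, 1, 1, 1))
  scene_c <- plate_scene(illumination = il, noise = no_noise(),
                         camera = fast_camera(), seed = 1)
  wbc <- render_white_block(scene_c)
  # analytic field, evaluated independently of the renderer
  field <- function(x, y) {
    W <- 127.76; H <- 85.48; h2 <- il$height_mm^2
    src <- rbind(c(0, 0), c(W, 0), c(0, H), c(W, H))
    sum(il$rel_intensity * (h2 / (h2 + (x - src[, 1])^2 + (y - src[, 2])^2))^(il$falloff / 2))
  }
  px_at <- function(x_mm, y_mm) {
    p <- apply_homography(scene_c$camera$H, cbind(x_mm, y_mm))
    wbc[round(p[2] + 0.5), round(p[1] + 0.5), 2]
  }
  centre <- px_at(127.76 / 2, 85.48 / 2)
  corner <- px_at(5, 5)
  expect_equal(corner / centre, field(5, 5) / field(127.76 / 2, 85.48 / 2),
               tolerance = 0.02)
})

test_that("scene and ground-truth round-trip through YAML/CSV bundle", {
  layout <- holdout_layout()
  scene <- scene_from_layout(layout, creatinine_assay(),
                             sample_conc = c(B1 = 0.221, B2 = 0.221),
                             camera = fast_camera(), seed = 9)
  tmp <- tempfile()
  write_scene(scene, paste0(tmp, ".yaml"))
  scene2 <- read_scene(paste0(tmp, ".yaml"))
  expect_equal(scene2$concentrations, scene$concentrations)
  expect_equal(scene2$camera$H, scene$camera$H, tolerance = 1e-12)
  r1 <- render_plate(scene); r2 <- render_plate(scene2)
  expect_identical(unclass(r1$image), unclass(r2$image))

  dir <- tempfile()
  write_synth_bundle(scene, dir)
  expect_true(all(file.exists(file.path(dir, c("plate.png", "white.png",
                                               "ground_truth.csv", "ground_truth.json")))))
  img <- read_plate_image(file.path(dir, "plate.png"))
  expect_equal(unclass(img)[, , 1], unclass(r1$image)[, , 1], ignore_attr = TRUE)
})

test_that("scene validation rejects broken geometry and concentration maps", {
  expect_error(plate_scene(concentrations = c(Z9 = 1)), "unknown well")
  expect_error(plate_scene(concentrations = c(A1 = -2)), "non-negative")
  g <- slas_geometry(); g$a1_x_mm <- 40   # grid no longer fits
  expect_error(plate_scene(geometry = g), "does not fit")
  cam <- fast_camera(); cam$H[3, ] <- c(0, 0, 0)
  expect_error(plate_scene(camera = cam), "not invertible")
})
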