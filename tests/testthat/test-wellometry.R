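test_that("histogram mode picks the majority bin, resists glare, and breaks ties low", {
  set.seed(1)
  v <- c(rep(180, 600), sample(0:255, 400, replace = TRUE))
  expect_equal(mode_intensity(v), 180)

  glare <- c(rep(255, 200), rep(140, 800))   # 20% saturated glare
  expect_equal(mode_intensity(glare), 140)

  bimodal <- c(rep(100, 500), rep(200, 500))
  expect_equal(mode_intensity(bimodal), 100)

  expect_error(mode_intensity(numeric()), "empty")
})

test_that("any >50% plurality value is the mode regardless of the remaining pixels", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(100:2000, 1)
    v <- sample(0:255, 1)
    k <- floor(n / 2) + 1L
    rest <- sample(0:255, n - k, replace = TRUE)
    expect_equal(mode_intensity(c(rep(v, k), rest)), v)
  }
})

test_that("spectral weights match direct evaluation of the printed sensitivities", {
  w_cr <- spectral_weights(0.07, 0.82, 0.66, 490)
  s <- 0.07 + 0.82 + 0.66
  expect_equal(c(w_cr$a, w_cr$b, w_cr$c), c(0.07, 0.82, 0.66) / s, tolerance = 1e-12)
  expect_equal(w_cr$a + w_cr$b + w_cr$c, 1, tolerance = 1e-9)
  expect_equal(c(w_cr$a, w_cr$b, w_cr$c), c(0.04516, 0.52903, 0.42581), tolerance = 1e-4)

  w_gl <- spectral_weights(0.13, 0.83, 0.11, 560)
  expect_equal(c(w_gl$a, w_gl$b, w_gl$c), c(0.13, 0.83, 0.11) / 1.07, tolerance = 1e-12)
  expect_equal(c(w_gl$a, w_gl$b, w_gl$c), c(0.12150, 0.77570, 0.10280), tolerance = 1e-4)

  w_eq <- spectral_weights(0.5, 0.5, 0.5)
  expect_equal(c(w_eq$a, w_eq$b, w_eq$c), rep(1 / 3, 3))

  expect_error(spectral_weights(0, 1, 1), "positive")
  expect_error(spectral_weights(0.1, -1, 1), "positive")
})

test_that("weighted intensity is the stated affine combination, bounded by channel extremes", {
  w <- spectral_weights(0.2, 0.5, 0.3)
  expect_equal(weighted_intensity(c(100, 200, 50), w), 135)
  w_cr <- spectral_weights(0.07, 0.82, 0.66, 490)
  expect_equal(weighted_intensity(c(255, 255, 255), w_cr), 255)
  expect_equal(weighted_intensity(c(80, 80, 80), w), 80)
  set.seed(7)
  for (i in 1:20) {
    m <- runif(3, 0, 255)
    y <- weighted_intensity(m, w)
    expect_gte(y, min(m)); expect_lte(y, max(m))
  }
})

test_that("well ROIs stay inside the drawn wells and fail on degenerate inputs", {
  s <- shared_noiseless()
  tr <- fit_transform(detect_fiducials(s$image), s$scene$fiducials$centers)
  aligned <- align(s$image, tr, scale = 3)
  rois <- segment_wells(aligned, s$layout)
  d <- dim(aligned)
  for (k in seq_len(96)) {
    idx <- rois[[k]]
    r <- (idx - 1L) %% d[1] + 1L
    cc <- (idx - 1L) %/% d[1] + 1L
    dist_mm <- sqrt(((cc - 0.5) / 3 - s$layout$x_mm[k])^2 +
                    ((r - 0.5) / 3 - s$layout$y_mm[k])^2)
    expect_true(all(dist_mm <= s$layout$radius_mm[k]))
  }

  g <- slas_geometry(); g$well_radius_mm <- 5   # 2r > 9 mm pitch
  expect_error(plate_layout(geometry = g), "overlap")

  sentinel <- plate_image(array(NA_real_, c(100, 140, 3)), pixels_per_mm = 1)
  expect_error(segment_wells(sentinel, s$layout), "A1.*usable pixels|fewer than")
})

test_that("on a uniformly lit noiseless render the RGB modes equal the ground-truth dye colours exactly", {
  assay <- creatinine_assay()
  layout <- holdout_layout(assay)
  scene <- scene_from_layout(layout, assay, sample_conc = c(B1 = 0.221, B2 = 0.221),
                             illumination = uniform_illum(), noise = no_noise(),
                             camera = fast_camera(), seed = 2)
  r <- render_plate(scene)
  tr <- fit_transform(detect_fiducials(r$image), scene$fiducials$centers)
  aligned <- align(r$image, tr, scale = 3)
  readings <- read_wells(aligned, layout, assay$weights)
  gt <- r$truth$wells
  expect_identical(readings$I_R, gt$R)
  expect_identical(readings$I_G, gt$G)
  expect_identical(readings$I_B, gt$B)
  # reading invariants
  expect_true(all(readings$n_px > 0))
  expect_true(all(readings$y >= pmin(readings$I_R, readings$I_G, readings$I_B) &
                  readings$y <= pmax(readings$I_R, readings$I_G, readings$I_B)))
})

test_that("sensitivity-curve interpolation reproduces the shipped presets", {
  curve <- data.frame(wavelength_nm = c(480, 490, 500, 550, 560, 570),
                      RS = c(0.06, 0.07, 0.08, 0.12, 0.13, 0.14),
                      GS = c(0.80, 0.82, 0.84, 0.84, 0.83, 0.80),
                      BS = c(0.70, 0.66, 0.60, 0.15, 0.11, 0.09))
  w <- weights_from_curve(curve, 490)
  expect_equal(c(w$RS, w$GS, w$BS), c(0.07, 0.82, 0.66))
  w2 <- weights_from_curve(curve, 495)
  expect_equal(w2$RS, 0.075)
  expect_error(weights_from_curve(curve, 400), "outside")
})
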