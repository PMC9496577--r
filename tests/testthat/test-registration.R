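test_that("fiducial centroids on a noiseless render match ground truth within 0.5 px", {
  s <- shared_noiseless()
  fids <- detect_fiducials(s$image)
  gt <- s$truth$fiducials
  expect_equal(fids$label, gt$label)
  expect_true(all(abs(fids$x_px - gt$x_px) < 0.5))
  expect_true(all(abs(fids$y_px - gt$y_px) < 0.5))
})

test_that("rotating the image 180 degrees swaps labels diagonally, same centroid set", {
  s <- shared_noiseless()
  img <- unclass(s$image)
  d <- dim(img)
  rot <- plate_image(img[d[1]:1, d[2]:1, , drop = FALSE], provenance = "test")
  f1 <- detect_fiducials(s$image)
  f2 <- detect_fiducials(rot)
  # TL of the rotated image is the original BR, reflected through the centre
  swap <- c(TL = "BR", TR = "BL", BL = "TR", BR = "TL")
  for (i in seq_len(4)) {
    j <- match(swap[f2$label[i]], f1$label)
    expect_equal(f2$x_px[i], d[2] - f1$x_px[j], tolerance = 1e-6)
    expect_equal(f2$y_px[i], d[1] - f1$y_px[j], tolerance = 1e-6)
  }
})

test_that("degenerate images are rejected with the candidate count", {
  blank <- plate_image(array(250, c(120, 160, 3)))
  expect_error(detect_fiducials(blank), "expected 4 fiducials, found 0")
  # dark filled wells (circles) must not be mistaken for fiducials
  s <- shared_noiseless()
  expect_equal(nrow(detect_fiducials(s$image)), 4L)
  # a fifth square on clear plate puts two candidates in one quadrant
  five <- unclass(s$image)
  five[100:115, 30:45, ] <- 25
  expect_error(detect_fiducials(plate_image(five)),
               "multiple fiducial candidates")
})

test_that("translating the image translates detected centroids identically", {
  s <- shared_noiseless()
  img <- unclass(s$image)
  d <- dim(img)
  dr <- 7L; dc <- 13L
  big <- array(250, c(d[1] + dr, d[2] + dc, 3L))
  big[(dr + 1):(dr + d[1]), (dc + 1):(dc + d[2]), ] <- img
  f1 <- detect_fiducials(s$image)
  f2 <- detect_fiducials(plate_image(big))
  expect_equal(f2$x_px, f1$x_px + dc, tolerance = 1e-6)
  expect_equal(f2$y_px, f1$y_px + dr, tolerance = 1e-6)
})

test_that("fit_transform is exact on its defining points", {
  can <- default_fiducials()$centers
  fid <- data.frame(label = rownames(can), x_px = can[, 1], y_px = can[, 2])
  tr <- fit_transform(fid, canonical = can)
  expect_equal(tr$H, diag(3), tolerance = 1e-9)
  expect_lt(tr$residual_mm, 1e-6)

  # pure translation
  fid2 <- transform(fid, x_px = x_px + 10, y_px = y_px + 20)
  tr2 <- fit_transform(fid2, canonical = can)
  expect_equal(tr2$H, matrix(c(1, 0, -10, 0, 1, -20, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("a known synthetic homography is recovered to 1e-3 entry-wise", {
  layout <- holdout_layout()
  scene <- scene_from_layout(layout, creatinine_assay(),
                             sample_conc = c(B1 = 0.221, B2 = 0.221),
                             noise = no_noise(),
                             camera = fast_camera(tilt = c(2e-4, -1.5e-4)),
                             seed = 21)
  r <- render_plate(scene)
  tr <- fit_transform(detect_fiducials(r$image),
                      canonical = scene$fiducials$centers)
  H_true <- scene$camera$H / scene$camera$H[3, 3]
  H_fit <- tr$Hinv / tr$Hinv[3, 3]
  expect_lt(max(abs(H_fit - H_true)) / max(abs(H_true)), 1e-3)
})

test_that("collinear fiducials are rejected", {
  fid <- data.frame(label = c("TL", "TR", "BL", "BR"),
                    x_px = c(0, 50, 100, 100), y_px = c(0, 50, 100, 0))
  expect_error(fit_transform(fid, canonical = default_fiducials()$centers),
               "degenerate fiducial geometry")
})

test_that("align with the identity transform is the identity away from borders", {
  s <- shared_noiseless()
  img <- unclass(s$image)
  tr <- structure(list(H = diag(3), Hinv = diag(3), residual_mm = 0),
                  class = "plate_transform")
  out <- align(s$image, tr, scale = 1, plate_dims = c(dim(img)[2], dim(img)[1]))
  inner_r <- 2:(dim(img)[1] - 1); inner_c <- 2:(dim(img)[2] - 1)
  expect_equal(unclass(out)[inner_r, inner_c, ], img[inner_r, inner_c, ],
               ignore_attr = TRUE)
  expect_error(align(s$image, tr, scale = -1), "positive")
})

test_that("registration round-trips a projective warp within interpolation error", {
  assay <- creatinine_assay()
  layout <- holdout_layout(assay)
  conc <- c(B1 = 0.221, B2 = 0.221)
  base <- list(layout = layout, assay = assay, sample_conc = conc,
               illumination = uniform_illum(), noise = no_noise(), seed = 3)
  # reference: fronto-parallel camera at 3 px/mm, no margin offset issues
  ref_scene <- scene_from_layout(layout, assay, sample_conc = conc,
                                 illumination = uniform_illum(),
                                 noise = no_noise(), camera = fast_camera(),
                                 seed = 3)
  warp_scene <- scene_from_layout(layout, assay, sample_conc = conc,
                                  illumination = uniform_illum(),
                                  noise = no_noise(),
                                  camera = fast_camera(scale = 3.3, tilt = c(3e-4, 2e-4)),
                                  seed = 3)
  ref <- render_plate(ref_scene)
  wrp <- render_plate(warp_scene)
  tr_ref <- fit_transform(detect_fiducials(ref$image), ref_scene$fiducials$centers)
  tr_wrp <- fit_transform(detect_fiducials(wrp$image), warp_scene$fiducials$centers)
  a_ref <- align(ref$image, tr_ref, scale = 3)
  a_wrp <- align(wrp$image, tr_wrp, scale = 3)
  rois <- segment_wells(a_ref, layout)
  for (idx in rois) {
    for (ch in 1:3) {
      v1 <- a_ref[, , ch][idx]; v2 <- a_wrp[, , ch][idx]
      expect_lt(mean(abs(v1 - v2), na.rm = TRUE), 2)
    }
  }
})

test_that("aligned fiducials land at their canonical positions within 0.5 px", {
  s <- shared_noiseless()
  tr <- fit_transform(detect_fiducials(s$image), s$scene$fiducials$centers)
  aligned <- align(s$image, tr, scale = 3)
  f <- detect_fiducials(aligned)
  can <- s$scene$fiducials$centers * 3   # mm -> px at 3 px/mm
  expect_true(all(abs(f$x_px - can[, 1]) < 0.5))
  expect_true(all(abs(f$y_px - can[, 2]) < 0.5))
})

test_that("plate transforms round-trip through JSON", {
  s <- shared_noiseless()
  tr <- fit_transform(detect_fiducials(s$image), s$scene$fiducials$centers)
  path <- tempfile(fileext = ".json")
  write_transform(tr, path)
  tr2 <- read_transform(path)
  expect_equal(tr2$H, tr$H, tolerance = 1e-12)
  expect_equal(tr2$residual_mm, tr$residual_mm, tolerance = 1e-12)
})
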