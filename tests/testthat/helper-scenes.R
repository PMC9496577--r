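# Shared fixture builders. Everything is generated in code; small camera
# scales keep renders fast.

no_noise <- function() list(sigma = 0, glare_n = 0, bubble_n = 0)

uniform_illum <- function() list(rel_intensity = c(1, 1, 1, 1), height_mm = 70, falloff = 0)

corner_illum <- function(rel = c(1, 0.95, 1.05, 0.9), falloff = 3)
  list(rel_intensity = rel, height_mm = 70, falloff = falloff)

fast_camera <- function(scale = 3, margin_px = 10, tilt = c(0, 0))
  camera_model(scale = scale, margin_px = margin_px, tilt = tilt)

# Layout: full standard series in row A, optional duplicate unknown wells.
holdout_layout <- function(assay = creatinine_assay(), holdout = 0.221,
                           unknown_wells = c("B1", "B2")) {
  std <- setdiff(assay$standards, holdout)
  role <- setNames(rep("standard", length(std)), paste0("A", seq_along(std)))
  conc <- setNames(std, paste0("A", seq_along(std)))
  role[unknown_wells] <- "sample"
  df <- setNames(rep(1, length(unknown_wells)), unknown_wells)
  grp <- setNames(rep("unknown", length(unknown_wells)), unknown_wells)
  plate_layout(role = role, concentration = conc, dilution_factor = df,
               replicate_group = grp)
}

# One cached noiseless corner-lit creatinine plate with unknowns at 0.221,
# rendered once per test run (registration, flatfield and pipeline tests
# all reuse it).
shared <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, cache)) assign(name, build(), cache)
    get(name, cache)
  }
})

shared_noiseless <- function() {
  shared("noiseless", function() {
    assay <- creatinine_assay()
    layout <- holdout_layout(assay)
    scene <- scene_from_layout(layout, assay,
                               sample_conc = c(B1 = 0.221, B2 = 0.221),
                               illumination = corner_illum(),
                               noise = no_noise(), camera = fast_camera(),
                               seed = 11)
    r <- render_plate(scene)
    list(assay = assay, layout = layout, scene = scene,
         image = r$image, truth = r$truth,
         white = render_white_block(scene))
  })
}

# Independent brute-force incident-light oracle: enumerates the 5x5 grid
# window explicitly per well, via an 8x12 grid of intensities.
brute_force_incident <- function(readings, w, window = 5L) {
  half <- (window - 1L) %/% 2L
  ymat <- matrix(NA_real_, 8, 12)
  ymat[cbind(readings$row, readings$col)] <- readings$y
  n <- nrow(readings)
  out <- data.frame(wL = numeric(n), P = integer(n), Q = integer(n),
                    fallback = logical(n))
  for (k in seq_len(n)) {
    sy <- c()
    for (dr in -half:half) for (dc in -half:half) {
      rr <- readings$row[k] + dr; cc <- readings$col[k] + dc
      if (rr >= 1 && rr <= 8 && cc >= 1 && cc <= 12 && !is.na(ymat[rr, cc]))
        sy <- c(sy, ymat[rr, cc])
    }
    sw <- sy[sy >= 0.95 * w]
    out$P[k] <- length(sy); out$Q[k] <- length(sw)
    if (length(sw)) out$wL[k] <- mean(sw) else { out$wL[k] <- w; out$fallback[k] <- TRUE }
  }
  out
}

# Random plate intensity configurations for photometry property tests:
# a bright empty-well cluster plus wells with arbitrary intensities.
random_readings <- function() {
  n_empty <- sample(20:70, 1)
  empty_idx <- sample(96, n_empty)
  y <- runif(96, 20, 255)
  y[empty_idx] <- round(runif(1, 200, 250)) + runif(n_empty, -1.5, 1.5)
  data.frame(well_id = well_ids(), row = rep(1:8, each = 12),
             col = rep(1:12, times = 8), y = y)
}
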