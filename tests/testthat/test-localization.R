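# Beamformer, camera geometry, spatial-spectrum peaks, calibration.

fs <- 384000

test_that("steering vectors match the delay model exactly", {
  geo <- fix_geometry()
  om <- 2 * pi * 70e3
  ## arbitrary position: unit-modulus entries, a^H a = m
  r <- c(0.03, -0.02, 0.25)
  sv <- steering_vector(r, om, geo)
  expect_equal(Mod(sv$a), rep(1, 4))
  expect_equal(sum(Mod(sv$a)^2), 4)
  expect_equal(sv$w, sv$a / 4)

  ## element-by-element direct evaluation of the printed formula
  tau <- sqrt(colSums((t(geo$positions) - r)^2)) / geo$c_sound
  expect_equal(unname(sv$a), unname(exp(-1i * om * tau)), tolerance = 1e-12)

  ## equidistant position: all entries equal
  sveq <- steering_vector(c(geo$centroid[1], geo$centroid[2], 0.25), om, geo)
  expect_equal(Mod(diff(sveq$a)), rep(0, 3), tolerance = 1e-12)

  expect_error(steering_vector(r, -1, geo), "positive")
})

test_that("P_norm is bounded by 1/m with equality at the matched source", {
  geo <- fix_geometry()
  om <- 2 * pi * 72e3
  r_true <- c(0.04, 0.01, 0.25)
  a <- steering_vector(r_true, om, geo)$a
  x <- a * (0.3 + 0.4i)               # noiseless matched snapshot
  expect_equal(beam_pnorm(r_true, om, x, geo), 0.25, tolerance = 1e-12)

  ## random snapshots and positions stay in [0, 1/m]
  with_seed(13, for (i in 1:50) {
    xr <- complex(real = stats::rnorm(4), imaginary = stats::rnorm(4))
    rr <- c(stats::runif(1, -0.2, 0.2), stats::runif(1, -0.2, 0.2), 0.25)
    p <- beam_pnorm(rr, om, xr, geo)
    expect_gte(p, 0)
    expect_lte(p, 0.25 + 1e-12)
  })

  expect_equal(beam_pnorm(r_true, om, c(0, 0, 0, 0), geo), 0)
})

test_that("frequency-domain beamformer equals the time-domain delay-and-sum oracle", {
  geo <- fix_geometry()
  f0 <- 96 * 750                       # exact STFT bin
  om <- 2 * pi * f0
  r_src <- c(0.06, -0.03, 0.25)
  tau_src <- propagation_delays(r_src, geo)
  n <- 512
  tt <- (0:(n - 1)) / fs
  ## analytic (complex) tone delayed per channel, windowed snapshot
  win <- dpss_tapers(n, 2, 3)[, 1]
  X <- vapply(1:4, function(j)
    sum(win * exp(2i * pi * f0 * (tt - tau_src[j])) * exp(-2i * pi * 96 * (0:(n - 1)) / n)),
    complex(1))
  for (r_test in list(r_src, c(0, 0, 0.25), c(-0.08, 0.05, 0.25))) {
    p_impl <- beam_pnorm(r_test, om, X, geo)
    ## oracle: advance each channel by tau_j(r_test) in the time domain,
    ## sum the aligned channels, and take the power ratio
    tau_t <- propagation_delays(r_test, geo)
    aligned <- vapply(1:4, function(j)
      sum(win * exp(2i * pi * f0 * (tt + tau_t[j] - tau_src[j])) *
            exp(-2i * pi * 96 * (0:(n - 1)) / n)),
      complex(1))
    p_oracle <- Mod(sum(aligned))^2 / (16 * sum(Mod(X)^2))
    expect_equal(p_impl, p_oracle, tolerance = 1e-6)
  }
})

test_that("pixel-floor projection round-trips and matches the field of view", {
  cam <- fix_camera()
  ## centre pixel lies on the optical axis at floor depth
  centre <- pixel_to_floor(cam, c(cam$cx, cam$cy))
  expect_equal(unname(centre), c(0, 0, cam$floor_z))

  ## horizontal image edge: ray at 35 degrees from the axis
  edge <- pixel_to_floor(cam, c(cam$cx + 320, cam$cy))
  expect_equal(atan2(edge[["x"]], edge[["z"]]) * 180 / pi, 35, tolerance = 1e-9)

  ## project/back-project identity
  with_seed(5, for (i in 1:20) {
    px <- c(stats::runif(1, 1, 640), stats::runif(1, 1, 480))
    expect_equal(unname(floor_to_pixel(cam, pixel_to_floor(cam, px))), px,
                 tolerance = 1e-6)
  })
})

test_that("spatial spectra are z-scored and localize a clean source", {
  geo <- fix_geometry(); cam <- fix_camera()
  pos <- c(0.05, 0.02, 0.25)
  ch <- tone_clip(70e3, pos, dur = 0.02, snr_db = 40, seed = 3)
  stft <- stft_tensor(ch, fs)
  pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)))
  spec <- segment_spatial_spectrum(pk, stft, geo, cam)
  expect_equal(mean(spec$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(spec$z), 1, tolerance = 1e-9)

  res <- find_spectrum_peaks(spec, cam)
  expect_equal(res$status, "localized")
  truepx <- floor_to_pixel(cam, pos)
  d <- sqrt((res$peaks$u_px - truepx[1])^2 + (res$peaks$v_px - truepx[2])^2)
  expect_lte(min(d), 5)   # within one 5-pixel bin of the projection

  ## localization is invariant to a global channel gain
  stft2 <- stft
  stft2$coef <- stft2$coef * 12.3
  spec2 <- segment_spatial_spectrum(pk, stft2, geo, cam)
  expect_equal(spec2$z, spec$z, tolerance = 1e-9)
})

test_that("sources in the margin outside the image are still found", {
  geo <- fix_geometry(); cam <- fix_camera()
  ## just beyond the right image edge but inside the 100-px margin; a
  ## frequency-modulated sweep so alias peaks average out
  pos_px <- c(cam$width + 60, cam$cy)
  pos <- pixel_to_floor(cam, pos_px)
  ct <- syllable_contour(c(0, 0.02), c(50e3, 80e3), c(1, 1))
  w <- render_source_waveform(ct, fs)
  ch <- propagate_to_array(w, pos, fix_geometry(), fs,
                           noise_std = max(abs(w)) / 100, seed = 8)
  stft <- stft_tensor(ch, fs)
  pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)))
  res <- find_spectrum_peaks(segment_spatial_spectrum(pk, stft, geo, cam), cam)
  expect_equal(res$status, "localized")
  expect_gt(res$top$u_px, cam$width)
})

test_that("spectrum peak finding applies both z thresholds", {
  cam <- fix_camera()
  grid <- beam_grid(fix_geometry(), cam)
  mk <- function(z) structure(list(z = z, pseg = z, u = grid$u, v = grid$v,
                                   grid = grid, mean = 0, sd = 1),
                              class = "spatial_spectrum")
  ## constant grid: no strict maxima -> unlocalized
  expect_equal(find_spectrum_peaks(mk(matrix(0, grid$nv, grid$nu)), cam)$status,
               "unlocalized")

  ## single bump z = 3: localized with one peak
  z <- matrix(0, grid$nv, grid$nu); z[60, 80] <- 3
  r1 <- find_spectrum_peaks(mk(z), cam)
  expect_equal(r1$status, "localized")
  expect_equal(nrow(r1$peaks), 1)

  ## bumps at 2.5 and 1.4: the small one is dropped, still localized
  z2 <- matrix(0, grid$nv, grid$nu); z2[60, 80] <- 2.5; z2[30, 40] <- 1.4
  r2 <- find_spectrum_peaks(mk(z2), cam)
  expect_equal(r2$status, "localized")
  expect_equal(nrow(r2$peaks), 1)

  ## bump at 1.8 only: retained but no clear peak -> unlocalized
  z3 <- matrix(0, grid$nv, grid$nu); z3[60, 80] <- 1.8
  expect_equal(find_spectrum_peaks(mk(z3), cam)$status, "unlocalized")
})

test_that("snout-peak distance is zero at a peak and exact elsewhere", {
  geo <- fix_geometry(); cam <- fix_camera()
  pos <- c(0.05, 0.02, 0.25)
  ch <- tone_clip(68.25e3, pos, dur = 0.02, snr_db = 40, seed = 9)
  stft <- stft_tensor(ch, fs)
  pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)))
  res <- find_spectrum_peaks(segment_spatial_spectrum(pk, stft, geo, cam), cam)
  at_peak <- snout_peak_distance(res, c(res$top$u_px, res$top$v_px), cam, geo)
  expect_equal(at_peak$mm, 0, tolerance = 1e-9)
  expect_equal(at_peak$deg, 0, tolerance = 1e-9)

  ## a snout 15.8 mm from the nearest peak reports 15.8 mm
  off <- c(res$top$x + 0.0158, res$top$y, res$top$z_m)
  spd <- snout_peak_distance(res, floor_to_pixel(cam, off), cam, geo)
  expect_equal(spd$mm, 15.8, tolerance = 0.2)

  unloc <- list(status = "unlocalized")
  expect_error(snout_peak_distance(unloc, c(1, 1), cam, geo), "unlocalized")
})

test_that("alias peak spacing halves when the frequency doubles", {
  geo <- fix_geometry(); cam <- fix_camera()
  centre <- c(geo$centroid[1], geo$centroid[2], 0.25)
  spacing_at <- function(f) {
    ch <- tone_clip(f, centre, dur = 0.02, snr_db = 50, seed = 2)
    stft <- stft_tensor(ch, fs)
    pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)),
                       band_hz = c(30e3, 120e3))
    spec <- segment_spatial_spectrum(pk, stft, geo, cam)
    res <- find_spectrum_peaks(spec, cam, z_keep = 1.0, z_clear = 1.0)
    pts <- cbind(res$peaks$x, res$peaks$y)
    d <- as.matrix(stats::dist(pts))
    min(d[d > 1e-6])
  }
  s45 <- spacing_at(45e3)
  s90 <- spacing_at(90e3)
  expect_gt(s45, s90)
  expect_equal(s45 / s90, 2, tolerance = 0.2)
})

test_that("calibration recovers perturbed microphone positions on clean data", {
  geo <- fix_geometry(); cam <- fix_camera()
  ## 20 noiseless syllables spread over the cage
  cal <- with_seed(17, lapply(1:20, function(i) {
    ct <- random_contour(0.03, kind = sample(c("up", "down", "mod"), 1))
    pos <- c(stats::runif(1, -0.1, 0.1), stats::runif(1, -0.07, 0.07), 0.25)
    ch <- propagate_to_array(render_source_waveform(ct, fs), pos, geo, fs)
    stft <- stft_tensor(ch, fs)
    pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)))
    list(snaps = segment_snapshots(pk, stft), snout_floor = pos)
  }))

  ## start at the true geometry: stays there (within a micrometre)
  same <- calibrate_mic_positions(cal, geo)
  expect_lt(max(abs(same$positions - geo$positions)), 1e-6)

  ## 1 mm per-microphone perturbation (zero common-mode displacement, which
  ## the delay-difference objective cannot see): recovered within 0.2 mm
  pert <- with_seed(23, {
    dp <- matrix(stats::rnorm(12), 4, 3)
    dp <- sweep(dp, 2, colMeans(dp))
    dp <- dp / sqrt(rowSums(dp^2)) * 1e-3
    dp <- sweep(dp, 2, colMeans(dp))
    g <- geo; g$positions <- geo$positions + dp; g
  })
  obj_true <- attr(calibrate_mic_positions(cal, geo), "objective0")
  obj_pert <- attr(calibrate_mic_positions(cal, pert), "objective0")
  expect_gt(obj_true, obj_pert)   # matched model maximizes the objective

  rec <- calibrate_mic_positions(cal, pert)
  err_mm <- sqrt(rowSums((rec$positions - geo$positions)^2)) * 1000
  expect_lt(max(err_mm), 0.2)
})
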