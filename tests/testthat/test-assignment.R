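# Assignment: screening, wrapped distance, signed-rank comparison,
# confidence table, decision rule, merging and features.

fs <- 384000

## a localized clip record reused across blocks
local_clip_record <- function(freq = 66e3, pos = c(0.03, 0.01, 0.25),
                              snr_db = 30, seed = 5) {
  geo <- fix_geometry(); cam <- fix_camera()
  ct <- syllable_contour(c(0, 0.03), c(freq - 8e3, freq + 8e3), c(1, 1))
  w <- render_source_waveform(ct, fs)
  ch <- propagate_to_array(w, pos, geo, fs,
                           noise_std = max(abs(w)) / 10^(snr_db / 20), seed = seed)
  stft <- stft_tensor(ch, fs)
  pk <- detect_peaks(flatten_spectrogram(multitaper_spectrogram(ch[, 1], fs)))
  loc <- localize_segment(pk, stft, geo, cam)
  list(loc = loc, geo = geo, cam = cam, pos = pos)
}

test_that("candidate screening applies the distance threshold", {
  r <- cached("assign_rec", local_clip_record())
  truepx <- floor_to_pixel(r$cam, r$pos)
  snouts <- data.frame(mouse_id = 1:2,
                       snout_x_px = c(truepx[1], truepx[1] + 540),
                       snout_y_px = c(truepx[2], truepx[2]))
  ## mouse 2 sits ~300 mm away: one candidate, direct assignment
  cand <- screen_candidates(r$loc$result, snouts, 60, r$cam, r$geo)
  expect_equal(cand$mouse_id, 1L)
  dec <- assign_segment(r$loc, snouts, NULL, 60, r$cam, r$geo)
  expect_equal(dec$outcome, "assigned")
  expect_equal(dec$mouse_id, 1L)
  expect_equal(dec$n_cand, 1L)

  ## all snouts beyond the threshold: unassigned
  far <- data.frame(mouse_id = 1:2, snout_x_px = c(5, 630), snout_y_px = c(5, 470))
  expect_equal(assign_segment(r$loc, far, NULL, 1, r$cam, r$geo)$outcome,
               "unassigned")

  ## missing snout data excludes a mouse from candidacy
  miss <- data.frame(mouse_id = 1:2, snout_x_px = c(NA, truepx[1]),
                     snout_y_px = c(NA, truepx[2]))
  cand2 <- screen_candidates(r$loc$result, miss, 60, r$cam, r$geo)
  expect_equal(cand2$mouse_id, 2L)
})

test_that("the screening threshold equals the empirical 99th percentile", {
  d <- with_seed(3, stats::rchisq(500, 3) * 2)
  expect_equal(snout_distance_threshold(d),
               unname(stats::quantile(d, 0.99)))
})

test_that("wrapped distance neutralizes alias-peak separation", {
  ## constructed result with two alias peaks one grid period apart
  res <- list(status = "localized",
              peaks = data.frame(u_px = c(100, 300), v_px = c(100, 100),
                                 z = c(3, 2.8), x = c(-0.05, 0.1),
                                 y = c(0, 0), z_m = 0.25))
  ## both snouts exactly at (different) peaks: d' = 0
  wd0 <- wrapped_distance(c(-0.05, 0, 0.25), c(0.1, 0, 0.25), res)
  expect_equal(wd0$d_prime_mm, 0)
  expect_equal(wd0$d_mm, 150)

  ## small jitter near different alias peaks: d' equals the jitter offset
  wd1 <- wrapped_distance(c(-0.05 + 0.002, 0, 0.25), c(0.1, 0.001, 0.25), res)
  expect_equal(wd1$d_prime_mm, sqrt(2^2 + 1^2), tolerance = 1e-9)
  expect_gt(wd1$d_mm, 100)

  ## single peak: d' equals the raw distance
  res1 <- list(status = "localized",
               peaks = res$peaks[1, , drop = FALSE])
  wd2 <- wrapped_distance(c(0, 0.01, 0.25), c(0.03, -0.01, 0.25), res1)
  expect_equal(wd2$d_prime_mm, wd2$d_mm, tolerance = 1e-9)
})

test_that("signed-rank power comparison matches exact enumeration", {
  r <- cached("assign_rec", local_clip_record())
  ## identical sequences: p = 1
  p_same <- compare_powers(r$loc$snaps, r$pos, r$pos, r$geo)
  expect_equal(p_same$p, 1)

  ## two-tailed symmetry under argument swap
  s2 <- c(r$pos[1] + 0.004, r$pos[2] - 0.003, 0.25)
  pa <- compare_powers(r$loc$snaps, r$pos, s2, r$geo)
  pb <- compare_powers(r$loc$snaps, s2, r$pos, r$geo)
  expect_equal(pa$p, pb$p, tolerance = 1e-12)

  ## n = 10 fixed differences: p equals full 2^10 enumeration
  snaps10 <- r$loc$snaps
  keep <- seq_len(10)
  snaps10$X <- snaps10$X[, keep]
  snaps10$omega <- snaps10$omega[keep]
  snaps10$n <- 10L
  cp <- compare_powers(snaps10, r$pos, s2, r$geo)
  d <- pnorm_peaks(r$pos, snaps10, r$geo) - pnorm_peaks(s2, snaps10, r$geo)
  expect_equal(cp$p, enumerate_signed_rank_p(d), tolerance = 1e-12)
})

test_that("confidence table tallies precision and interpolates conservatively", {
  ## toy tally: 99 hits / 1 error in one cell
  trials <- data.frame(p = rep(1e-4, 100), d_prime_mm = 12,
                       n_cand = 2L, hit = c(rep(TRUE, 99), FALSE))
  lut <- build_confidence_lut(trials)
  expect_equal(lut_confidence(lut, 1e-4, 12, 2), 0.99, tolerance = 1e-6)

  ## unpopulated regions yield NA -> unassigned
  expect_true(is.na(lut_confidence(lut, 1e-4, 150, 2)))

  ## on the simulation-built table: precision is a proper probability and
  ## grows with wrapped distance (the reason the table is indexed by d'):
  ## close snouts are confusable regardless of p, separated ones are not
  big <- validation_lut()
  pr <- big$precision
  expect_true(all(pr[!is.na(pr)] >= 0 & pr[!is.na(pr)] <= 1))
  loosest <- pr[length(big$p_grid), , 1]          # p threshold 1, Nc = 2
  populated <- which(!is.na(loosest))
  expect_gte(length(populated), 2)
  expect_gt(loosest[max(populated)], loosest[min(populated)])
  ## somewhere the table certifies near-perfect precision
  expect_gte(max(pr, na.rm = TRUE), 0.95)
})

test_that("the confidence gate controls assignment", {
  r <- cached("assign_rec", local_clip_record())
  truepx <- floor_to_pixel(r$cam, r$pos)
  near <- data.frame(mouse_id = 1:2,
                     snout_x_px = c(truepx[1], truepx[1] + 12),
                     snout_y_px = c(truepx[2], truepx[2]))
  mk_lut <- function(prec) {
    tr <- data.frame(p = rep(10^seq(-6, 0, length.out = 50), 4),
                     d_prime_mm = rep(c(3, 8, 12, 20), each = 50),
                     n_cand = 2L, hit = TRUE)
    tr <- tr[rep(seq_len(nrow(tr)), each = 20), ]
    tr$hit <- stats::runif(nrow(tr)) < prec
    build_confidence_lut(tr)
  }
  hi <- with_seed(1, mk_lut(0.999))
  lo <- with_seed(2, mk_lut(0.90))
  dhi <- assign_segment(r$loc, near, hi, 60, r$cam, r$geo)
  dlo <- assign_segment(r$loc, near, lo, 60, r$cam, r$geo)
  expect_equal(dhi$outcome, "assigned")
  expect_gt(dhi$confidence, 0.99)
  expect_equal(dlo$outcome, "unassigned")
  expect_equal(dlo$reason, "confidence below threshold")
  expect_equal(dhi$n_cand, 2L)
})

test_that("relabeling mice permutes decisions without changing the winner", {
  r <- cached("assign_rec", local_clip_record())
  truepx <- floor_to_pixel(r$cam, r$pos)
  snouts <- data.frame(mouse_id = 1:2,
                       snout_x_px = c(truepx[1], truepx[1] + 10),
                       snout_y_px = c(truepx[2], truepx[2] + 6))
  flipped <- snouts[2:1, ]; flipped$mouse_id <- 1:2
  d1 <- assign_segment(r$loc, snouts, NULL, 60, r$cam, r$geo)
  d2 <- assign_segment(r$loc, flipped, NULL, 60, r$cam, r$geo)
  ## mouse 1 in the first labelling is mouse 2 in the second
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(d1$best_mouse, c(2L, 1L)[d2$best_mouse])
})

test_that("segments merge into syllables by the 30 ms gap rule", {
  segs <- list(
    table = data.frame(segment = 1:3,
                       onset_s = c(0.000, 0.025, 0.100),
                       offset_s = c(0.010, 0.040, 0.130),
                       duration_s = c(0.010, 0.015, 0.030),
                       n_peaks = c(8L, 2L, 10L)),
    peaks = NULL)
  dec <- data.frame(segment = 1:3,
                    outcome = c("assigned", "unassigned", "assigned"),
                    mouse_id = c(1L, NA, 1L))
  syl <- merge_into_syllables(dec, segs)
  ## 15 ms gap merges, 60 ms gap does not
  expect_equal(nrow(syl), 2)
  expect_equal(syl$n_segments[1], 2)
  ## 8 assigned points over 10 total
  expect_equal(syl$assignment_rate[1], 0.8)
  expect_equal(syl$assignment_rate[2], 1.0)

  ## 35 ms gap -> two syllables
  segs2 <- segs
  segs2$table$onset_s[2] <- 0.045
  segs2$table$offset_s[2] <- 0.060
  dec2 <- dec; dec2$outcome[2] <- "assigned"; dec2$mouse_id[2] <- 1L
  expect_equal(nrow(merge_into_syllables(dec2, segs2)), 3)

  ## merging is idempotent: re-merging the merged table changes nothing
  segs3 <- list(table = data.frame(segment = 1:2,
                                   onset_s = syl$onset_s[1:2],
                                   offset_s = syl$offset_s[1:2],
                                   duration_s = syl$offset_s[1:2] - syl$onset_s[1:2],
                                   n_peaks = syl$n_points[1:2]))
  dec3 <- data.frame(segment = 1:2, outcome = "assigned", mouse_id = 1L)
  again <- merge_into_syllables(dec3, segs3)
  expect_equal(nrow(again), 2)
  expect_equal(again$onset_s, syl$onset_s[1:2])
})

test_that("syllable features follow their definitions", {
  ## constant 70 kHz, 50 ms
  flat <- data.frame(frame = 0:100, time_s = (0:100) * 5e-4, freq_hz = 70e3,
                     amp_db = 10)
  f1 <- syllable_features(flat)$traditional
  expect_equal(unname(f1[c("median_freq", "min_freq", "max_freq", "peak_freq")]),
               rep(70e3, 4))
  expect_equal(unname(f1["delta_freq"]), 0)
  expect_equal(unname(f1["slope"]), 0, tolerance = 1e-9)
  expect_equal(unname(f1["duration"]), 0.05)

  ## linear 40 -> 80 kHz over 100 ms
  lin <- data.frame(frame = 0:200, time_s = (0:200) * 5e-4,
                    freq_hz = seq(40e3, 80e3, length.out = 201), amp_db = 10)
  f2 <- syllable_features(lin)
  expect_equal(unname(f2$traditional["delta_freq"]), 40e3)
  expect_equal(unname(f2$traditional["slope"]), 400e3, tolerance = 1e-6)
  expect_equal(unname(f2$traditional["sinuosity"]), 1, tolerance = 1e-9)
  expect_length(f2$contour10, 20)

  ## single-point syllable: slope flagged undefined
  single <- data.frame(frame = 1, time_s = 5e-4, freq_hz = 70e3, amp_db = 0)
  expect_true(is.na(syllable_features(single)$traditional["slope"]))

  ## z-scored feature matrix: columns mean 0, SD 1
  m <- with_seed(4, matrix(stats::rnorm(60, 5, 3), 20, 3))
  zm <- zscore_features(m)
  expect_equal(unname(colMeans(zm)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 2, stats::sd)), rep(1, 3), tolerance = 1e-12)
})
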