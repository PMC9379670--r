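## Validation experiments built on the simulator: synthetic single-mouse
## sessions (the basis of the screening threshold, the confidence lookup
## table and the localization error medians) and virtual-mouse assignment
## trials.

#' Simulate a single-mouse session as short clips
#'
#' Renders `n` syllables, each from a random floor position inside the cage,
#' as an independent short 4-channel clip at the requested peak
#' signal-to-noise ratio, with the snout track given by the pixel-projected
#' true position plus tracking jitter.
#'
#' @param n number of syllables.
#' @param seed master seed; every clip derives its own stream.
#' @param snr_db peak-signal to noise-std ratio per channel (default 20 dB).
#' @param geometry,camera array and camera models.
#' @param cage floor extent sampled for source positions, list with `x` and
#'   `y` ranges in m (default the imaged central area of a home cage).
#' @param snout_jitter_px tracking jitter applied to the snout pixels
#'   (default 5 px, roughly 2.7 mm on the floor).
#' @return list of clips, each with `samples`, `sample_rate`, `true_floor`,
#'   `snout_px`, `contour`; attribute `cage`.
#' @export
simulate_usv_clips <- function(n, seed = 1, snr_db = 20,
                               geometry = mic_array(), camera = camera_model(),
                               cage = list(x = c(-0.11, 0.11), y = c(-0.075, 0.075)),
                               snout_jitter_px = 5) {
  fs <- 384000
  clips <- with_seed(seed, lapply(seq_len(n), function(i) {
    ct <- random_contour()
    pos <- c(stats::runif(1, cage$x[1], cage$x[2]),
             stats::runif(1, cage$y[1], cage$y[2]), camera$floor_z)
    wave <- render_source_waveform(ct, fs)
    noise_std <- max(abs(wave)) / 10^(snr_db / 20)
    ch <- propagate_to_array(wave, pos, geometry, fs, noise_std = noise_std,
                             pad_s = 0.004)
    ## lead-in noise so the segment does not start at the first frame
    lead <- matrix(stats::rnorm(round(0.004 * fs) * geometry$m, sd = noise_std),
                   ncol = geometry$m)
    px <- floor_to_pixel(camera, pos)
    list(samples = rbind(lead, ch), sample_rate = fs, true_floor = pos,
         snout_px = px + stats::rnorm(2, sd = snout_jitter_px), contour = ct)
  }))
  attr(clips, "cage") <- cage
  clips
}

#' Segment and localize a set of clips into a session record
#'
#' Runs the spectral front end, segmentation and beamforming localization on
#' every clip; keeps the largest segment per clip (a clip holds one
#' syllable). The snout-peak distances of the localized segments give the
#' screening threshold, and the localization errors against ground truth give
#' the error medians.
#'
#' @param clips from [simulate_usv_clips()].
#' @param geometry,camera array and camera models.
#' @param grid optional precomputed [beam_grid()].
#' @param detect_args extra arguments for [detect_peaks()].
#' @return object of class `usv_session`: `records` (per localized clip:
#'   `snaps`, `result`, `snout_px`, `true_floor`, `n_peaks`), `errors`
#'   data.frame (`deg`, `mm`, `snout_mm`), `threshold_mm` (99th percentile of
#'   snout-peak distances), `geometry`, `camera`, `cage`, `n_unlocalized`.
#' @export
analyze_clips <- function(clips, geometry = mic_array(), camera = camera_model(),
                          grid = NULL, detect_args = list()) {
  if (is.null(grid)) grid <- beam_grid(geometry, camera)
  records <- list()
  errors <- NULL
  n_unloc <- 0L
  for (clip in clips) {
    stft <- stft_tensor(clip$samples, clip$sample_rate)
    mt <- multitaper_spectrogram(clip$samples[, 1], clip$sample_rate)
    peaks <- do.call(detect_peaks, c(list(flatten_spectrogram(mt)), detect_args))
    if (nrow(peaks) == 0) { n_unloc <- n_unloc + 1L; next }
    segs <- segment_usv(peaks)
    if (nrow(segs$table) == 0) { n_unloc <- n_unloc + 1L; next }
    big <- segs$table$segment[which.max(segs$table$n_peaks)]
    segpk <- segs$peaks[!is.na(segs$peaks$segment) & segs$peaks$segment == big, ]
    loc <- localize_segment(segpk, stft, geometry, camera, grid)
    if (loc$status != "localized") { n_unloc <- n_unloc + 1L; next }
    spd <- snout_peak_distance(loc$result, clip$snout_px, camera, geometry)
    ## localization error against ground truth
    d_true <- sqrt((loc$result$peaks$x - clip$true_floor[1])^2 +
                   (loc$result$peaks$y - clip$true_floor[2])^2)
    ang <- direction_angle_deg(geometry, clip$true_floor,
                               c(loc$result$top$x, loc$result$top$y, loc$result$top$z_m))
    errors <- rbind(errors, data.frame(deg = ang, mm = min(d_true) * 1000,
                                       snout_mm = spd$mm))
    records[[length(records) + 1]] <- list(
      snaps = loc$snaps, result = loc$result, snout_px = clip$snout_px,
      true_floor = clip$true_floor, n_peaks = nrow(segpk))
  }
  structure(list(records = records, errors = errors,
                 threshold_mm = snout_distance_threshold(errors$snout_mm),
                 geometry = geometry, camera = camera,
                 cage = attr(clips, "cage") %||%
                   list(x = c(-0.11, 0.11), y = c(-0.075, 0.075)),
                 n_unlocalized = n_unloc),
            class = "usv_session")
}

#' @export
print.usv_session <- function(x, ...) {
  cat(sprintf("<usv_session> %d localized segments (%d unlocalized)\n",
              length(x$records), x$n_unlocalized))
  cat(sprintf("  median error: %.2f deg / %.2f mm; screening threshold %.1f mm\n",
              stats::median(x$errors$deg), stats::median(x$errors$mm),
              x$threshold_mm))
  invisible(x)
}

## place a point at distance d from origin inside rectangular bounds
place_at_distance <- function(origin_xy, d_m, cage, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    th <- stats::runif(1, 0, 2 * pi)
    p <- origin_xy + d_m * c(cos(th), sin(th))
    if (p[1] >= cage$x[1] && p[1] <= cage$x[2] &&
        p[2] >= cage$y[1] && p[2] <= cage$y[2]) return(p)
  }
  c(min(max(p[1], cage$x[1]), cage$x[2]), min(max(p[2], cage$y[1]), cage$y[2]))
}

#' Run virtual-mouse assignment trials on a session
#'
#' For every trial, `n_virtual` virtual snouts are placed at a given distance
#' from the real mouse (uniform direction, clipped to the cage), and the full
#' assignment rule runs on the segment. With `lut = NULL` the trials record
#' the raw (p, d', candidate count, hit) tuples used to build the confidence
#' table; with a table supplied, the confidence gate is applied and the
#' realized decision recorded.
#'
#' @param session an [analyze_clips()] session.
#' @param design data.frame with one row per trial: `record` (index into
#'   `session$records`), `n_virtual`, `d_mm`.
#' @param seed RNG seed for the placements.
#' @param lut optional [build_confidence_lut()].
#' @param threshold_mm screening threshold (default: the session's own).
#' @param confidence_threshold assignment gate (default 0.99).
#' @return data.frame: design columns plus `outcome`, `mouse_id`,
#'   `best_mouse`, `n_cand`, `p`, `d_mm_obs`, `d_prime_mm`, `confidence`,
#'   `hit` (best mouse is the real one, among tested trials) and
#'   `assigned_correct`.
#' @export
virtual_mouse_trials <- function(session, design, seed = 1, lut = NULL,
                                 threshold_mm = session$threshold_mm,
                                 confidence_threshold = 0.99) {
  cage <- session$cage
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      rec <- session$records[[design$record[i]]]
      real_floor <- pixel_to_floor(session$camera, rec$snout_px)
      snouts <- data.frame(mouse_id = 1L, snout_x_px = rec$snout_px[1],
                           snout_y_px = rec$snout_px[2])
      for (v in seq_len(design$n_virtual[i])) {
        pv <- place_at_distance(real_floor[1:2], design$d_mm[i] / 1000, cage)
        pxv <- floor_to_pixel(session$camera,
                              c(pv, session$camera$floor_z))
        snouts <- rbind(snouts, data.frame(mouse_id = v + 1L,
                                           snout_x_px = pxv[1],
                                           snout_y_px = pxv[2]))
      }
      dec <- assign_segment(list(status = "localized", result = rec$result,
                                 snaps = rec$snaps),
                            snouts, lut, threshold_mm,
                            session$camera, session$geometry,
                            confidence_threshold)
      cbind(design[i, , drop = FALSE],
            data.frame(outcome = dec$outcome, mouse_id = dec$mouse_id,
                       best_mouse = dec$best_mouse, n_cand = dec$n_cand,
                       p = dec$p, d_mm_obs = dec$d_mm,
                       d_prime_mm = dec$d_prime_mm,
                       confidence = dec$confidence,
                       hit = if (is.na(dec$best_mouse)) NA else dec$best_mouse == 1L,
                       assigned_correct = if (dec$outcome == "assigned")
                         identical(dec$mouse_id, 1L) else NA))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Build the confidence lookup table from a single-mouse session
#'
#' Sweeps virtual-mouse placements over all combinations of distance bins and
#' candidate counts on every localized segment and tabulates the precision.
#'
#' @param session an [analyze_clips()] session.
#' @param seed RNG seed (recorded in the metadata).
#' @param d_breaks wrapped-distance bin edges (mm; default 0..200 by 5).
#' @param nc_values candidate counts simulated (virtual mice = `nc - 1`).
#' @param reps placements per (segment, distance, count) combination.
#' @param p_grid p-value threshold grid.
#' @return a [build_confidence_lut()] object.
#' @export
build_session_lut <- function(session, seed = 1,
                              d_breaks = seq(0, 200, by = 5), nc_values = 2:4,
                              reps = 1, p_grid = 10^seq(-6, 0, length.out = 20)) {
  d_centers <- (d_breaks[-1] + d_breaks[-length(d_breaks)]) / 2
  design <- expand.grid(record = seq_along(session$records),
                        n_virtual = nc_values - 1L, d_mm = d_centers,
                        rep = seq_len(reps))
  trials <- virtual_mouse_trials(session, design, seed = seed, lut = NULL)
  tested <- trials[trials$n_cand >= 2 & !is.na(trials$p), ]
  build_confidence_lut(
    data.frame(p = tested$p, d_prime_mm = tested$d_prime_mm,
               n_cand = tested$n_cand, hit = tested$hit),
    p_grid = p_grid, d_breaks = d_breaks, nc_values = nc_values,
    meta = list(seed = seed, n_session_segments = length(session$records),
                reps = reps, min_count = 10))
}
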