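## Acoustic array simulator. Renders frequency-modulated USV syllables emitted
## from point sources on the cage floor, propagates them to the microphone
## array with exact sub-sample (frequency-domain) delays, and produces the
## snout tracks and ground truth needed to validate segmentation, localization
## and assignment without real recordings.

#' Frequency/amplitude contour of one syllable
#'
#' @param times sample times in seconds, strictly increasing, starting at 0.
#' @param freq_hz instantaneous frequency at `times` (Hz, must be > 0).
#' @param amp instantaneous linear amplitude at `times` (>= 0).
#' @return an object of class `syllable_contour`.
#' @export
syllable_contour <- function(times, freq_hz, amp) {
  stopifnot(length(times) == length(freq_hz), length(times) == length(amp))
  if (any(diff(times) <= 0)) stopf("contour times must be strictly increasing")
  if (any(freq_hz <= 0)) stopf("contour frequency must be positive everywhere")
  duration <- times[length(times)] - times[1]
  if (duration <= 0) stopf("contour duration must be positive")
  structure(list(times = times - times[1], freq_hz = freq_hz, amp = amp,
                 duration = duration),
            class = "syllable_contour")
}

#' Random USV-like syllable contour
#'
#' Draws a frequency-modulated contour of one of four shapes commonly seen in
#' adult mouse repertoires: flat, upward sweep, downward sweep, or a modulated
#' ("complex") call. Frequencies stay in the 40-90 kHz band; durations
#' 30-80 ms; amplitude has 5 ms cosine on/off ramps.
#'
#' @param duration_s syllable duration (s); default drawn uniformly 0.03-0.08.
#' @param kind one of "flat", "up", "down", "mod" or "random".
#' @return a [syllable_contour()].
#' @export
random_contour <- function(duration_s = runif(1, 0.03, 0.08), kind = "random") {
  if (kind == "random") kind <- sample(c("flat", "up", "down", "mod"), 1)
  tt <- seq(0, duration_s, by = 1e-4)
  f0 <- runif(1, 45e3, 80e3)
  fr <- switch(kind,
    flat = rep(f0, length(tt)),
    up   = f0 + (tt / duration_s) * runif(1, 10e3, 25e3),
    down = f0 - (tt / duration_s) * runif(1, 10e3, 25e3),
    mod  = f0 + runif(1, 5e3, 12e3) * sin(2 * pi * runif(1, 15, 40) * tt + runif(1, 0, 2 * pi))
  )
  fr <- pmin(pmax(fr, 35e3), 95e3)
  ramp <- 0.005
  a <- pmin(1, pmin(tt, rev(tt)) / ramp)
  a <- 0.5 * (1 - cos(pi * pmin(a, 1)))      # cosine ramps
  syllable_contour(tt, fr, a)
}

#' Synthesize the source waveform of a syllable
#'
#' `x(t) = a(t) sin(2 pi integral_0^t f(tau) d tau)`: the phase is the
#' cumulative integral of the instantaneous frequency.
#'
#' @param contour a [syllable_contour()].
#' @param sample_rate sampling rate (Hz); must exceed twice the maximum
#'   contour frequency.
#' @return numeric waveform of length `round(duration * sample_rate)`.
#' @export
render_source_waveform <- function(contour, sample_rate = 384000) {
  fmax <- max(contour$freq_hz)
  if (sample_rate <= 2 * fmax)
    stopf("contour frequency %.0f Hz exceeds Nyquist (%.0f Hz)", fmax, sample_rate / 2)
  n <- round(contour$duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  f <- stats::approx(contour$times, contour$freq_hz, xout = tt, rule = 2)$y
  a <- stats::approx(contour$times, contour$amp, xout = tt, rule = 2)$y
  phase <- 2 * pi * cumsum(f) / sample_rate
  a * sin(phase)
}

#' Propagate a source waveform to the microphone array
#'
#' Each channel `j` is the source waveform delayed by `tau_j = |r - r_j| / c`.
#' Delays are applied with sub-sample precision by frequency-domain phase
#' rotation, optionally 1/distance amplitude-scaled (relative to the array
#' centroid distance), with seeded white Gaussian noise added per channel.
#'
#' @param waveform numeric source waveform.
#' @param source_position length-3 position (m, camera frame).
#' @param geometry a [mic_array()].
#' @param sample_rate sampling rate (Hz).
#' @param noise_std standard deviation of per-channel white noise (linear).
#' @param seed RNG seed for the noise (`NULL` = use current RNG state).
#' @param attenuate apply 1/distance amplitude scaling (default `TRUE`).
#' @param pad_s extra zero-padding appended after the delayed signal (s).
#' @return numeric matrix, samples x m channels.
#' @export
propagate_to_array <- function(waveform, source_position, geometry,
                               sample_rate = 384000, noise_std = 0,
                               seed = NULL, attenuate = TRUE, pad_s = 0.002) {
  if (any(!is.finite(source_position))) stopf("source position must be finite")
  tau <- propagation_delays(source_position, geometry)
  npad <- length(waveform) + ceiling((max(tau) + pad_s) * sample_rate)
  x <- c(waveform, numeric(npad - length(waveform)))
  X <- stats::fft(x)
  k <- seq_len(npad) - 1
  fgrid <- ifelse(k <= npad / 2, k, k - npad) * sample_rate / npad
  dist_ref <- sqrt(sum((source_position - geometry$centroid)^2))
  out <- matrix(0, npad, geometry$m)
  for (j in seq_len(geometry$m)) {
    ch <- Re(stats::fft(X * exp(-2i * pi * fgrid * tau[j]), inverse = TRUE)) / npad
    if (attenuate) {
      dj <- sqrt(sum((source_position - geometry$positions[j, ])^2))
      ch <- ch * dist_ref / dj
    }
    out[, j] <- ch
  }
  if (noise_std > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(npad * geometry$m, sd = noise_std),
                                        npad, geometry$m))
  }
  out
}

#' Define a simulation scenario
#'
#' @param duration_s recording duration (s).
#' @param mice list of per-mouse trajectories: each a data.frame with columns
#'   `frame`, `x`, `y` (floor position, m) covering all video frames; `z` is
#'   the camera floor depth. A length-2 numeric is taken as a constant (x, y).
#' @param schedule data.frame with columns `mouse` (index into `mice`),
#'   `onset_s`, and a list-column `contour` of [syllable_contour()]s.
#' @param noise_std per-channel white-noise standard deviation (linear). The
#'   default corresponds to roughly 20 dB peak-signal-to-noise for unit-peak
#'   syllables.
#' @param bbv optional data.frame of audible squeak bursts: `onset_s`,
#'   `duration_s`, `level` (linear amplitude).
#' @param geometry,camera array and camera models.
#' @param sample_rate,frame_rate audio (Hz) and video (frames/s) rates.
#' @param seed master RNG seed; rendering is reproducible given the seed.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(duration_s, mice, schedule, noise_std = 0.1,
                         bbv = NULL, geometry = mic_array(),
                         camera = camera_model(), sample_rate = 384000,
                         frame_rate = 30, seed = 1) {
  nframes <- ceiling(duration_s * frame_rate) + 1
  mice <- lapply(mice, function(tr) {
    if (is.numeric(tr) && length(tr) == 2)
      tr <- data.frame(frame = seq_len(nframes), x = tr[1], y = tr[2])
    tr$z <- camera$floor_z
    tr
  })
  if (nrow(schedule) > 0) {
    if (any(schedule$onset_s < 0 | schedule$onset_s > duration_s))
      stopf("syllable onsets must lie within the recording duration")
    if (anyDuplicated(schedule[, c("mouse", "onset_s")]))
      stopf("duplicate (mouse, onset) pairs in the schedule")
  }
  structure(list(duration_s = duration_s, mice = mice, schedule = schedule,
                 noise_std = noise_std, bbv = bbv, geometry = geometry,
                 camera = camera, sample_rate = sample_rate,
                 frame_rate = frame_rate, seed = seed, nframes = nframes),
            class = "sim_scenario")
}

## position of mouse i at time t (nearest video frame)
mouse_position_at <- function(scenario, mouse, time_s) {
  tr <- scenario$mice[[mouse]]
  fr <- pmin(pmax(round(time_s * scenario$frame_rate) + 1, 1), nrow(tr))
  c(tr$x[fr], tr$y[fr], tr$z[fr])
}

## stylized squeak: band-limited noise in harmonic-like bands at 3/8/13 kHz
## (steep band edges so the spectral gaps between "harmonics" stay clean,
## as in real squeaks), with a flat-top 10 ms-ramp envelope
render_bbv_burst <- function(duration_s, level, sample_rate) {
  n <- round(duration_s * sample_rate)
  out <- numeric(n)
  for (fc in c(3e3, 8e3, 13e3)) {
    bp <- signal::butter(4, c(fc - 500, fc + 500) / (sample_rate / 2), type = "pass")
    out <- out + signal::filtfilt(bp, stats::rnorm(n))
  }
  tt <- seq(0, duration_s, length.out = n)
  ramp <- min(0.01, duration_s / 4)
  env <- pmin(1, pmin(tt, duration_s - tt) / ramp)
  env <- 0.5 * (1 - cos(pi * env))
  lvl <- stats::sd(out)
  if (lvl > 0) out <- out / lvl
  out * env * level
}

#' Render a scenario into a recording, snout tracks and ground truth
#'
#' Mixes all scheduled syllables (propagated per-channel with their true
#' delays) and squeak bursts into one multi-channel recording, and reports the
#' pixel-projected snout tracks and a complete ground-truth table.
#'
#' @param scenario a [sim_scenario()].
#' @param snout_jitter_px pixel-level Gaussian jitter added to the projected
#'   snout tracks (emulates video tracking error; default 5 px).
#' @return list with `samples` (samples x m matrix), `sample_rate`,
#'   `timestamps` (per video frame, s), `tracks` (frame, mouse_id,
#'   snout_x_px, snout_y_px), and `truth` (list: `syllables` data.frame with
#'   emitter, onset/offset, true position; `points` with per
#'   time-frequency-point emitter labels on the spectrogram raster, for
#'   contamination scoring; `bbv` intervals data.frame).
#' @export
render_scenario <- function(scenario, snout_jitter_px = 5) {
  fs <- scenario$sample_rate
  ntot <- ceiling(scenario$duration_s * fs)
  mix <- matrix(0, ntot, scenario$geometry$m)
  syl <- NULL
  pts <- list()
  sched <- scenario$schedule
  if (nrow(sched) > 0) {
    for (i in seq_len(nrow(sched))) {
      ct <- sched$contour[[i]]
      pos <- mouse_position_at(scenario, sched$mouse[i], sched$onset_s[i])
      wave <- render_source_waveform(ct, fs)
      chans <- propagate_to_array(wave, pos, scenario$geometry, fs,
                                  noise_std = 0, attenuate = TRUE)
      i0 <- round(sched$onset_s[i] * fs)
      idx <- i0 + seq_len(nrow(chans))
      keep <- idx <= ntot
      mix[idx[keep], ] <- mix[idx[keep], ] + chans[keep, ]
      syl <- rbind(syl, data.frame(
        emitter = sched$mouse[i], onset_s = sched$onset_s[i],
        offset_s = sched$onset_s[i] + ct$duration,
        x = pos[1], y = pos[2], z = pos[3]))
      cp <- contour_peaks(ct)
      cp$frame <- cp$frame + round(sched$onset_s[i] / 5e-4)
      cp$emitter <- sched$mouse[i]
      pts[[length(pts) + 1]] <- cp
    }
  }
  bbv_truth <- NULL
  with_seed(child_seed(scenario$seed, 1), {
    if (!is.null(scenario$bbv) && nrow(scenario$bbv) > 0) {
      for (i in seq_len(nrow(scenario$bbv))) {
        b <- scenario$bbv[i, ]
        burst <- render_bbv_burst(b$duration_s, b$level, fs)
        i0 <- round(b$onset_s * fs)
        idx <- i0 + seq_along(burst)
        keep <- idx <= ntot
        mix[idx[keep], ] <- mix[idx[keep], ] + burst[keep]   # same on all channels
        bbv_truth <- rbind(bbv_truth, data.frame(
          onset_s = b$onset_s, offset_s = b$onset_s + b$duration_s))
      }
    }
    if (scenario$noise_std > 0)
      mix <- mix + matrix(stats::rnorm(length(mix), sd = scenario$noise_std),
                          nrow(mix), ncol(mix))
  })
  timestamps <- (seq_len(scenario$nframes) - 1) / scenario$frame_rate
  tracks <- with_seed(child_seed(scenario$seed, 2), {
    do.call(rbind, lapply(seq_along(scenario$mice), function(mi) {
      tr <- scenario$mice[[mi]]
      px <- floor_to_pixel(scenario$camera, as.matrix(tr[, c("x", "y", "z")]))
      px <- matrix(px, ncol = 2)
      data.frame(frame = tr$frame, mouse_id = mi,
                 snout_x_px = px[, 1] + stats::rnorm(nrow(px), sd = snout_jitter_px),
                 snout_y_px = px[, 2] + stats::rnorm(nrow(px), sd = snout_jitter_px))
    }))
  })
  list(samples = mix, sample_rate = fs, timestamps = timestamps,
       tracks = tracks,
       truth = list(syllables = syl,
                    points = if (length(pts)) do.call(rbind, pts) else NULL,
                    bbv = bbv_truth))
}

#' Overlay pairs of syllable peak sets with random time shifts
#'
#' Emulates temporally crossing syllables from two mice: two peak sets from
#' the library are overlaid with a uniform random shift (within
#' `+/- max_shift_ms`); where peaks from the two sources fall in the same
#' time frame within a narrow bandwidth, only the stronger peak is retained.
#' Per-point source labels are kept for contamination scoring.
#'
#' @param syllable_library list of peak data.frames (columns `frame`, `bin`,
#'   `amp_db`), e.g. from [contour_peaks()].
#' @param n_pairs number of composites to generate.
#' @param max_shift_ms maximum absolute time shift (default 20 ms).
#' @param narrow_bw_hz collision bandwidth (default 750 Hz = one raster pixel).
#' @param seed RNG seed.
#' @param bin_hz,hop_ms raster resolution of the peak sets.
#' @return list of data.frames (`frame`, `bin`, `amp_db`, `source`).
#' @export
make_overlap_pairs <- function(syllable_library, n_pairs, max_shift_ms = 20,
                               narrow_bw_hz = 750, seed = 1,
                               bin_hz = 750, hop_ms = 0.5) {
  stopifnot(length(syllable_library) > 0)
  max_shift_frames <- round(max_shift_ms / hop_ms)
  bw_bins <- narrow_bw_hz / bin_hz
  with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      pick <- sample(length(syllable_library), 2, replace = TRUE)
      a <- syllable_library[[pick[1]]]
      b <- syllable_library[[pick[2]]]
      b$frame <- b$frame + sample(-max_shift_frames:max_shift_frames, 1)
      a$source <- 1L; b$source <- 2L
      both <- rbind(a, b)
      ## collision rule: within one frame and the narrow bandwidth, keep the
      ## stronger peak only
      both <- both[order(both$frame, -both$amp_db), ]
      keep <- rep(TRUE, nrow(both))
      for (fr in unique(both$frame)) {
        ii <- which(both$frame == fr)
        if (length(ii) < 2) next
        taken <- numeric(0)
        for (j in ii) {            # strongest first within the frame
          if (length(taken) && any(abs(both$bin[j] - taken) <= bw_bins)) {
            keep[j] <- FALSE
          } else taken <- c(taken, both$bin[j])
        }
      }
      out <- both[keep, ]
      rownames(out) <- NULL
      out
    })
  })
}

#' Quantize a contour onto the spectrogram raster as a peak set
#'
#' One peak per 0.5 ms time frame at the nearest 750 Hz frequency bin, with
#' the contour's amplitude in dB. This is the idealized peak set a clean
#' recording of the contour would produce.
#'
#' @param contour a [syllable_contour()].
#' @param bin_hz,hop_ms raster resolution.
#' @param amp_db_ref peak amplitude in dB assigned to amplitude 1.
#' @return data.frame with `frame`, `bin`, `amp_db`.
#' @export
contour_peaks <- function(contour, bin_hz = 750, hop_ms = 0.5, amp_db_ref = 20) {
  tt <- seq(0, contour$duration, by = hop_ms / 1000)
  f <- stats::approx(contour$times, contour$freq_hz, xout = tt, rule = 2)$y
  a <- stats::approx(contour$times, contour$amp, xout = tt, rule = 2)$y
  keep <- a > 1e-3
  data.frame(frame = round(tt[keep] / (hop_ms / 1000)),
             bin = round(f[keep] / bin_hz),
             amp_db = amp_db_ref + db(a[keep]))
}

#' Render a time-frequency peak track as audible sound
#'
#' Frequencies are linearly mapped from 0-192 kHz down to 1-6 kHz and the
#' waveform synthesized as `a(t) sin(2 pi integral f)`; the output contains no
#' background noise.
#'
#' @param peak_track data.frame with columns `time_s`, `freq_hz`, `amp`
#'   (linear). Gaps (no rows) are rendered as silence.
#' @param sample_rate output rate (Hz, default 44100).
#' @param duration_s total output duration (default: end of the track).
#' @return numeric audible waveform.
#' @export
render_audible <- function(peak_track, sample_rate = 44100, duration_s = NULL) {
  if (any(peak_track$freq_hz < 0 | peak_track$freq_hz > 192e3))
    stopf("peak frequency outside 0-192 kHz: %.0f Hz",
          peak_track$freq_hz[which(peak_track$freq_hz < 0 | peak_track$freq_hz > 192e3)[1]])
  if (is.null(duration_s)) duration_s <- max(peak_track$time_s) + 0.005
  n <- round(duration_s * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  f_aud <- 1e3 + peak_track$freq_hz / 192e3 * 5e3
  ## carry the mapped frequency across the track, zero amplitude in gaps
  fi <- stats::approx(peak_track$time_s, f_aud, xout = tt, rule = 2)$y
  ai <- rep(0, n)
  ## amplitude only within a half-frame of an actual peak
  half <- 0.5 * stats::median(diff(sort(unique(peak_track$time_s))), na.rm = TRUE)
  if (!is.finite(half)) half <- 1 / sample_rate
  idx <- findInterval(tt, sort(peak_track$time_s) - half)
  near <- sapply(tt, function(x) min(abs(x - peak_track$time_s)))
  ai <- stats::approx(peak_track$time_s, peak_track$amp, xout = tt, rule = 2)$y
  ai[near > 2 * half] <- 0
  phase <- 2 * pi * cumsum(fi) / sample_rate
  ai * sin(phase)
}
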