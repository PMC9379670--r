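## File formats, audio-video synchronization, configuration and the pipeline
## driver. All tables are tab-separated text with headers, re-parseable by
## the package's own readers.

#' Read / write delimited pipeline tables
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_table_tsv` returns a data.frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a recording with its video-frame timestamps
#'
#' @param audio_path multi-channel WAV path.
#' @param timestamps_path sidecar table (`frame_index`, `time_s`).
#' @param geometry the [mic_array()] the channels map to.
#' @return object of class `audio_recording`: `samples`, `sample_rate`,
#'   `timestamps`.
#' @export
read_recording <- function(audio_path, timestamps_path, geometry = mic_array()) {
  w <- read_wav(audio_path)
  if (ncol(w$samples) != geometry$m)
    stopf("channel mismatch: %d channels in %s, %d microphones in geometry",
          ncol(w$samples), audio_path, geometry$m)
  if (!file.exists(timestamps_path)) stopf("missing timestamps file: %s", timestamps_path)
  ts <- read_table_tsv(timestamps_path)
  if (is.null(ts$time_s)) stopf("timestamps file needs a time_s column")
  if (any(diff(ts$time_s) <= 0)) stopf("video timestamps must be strictly increasing")
  structure(list(samples = w$samples, sample_rate = w$sample_rate,
                 timestamps = ts$time_s),
            class = "audio_recording")
}

#' Write a rendered scenario to disk
#'
#' WAV audio (32-bit float), tracking table, timestamps table and ground
#' truth tables, as the recording hardware + tracker would produce them.
#'
#' @param rendered a [render_scenario()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_rendered_scenario <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    audio = file.path(dir, "audio.wav"),
    tracks = file.path(dir, "tracks.tsv"),
    timestamps = file.path(dir, "timestamps.tsv"),
    truth_syllables = file.path(dir, "truth_syllables.tsv"),
    truth_bbv = file.path(dir, "truth_bbv.tsv"))
  write_wav(rendered$samples, paths$audio, rendered$sample_rate, bits = 32)
  write_table_tsv(rendered$tracks, paths$tracks)
  write_table_tsv(data.frame(frame_index = seq_along(rendered$timestamps),
                             time_s = rendered$timestamps), paths$timestamps)
  write_table_tsv(rendered$truth$syllables %||%
                    data.frame(emitter = integer(), onset_s = numeric(),
                               offset_s = numeric(), x = numeric(),
                               y = numeric(), z = numeric()),
                  paths$truth_syllables)
  write_table_tsv(rendered$truth$bbv %||%
                    data.frame(onset_s = numeric(), offset_s = numeric()),
                  paths$truth_bbv)
  paths
}

#' Median-filtered snout positions at a given time
#'
#' Locates the video frame by timestamp (nearest frame) and returns each
#' mouse's snout pixel position after median filtering over the surrounding
#' window; masked/missing positions return NA.
#'
#' @param tracks tracking table (`frame`, `mouse_id`, `snout_x_px`,
#'   `snout_y_px`).
#' @param timestamps per-frame times (s).
#' @param time_s query time.
#' @param median_window_s median-filter window (default 0.16 s).
#' @return data.frame: `mouse_id`, `snout_x_px`, `snout_y_px`.
#' @export
snout_at <- function(tracks, timestamps, time_s, median_window_s = 0.16) {
  fr <- which.min(abs(timestamps - time_s))
  dt <- stats::median(diff(timestamps))
  half <- max(0, round(median_window_s / dt / 2))
  win <- (fr - half):(fr + half)
  do.call(rbind, lapply(sort(unique(tracks$mouse_id)), function(mo) {
    tm <- tracks[tracks$mouse_id == mo & tracks$frame %in% win, ]
    data.frame(mouse_id = mo,
               snout_x_px = stats::median(tm$snout_x_px, na.rm = TRUE),
               snout_y_px = stats::median(tm$snout_y_px, na.rm = TRUE))
  }))
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: raster
#' 0.5 ms x 750 Hz, minimum segment duration 3 ms, spatial-spectrum z
#' thresholds 1.6 / 2.3, 5 x 5-pixel bins with 100-pixel margins, 30 ms
#' syllable merge gap, 28 dB squeak threshold, 0.99 confidence gate.
#'
#' @return nested list of defaults; override via [read_config()].
#' @export
default_config <- function() {
  list(
    sample_rate = 384000,
    geometry = list(side_mm = 8, center_mm = c(54, 9, 6.5), c_sound = 346),
    camera = list(width = 640, height = 480, fov_x_deg = 70, fov_y_deg = 55,
                  floor_z_m = 0.25),
    spectral = list(nfft = 512, hop = 192, tapers = 3, lifter_cutoff = 12,
                    threshold_sigma = 4.5, band_khz = c(30, 120),
                    narrow_bw_hz = 750),
    segmentation = list(corner_cut = TRUE, corner_quality = 0.25,
                        rect = c(3, 15), min_duration_ms = 3),
    localization = list(bin_px = 5, margin_px = 100, z_keep = 1.6,
                        z_clear = 2.3),
    assignment = list(confidence_threshold = 0.99, merge_gap_ms = 30,
                      threshold_mm = NA, lut = NA),
    bbv = list(threshold_db = 28),
    paths = list(audio = NA, tracks = NA, timestamps = NA, outdir = "."),
    seed = 1
  )
}

#' Read a pipeline configuration file
#'
#' YAML file; missing entries fall back to [default_config()].
#'
#' @param path YAML config path (or `NULL` for pure defaults).
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  modify(cfg, user)
}

config_geometry <- function(cfg) {
  mic_array(side = cfg$geometry$side_mm / 1000,
            center = cfg$geometry$center_mm / 1000,
            c_sound = cfg$geometry$c_sound)
}

config_camera <- function(cfg) {
  camera_model(cfg$camera$width, cfg$camera$height, cfg$camera$fov_x_deg,
               cfg$camera$fov_y_deg, cfg$camera$floor_z_m)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Segmentation, squeak exclusion, localization, assignment and syllable
#' merging on a recorded (or simulated) session, writing every stage's table
#' and a run log. Individual stages can be run alone (the CLI subcommands do
#' exactly this); later stages read the earlier stages' tables from
#' `paths$outdir`.
#'
#' @param cfg configuration list (see [read_config()]); `paths$audio`,
#'   `paths$tracks`, `paths$timestamps` must point to the inputs, and
#'   `assignment$lut` to a serialized confidence table (required for the
#'   assign stage).
#' @param stages character vector of stages to run, in order, from
#'   `"segment"`, `"bbv"`, `"localize"`, `"assign"`.
#' @return named list of written paths, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("segment", "bbv", "localize", "assign")) {
  out <- cfg$paths$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  geometry <- config_geometry(cfg)
  camera <- config_camera(cfg)
  paths <- list(segments = file.path(out, "segments.tsv"),
                peaks = file.path(out, "segment_peaks.tsv"),
                bbv = file.path(out, "bbv_intervals.tsv"),
                localization = file.path(out, "localization.tsv"),
                assignments = file.path(out, "assignments.tsv"),
                syllables = file.path(out, "syllables.tsv"),
                log = file.path(out, "run_log.txt"))
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = paths$log,
                            append = TRUE)
  cat(sprintf("usvloc run %s\nseed: %d\n", format(Sys.time()), cfg$seed),
      file = paths$log)
  rec <- with_stage("read", read_recording(cfg$paths$audio, cfg$paths$timestamps,
                                           geometry))
  sp <- cfg$spectral

  if ("segment" %in% stages) with_stage("segment", {
    mt <- multitaper_spectrogram(rec$samples[, 1], rec$sample_rate,
                                 nfft = sp$nfft, hop = sp$hop, k = sp$tapers)
    peaks <- detect_peaks(flatten_spectrogram(mt, sp$lifter_cutoff),
                          threshold_sigma = sp$threshold_sigma,
                          band_hz = sp$band_khz * 1000,
                          narrow_bw_hz = sp$narrow_bw_hz)
    segs <- segment_usv(peaks, corner_cut = cfg$segmentation$corner_cut,
                        min_duration_s = cfg$segmentation$min_duration_ms / 1000,
                        corner_quality = cfg$segmentation$corner_quality,
                        rect = cfg$segmentation$rect)
    write_table_tsv(segs$table, paths$segments)
    write_table_tsv(segs$peaks[!is.na(segs$peaks$segment), ], paths$peaks)
    logf("segment: %d segments, %d peaks", nrow(segs$table),
         sum(!is.na(segs$peaks$segment)))
  })

  if ("bbv" %in% stages) with_stage("bbv", {
    iv <- detect_bbv(rec$samples, rec$sample_rate,
                     threshold_db = cfg$bbv$threshold_db)
    write_table_tsv(iv, paths$bbv)
    logf("bbv: %d intervals", nrow(iv))
  })

  if ("localize" %in% stages) with_stage("localize", {
    segtab <- read_table_tsv(paths$segments)
    segpk <- read_table_tsv(paths$peaks)
    iv <- if (file.exists(paths$bbv)) read_table_tsv(paths$bbv) else
      data.frame(onset_s = numeric(), offset_s = numeric())
    part <- exclude_bbv_overlaps(segtab, iv)
    stft <- stft_tensor(rec$samples, rec$sample_rate, sp$nfft, sp$hop)
    grid <- beam_grid(geometry, camera, cfg$localization$bin_px,
                      cfg$localization$margin_px)
    rows <- lapply(seq_len(nrow(segtab)), function(i) {
      sg <- segtab$segment[i]
      base <- data.frame(segment = sg, status = "bbv_excluded",
                         top_u_px = NA_real_, top_v_px = NA_real_,
                         z_height = NA_real_, n_retained = 0L)
      if (!(sg %in% part$kept$segment)) return(base)
      pk <- segpk[segpk$segment == sg, ]
      loc <- localize_segment(pk, stft, geometry, camera, grid,
                              cfg$localization$z_keep, cfg$localization$z_clear)
      base$status <- loc$status
      if (loc$status == "localized") {
        base$top_u_px <- loc$result$top$u_px
        base$top_v_px <- loc$result$top$v_px
        base$z_height <- loc$result$top$z
        base$n_retained <- nrow(loc$result$peaks)
      }
      base
    })
    write_table_tsv(do.call(rbind, rows), paths$localization)
    logf("localize: %d kept, %d bbv-excluded", nrow(part$kept), nrow(part$excluded))
  })

  if ("assign" %in% stages) with_stage("assign", {
    if (is.na(cfg$assignment$lut) || !file.exists(cfg$assignment$lut))
      stopf("no confidence table configured; build one with the lut-build command and set assignment$lut")
    lut <- read_conf_lut(cfg$assignment$lut)
    if (is.na(cfg$assignment$threshold_mm))
      stopf("assignment$threshold_mm is required (99th percentile of single-mouse snout-peak distances)")
    segtab <- read_table_tsv(paths$segments)
    segpk <- read_table_tsv(paths$peaks)
    loctab <- read_table_tsv(paths$localization)
    tracks <- read_table_tsv(cfg$paths$tracks)
    stft <- stft_tensor(rec$samples, rec$sample_rate, sp$nfft, sp$hop)
    grid <- beam_grid(geometry, camera, cfg$localization$bin_px,
                      cfg$localization$margin_px)
    decs <- lapply(seq_len(nrow(segtab)), function(i) {
      sg <- segtab$segment[i]
      st <- loctab$status[loctab$segment == sg]
      mid <- (segtab$onset_s[i] + segtab$offset_s[i]) / 2
      if (st %in% c("bbv_excluded", "unlocalized")) {
        dec <- data.frame(outcome = st, mouse_id = NA_integer_,
                          best_mouse = NA_integer_, n_cand = 0L, p = NA_real_,
                          d_mm = NA_real_, d_prime_mm = NA_real_,
                          confidence = NA_real_, reason = NA_character_)
      } else {
        pk <- segpk[segpk$segment == sg, ]
        loc <- localize_segment(pk, stft, geometry, camera, grid,
                                cfg$localization$z_keep, cfg$localization$z_clear)
        snouts <- snout_at(tracks, rec$timestamps, mid)
        dec <- assign_segment(loc, snouts, lut, cfg$assignment$threshold_mm,
                              camera, geometry,
                              cfg$assignment$confidence_threshold)
      }
      cbind(data.frame(segment = sg), dec)
    })
    decisions <- do.call(rbind, decs)
    write_table_tsv(decisions, paths$assignments)
    segs_obj <- list(table = segtab, peaks = segpk)
    syl <- merge_into_syllables(decisions, segs_obj,
                                min_gap_s = cfg$assignment$merge_gap_ms / 1000)
    write_table_tsv(syl, paths$syllables)
    logf("assign: %d assigned / %d segments; %d syllables",
         sum(decisions$outcome == "assigned"), nrow(decisions), nrow(syl))
  })
  invisible(paths)
}
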