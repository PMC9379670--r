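## Audible broadband vocalization ("squeak") detection. Squeaks are loud
## audible harmonic sounds; ultrasound segments overlapping them are excluded
## from assignment. The detector: anti-alias low-pass, decimate to 38.4 kHz,
## 10 ms-window spectrogram restricted to 2-16 kHz, per-frequency-bin and
## per-time-bin median subtraction, a 0.5 kHz median filter along frequency,
## and a threshold (28 dB) on the per-frame maximum.

#' Detect audible broadband vocalizations
#'
#' @param samples waveform: numeric vector or matrix (samples x channels;
#'   channels are averaged before detection).
#' @param sample_rate input rate (Hz).
#' @param threshold_db detection threshold in dB above the flattened
#'   (median-subtracted) floor; default 28.
#' @param target_rate decimated rate (default 38.4 kHz).
#' @param window_s spectrogram window (default 10 ms; hop = half window).
#' @param band_hz analysis band (default 2-16 kHz).
#' @param medfilt_hz median-filter window along frequency (default 0.5 kHz).
#' @return data.frame of class `bbv_intervals`: `onset_s`, `offset_s`
#'   (possibly zero rows); attribute `threshold_db`.
#' @export
detect_bbv <- function(samples, sample_rate = 384000, threshold_db = 28,
                       target_rate = 38400, window_s = 0.010,
                       band_hz = c(2e3, 16e3), medfilt_hz = 500) {
  x <- if (is.null(dim(samples))) samples else rowMeans(samples)
  dec <- round(sample_rate / target_rate)
  if (dec > 1) {
    ## anti-alias low-pass (cascaded 4th-order Butterworth = 8th order,
    ## cutoff 17 kHz) before decimation, so USVs cannot alias into the band
    lp <- signal::butter(4, 17e3 / (sample_rate / 2), type = "low")
    x <- signal::filtfilt(lp, x)
    x <- signal::filtfilt(lp, x)
    x <- x[seq(1, length(x), by = dec)]
  }
  fs <- sample_rate / dec
  nfft <- round(window_s * fs)
  hop <- max(1, round(nfft / 2))
  if (length(x) < nfft)
    return(structure(data.frame(onset_s = numeric(), offset_s = numeric()),
                     threshold_db = threshold_db, class = c("bbv_intervals", "data.frame")))
  fr <- frame_signal(x, nfft, hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  S <- Mod(stats::mvfft(fr * win)[seq_len(nfft %/% 2 + 1), , drop = FALSE])
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  keep <- freq >= band_hz[1] & freq <= band_hz[2]
  g <- 20 * log10(pmax(S[keep, , drop = FALSE], 1e-12))
  g <- g - apply(g, 1, stats::median)          # continuous background per freq bin
  g <- sweep(g, 2, apply(g, 2, stats::median)) # impulsive broadband per time bin
  kmed <- round(medfilt_hz / (fs / nfft))
  if (kmed %% 2 == 0) kmed <- kmed + 1
  if (kmed >= 3 && nrow(g) > kmed)
    g <- apply(g, 2, function(col) stats::runmed(col, kmed))
  marked <- apply(g, 2, max) > threshold_db
  times <- ((seq_len(ncol(g)) - 1) * hop) / fs
  iv <- NULL
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    iv <- rbind(iv, data.frame(onset_s = times[starts[i]],
                               offset_s = times[ends[i]] + nfft / fs))
  }
  if (is.null(iv)) iv <- data.frame(onset_s = numeric(), offset_s = numeric())
  attr(iv, "threshold_db") <- threshold_db
  class(iv) <- c("bbv_intervals", "data.frame")
  iv
}

#' Exclude ultrasound segments overlapping squeak intervals
#'
#' A segment is excluded iff its `[onset, offset]` intersects any interval
#' (closed intervals); the partition is exhaustive and disjoint.
#'
#' @param segment_table data.frame with `onset_s`, `offset_s` (e.g.
#'   `usv_segments$table`).
#' @param intervals a [detect_bbv()] result.
#' @return list: `kept` and `excluded` (disjoint subsets of
#'   `segment_table`).
#' @export
exclude_bbv_overlaps <- function(segment_table, intervals) {
  if (nrow(segment_table) == 0 || nrow(intervals) == 0)
    return(list(kept = segment_table, excluded = segment_table[0, ]))
  overl <- vapply(seq_len(nrow(segment_table)), function(i)
    any(segment_table$onset_s[i] <= intervals$offset_s &
        intervals$onset_s <= segment_table$offset_s[i]), logical(1))
  list(kept = segment_table[!overl, , drop = FALSE],
       excluded = segment_table[overl, , drop = FALSE])
}
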