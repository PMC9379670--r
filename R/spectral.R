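## Spectrogram front end: a stable multitaper magnitude spectrogram with
## cepstral-domain flattening and per-frame peak picking, plus the complex
## multi-channel STFT that the beamformer consumes. Both use the same framing
## (512-point FFT, 0.5 ms hop at 384 kHz) so that detected peaks (omega_k,
## t_k) index STFT snapshots directly.

.spectral_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; the first
#' `k` tapers concentrate energy in the half-bandwidth `nw/n` cycles/sample.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default 3; requires `k <= 2*nw - 1`).
#' @return `n x k` matrix of unit-norm tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {       # sign convention: positive mean / leading lobe
    s <- sum(tap[, j])
    if ((j %% 2 == 1 && s < 0) || (j %% 2 == 0 && tap[2, j] < 0)) tap[, j] <- -tap[, j]
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
  }
  .spectral_cache[[key]] <- tap
  tap
}

## frame a signal into overlapping columns (nfft x nframes)
frame_signal <- function(x, nfft, hop) {
  n <- length(x)
  if (n < nfft) stopf("waveform shorter than one analysis window (%d < %d)", n, nfft)
  nframes <- 1 + floor((n - nfft) / hop)
  starts <- (seq_len(nframes) - 1) * hop
  idx <- outer(seq_len(nfft), starts, `+`)
  matrix(x[idx], nrow = nfft)
}

#' Complex multi-channel short-term Fourier transform
#'
#' One complex coefficient grid per microphone channel, windowed with the
#' first Slepian taper. The time axis marks frame centres.
#'
#' @param samples numeric matrix (samples x channels) or vector.
#' @param sample_rate sampling rate (Hz).
#' @param nfft FFT size (default 512; 750 Hz bins at 384 kHz).
#' @param hop hop size in samples (default 192; 0.5 ms at 384 kHz).
#' @return object of class `stft_tensor`: list with `coef` (complex array
#'   freq x time x channel), `freq_hz`, `time_s`, `nfft`, `hop`,
#'   `sample_rate`.
#' @export
stft_tensor <- function(samples, sample_rate = 384000, nfft = 512, hop = 192) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  win <- dpss_tapers(nfft, 2, 3)[, 1]
  nfreq <- nfft / 2 + 1
  nch <- ncol(samples)
  fr1 <- frame_signal(samples[, 1], nfft, hop)
  nframes <- ncol(fr1)
  coef <- array(0i, c(nfreq, nframes, nch))
  for (ch in seq_len(nch)) {
    fr <- if (ch == 1) fr1 else frame_signal(samples[, ch], nfft, hop)
    coef[, , ch] <- stats::mvfft(fr * win)[seq_len(nfreq), , drop = FALSE]
  }
  structure(list(
    coef = coef,
    freq_hz = (seq_len(nfreq) - 1) * sample_rate / nfft,
    time_s = ((seq_len(nframes) - 1) * hop + nfft / 2) / sample_rate,
    nfft = nfft, hop = hop, sample_rate = sample_rate
  ), class = "stft_tensor")
}

#' Multitaper magnitude spectrogram
#'
#' Averages `k` Slepian-tapered periodograms per frame, which stabilizes the
#' noise floor relative to a single-taper spectrogram.
#'
#' @param waveform mono numeric waveform.
#' @param sample_rate sampling rate (Hz).
#' @param nfft,hop framing parameters (defaults as in [stft_tensor()]).
#' @param k number of tapers (default 3).
#' @param floor_db magnitude floor (dB) applied before returning.
#' @return list of class `mt_spectrogram`: `mag_db` (freq x time), `freq_hz`,
#'   `time_s`, plus framing metadata.
#' @export
multitaper_spectrogram <- function(waveform, sample_rate = 384000,
                                   nfft = 512, hop = 192, k = 3,
                                   floor_db = -120) {
  taps <- dpss_tapers(nfft, 2, k)
  fr <- frame_signal(waveform, nfft, hop)
  nfreq <- nfft / 2 + 1
  pow <- 0
  for (j in seq_len(k)) {
    S <- stats::mvfft(fr * taps[, j])[seq_len(nfreq), , drop = FALSE]
    pow <- pow + Mod(S)^2
  }
  pow <- pow / k
  structure(list(
    mag_db = pmax(10 * log10(pmax(pow, 10^(floor_db / 10))), floor_db),
    freq_hz = (seq_len(nfreq) - 1) * sample_rate / nfft,
    time_s = ((seq_len(ncol(fr)) - 1) * hop + nfft / 2) / sample_rate,
    nfft = nfft, hop = hop, sample_rate = sample_rate
  ), class = "mt_spectrogram")
}

## low-quefrency reconstruction of one log-spectrum frame via even-extension
## FFT; keeps cepstral coefficients below `cutoff`
cepstral_envelope <- function(s, cutoff) {
  n <- length(s)
  e <- c(s, rev(s[2:(n - 1)]))          # even extension, length 2n - 2
  E <- stats::fft(e)
  len <- length(E)
  mask <- rep(0, len)
  keep <- seq_len(cutoff)               # quefrencies 0 .. cutoff-1
  mask[keep] <- 1
  if (cutoff > 1) mask[len - (1:(cutoff - 1)) + 1] <- 1
  Re(stats::fft(E * mask, inverse = TRUE))[seq_len(n)] / len
}

#' Flatten a spectrogram by liftering in the cepstral domain
#'
#' Removes the slowly varying spectral envelope (low-quefrency components) of
#' every frame, so that tonal USV ridges stand on a flat ~0 dB floor
#' regardless of the recording's broadband tilt or overall gain.
#'
#' @param spec an [multitaper_spectrogram()] result (or any list with
#'   `mag_db`, `freq_hz`, `time_s`).
#' @param lifter_cutoff number of low cepstral coefficients removed
#'   (default 12).
#' @return same structure with flattened `mag_db`, class
#'   `flattened_spectrogram`.
#' @export
flatten_spectrogram <- function(spec, lifter_cutoff = 12) {
  flat <- apply(spec$mag_db, 2, function(s) s - cepstral_envelope(s, lifter_cutoff))
  ## reference the flattened grid to its median floor
  flat <- flat - stats::median(flat)
  out <- spec
  out$mag_db <- flat
  class(out) <- "flattened_spectrogram"
  out
}

#' Detect spectral peaks per time frame
#'
#' Local maxima of the flattened spectrogram above a detection threshold,
#' restricted to the USV band; within each frame, maxima closer than the
#' narrow bandwidth are reduced to the strongest one.
#'
#' @param flat a [flatten_spectrogram()] result.
#' @param threshold_db absolute detection threshold in flattened dB, or
#'   `NULL` (default) to use `threshold_sigma` times the robust spread (MAD)
#'   of the flattened grid.
#' @param threshold_sigma multiplier for the adaptive threshold (default 4.5).
#' @param band_hz detection band (default 30-120 kHz).
#' @param narrow_bw_hz merge radius within a frame (default 750 Hz).
#' @return data.frame of class `peak_set`: `frame`, `bin` (0-based frequency
#'   bin), `time_s`, `freq_hz`, `amp_db`; attributes `bin_hz`, `hop_s`,
#'   `threshold_db`.
#' @export
detect_peaks <- function(flat, threshold_db = NULL, threshold_sigma = 4.5,
                         band_hz = c(30e3, 120e3), narrow_bw_hz = 750) {
  nyq <- max(flat$freq_hz)
  if (band_hz[1] < 0 || band_hz[2] > nyq) stopf("band must lie within [0, Nyquist]")
  if (is.null(threshold_db))
    threshold_db <- threshold_sigma * stats::mad(flat$mag_db)
  rows <- which(flat$freq_hz >= band_hz[1] & flat$freq_hz <= band_hz[2])
  g <- flat$mag_db[rows, , drop = FALSE]
  nr <- nrow(g)
  out <- vector("list", ncol(g))
  for (j in seq_len(ncol(g))) {
    v <- g[, j]
    is_max <- v > threshold_db &
      v >= c(-Inf, v[-nr]) & v >= c(v[-1], -Inf)
    ii <- which(is_max)
    if (!length(ii)) next
    ## strongest-first merge within the narrow bandwidth
    ord <- ii[order(-v[ii])]
    taken <- numeric(0)
    sel <- integer(0)
    for (i in ord) {
      fi <- flat$freq_hz[rows[i]]
      if (!length(taken) || all(abs(fi - taken) > narrow_bw_hz)) {
        sel <- c(sel, i); taken <- c(taken, fi)
      }
    }
    sel <- sort(sel)
    out[[j]] <- data.frame(frame = j, bin = rows[sel] - 1,
                           time_s = flat$time_s[j],
                           freq_hz = flat$freq_hz[rows[sel]],
                           amp_db = v[sel])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), bin = integer(), time_s = numeric(),
                      freq_hz = numeric(), amp_db = numeric())
  attr(res, "bin_hz") <- flat$freq_hz[2] - flat$freq_hz[1]
  attr(res, "hop_s") <- if (length(flat$time_s) > 1) flat$time_s[2] - flat$time_s[1] else NA_real_
  attr(res, "threshold_db") <- threshold_db
  class(res) <- c("peak_set", "data.frame")
  res
}
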