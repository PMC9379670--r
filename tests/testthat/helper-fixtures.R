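# Shared fixtures, built in code. Expensive session objects are cached for
# the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fix_geometry <- function() mic_array()
fix_camera <- function() camera_model()

## two 1-pixel-wide chirps crossing at +-1 bin/frame (an "X"), with source
## labels for contamination scoring
x_cross_peaks <- function(n = 60, slope = 1) {
  up <- data.frame(frame = 1:n, bin = 100 + round((1:n) * slope) - round(n * slope / 2),
                   amp_db = 10, source = 1L)
  dn <- data.frame(frame = 1:n, bin = 100 - round((1:n) * slope) + round(n * slope / 2),
                   amp_db = 12, source = 2L)
  rbind(up, dn)
}

## clean multichannel clip of a single syllable from a known position
tone_clip <- function(freq_hz = 70e3, pos = c(0.05, 0.02, 0.25), dur = 0.02,
                      snr_db = Inf, seed = 1, fs = 384000,
                      geometry = fix_geometry()) {
  ct <- syllable_contour(c(0, dur), c(freq_hz, freq_hz), c(1, 1))
  w <- render_source_waveform(ct, fs)
  noise <- if (is.finite(snr_db)) max(abs(w)) / 10^(snr_db / 20) else 0
  propagate_to_array(w, pos, geometry, fs, noise_std = noise, seed = seed)
}

## exact signed-rank two-tailed p by enumerating all 2^n sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

## small synthetic single-mouse sessions shared by the acceptance tests
validation_session <- function(which = c("lut", "eval"), seed_base = 20260901) {
  which <- match.arg(which)
  n <- if (which == "lut") 200 else 120
  cached(paste0("session_", which), {
    clips <- simulate_usv_clips(n, seed = seed_base + (which == "eval"))
    analyze_clips(clips)
  })
}

validation_lut <- function() {
  cached("lut", build_session_lut(validation_session("lut"), seed = 101))
}
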