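## Delay-and-sum (Bartlett) beamformer over camera-floor coordinates.
## For a hypothesized floor position r the steering vector is
##   a(r, omega) = [exp(-i omega tau_1(r)), ..., exp(-i omega tau_m(r))],
##   w = a / (a^H a),
## and the normalized spatial spectrum
##   P_norm(r, omega, t) = |w^H x(omega, t) / ||x(omega, t)|| |^2,
## which lies in [0, 1/m] with equality at a perfectly matched source.
## A segment's spatial spectrum P_seg(r) averages P_norm over its spectrogram
## peaks; it is evaluated on 5x5-pixel bins over the image plus 100-pixel
## margins, z-score normalized, and its local maxima are the source
## candidates.

#' Steering vector and beamformer weights
#'
#' @param r floor position (length-3, m).
#' @param omega angular frequency (rad/s), `> 0`.
#' @param geometry a [mic_array()].
#' @return list with `a` (unit-modulus complex m-vector), `w` (`a / (a^H a)` =
#'   `a / m`), and `tau` (delays, s).
#' @export
steering_vector <- function(r, omega, geometry) {
  if (omega <= 0) stopf("omega must be positive")
  tau <- propagation_delays(r, geometry)
  a <- exp(-1i * omega * tau)
  list(a = a, w = a / geometry$m, tau = tau)
}

#' Normalized beamformer power at one position and time-frequency point
#'
#' @param r floor position (length-3, m).
#' @param omega angular frequency (rad/s).
#' @param snapshot complex m-vector `x(omega, t)` of STFT coefficients.
#' @param geometry a [mic_array()].
#' @return `P_norm` in `[0, 1/m]`; 0 for a zero snapshot.
#' @export
beam_pnorm <- function(r, omega, snapshot, geometry) {
  nx <- sqrt(sum(Mod(snapshot)^2))
  if (nx == 0) return(0)
  sv <- steering_vector(r, omega, geometry)
  Mod(sum(Conj(sv$w) * snapshot))^2 / nx^2
}

#' Extract STFT snapshots at a segment's peaks
#'
#' @param peaks data.frame with `frame` and `bin` columns (0-based bins).
#' @param stft an [stft_tensor()].
#' @return list of class `segment_snapshots`: `X` (complex m x n matrix of
#'   unit-norm snapshots; zero snapshots stay zero), `omega` (rad/s per peak),
#'   `freq_hz`, `n`, `m`.
#' @export
segment_snapshots <- function(peaks, stft) {
  nfreq <- dim(stft$coef)[1]
  nframes <- dim(stft$coef)[2]
  if (any(peaks$bin + 1 > nfreq) || any(peaks$frame > nframes) || any(peaks$frame < 1))
    stopf("segment peaks fall outside the STFT grid")
  m <- dim(stft$coef)[3]
  n <- nrow(peaks)
  X <- matrix(0i, m, n)
  for (k in seq_len(n))
    X[, k] <- stft$coef[peaks$bin[k] + 1, peaks$frame[k], ]
  nrm <- sqrt(colSums(Mod(X)^2))
  nz <- nrm > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, nrm[nz], `/`)
  structure(list(X = X, omega = 2 * pi * peaks$bin * stft$sample_rate / stft$nfft,
                 freq_hz = peaks$bin * stft$sample_rate / stft$nfft, n = n, m = m),
            class = "segment_snapshots")
}

#' Beamforming grid over the imaged floor
#'
#' Bin centres of 5 x 5-pixel bins covering the camera image plus margins,
#' back-projected to the floor plane, with per-bin microphone delays
#' precomputed.
#'
#' @param geometry,camera array and camera models.
#' @param bin_px bin size in pixels (default 5).
#' @param margin_px margin width in pixels on each side (default 100).
#' @return list of class `beam_grid`: pixel bin centres `u`, `v`, floor
#'   positions `floor` (nbins x 3, row-major over the `v` x `u` grid), delay
#'   matrix `tau` (nbins x m), and grid dims `nv`, `nu`.
#' @export
beam_grid <- function(geometry, camera, bin_px = 5, margin_px = 100) {
  u <- seq(1 - margin_px + (bin_px - 1) / 2, camera$width + margin_px, by = bin_px)
  v <- seq(1 - margin_px + (bin_px - 1) / 2, camera$height + margin_px, by = bin_px)
  px <- cbind(rep(u, each = length(v)), rep(v, length(u)))  # column-major in v
  fl <- pixel_to_floor(camera, px)
  tau <- propagation_delays(fl, geometry)
  structure(list(u = u, v = v, floor = fl, tau = tau,
                 nv = length(v), nu = length(u),
                 bin_px = bin_px, margin_px = margin_px),
            class = "beam_grid")
}

## mean P_norm over snapshots, evaluated at arbitrary delay rows
## tau: npts x m, snaps: segment_snapshots. Returns vector length npts.
pseg_at_tau <- function(tau, snaps) {
  npts <- nrow(tau)
  P <- numeric(npts)
  for (om in unique(snaps$omega)) {
    kk <- which(snaps$omega == om)
    E <- exp(1i * om * tau)                    # conj(a) rows
    M <- E %*% snaps$X[, kk, drop = FALSE]     # a^H x for each point/snapshot
    P <- P + rowSums(Mod(M)^2)
  }
  P / (snaps$m^2 * snaps$n)
}

#' Average spatial spectrum of a USV segment
#'
#' Evaluates `P_seg(r) = mean_k P_norm(r, omega_k, t_k)` at every grid bin
#' centre and z-score-normalizes the grid.
#'
#' @param peaks the segment's peaks (`frame`, `bin`).
#' @param stft an [stft_tensor()].
#' @param geometry,camera array and camera models.
#' @param grid optional precomputed [beam_grid()].
#' @return object of class `spatial_spectrum`: `z` and `pseg` (nv x nu
#'   matrices), `u`, `v` (pixel bin centres), `grid`, `mean`, `sd`.
#' @export
segment_spatial_spectrum <- function(peaks, stft, geometry, camera, grid = NULL) {
  if (nrow(peaks) < 1) stopf("segment needs at least one peak")
  if (is.null(grid)) grid <- beam_grid(geometry, camera)
  snaps <- segment_snapshots(peaks, stft)
  P <- pseg_at_tau(grid$tau, snaps)
  mu <- mean(P); sdev <- stats::sd(P)
  z <- if (sdev > 0) (P - mu) / sdev else P * 0
  structure(list(
    z = matrix(z, grid$nv, grid$nu), pseg = matrix(P, grid$nv, grid$nu),
    u = grid$u, v = grid$v, grid = grid, mean = mu, sd = sdev
  ), class = "spatial_spectrum")
}

#' @export
print.spatial_spectrum <- function(x, ...) {
  cat(sprintf("<spatial_spectrum> %d x %d bins, z in [%.2f, %.2f]\n",
              nrow(x$z), ncol(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Find and threshold peaks of a spatial spectrum
#'
#' Local maxima are bins whose value equals the 5 x 5 maximum-filtered grid
#' (exact float equality); plateaus of equal value collapse to their centroid
#' bin. Peaks with `z < z_keep` (default 1.6) are excluded; the segment is
#' `localized` only if some peak reaches `z_clear` (default 2.3).
#'
#' @param spec a [segment_spatial_spectrum()] result.
#' @param camera the camera model (for floor coordinates of the peaks).
#' @param z_keep,z_clear retention and clear-peak thresholds.
#' @param window maximum-filter window in bins (default 5).
#' @return object of class `localization_result`: `status` ("localized" or
#'   "unlocalized"), `peaks` (data.frame `u_px`, `v_px`, `z`, `x`, `y`, `z_m`,
#'   sorted by height, ties broken row-major), and `top` (first row).
#' @export
find_spectrum_peaks <- function(spec, camera, z_keep = 1.6, z_clear = 2.3,
                                window = 5) {
  z <- spec$z
  mx <- max_filter(z, window)
  is_pk <- (z == mx) & (z >= z_keep)
  ## drop flat grids (everything equals the filter output)
  if (all(z == mx) || !any(is_pk)) {
    return(structure(list(status = "unlocalized",
                          peaks = data.frame(u_px = numeric(), v_px = numeric(),
                                             z = numeric(), x = numeric(),
                                             y = numeric(), z_m = numeric()),
                          top = NULL), class = "localization_result"))
  }
  ## collapse plateaus: equal-valued adjacent peak bins -> centroid
  lab <- label8(matrix(as.integer(is_pk), nrow(z)))
  rows <- integer(0); cols <- integer(0); zs <- numeric(0)
  for (l in seq_len(max(lab))) {
    cells <- which(lab == l, arr.ind = TRUE)
    vals <- z[cells]
    ## only merge cells of identical value; otherwise keep each
    for (vv in unique(vals)) {
      sub <- cells[vals == vv, , drop = FALSE]
      rows <- c(rows, round(mean(sub[, 1])))
      cols <- c(cols, round(mean(sub[, 2])))
      zs <- c(zs, vv)
    }
  }
  ord <- order(-zs, rows, cols)
  pk_px <- cbind(spec$u[cols[ord]], spec$v[rows[ord]])
  fl <- pixel_to_floor(camera, pk_px)
  fl <- matrix(fl, ncol = 3)
  peaks <- data.frame(u_px = pk_px[, 1], v_px = pk_px[, 2], z = zs[ord],
                      x = fl[, 1], y = fl[, 2], z_m = fl[, 3])
  status <- if (peaks$z[1] >= z_clear) "localized" else "unlocalized"
  structure(list(status = status, peaks = peaks, top = peaks[1, ]),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> %s, %d retained peak(s)\n",
              x$status, nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 5))
  invisible(x)
}

#' Distance from a snout to the nearest spatial-spectrum peak
#'
#' @param result a localized [find_spectrum_peaks()] result.
#' @param snout_px snout pixel position `(u, v)`.
#' @param camera,geometry camera and array models.
#' @return list: `mm` (floor-plane distance to the nearest retained peak),
#'   `deg` (angle between the directions to snout and that peak from the
#'   array centroid), `nearest` (index into `result$peaks`).
#' @export
snout_peak_distance <- function(result, snout_px, camera, geometry) {
  if (result$status != "localized") stopf("segment is unlocalized: no snout-peak distance")
  sf <- pixel_to_floor(camera, snout_px)
  d <- sqrt((result$peaks$x - sf[1])^2 + (result$peaks$y - sf[2])^2)
  i <- which.min(d)
  pk <- c(result$peaks$x[i], result$peaks$y[i], result$peaks$z_m[i])
  list(mm = d[i] * 1000,
       deg = direction_angle_deg(geometry, sf, pk),
       nearest = i)
}

#' Localize one segment
#'
#' Convenience wrapper: spatial spectrum, peak finding, and snapshot caching
#' in one record (the cached snapshots let assignment evaluate beam power at
#' arbitrary snout positions cheaply).
#'
#' @param peaks segment peak rows.
#' @param stft the recording's [stft_tensor()].
#' @param geometry,camera,grid as in [segment_spatial_spectrum()].
#' @param z_keep,z_clear thresholds for [find_spectrum_peaks()].
#' @return list: `status`, `result` (localization_result), `snaps`
#'   (segment_snapshots), `spectrum`.
#' @export
localize_segment <- function(peaks, stft, geometry, camera, grid = NULL,
                             z_keep = 1.6, z_clear = 2.3) {
  spec <- segment_spatial_spectrum(peaks, stft, geometry, camera, grid)
  res <- find_spectrum_peaks(spec, camera, z_keep, z_clear)
  list(status = res$status, result = res,
       snaps = segment_snapshots(peaks, stft), spectrum = spec)
}

#' Calibrate microphone positions against known snout locations
#'
#' Maximizes the summed segment-average beam power at the snout locations of
#' selected calibration syllables over the microphone coordinates, by bounded
#' quasi-Newton (L-BFGS-B) ascent around the nominal geometry.
#'
#' @param cal list of calibration syllables, each a list with `snaps`
#'   (a [segment_snapshots()]) and `snout_floor` (length-3 floor position, m).
#' @param geometry initial [mic_array()].
#' @param bounds_m box half-width around each nominal coordinate (m,
#'   default 3 mm).
#' @return the calibrated `mic_array`, with attributes `objective` (final
#'   summed power) and `objective0` (at the start).
#' @export
calibrate_mic_positions <- function(cal, geometry, bounds_m = 0.003) {
  stopifnot(length(cal) >= 1)
  p0 <- as.numeric(geometry$positions)
  obj <- function(p) {
    g <- geometry
    g$positions <- matrix(p, geometry$m, 3)
    tot <- 0
    for (s in cal) {
      tau <- propagation_delays(s$snout_floor, g)
      tot <- tot + pseg_at_tau(matrix(tau, 1), s$snaps)
    }
    if (!is.finite(tot)) stopf("non-finite calibration objective")
    tot
  }
  f0 <- obj(p0)
  fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = p0 - bounds_m, upper = p0 + bounds_m,
                      control = list(fnscale = -1, maxit = 200))
  out <- geometry
  out$positions <- matrix(fit$par, geometry$m, 3)
  out$centroid <- colMeans(out$positions)
  attr(out, "objective") <- fit$value
  attr(out, "objective0") <- f0
  out
}
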