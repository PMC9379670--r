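## Assignment of localized USV segments to individual mice: candidate
## screening by snout-peak distance, a paired two-tailed Wilcoxon signed-rank
## comparison of beam power at the two best snouts, aliasing-aware wrapped
## snout distance, and a simulation-built confidence lookup table gated at
## confidence > 0.99.

#' Per-peak normalized beam power at a floor position
#'
#' @param point_floor length-3 floor position (m).
#' @param snaps a [segment_snapshots()].
#' @param geometry a [mic_array()].
#' @return numeric vector: `P_norm` at each of the segment's peaks.
#' @export
pnorm_peaks <- function(point_floor, snaps, geometry) {
  tau <- propagation_delays(point_floor, geometry)
  A <- exp(1i * snaps$omega %o% tau)          # n x m, rows = conj(a)^T
  Mod(rowSums(A * t(snaps$X)))^2 / snaps$m^2
}

#' Screen candidate mice by snout-peak distance
#'
#' Mice whose snout-peak distance is within the threshold become source
#' candidates; mice with missing snout data are excluded from candidacy.
#'
#' @param result a localized [find_spectrum_peaks()] result.
#' @param snouts_px data.frame with `mouse_id`, `snout_x_px`, `snout_y_px`
#'   (NA = missing at this frame).
#' @param threshold_mm distance threshold (99th percentile of the
#'   single-mouse snout-peak distance distribution; see
#'   [snout_distance_threshold()]).
#' @param camera,geometry camera and array models.
#' @return data.frame of candidates: `mouse_id`, `mm`, `deg`, `nearest_peak`,
#'   with attribute `all` holding every mouse's distance.
#' @export
screen_candidates <- function(result, snouts_px, threshold_mm, camera, geometry) {
  rows <- lapply(seq_len(nrow(snouts_px)), function(i) {
    if (is.na(snouts_px$snout_x_px[i]) || is.na(snouts_px$snout_y_px[i])) return(NULL)
    d <- snout_peak_distance(result, c(snouts_px$snout_x_px[i], snouts_px$snout_y_px[i]),
                             camera, geometry)
    data.frame(mouse_id = snouts_px$mouse_id[i], mm = d$mm, deg = d$deg,
               nearest_peak = d$nearest)
  })
  all <- do.call(rbind, rows)
  if (is.null(all)) all <- data.frame(mouse_id = integer(), mm = numeric(),
                                      deg = numeric(), nearest_peak = integer())
  cand <- all[all$mm <= threshold_mm, , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "all") <- all
  cand
}

#' Empirical snout-peak distance threshold from a single-mouse session
#'
#' @param distances_mm snout-peak distances from a single-mouse session.
#' @param prob percentile (default 0.99).
#' @return threshold in mm.
#' @export
snout_distance_threshold <- function(distances_mm, prob = 0.99) {
  as.numeric(stats::quantile(distances_mm, prob, na.rm = TRUE))
}

#' Wrapped snout-snout distance
#'
#' Expresses each snout relative to its nearest retained spatial-spectrum
#' peak ("wrapping" the positions in one period of the aliased spectrum) and
#' returns the distance between the two offsets, which restores a meaningful
#' proximity measure when the snouts sit near different alias peaks.
#'
#' @param snout_a_floor,snout_b_floor length-3 floor positions (m).
#' @param result a localized [find_spectrum_peaks()] result.
#' @return list: `d_mm` (raw snout-snout distance), `d_prime_mm` (wrapped).
#' @export
wrapped_distance <- function(snout_a_floor, snout_b_floor, result) {
  if (nrow(result$peaks) < 1) stopf("need at least one retained peak")
  off <- function(s) {
    d <- sqrt((result$peaks$x - s[1])^2 + (result$peaks$y - s[2])^2)
    i <- which.min(d)
    c(s[1] - result$peaks$x[i], s[2] - result$peaks$y[i])
  }
  oa <- off(snout_a_floor); ob <- off(snout_b_floor)
  list(d_mm = sqrt(sum((snout_a_floor[1:2] - snout_b_floor[1:2])^2)) * 1000,
       d_prime_mm = sqrt(sum((oa - ob)^2)) * 1000)
}

#' Compare beam powers at two snouts with a signed-rank test
#'
#' Two-tailed Wilcoxon signed-rank test over the paired per-peak `P_norm`
#' values at the two snout positions: exact null distribution for n <= 25
#' non-zero differences, normal approximation with continuity correction
#' above; all-zero differences give p = 1.
#'
#' @param snaps a [segment_snapshots()].
#' @param snout_a_floor,snout_b_floor floor positions of the two snouts (m).
#' @param geometry a [mic_array()].
#' @return list: `p`, `mean_a`, `mean_b`, `n` (non-zero differences).
#' @export
compare_powers <- function(snaps, snout_a_floor, snout_b_floor, geometry) {
  if (snaps$n < 1) stopf("segment has no peaks")
  pa <- pnorm_peaks(snout_a_floor, snaps, geometry)
  pb <- pnorm_peaks(snout_b_floor, snaps, geometry)
  d <- pa - pb
  nz <- sum(d != 0)
  p <- if (nz == 0) 1 else {
    suppressWarnings(stats::wilcox.test(pa, pb, paired = TRUE,
                                        exact = nz <= 25, correct = TRUE)$p.value)
  }
  list(p = p, mean_a = mean(pa), mean_b = mean(pb), n = nz)
}

#' Build the assignment confidence lookup table from simulation trials
#'
#' Bins trials by wrapped snout distance and candidate count; within each
#' cell, the precision at a p-value threshold is the hit fraction among
#' trials with observed `p <=` that threshold.
#'
#' @param trials data.frame with columns `p`, `d_prime_mm`, `n_cand`,
#'   `hit` (logical), e.g. from [virtual_mouse_trials()].
#' @param p_grid p-value threshold grid (default 20 log-spaced points
#'   1e-6..1).
#' @param d_breaks wrapped-distance bin edges in mm (default 0..200 by 5).
#' @param nc_values candidate counts covered (default 2:4; larger counts
#'   clamp to the last).
#' @param min_count minimum trials per (p, d) cell for a defined precision;
#'   sparser cells are flagged empty (NA).
#' @param meta list of build metadata stored with the table (seed etc.).
#' @return object of class `conf_lut`.
#' @export
build_confidence_lut <- function(trials, p_grid = 10^seq(-6, 0, length.out = 20),
                                 d_breaks = seq(0, 200, by = 5),
                                 nc_values = 2:4, min_count = 10, meta = list()) {
  nd <- length(d_breaks) - 1
  np <- length(p_grid)
  nn <- length(nc_values)
  hits <- totals <- array(0, c(np, nd, nn))
  trials$n_cand <- pmin(trials$n_cand, max(nc_values))
  trials$dbin <- pmin(pmax(findInterval(trials$d_prime_mm, d_breaks,
                                        rightmost.closed = TRUE), 1), nd)
  for (k in seq_len(nn)) {
    tk <- trials[trials$n_cand == nc_values[k], ]
    if (!nrow(tk)) next
    for (j in unique(tk$dbin)) {
      tj <- tk[tk$dbin == j, ]
      for (i in seq_len(np)) {
        sel <- tj$p <= p_grid[i]
        totals[i, j, k] <- sum(sel)
        hits[i, j, k] <- sum(tj$hit[sel])
      }
    }
  }
  precision <- ifelse(totals >= min_count, hits / pmax(totals, 1), NA)
  structure(list(p_grid = p_grid, d_breaks = d_breaks,
                 d_centers = (d_breaks[-1] + d_breaks[-length(d_breaks)]) / 2,
                 nc_values = nc_values, hits = hits, totals = totals,
                 precision = precision, n_trials = nrow(trials), meta = meta),
            class = "conf_lut")
}

#' @export
print.conf_lut <- function(x, ...) {
  cat(sprintf("<conf_lut> %d trials; p: %d pts [%.1e, %g]; d': %d bins (0-%g mm); Nc: %s\n",
              x$n_trials, length(x$p_grid), min(x$p_grid), max(x$p_grid),
              length(x$d_centers), max(x$d_breaks),
              paste(x$nc_values, collapse = ",")))
  cat(sprintf("  empty cells: %d / %d\n", sum(is.na(x$precision)), length(x$precision)))
  invisible(x)
}

#' Look up assignment confidence
#'
#' Bilinear interpolation of the tabulated precision over (log10 p, wrapped
#' distance) at the given candidate count. Out-of-range queries clamp to the
#' nearest tabulated cell; when some neighbouring cells are empty, the lowest
#' available precision among them is used (conservative); if all are empty,
#' `NA` is returned.
#'
#' @param lut a [build_confidence_lut()].
#' @param p observed p-value.
#' @param d_prime_mm observed wrapped snout distance (mm).
#' @param n_cand candidate count.
#' @return confidence in `[0, 1]`, or `NA` if the region is uncharted.
#' @export
lut_confidence <- function(lut, p, d_prime_mm, n_cand) {
  k <- which(lut$nc_values == min(max(n_cand, min(lut$nc_values)), max(lut$nc_values)))
  lp <- log10(max(p, min(lut$p_grid)))
  lgrid <- log10(lut$p_grid)
  i <- findInterval(lp, lgrid, all.inside = TRUE)
  wi <- (lp - lgrid[i]) / (lgrid[i + 1] - lgrid[i])
  wi <- min(max(wi, 0), 1)
  dc <- lut$d_centers
  dd <- min(max(d_prime_mm, dc[1]), dc[length(dc)])
  j <- findInterval(dd, dc, all.inside = TRUE)
  wj <- (dd - dc[j]) / (dc[j + 1] - dc[j])
  corners <- c(lut$precision[i, j, k], lut$precision[i + 1, j, k],
               lut$precision[i, j + 1, k], lut$precision[i + 1, j + 1, k])
  wts <- c((1 - wi) * (1 - wj), wi * (1 - wj), (1 - wi) * wj, wi * wj)
  if (all(is.na(corners))) return(NA_real_)
  if (anyNA(corners)) return(min(corners, na.rm = TRUE))
  sum(corners * wts)
}

#' Decide the assignment of one localized segment
#'
#' Implements the full decision rule: screening (0 candidates = unassigned,
#' 1 = direct assignment), then for >= 2 candidates the signed-rank power
#' comparison of the two best mice, the wrapped snout distance, and the
#' confidence lookup gated at `confidence_threshold`.
#'
#' @param loc a [localize_segment()] record (needs `status`, `result`,
#'   `snaps`).
#' @param snouts_px per-mouse snout pixels (see [screen_candidates()]).
#' @param lut a [build_confidence_lut()] (may be `NULL` when at most one
#'   candidate can occur).
#' @param threshold_mm screening distance threshold (mm).
#' @param camera,geometry camera and array models.
#' @param confidence_threshold assignment gate (default 0.99, exclusive).
#' @return one-row data.frame: `outcome` ("assigned", "unassigned",
#'   "unlocalized"), `mouse_id`, `n_cand`, `p`, `d_mm`, `d_prime_mm`,
#'   `confidence`, `reason`.
#' @export
assign_segment <- function(loc, snouts_px, lut, threshold_mm, camera, geometry,
                           confidence_threshold = 0.99) {
  dec <- data.frame(outcome = "unassigned", mouse_id = NA_integer_,
                    best_mouse = NA_integer_, n_cand = 0L, p = NA_real_,
                    d_mm = NA_real_, d_prime_mm = NA_real_,
                    confidence = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (loc$status != "localized") {
    dec$outcome <- "unlocalized"
    return(dec)
  }
  cand <- screen_candidates(loc$result, snouts_px, threshold_mm, camera, geometry)
  dec$n_cand <- nrow(cand)
  if (nrow(attr(cand, "all")) == 0) {
    dec$reason <- "no snout data"
    return(dec)
  }
  if (nrow(cand) == 0) {
    dec$reason <- "no candidate within threshold"
    return(dec)
  }
  snout_floor <- function(mid) {
    i <- which(snouts_px$mouse_id == mid)
    pixel_to_floor(camera, c(snouts_px$snout_x_px[i], snouts_px$snout_y_px[i]))
  }
  if (nrow(cand) == 1) {
    dec$outcome <- "assigned"
    dec$mouse_id <- cand$mouse_id[1]
    dec$best_mouse <- cand$mouse_id[1]
    dec$reason <- "single candidate"
    return(dec)
  }
  pw <- vapply(cand$mouse_id,
               function(mid) mean(pnorm_peaks(snout_floor(mid), loc$snaps, geometry)),
               numeric(1))
  ord <- order(-pw)
  best <- cand$mouse_id[ord[1]]; second <- cand$mouse_id[ord[2]]
  dec$best_mouse <- best
  cp <- compare_powers(loc$snaps, snout_floor(best), snout_floor(second), geometry)
  wd <- wrapped_distance(snout_floor(best), snout_floor(second), loc$result)
  dec$p <- cp$p; dec$d_mm <- wd$d_mm; dec$d_prime_mm <- wd$d_prime_mm
  if (is.null(lut)) {
    dec$reason <- "no confidence table"
    return(dec)
  }
  conf <- lut_confidence(lut, cp$p, wd$d_prime_mm, nrow(cand))
  dec$confidence <- conf
  if (is.na(conf)) {
    dec$reason <- "empty confidence cell"
  } else if (conf > confidence_threshold) {
    dec$outcome <- "assigned"
    dec$mouse_id <- best
  } else {
    dec$reason <- "confidence below threshold"
  }
  dec
}

#' Merge assigned segments into syllables
#'
#' Per mouse, that mouse's assigned segments plus interleaved unassigned
#' segments are chained whenever the gap to the next segment is below the
#' merge threshold (default 30 ms); chains containing at least one assigned
#' segment become syllables. An unassigned segment eligible for syllables of
#' several mice is merged into the nearest-in-time one only, and the
#' ambiguity is counted.
#'
#' @param decisions data.frame with one row per segment (`segment`,
#'   `outcome`, `mouse_id`), as produced by [assign_segment()] rows bound
#'   together.
#' @param segments the `usv_segments` object the decisions refer to.
#' @param min_gap_s merge threshold (default 0.030, strict: gaps `< min_gap_s`
#'   merge).
#' @return data.frame of class `syllable_table`: `syllable`, `mouse_id`,
#'   `onset_s`, `offset_s`, `n_segments`, `n_points`, `n_points_assigned`,
#'   `assignment_rate`, `segment_ids` (comma-separated); attribute
#'   `ambiguous_unassigned` counts doubly-claimed unassigned segments.
#' @export
merge_into_syllables <- function(decisions, segments, min_gap_s = 0.030) {
  tab <- merge(segments$table, decisions, by = "segment")
  tab <- tab[order(tab$onset_s), ]
  mice <- sort(unique(tab$mouse_id[tab$outcome == "assigned"]))
  claims <- list()   # per unassigned segment: candidate (mouse, syllable onset dist)
  chains <- list()
  for (mo in mice) {
    sel <- tab[tab$outcome == "unassigned" |
               (tab$outcome == "assigned" & tab$mouse_id == mo), ]
    if (!nrow(sel)) next
    gap_new <- c(TRUE, sel$onset_s[-1] - sel$offset_s[-nrow(sel)] >= min_gap_s)
    chain_id <- cumsum(gap_new)
    for (cid in unique(chain_id)) {
      ch <- sel[chain_id == cid, ]
      if (!any(ch$outcome == "assigned")) next
      chains[[length(chains) + 1]] <- list(mouse = mo, segs = ch)
    }
  }
  ## resolve unassigned segments claimed by chains of different mice:
  ## keep them only in the nearest-in-time chain
  seg_claims <- do.call(rbind, lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]$segs
    un <- ch[ch$outcome == "unassigned", ]
    if (!nrow(un)) return(NULL)
    asg <- ch[ch$outcome == "assigned", ]
    data.frame(chain = i, segment = un$segment,
               dist = vapply(seq_len(nrow(un)), function(j)
                 min(abs(un$onset_s[j] - asg$onset_s), abs(un$onset_s[j] - asg$offset_s)),
                 numeric(1)))
  }))
  ambiguous <- 0L
  drop_from <- NULL
  if (!is.null(seg_claims) && nrow(seg_claims)) {
    for (sg in unique(seg_claims$segment)) {
      cl <- seg_claims[seg_claims$segment == sg, ]
      if (nrow(cl) > 1) {
        ambiguous <- ambiguous + 1L
        lose <- cl$chain[-which.min(cl$dist)]
        drop_from <- rbind(drop_from, data.frame(chain = lose, segment = sg))
      }
    }
  }
  out <- do.call(rbind, lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]$segs
    if (!is.null(drop_from)) {
      dr <- drop_from$segment[drop_from$chain == i]
      ch <- ch[!(ch$segment %in% dr), ]
    }
    if (!any(ch$outcome == "assigned")) return(NULL)
    n_pts <- sum(ch$n_peaks)
    n_asg <- sum(ch$n_peaks[ch$outcome == "assigned"])
    data.frame(mouse_id = chains[[i]]$mouse, onset_s = min(ch$onset_s),
               offset_s = max(ch$offset_s), n_segments = nrow(ch),
               n_points = n_pts, n_points_assigned = n_asg,
               assignment_rate = n_asg / n_pts,
               segment_ids = paste(ch$segment, collapse = ","))
  }))
  if (is.null(out))
    out <- data.frame(mouse_id = integer(), onset_s = numeric(),
                      offset_s = numeric(), n_segments = integer(),
                      n_points = integer(), n_points_assigned = integer(),
                      assignment_rate = numeric(), segment_ids = character())
  out <- out[order(out$onset_s, out$mouse_id), ]
  out <- cbind(syllable = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "ambiguous_unassigned") <- ambiguous
  class(out) <- c("syllable_table", "data.frame")
  out
}

#' Acoustic features of one syllable
#'
#' Computed from the syllable contour (the frequency of the
#' maximum-amplitude peak at each time point): median/min/max/delta
#' frequency, frequency SD, slope (least-squares line), sinuosity (contour
#' arc length over straight chord, in ms x kHz space), mean amplitude, peak
#' frequency (frequency at the maximum amplitude) and duration, plus 10-bin
#' contour features (per-bin mean frequency and its first difference, and
#' duration).
#'
#' @param peaks the syllable's peaks (`time_s`, `freq_hz`, `amp_db`,
#'   `frame`).
#' @return list: `traditional` (named numeric; `slope` is `NA` for a
#'   single-point contour), `contour10` (named numeric of length 20:
#'   10 bin frequencies, 9 first differences, duration).
#' @export
syllable_features <- function(peaks) {
  ## contour: max-amplitude peak per frame
  ct <- do.call(rbind, lapply(split(peaks, peaks$frame), function(d)
    d[which.max(d$amp_db), c("time_s", "freq_hz", "amp_db")]))
  ct <- ct[order(ct$time_s), ]
  dur <- max(ct$time_s) - min(ct$time_s)
  f <- ct$freq_hz
  single <- nrow(ct) < 2
  slope <- if (single) NA_real_ else
    unname(stats::coef(stats::lm(f ~ ct$time_s))[2])
  sinuosity <- if (single) NA_real_ else {
    tm <- (ct$time_s - ct$time_s[1]) * 1000   # ms
    fk <- f / 1000                            # kHz
    arc <- sum(sqrt(diff(tm)^2 + diff(fk)^2))
    chord <- sqrt((tm[length(tm)] - tm[1])^2 + (fk[length(fk)] - fk[1])^2)
    if (chord > 0) arc / chord else NA_real_
  }
  trad <- c(median_freq = stats::median(f), min_freq = min(f), max_freq = max(f),
            delta_freq = max(f) - min(f), sd_freq = stats::sd(f),
            slope = slope, sinuosity = sinuosity,
            mean_amp = mean(ct$amp_db),
            peak_freq = ct$freq_hz[which.max(ct$amp_db)],
            duration = dur)
  ## 10-bin contour
  brk <- seq(min(ct$time_s), max(ct$time_s), length.out = 11)
  bin <- pmin(pmax(findInterval(ct$time_s, brk, rightmost.closed = TRUE), 1), 10)
  fbin <- vapply(1:10, function(b) {
    v <- f[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ## carry nearest observation into empty bins
  filled <- which(!is.na(fbin))
  for (b in which(is.na(fbin)))
    fbin[b] <- fbin[filled[which.min(abs(filled - b))]]
  c10 <- c(stats::setNames(fbin, paste0("cfreq", 1:10)),
           stats::setNames(diff(fbin), paste0("cshape", 1:9)),
           duration = dur)
  list(traditional = trad, contour10 = c10)
}

#' Column-wise z-scoring of a feature matrix
#'
#' @param x numeric matrix (syllables x features).
#' @return matrix with each column standardized to mean 0, SD 1 (constant
#'   columns become 0).
#' @export
zscore_features <- function(x) {
  apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(col * 0)
    (col - mean(col)) / s
  })
}

#' Serialize / load a confidence lookup table
#'
#' JSON with the grids, counts and metadata; round-trips exactly enough for
#' assignment (precision is rebuilt from the stored counts).
#'
#' @param lut a `conf_lut`.
#' @param path file path.
#' @return `read_conf_lut` returns the `conf_lut`.
#' @export
write_conf_lut <- function(lut, path) {
  obj <- list(p_grid = lut$p_grid, d_breaks = lut$d_breaks,
              nc_values = lut$nc_values,
              hits = as.numeric(lut$hits), totals = as.numeric(lut$totals),
              dim = dim(lut$hits), n_trials = lut$n_trials,
              min_count = lut$meta$min_count %||% 10, meta = lut$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_conf_lut
#' @export
read_conf_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hits <- array(obj$hits, obj$dim)
  totals <- array(obj$totals, obj$dim)
  min_count <- obj$min_count %||% 10
  precision <- ifelse(totals >= min_count, hits / pmax(totals, 1), NA)
  d_breaks <- obj$d_breaks
  structure(list(p_grid = obj$p_grid, d_breaks = d_breaks,
                 d_centers = (d_breaks[-1] + d_breaks[-length(d_breaks)]) / 2,
                 nc_values = obj$nc_values, hits = hits, totals = totals,
                 precision = precision, n_trials = obj$n_trials,
                 meta = as.list(obj$meta)),
            class = "conf_lut")
}
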