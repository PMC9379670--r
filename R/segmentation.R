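## Grouping of spectral peaks into USV segments on a binary raster
## (0.5 ms x 750 Hz pixels), with a corner-cut + watershed step that separates
## syllables crossing in time-frequency. Rows index frequency bins, columns
## index time frames.

## 8-connected labelling of a binary matrix (EBImage::bwlabel is 4-connected)
label8 <- function(img) {
  lab <- matrix(0L, nrow(img), ncol(img))
  nr <- nrow(img)
  fg <- which(img > 0)
  nxt <- 0L
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  rowof <- function(i) ((i - 1L) %% nr) + 1L
  for (p in fg) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- rowof(q)
      nb <- q + offs
      ok <- nb >= 1L & nb <= length(img) & abs(rowof(nb) - r) <= 1L
      nb <- nb[ok]
      nb <- nb[img[nb] > 0 & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Rasterize a peak set into a binary time-frequency image
#'
#' One set pixel per occupied 0.5 ms x 750 Hz cell. The image is padded by
#' `pad` pixels on every side so that subsequent morphology has room.
#'
#' @param peaks a [detect_peaks()] result or any data.frame with integer
#'   `frame` and `bin` columns.
#' @param band_bins optional integer range `c(lo, hi)` of allowed frequency
#'   bins; peaks outside it raise an error naming the offender.
#' @param pad padding in pixels (default 8).
#' @return binary integer matrix of class `segment_image` with attributes
#'   `frame0` and `bin0` mapping `img[r, c]` to
#'   `frame = c + frame0`, `bin = r + bin0`.
#' @export
rasterize_peaks <- function(peaks, band_bins = NULL, pad = 8) {
  if (!is.null(band_bins)) {
    bad <- which(peaks$bin < band_bins[1] | peaks$bin > band_bins[2])
    if (length(bad))
      stopf("peak out of band: frame %d, bin %d", peaks$frame[bad[1]], peaks$bin[bad[1]])
  }
  if (nrow(peaks) == 0) {
    img <- matrix(0L, 1 + 2 * pad, 1 + 2 * pad)
    attr(img, "frame0") <- -pad
    attr(img, "bin0") <- -pad
    class(img) <- c("segment_image", class(img))
    return(img)
  }
  frame0 <- min(peaks$frame) - pad - 1L
  bin0 <- min(peaks$bin) - pad - 1L
  img <- matrix(0L, max(peaks$bin) - bin0 + pad, max(peaks$frame) - frame0 + pad)
  img[cbind(peaks$bin - bin0, peaks$frame - frame0)] <- 1L
  attr(img, "frame0") <- frame0
  attr(img, "bin0") <- bin0
  class(img) <- c("segment_image", class(img))
  img
}

keep_attrs <- function(new, old) {
  attr(new, "frame0") <- attr(old, "frame0")
  attr(new, "bin0") <- attr(old, "bin0")
  class(new) <- c("segment_image", class(new))
  new
}

#' Connect neighbouring peak pixels
#'
#' Dilates twice then erodes once with a 3 x 3 square structuring element, so
#' runs up to 2 pixels apart become 8-connected.
#'
#' @param img a binary [rasterize_peaks()] image.
#' @return connected binary image (same attributes).
#' @export
connect_components <- function(img) {
  b <- EBImage::makeBrush(3, "box")
  out <- EBImage::erode(EBImage::dilate(EBImage::dilate(unclass(img), b), b), b)
  keep_attrs(matrix(as.integer(out > 0), nrow(img)), img)
}

## Harris corner response of a binary image
harris_response <- function(img, sigma = 1, kappa = 0.04) {
  g <- matrix(as.numeric(img), nrow(img))
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(g, sob)
  gy <- EBImage::filter2(g, t(sob))
  sxx <- EBImage::gblur(gx * gx, sigma)
  syy <- EBImage::gblur(gy * gy, sigma)
  sxy <- EBImage::gblur(gx * gy, sigma)
  (sxx * syy - sxy^2) - kappa * (sxx + syy)^2
}

#' Erase rectangles around detected corners
#'
#' Detects corner points (crossings and sharp edges) of the connected binary
#' image with a Harris-style corner measure and erases a rectangle (default
#' 3 pixels along frequency x 15 along time) centred on each corner, cutting
#' contours at their crossing points.
#'
#' @param img connected binary image.
#' @param quality corner quality threshold relative to the strongest corner
#'   response (default 0.25; tuned so that crossings fire but smooth chirp
#'   ridges do not).
#' @param rect erase rectangle as `c(freq_pixels, time_pixels)`, default
#'   `c(3, 15)`.
#' @return cut binary image (same attributes).
#' @export
cut_at_corners <- function(img, quality = 0.25, rect = c(3, 15)) {
  if (!any(img > 0)) return(img)
  R <- harris_response(img)
  thr <- quality * max(R)
  if (thr <= 0) return(img)
  mx <- max_filter(R, 3)
  cand <- which(R == mx & R > thr, arr.ind = TRUE)
  out <- unclass(img)
  hr <- (rect[1] - 1) %/% 2
  hc <- (rect[2] - 1) %/% 2
  for (i in seq_len(nrow(cand))) {
    rr <- max(1, cand[i, 1] - hr):min(nrow(out), cand[i, 1] + hr)
    cc <- max(1, cand[i, 2] - hc):min(ncol(out), cand[i, 2] + hc)
    out[rr, cc] <- 0L
  }
  keep_attrs(out, img)
}

#' Group peaks into segments by marker-based watershed
#'
#' The post-cut components seed a watershed of the distance transform of the
#' pre-cut (connected) foreground; every original peak is assigned to exactly
#' one region. Components fully erased by the cut step keep their own label.
#' Segments spanning `<= min_duration_s` are dropped.
#'
#' @param img_cut image after [cut_at_corners()].
#' @param img_connected image after [connect_components()] (pre-cut).
#' @param peaks the peak set that was rasterized (needs `frame`, `bin`,
#'   `time_s`, `freq_hz`, `amp_db`).
#' @param min_duration_s minimum segment time span (default 3.0 ms,
#'   exclusive).
#' @return object of class `usv_segments`: list with `peaks` (the input rows
#'   plus a `segment` column; dropped-short-segment peaks carry `segment = NA`)
#'   and `table` (`segment`, `onset_s`, `offset_s`, `duration_s`, `n_peaks`).
#' @export
watershed_group <- function(img_cut, img_connected, peaks,
                            min_duration_s = 0.003) {
  frame0 <- attr(img_connected, "frame0")
  bin0 <- attr(img_connected, "bin0")
  seeds <- label8(img_cut)
  mask <- unclass(img_connected) > 0
  if (any(seeds > 0)) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- EBImage::propagate(dm, EBImage::Image(seeds), mask = EBImage::Image(mask * 1))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img_connected))
  } else {
    lab <- matrix(0L, nrow(img_connected), ncol(img_connected))
  }
  ## components of the connected image that received no seed keep themselves
  unlabeled <- mask & lab == 0L
  if (any(unlabeled)) {
    extra <- label8(matrix(as.integer(unlabeled), nrow(lab)))
    lab[unlabeled] <- max(lab) + extra[unlabeled]
  }
  pk_lab <- lab[cbind(peaks$bin - bin0, peaks$frame - frame0)]
  ## peaks on pixels eroded away by the closing: snap to the nearest labelled pixel
  if (any(pk_lab == 0L) && any(lab > 0L)) {
    labbed <- which(lab > 0L, arr.ind = TRUE)
    for (i in which(pk_lab == 0L)) {
      d2 <- (labbed[, 1] - (peaks$bin[i] - bin0))^2 +
            (labbed[, 2] - (peaks$frame[i] - frame0))^2
      pk_lab[i] <- lab[labbed[which.min(d2), , drop = FALSE]]
    }
  }
  peaks$segment <- pk_lab
  ## order segments by onset, drop too-short ones
  spans <- tapply(peaks$time_s, peaks$segment, function(x) max(x) - min(x))
  good <- names(spans)[spans > min_duration_s]
  peaks$segment[!(peaks$segment %in% as.integer(good))] <- NA
  onsets <- tapply(peaks$time_s[!is.na(peaks$segment)],
                   peaks$segment[!is.na(peaks$segment)], min)
  remap <- stats::setNames(rank(onsets, ties.method = "first"), names(onsets))
  peaks$segment <- as.integer(remap[as.character(peaks$segment)])
  kept <- peaks[!is.na(peaks$segment), ]
  tab <- if (nrow(kept)) {
    do.call(rbind, lapply(split(kept, kept$segment), function(d) data.frame(
      segment = d$segment[1], onset_s = min(d$time_s), offset_s = max(d$time_s),
      duration_s = max(d$time_s) - min(d$time_s), n_peaks = nrow(d))))
  } else {
    data.frame(segment = integer(), onset_s = numeric(), offset_s = numeric(),
               duration_s = numeric(), n_peaks = integer())
  }
  rownames(tab) <- NULL
  structure(list(peaks = peaks, table = tab), class = "usv_segments")
}

#' @export
print.usv_segments <- function(x, ...) {
  cat(sprintf("<usv_segments> %d segments, %d peaks (%d unsegmented)\n",
              nrow(x$table), sum(!is.na(x$peaks$segment)),
              sum(is.na(x$peaks$segment))))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Segment a peak set into USV segments
#'
#' Full segmentation chain: rasterize, connect neighbouring pixels, cut at
#' corner points (optional; disabling reduces the pipeline to plain
#' connected-component grouping), and group peaks by marker-based watershed.
#'
#' @param peaks a [detect_peaks()] result (or compatible data.frame; missing
#'   `time_s`/`freq_hz` are derived from `frame`/`bin` and the raster
#'   resolution).
#' @param corner_cut apply the crossing-point separation step (default TRUE).
#' @param min_duration_s minimum segment span (default 3.0 ms, exclusive).
#' @param corner_quality,rect passed to [cut_at_corners()].
#' @param hop_s,bin_hz raster resolution used when `time_s`/`freq_hz` absent.
#' @return an `usv_segments` object (see [watershed_group()]).
#' @export
segment_usv <- function(peaks, corner_cut = TRUE, min_duration_s = 0.003,
                        corner_quality = 0.25, rect = c(3, 15),
                        hop_s = 5e-4, bin_hz = 750) {
  if (is.null(peaks$time_s)) peaks$time_s <- peaks$frame * hop_s
  if (is.null(peaks$freq_hz)) peaks$freq_hz <- peaks$bin * bin_hz
  if (is.null(peaks$amp_db)) peaks$amp_db <- 0
  img <- rasterize_peaks(peaks)
  conn <- connect_components(img)
  cut <- if (corner_cut) cut_at_corners(conn, quality = corner_quality, rect = rect) else conn
  watershed_group(cut, conn, peaks, min_duration_s = min_duration_s)
}

#' Contamination ratio of a segmentation against ground-truth labels
#'
#' For each segment the minority-source points count as contaminated;
#' the ratio is `sum(n_i) / N` over all segmented points.
#'
#' @param segments an `usv_segments` object whose peaks carry ground-truth
#'   source labels, either as a `source` column or joined from `point_labels`.
#' @param point_labels optional data.frame (`frame`, `bin`, `source`) to join
#'   by raster cell; every segmented point must receive a label.
#' @return list of class `contamination_report`: `per_segment` (segment,
#'   n_points, n_contaminated), `n_total`, `ratio`.
#' @export
contamination_ratio <- function(segments, point_labels = NULL) {
  pk <- segments$peaks[!is.na(segments$peaks$segment), ]
  if (!is.null(point_labels)) {
    key <- paste(pk$frame, pk$bin)
    lut <- stats::setNames(point_labels$source, paste(point_labels$frame, point_labels$bin))
    pk$source <- lut[key]
  }
  if (is.null(pk$source) || anyNA(pk$source))
    stopf("every segmented point needs a ground-truth source label")
  per <- do.call(rbind, lapply(split(pk, pk$segment), function(d) {
    n_min <- nrow(d) - max(table(d$source))
    data.frame(segment = d$segment[1], n_points = nrow(d), n_contaminated = n_min)
  }))
  rownames(per) <- NULL
  n_total <- sum(per$n_points)
  structure(list(per_segment = per, n_total = n_total,
                 ratio = if (n_total > 0) sum(per$n_contaminated) / n_total else 0),
            class = "contamination_report")
}
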