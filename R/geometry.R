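## Physical model: microphone array geometry and the pinhole camera that maps
## image pixels to positions on the cage floor. Coordinates are metres in the
## camera frame: origin at the optical centre, x right along image columns,
## y down along image rows, z along the optical axis towards the floor.

#' Microphone array geometry
#'
#' Describes the compact phased array: an `m`-microphone layout (by default a
#' square, 8 mm on each side, mounted 54 x 9 mm laterally and 6.5 mm in front
#' of the camera's optical centre) and the speed of sound.
#'
#' @param positions numeric `m x 3` matrix of microphone positions (m, camera
#'   frame). Default: the nominal 8 mm square.
#' @param c_sound speed of sound in m/s. Default 346 (air at ~25 degrees C).
#' @param side side length of the default square layout (m).
#' @param center centre of the default square layout (m, camera frame).
#' @return an object of class `mic_array` with elements `positions`, `c_sound`,
#'   `m` and `centroid`.
#' @export
mic_array <- function(positions = NULL, c_sound = 346,
                      side = 0.008, center = c(0.054, 0.009, 0.0065)) {
  if (is.null(positions)) {
    h <- side / 2
    positions <- cbind(
      x = center[1] + c(-h, h, h, -h),
      y = center[2] + c(-h, -h, h, h),
      z = center[3]
    )
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stopf("microphone positions must be m x 3")
  if (nrow(positions) < 2) stopf("need at least 2 microphones")
  d <- as.matrix(dist(positions))
  if (any(d[upper.tri(d)] < 1e-9)) stopf("microphone positions must be pairwise distinct")
  structure(list(
    positions = positions,
    c_sound = c_sound,
    m = nrow(positions),
    centroid = colMeans(positions)
  ), class = "mic_array")
}

#' @export
print.mic_array <- function(x, ...) {
  cat(sprintf("<mic_array> %d microphones, c = %g m/s\n", x$m, x$c_sound))
  print(round(x$positions * 1000, 3))
  invisible(x)
}

#' Expected propagation delays from a source to each microphone
#'
#' `tau_j(r) = |r - r_j| / c` for every microphone `j`.
#'
#' @param r numeric length-3 source position (m) or `n x 3` matrix.
#' @param geometry a [mic_array()].
#' @return delays in seconds; `n x m` matrix (drops to a vector for one source).
#' @export
propagation_delays <- function(r, geometry) {
  r <- if (is.null(dim(r))) matrix(r, nrow = 1) else as.matrix(r)
  if (any(!is.finite(r))) stopf("source position must be finite")
  tau <- sapply(seq_len(geometry$m), function(j) {
    dr <- sweep(r, 2, geometry$positions[j, ])
    sqrt(rowSums(dr^2)) / geometry$c_sound
  })
  if (nrow(r) == 1) as.numeric(tau) else tau
}

#' Pinhole camera over the cage floor
#'
#' An ideal pinhole derived from the stated field of view: focal lengths
#' `fx = (W/2)/tan(fov_x/2)`, `fy = (H/2)/tan(fov_y/2)`, principal point at the
#' image centre. Sound sources are assumed to lie on the cage floor, a plane of
#' constant depth `floor_z` along the optical axis.
#'
#' @param width,height image size in pixels (default 640 x 480).
#' @param fov_x_deg,fov_y_deg field of view in degrees (default 70 x 55).
#' @param floor_z depth of the cage floor from the camera (m, default 0.25).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(width = 640, height = 480,
                         fov_x_deg = 70, fov_y_deg = 55, floor_z = 0.25) {
  if (fov_x_deg <= 0 || fov_y_deg <= 0) stopf("field of view must be positive")
  structure(list(
    width = width, height = height,
    fov_x_deg = fov_x_deg, fov_y_deg = fov_y_deg,
    fx = (width / 2) / tan(fov_x_deg / 2 * pi / 180),
    fy = (height / 2) / tan(fov_y_deg / 2 * pi / 180),
    cx = (width + 1) / 2, cy = (height + 1) / 2,
    floor_z = floor_z
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, FOV %gx%g deg, floor at %g m\n",
              x$width, x$height, x$fov_x_deg, x$fov_y_deg, x$floor_z))
  invisible(x)
}

#' Back-project image pixels onto the cage floor
#'
#' Intersects each pixel's viewing ray with the constant-depth floor plane.
#'
#' @param camera a [camera_model()].
#' @param px pixel coordinates: length-2 vector `(u, v)` or `n x 2` matrix.
#'   Pixel centres are at integer coordinates `1..width` / `1..height`;
#'   coordinates outside the image (margins) are allowed.
#' @return floor positions (m): `n x 3` matrix (vector for a single pixel),
#'   with z equal to `floor_z`.
#' @export
pixel_to_floor <- function(camera, px) {
  px <- if (is.null(dim(px))) matrix(px, nrow = 1) else as.matrix(px)
  x <- (px[, 1] - camera$cx) / camera$fx * camera$floor_z
  y <- (px[, 2] - camera$cy) / camera$fy * camera$floor_z
  out <- cbind(x = x, y = y, z = camera$floor_z)
  if (nrow(out) == 1) out[1, ] else out
}

#' Project floor positions into the image
#'
#' Inverse of [pixel_to_floor()] for points on (or off) the floor plane.
#'
#' @param camera a [camera_model()].
#' @param xyz floor position(s) (m): length-3 vector or `n x 3` matrix.
#' @return pixel coordinates `(u, v)` (matrix for multiple points).
#' @export
floor_to_pixel <- function(camera, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, nrow = 1) else as.matrix(xyz)
  if (any(xyz[, 3] <= 0)) stopf("point behind the camera (z <= 0): cannot project")
  u <- camera$cx + camera$fx * xyz[, 1] / xyz[, 3]
  v <- camera$cy + camera$fy * xyz[, 2] / xyz[, 3]
  out <- cbind(u = u, v = v)
  if (nrow(out) == 1) out[1, ] else out
}

## angle (degrees) between directions to two points as seen from the array centroid
direction_angle_deg <- function(geometry, p1, p2) {
  v1 <- p1 - geometry$centroid
  v2 <- p2 - geometry$centroid
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
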