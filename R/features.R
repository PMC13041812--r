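#' Frame-wise kinematic and postural features
#'
#' Computes, per frame: maze zone, speed (cm/s), acceleration (cm/s^2),
#' horizontal movement (per-frame Euclidean centroid displacement, cm),
#' bounding-box area (cm^2), aspect ratio (height / width), its per-frame
#' change, and heading (degrees, angle of the centroid-to-head vector in
#' the maze frame, in [0, 360)).
#'
#' Edge rule: the first frame's speed, acceleration, horizontal movement
#' and d_aspect are copied from the first defined value so the table stays
#' rectangular with no NA propagation.
#'
#' @param track A [pose_track()].
#' @param geom A [maze_geometry()].
#' @return A data.frame of class `frame_features`, one row per frame.
#' @export
frame_features <- function(track, geom) {
  kin <- compute_kinematics(track)
  pose <- compute_pose_features(track)
  z <- zone_of(cbind(track$centroid_x, track$centroid_y), geom)
  out <- cbind(data.frame(time = track$time), z, kin, pose)
  class(out) <- c("frame_features", "data.frame")
  out
}

#' Speed, acceleration and horizontal movement from a pose track
#'
#' `horizontal_movement` is the per-frame Euclidean centroid displacement;
#' `speed` divides it by the frame interval; `acceleration` is the first
#' difference of speed over the interval. First-frame values are copied
#' from the first defined value (edge rule).
#'
#' @param track A [pose_track()] with at least 3 frames.
#' @return data.frame with columns `speed`, `acceleration`,
#'   `horizontal_movement`.
#' @export
compute_kinematics <- function(track) {
  if (nrow(track) < 3) stop("compute_kinematics() needs at least 3 frames")
  dt <- diff(track$time)
  if (any(dt == 0)) stop("duplicate timestamps in pose track")
  disp <- sqrt(diff(track$centroid_x)^2 + diff(track$centroid_y)^2)
  speed <- c(NA, disp / dt)
  speed[1] <- speed[2]
  acc <- c(NA, diff(speed) / dt)
  acc[1] <- acc[2]
  hm <- c(disp[1], disp)
  data.frame(speed = speed, acceleration = acc, horizontal_movement = hm)
}

#' Bounding-box and heading features from a pose track
#'
#' `bbox_area = width * height`; `aspect_ratio = height / width` (flagged
#' `NA` with a warning where the width is zero, never silently dropped);
#' `d_aspect` is the frame-to-frame aspect difference (edge rule as in
#' [compute_kinematics()]); `heading` is the angle of `head - centroid`.
#'
#' @param track A [pose_track()].
#' @return data.frame with columns `bbox_area`, `aspect_ratio`, `d_aspect`,
#'   `heading`.
#' @export
compute_pose_features <- function(track) {
  w <- track$bbox_width; h <- track$bbox_height
  if (any(w < 0) || any(h < 0)) stop("bounding-box dimensions must be >= 0")
  area <- w * h
  aspect <- rep(NA_real_, length(w))
  ok <- w > 0
  if (!all(ok))
    warning(sprintf("aspect ratio undefined for %d zero-width frames (flagged NA)",
                    sum(!ok)))
  aspect[ok] <- h[ok] / w[ok]
  da <- c(NA, diff(aspect))
  da[1] <- da[2]
  hx <- track$head_x - track$centroid_x
  hy <- track$head_y - track$centroid_y
  heading <- (atan2(hy, hx) * 180 / pi) %% 360
  data.frame(bbox_area = area, aspect_ratio = aspect, d_aspect = da,
             heading = heading)
}

#' Polar histogram of heading directions
#'
#' Bins headings into `n_bins` half-open bins `[k * 360/n, (k+1) * 360/n)`
#' and reports per-bin densities (fractions summing to 1). The default 32
#' bins give 11.25-degree bars.
#'
#' @param headings Headings in degrees (any real; reduced modulo 360).
#' @param n_bins Number of bins, at least 4 (default 32).
#' @return List of class `polar_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `bin_centers`, `counts` and `density`.
#' @export
heading_histogram <- function(headings, n_bins = 32) {
  if (length(headings) == 0) stop("heading_histogram() needs a non-empty input")
  if (n_bins < 4) stop("n_bins must be >= 4")
  h <- headings %% 360
  width <- 360 / n_bins
  idx <- pmin(floor(h / width), n_bins - 1) + 1
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    bin_edges = seq(0, 360, by = width),
    bin_centers = seq(width / 2, 360 - width / 2, by = width),
    counts = counts,
    density = counts / sum(counts)
  ), class = "polar_histogram")
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether headings are uniformly distributed on the circle.
#' `r` is the mean resultant length; the p-value uses the standard
#' second-order series approximation of the Rayleigh statistic
#' `Z = n r^2`.
#'
#' @param headings Headings in degrees, length >= 2.
#' @return List with `r` (in \[0, 1\]), `z`, `p` (clipped to (0, 1\]) and `n`.
#' @export
rayleigh_test <- function(headings) {
  n <- length(headings)
  if (n < 2) stop("rayleigh_test() needs at least 2 angles")
  a <- headings * pi / 180
  C <- sum(cos(a)); S <- sum(sin(a))
  r <- sqrt(C^2 + S^2) / n
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(r = r, z = z, p = p, n = n)
}

#' ECDF of horizontal movement within selected zones
#'
#' Restricts frame features to frames whose zone is in `zones` and returns
#' the empirical cumulative distribution function of
#' `horizontal_movement` (a right-continuous step function from 0 to 1).
#'
#' @param features A [frame_features()] table.
#' @param zones Character vector of zone labels (e.g.
#'   `c("open-proximal", "open-distal")`).
#' @return A stats [stats::ecdf()] function with attribute `n`.
#' @export
movement_ecdf <- function(features, zones) {
  sel <- features$zone %in% zones
  if (!any(sel))
    stop(sprintf("no frames in zones: %s", paste(zones, collapse = ", ")))
  f <- stats::ecdf(features$horizontal_movement[sel])
  attr(f, "n") <- sum(sel)
  f
}
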