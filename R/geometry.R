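#' Elevated plus maze geometry
#'
#' Describes the physical maze and the zone fractions used by the sequence
#' rules. The coordinate frame has its origin at the center of the central
#' platform, with one maze axis carrying the closed arms and the orthogonal
#' axis the open arms. Arms span from the edge of the central square
#' (`center_side / 2`) to `center_side / 2 + arm_length`; the
#' proximal/distal split sits at `proximal_fraction` of the arm length and
#' the sequence stop threshold at `stop_threshold_fraction`.
#'
#' @param arm_length Arm length in cm (default 27.8).
#' @param center_side Side of the central square platform in cm (default 7.8).
#' @param closed_axis Which axis carries the closed arms, `"y"` or `"x"`.
#' @param start_zone_fraction Distal fraction of a closed arm that counts as
#'   a sequence start zone (default 0.5).
#' @param proximal_fraction Proximal fraction of an open arm defining the
#'   risk-assessment region (default 0.5).
#' @param stop_threshold_fraction Fraction of arm length an animal must
#'   cross into a non-originating arm to terminate a sequence (default 0.5;
#'   ties at the threshold count as crossed).
#' @return An object of class `maze_geometry`.
#' @examples
#' geom <- maze_geometry()
#' zone_of(cbind(0, 0), geom)       # center
#' zone_of(cbind(0, 20), geom)      # closed-distal
#' @export
maze_geometry <- function(arm_length = 27.8, center_side = 7.8,
                          closed_axis = c("y", "x"),
                          start_zone_fraction = 0.5,
                          proximal_fraction = 0.5,
                          stop_threshold_fraction = 0.5) {
  closed_axis <- match.arg(closed_axis)
  stopifnot(arm_length > 0, center_side > 0)
  fr <- c(start_zone_fraction, proximal_fraction, stop_threshold_fraction)
  if (any(fr <= 0) || any(fr > 1))
    stop("zone fractions must lie in (0, 1]")
  structure(list(
    arm_length = arm_length,
    center_side = center_side,
    closed_axis = closed_axis,
    start_zone_fraction = start_zone_fraction,
    proximal_fraction = proximal_fraction,
    stop_threshold_fraction = stop_threshold_fraction
  ), class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf(
    "EPM geometry: arms %.1f cm, center %.1f x %.1f cm, closed arms on %s axis\n",
    x$arm_length, x$center_side, x$center_side, x$closed_axis))
  cat(sprintf("  arm span %.1f-%.1f cm from origin; distal/stop threshold at %.1f cm\n",
              arm_inner(x), arm_outer(x), arm_threshold(x)))
  invisible(x)
}

# distances from the maze origin along an arm axis
arm_inner <- function(geom) geom$center_side / 2
arm_outer <- function(geom) geom$center_side / 2 + geom$arm_length
arm_threshold <- function(geom, fraction = geom$stop_threshold_fraction) {
  arm_inner(geom) + fraction * geom$arm_length
}

#' Arm identifiers
#'
#' Arms are identified as `"closed+"`, `"closed-"`, `"open+"`, `"open-"`,
#' the sign giving the direction along the carrying axis.
#'
#' @param geom A [maze_geometry()].
#' @return Character vector of the four arm ids.
#' @export
arm_ids <- function(geom) c("closed+", "closed-", "open+", "open-")

# signed coordinate along an arm's axis for a matrix of points
arm_axis_coord <- function(xy, arm, geom) {
  axis_is_y <- (substr(arm, 1, 6) == "closed") == (geom$closed_axis == "y")
  s <- if (substr(arm, nchar(arm), nchar(arm)) == "+") 1 else -1
  s * (if (axis_is_y) xy[, 2] else xy[, 1])
}

#' Assign maze zones to points
#'
#' Partitions the maze footprint into the central platform, and
#' proximal/distal halves of each arm. Every in-maze point receives exactly
#' one label; points outside the footprint are labeled `"off-maze"`.
#'
#' @param xy Numeric matrix (or 2-vector) of x, y coordinates in cm.
#' @param geom A [maze_geometry()].
#' @return A data.frame with columns `zone` (one of `center`,
#'   `closed-proximal`, `closed-distal`, `open-proximal`, `open-distal`,
#'   `off-maze`) and `arm` (arm id or `NA`).
#' @export
zone_of <- function(xy, geom) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must have two columns")
  if (any(!is.finite(xy))) stop("non-finite coordinates in zone_of()")
  half <- geom$center_side / 2
  inner <- arm_inner(geom)
  outer <- arm_outer(geom)
  x <- xy[, 1]; y <- xy[, 2]
  zone <- rep("off-maze", nrow(xy))
  arm <- rep(NA_character_, nrow(xy))

  in_center <- abs(x) <= half & abs(y) <= half
  zone[in_center] <- "center"

  # arm membership: along-axis coordinate in (inner, outer], cross-axis within half width
  for (a in arm_ids(geom)) {
    d <- arm_axis_coord(xy, a, geom)
    cross <- if ((substr(a, 1, 6) == "closed") == (geom$closed_axis == "y"))
      abs(x) else abs(y)
    in_arm <- !in_center & d > inner & d <= outer & cross <= half
    if (!any(in_arm)) next
    kind <- substr(a, 1, nchar(a) - 1)
    thr <- arm_threshold(geom, if (kind == "closed")
      geom$start_zone_fraction else geom$proximal_fraction)
    # distal begins at the threshold; ties count as distal ("crossing >= 50%")
    zone[in_arm] <- ifelse(d[in_arm] >= thr,
                           paste0(kind, "-distal"), paste0(kind, "-proximal"))
    arm[in_arm] <- a
  }
  data.frame(zone = zone, arm = arm, stringsAsFactors = FALSE)
}

# unit vector pointing from an arm toward the maze center
arm_to_center_direction <- function(arm, geom) {
  axis_is_y <- (substr(arm, 1, 6) == "closed") == (geom$closed_axis == "y")
  s <- if (substr(arm, nchar(arm), nchar(arm)) == "+") -1 else 1
  if (axis_is_y) c(0, s) else c(s, 0)
}
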