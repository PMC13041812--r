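#' Construct a pose track
#'
#' A pose track is a frame-indexed table of keypoints (centroid, head,
#' tail base) and bounding-box dimensions, all in maze-frame cm.
#'
#' @param time Frame timestamps in seconds, strictly increasing.
#' @param centroid,head,tailbase Two-column matrices of x, y positions (cm).
#' @param bbox_width,bbox_height Bounding-box dimensions (cm); the height is
#'   the along-body extent so `aspect = height / width`.
#' @return A data.frame of class `pose_track` with columns `time`,
#'   `centroid_x/y`, `head_x/y`, `tailbase_x/y`, `bbox_width`, `bbox_height`.
#' @export
pose_track <- function(time, centroid, head, tailbase,
                       bbox_width, bbox_height) {
  n <- length(time)
  if (n < 1) stop("empty pose track")
  if (any(diff(time) <= 0)) stop("pose track times must be strictly increasing")
  centroid <- as.matrix(centroid); head <- as.matrix(head)
  tailbase <- as.matrix(tailbase)
  if (any(!is.finite(centroid)) || any(!is.finite(head)) ||
      any(!is.finite(tailbase)))
    stop("pose track coordinates must be finite")
  out <- data.frame(
    time = time,
    centroid_x = centroid[, 1], centroid_y = centroid[, 2],
    head_x = head[, 1], head_y = head[, 2],
    tailbase_x = tailbase[, 1], tailbase_y = tailbase[, 2],
    bbox_width = rep_len(bbox_width, n),
    bbox_height = rep_len(bbox_height, n)
  )
  class(out) <- c("pose_track", "data.frame")
  out
}

track_rate <- function(track) 1 / stats::median(diff(track$time))

#' Read a pose-tracking CSV
#'
#' Reads a wide per-frame keypoint table. Two dialects are supported:
#' `"wide"` expects one header row with columns `<keypoint>_x`,
#' `<keypoint>_y` and optional `<keypoint>_likelihood`; `"dlc"` expects the
#' DeepLabCut-style three-row header (scorer / bodyparts / coords). Frames
#' are 0-based; times come from a `time` column when present, otherwise
#' `frame / fps`. Keypoint samples whose likelihood falls below
#' `likelihood_min` are linearly interpolated.
#'
#' Pixel-to-cm calibration: if `calibration` is given as a list with
#' `points` (2 x 2 matrix, the two opposite arm ends in pixel coordinates)
#' and `span_cm` (their true separation, default `2 * arm + center`), input
#' coordinates are centered on the midpoint and scaled accordingly.
#'
#' @param path CSV path.
#' @param fps Video frame rate (frames/s), used when no time column exists.
#' @param dialect `"wide"` or `"dlc"`.
#' @param likelihood_min Keypoints below this tracking likelihood are
#'   interpolated (default 0.6).
#' @param calibration Optional 2-point pixel calibration (see Details).
#' @return A [pose_track()].
#' @export
read_pose_csv <- function(path, fps = 30, dialect = c("wide", "dlc"),
                          likelihood_min = 0.6, calibration = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- utils::read.csv(path, check.names = FALSE)
  } else {
    hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                           check.names = FALSE)
    df <- utils::read.csv(path, header = FALSE, skip = 3,
                          check.names = FALSE)
    nm <- paste(as.character(unlist(hdr[2, ])),
                as.character(unlist(hdr[3, ])), sep = "_")
    nm[1] <- "frame"
    names(df) <- nm
  }
  get_kp <- function(kp) {
    xs <- df[[paste0(kp, "_x")]]; ys <- df[[paste0(kp, "_y")]]
    if (is.null(xs) || is.null(ys))
      stop(sprintf("keypoint '%s' not found in %s", kp, path))
    lk <- df[[paste0(kp, "_likelihood")]]
    if (!is.null(lk)) {
      bad <- !is.na(lk) & lk < likelihood_min
      xs <- interp_bad(xs, bad); ys <- interp_bad(ys, bad)
    }
    cbind(xs, ys)
  }
  cen <- get_kp("centroid"); hd <- get_kp("head"); tb <- get_kp("tailbase")
  if (!is.null(calibration)) {
    pts <- as.matrix(calibration$points)
    span_px <- sqrt(sum((pts[2, ] - pts[1, ])^2))
    span_cm <- calibration$span_cm %||% NA_real_
    if (!is.finite(span_cm)) stop("calibration$span_cm is required")
    scale <- span_cm / span_px
    mid <- colMeans(pts)
    conv <- function(m) sweep(m, 2, mid) * scale
    cen <- conv(cen); hd <- conv(hd); tb <- conv(tb)
  }
  time <- df[["time"]]
  if (is.null(time)) {
    fr <- df[["frame"]] %||% (seq_len(nrow(df)) - 1)
    time <- fr / fps
  }
  w <- df[["bbox_width"]] %||% abs(cen[, 1] - hd[, 1]) + 1
  h <- df[["bbox_height"]] %||% sqrt(rowSums((hd - tb)^2))
  pose_track(time, cen, hd, tb, w, h)
}

#' Write a pose track as CSV (wide dialect)
#' @param track A [pose_track()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path) {
  df <- as.data.frame(track)
  df <- cbind(frame = seq_len(nrow(df)) - 1L, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear interpolation over flagged samples; endpoints carried
interp_bad <- function(x, bad) {
  if (!any(bad)) return(x)
  if (all(bad)) stop("all samples below likelihood threshold")
  idx <- seq_along(x)
  stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
}
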