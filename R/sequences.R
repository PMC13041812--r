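#' Sequence type levels, in increasing order of risk commitment
#' @export
sequence_types <- function() c("CC", "NoGo", "Go", "CO")

#' Segment a session into risk-ranked behavioral sequences
#'
#' A sequence opens at the first frame in a closed-arm distal zone
#' (sequence start zone) whose heading lies within +/-90 degrees of the
#' arm-to-center direction AND whose centroid velocity component toward
#' the center is positive, with both conditions sustained for at least
#' `min_gate_frames` consecutive frames (jitter suppression). It closes at
#' the first frame at or past the stop-threshold fraction of a
#' non-originating arm (ties count as crossed). Risk-assessment events
#' falling inside the open interval and located in the proximal open arm
#' are attached; events elsewhere are ignored for classification with a
#' warning. Sequences left unresolved at session end are dropped and
#' logged. Excursions originating in an open arm are outside the
#' closed-origin taxonomy and are never opened.
#'
#' @param features A [frame_features()] table.
#' @param events An [event_table()] sharing the session time base.
#' @param geom A [maze_geometry()].
#' @param min_gate_frames Consecutive frames the orientation gate must hold
#'   (default 3, i.e. 0.1 s at 30 fps).
#' @return A data.frame of class `sequence_list`: one row per sequence with
#'   columns `type`, `origin_arm`, `terminal_arm`, `t_start`, `t_center`,
#'   `t_first_risk`, `t_stop`, `duration`, `n_risk_events`. Attribute
#'   `log` records dropped/ignored items.
#' @export
detect_sequences <- function(features, events, geom, min_gate_frames = 3) {
  t <- features$time
  n <- length(t)
  if (nrow(events) > 0 &&
      (min(events$time) < t[1] - 1e-9 || max(events$time) > t[n] + 1e-9))
    stop("events fall outside the session time span")
  risk_t <- events$time[events$behavior == "risk_assessment"]

  xy <- cbind(features_centroid_x(features), features_centroid_y(features))
  vx <- c(diff(xy[, 1]), 0); vy <- c(diff(xy[, 2]), 0)

  # per-frame gate: in closed-distal, heading and velocity toward center
  gate <- logical(n)
  closed_distal <- features$zone == "closed-distal"
  for (a in c("closed+", "closed-")) {
    sel <- closed_distal & !is.na(features$arm) & features$arm == a
    if (!any(sel)) next
    dir <- arm_to_center_direction(a, geom)
    hx <- cos(features$heading[sel] * pi / 180)
    hy <- sin(features$heading[sel] * pi / 180)
    head_ok <- (hx * dir[1] + hy * dir[2]) > 0       # within +/-90 deg
    vel_ok <- (vx[sel] * dir[1] + vy[sel] * dir[2]) > 0
    gate[sel] <- head_ok & vel_ok
  }
  gate[is.na(features$zone) | features$zone == "off-maze"] <- FALSE

  sustained <- run_at_least(gate, min_gate_frames)

  log <- character()
  rows <- list()
  i <- 1
  while (i <= n) {
    if (!sustained[i]) { i <- i + 1; next }
    origin <- features$arm[i]
    t_start <- t[i]
    # find stop: first frame at/past threshold of a non-originating arm
    j <- i + 1
    t_stop <- NA_real_; terminal <- NA_character_; t_center <- NA_real_
    while (j <= n) {
      if (is.na(t_center) && features$zone[j] == "center") t_center <- t[j]
      zj <- features$zone[j]; aj <- features$arm[j]
      if (!is.na(aj) && aj != origin &&
          zj %in% c("closed-distal", "open-distal")) {
        # distal zones begin exactly at the 50% threshold
        d <- arm_axis_coord(xy[j, , drop = FALSE], aj, geom)
        if (d >= arm_threshold(geom)) {
          t_stop <- t[j]; terminal <- aj
          break
        }
      }
      j <- j + 1
    }
    if (is.na(t_stop)) {
      log <- c(log, sprintf(
        "sequence opened at %.2f s unresolved at session end; dropped", t_start))
      break
    }
    rk <- risk_t[risk_t >= t_start & risk_t < t_stop]
    # only risk events located in the proximal open arm count
    if (length(rk) > 0) {
      zi <- vapply(rk, function(tt) {
        k <- findInterval(tt, t)
        features$zone[max(k, 1)]
      }, character(1))
      bad <- zi != "open-proximal"
      if (any(bad)) {
        warning(sprintf(
          "%d risk-assessment event(s) outside the proximal open arm ignored",
          sum(bad)))
        rk <- rk[!bad]
      }
    }
    type <- classify_sequence(terminal_arm = terminal, n_risk = length(rk))
    rows[[length(rows) + 1]] <- data.frame(
      type = type, origin_arm = origin, terminal_arm = terminal,
      t_start = t_start, t_center = t_center,
      t_first_risk = if (length(rk) > 0) min(rk) else NA_real_,
      t_stop = t_stop, duration = t_stop - t_start,
      n_risk_events = length(rk), stringsAsFactors = FALSE)
    i <- j + 1
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(type = character(), origin_arm = character(),
               terminal_arm = character(), t_start = numeric(),
               t_center = numeric(), t_first_risk = numeric(),
               t_stop = numeric(), duration = numeric(),
               n_risk_events = integer())
  attr(out, "log") <- log
  class(out) <- c("sequence_list", "data.frame")
  out
}

# helpers to fetch centroid columns whether features carries them or not
features_centroid_x <- function(f) f[["centroid_x"]] %||% f[["x"]]
features_centroid_y <- function(f) f[["centroid_y"]] %||% f[["y"]]

# TRUE where x starts a run of >= k consecutive TRUEs (marked at run start)
run_at_least <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  r <- rle(x)
  out <- logical(n)
  pos <- cumsum(c(1, r$lengths))
  for (m in seq_along(r$lengths))
    if (r$values[m] && r$lengths[m] >= k) out[pos[m]] <- TRUE
  out
}

#' Classify a terminated sequence
#'
#' Rule table: terminal closed arm without risk event -> `CC`; terminal
#' closed with >= 1 risk event -> `NoGo`; terminal open with >= 1 risk
#' event -> `Go`; terminal open without risk event -> `CO`. The 2 x 2
#' table is exhaustive.
#'
#' @param terminal_arm Arm id the sequence terminated in.
#' @param n_risk Number of attached risk-assessment events.
#' @return One of `"CC"`, `"NoGo"`, `"Go"`, `"CO"`.
#' @export
classify_sequence <- function(terminal_arm, n_risk) {
  if (is.na(terminal_arm)) stop("sequence has no terminal arm")
  closed <- substr(terminal_arm, 1, 6) == "closed"
  if (closed && n_risk == 0) "CC"
  else if (closed) "NoGo"
  else if (n_risk > 0) "Go"
  else "CO"
}

#' Per-sequence duration, speed and posture metrics
#'
#' Averages frame features over the half-open interval
#' `[t_start, t_stop)` of each sequence.
#'
#' @param sequences A `sequence_list` from [detect_sequences()].
#' @param features The matching [frame_features()] table.
#' @return data.frame with `type`, `duration`, `mean_speed`,
#'   `mean_aspect_ratio`, one row per sequence.
#' @export
sequence_metrics <- function(sequences, features) {
  if (nrow(sequences) == 0)
    return(data.frame(type = character(), duration = numeric(),
                      mean_speed = numeric(), mean_aspect_ratio = numeric()))
  out <- lapply(seq_len(nrow(sequences)), function(i) {
    s <- sequences[i, ]
    sel <- features$time >= s$t_start & features$time < s$t_stop
    if (!any(sel))
      stop(sprintf("sequence %d has no frames in [%.2f, %.2f)",
                   i, s$t_start, s$t_stop))
    data.frame(type = s$type, duration = s$t_stop - s$t_start,
               mean_speed = mean(features$speed[sel]),
               mean_aspect_ratio = mean(features$aspect_ratio[sel],
                                        na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Sequence counts by type
#'
#' @param sequences A `sequence_list` (or any data.frame with a `type`
#'   column).
#' @return Named integer vector over exactly the four types
#'   (`CC`, `NoGo`, `Go`, `CO`); absent types report 0.
#' @export
counts_by_type <- function(sequences) {
  tys <- sequence_types()
  cnt <- table(factor(sequences$type, levels = tys))
  stats::setNames(as.integer(cnt), tys)
}

#' Risk assessment index
#'
#' The proportion of sequences involving risk assessment (NoGo + Go)
#' relative to the total sequence count.
#'
#' @param sequences A `sequence_list`, or a named count vector as returned
#'   by [counts_by_type()].
#' @return A fraction in \[0, 1\].
#' @export
risk_assessment_index <- function(sequences) {
  cnt <- if (is.numeric(sequences)) {
    miss <- setdiff(sequence_types(), names(sequences))
    c(sequences, stats::setNames(rep(0, length(miss)), miss))
  } else counts_by_type(sequences)
  total <- sum(cnt)
  if (total == 0)
    stop("no sequences detected: risk assessment index undefined ",
         "(empty sequence table, not an I/O failure)")
  unname((cnt[["NoGo"]] + cnt[["Go"]]) / total)
}

#' Write a tidy sequence-table CSV
#' @param sequences A `sequence_list`.
#' @param path Output path.
#' @param animal Animal id column value.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(sequences, path, animal = "animal1") {
  utils::write.csv(cbind(animal = animal, as.data.frame(sequences)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy sequence-table CSV
#' @param path CSV path.
#' @return `sequence_list` data.frame (with `animal` column if present).
#' @export
read_sequence_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("sequence_list", "data.frame")
  out
}
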