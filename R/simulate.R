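#' Simulation configuration
#'
#' Defines a scripted synthetic EPM session: a 10-min session at 30 fps by
#' default, with interleaved two-channel photometry at 40 samples/s per
#' channel, and an ordered script of sequence bouts. All randomness is
#' governed by `seed`.
#'
#' Default photometry effect amplitudes follow the observed ordering of
#' peri-event calcium dynamics across sequence types: closed-to-closed
#' elevated post-event, NoGo intermediate, Go suppressed. Amplitudes are
#' expressed as fractional dF/F deflections relative to the baseline
#' fluorescence, scaled so that after session z-scoring they land near the
#' stated z-unit targets for the default noise level.
#'
#' @param session_duration Session length, seconds (default 600).
#' @param video_rate Video frame rate, frames/s (default 30).
#' @param photometry_rate Per-channel photometry sampling rate, frames/s
#'   (default 40).
#' @param sequence_script data.frame with columns `type` (one of
#'   `CC`, `NoGo`, `Go`, `CO`) and `start` (s), strictly increasing and
#'   separated by more than the scripted bout duration; or `NULL` for an
#'   idle session.
#' @param n_risk_events_per_sequence Risk-assessment point events emitted
#'   per NoGo/Go bout (default 2).
#' @param effect_amplitudes Named numeric map type -> peri-event deflection
#'   in nominal z units (defaults `CC = 1, NoGo = 0.4, Go = -0.8, CO = 0`).
#' @param transient_tau_rise,transient_tau_decay Calcium transient rise and
#'   decay time constants, s (defaults 0.1 and 1.0).
#' @param artifact_amplitude Shared multiplicative motion-artifact
#'   amplitude as a fraction of baseline (default 0.05).
#' @param bleach_tau Photobleaching exponential time constant, s
#'   (default 2000).
#' @param noise_sd Additive fluorescence noise SD, raw units
#'   (default 1.5 on a 200-unit baseline).
#' @param seed Integer seed; fully determines all outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(session_duration = 600, video_rate = 30,
                       photometry_rate = 40, sequence_script = NULL,
                       n_risk_events_per_sequence = 2,
                       effect_amplitudes = c(CC = 1, NoGo = 0.4,
                                             Go = -0.8, CO = 0),
                       transient_tau_rise = 0.1, transient_tau_decay = 1,
                       artifact_amplitude = 0.05, bleach_tau = 2000,
                       noise_sd = 1.5, seed = 1) {
  if (session_duration <= 0) stop("session_duration must be > 0")
  if (video_rate <= 0 || photometry_rate <= 0)
    stop("sampling rates must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(sequence_script)) {
    if (!all(sequence_script$type %in% sequence_types()))
      stop("unknown sequence type(s) in script")
    if (any(diff(sequence_script$start) <= 0))
      stop("scripted starts must be strictly increasing")
  }
  structure(list(
    session_duration = session_duration, video_rate = video_rate,
    photometry_rate = photometry_rate, sequence_script = sequence_script,
    n_risk_events_per_sequence = n_risk_events_per_sequence,
    effect_amplitudes = effect_amplitudes,
    transient_tau_rise = transient_tau_rise,
    transient_tau_decay = transient_tau_decay,
    artifact_amplitude = artifact_amplitude, bleach_tau = bleach_tau,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build a random sequence script
#'
#' Draws `n_bouts` types (uniform over the requested types) at evenly
#' spaced starts with enough separation for the longest bout.
#'
#' @param n_bouts Number of bouts.
#' @param types Types to draw from (default all four).
#' @param first_start First bout start, s (default 20).
#' @param spacing Start-to-start spacing, s (default 25; bouts last < 20 s).
#' @param seed Integer seed.
#' @return data.frame with columns `type`, `start`.
#' @export
random_script <- function(n_bouts, types = sequence_types(),
                          first_start = 20, spacing = 25, seed = 1) {
  local_seed(seed)
  data.frame(type = sample(types, n_bouts, replace = TRUE),
             start = first_start + spacing * (seq_len(n_bouts) - 1))
}

# run code under a temporary RNG state, restoring the caller's state
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (is.null(old))
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  else bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# ---- trajectory ------------------------------------------------------------

# waypoint schedule for one bout; origin/other alternate between closed arms.
# Returns list(waypoints = data.frame(t, x, y, pause), truth = list(...))
bout_plan <- function(type, t0, origin, geom, n_risk, risk_dwell = 0.6) {
  dirc <- arm_to_center_direction(origin, geom)       # toward center
  other <- if (origin == "closed+") "closed-" else "closed+"
  open_arm <- "open+"
  inner <- arm_inner(geom); thr <- arm_threshold(geom)
  idle_d <- (thr + arm_outer(geom)) / 2                # mid-distal
  pt <- function(arm, d) {
    dir <- -arm_to_center_direction(arm, geom)         # center -> arm
    c(dir[1], dir[2]) * d
  }
  speed <- 12                                          # cm/s, cruising
  wp <- list(list(t = t0, p = pt(origin, idle_d), pause = 0))
  add <- function(p, pause = 0) {
    last <- wp[[length(wp)]]
    dt <- sqrt(sum((p - last$p)^2)) / speed + last$pause
    wp[[length(wp) + 1]] <<- list(t = last$t + dt, p = p, pause = pause)
  }
  add(c(0, 0))                                         # center
  risk_times <- numeric(0)
  if (type %in% c("NoGo", "Go")) {
    ra_pt <- pt(open_arm, (inner + thr) / 2)           # mid open-proximal
    add(ra_pt, pause = n_risk * risk_dwell)
    risk_times <- wp[[length(wp)]]$t + risk_dwell * (seq_len(n_risk) - 1)
  }
  terminal <- switch(type, CC = other, NoGo = other, Go = open_arm,
                     CO = open_arm)
  if (type %in% c("NoGo")) add(c(0, 0))                # back through center
  add(pt(terminal, thr + 1.5))                         # just past threshold
  add(pt(terminal, idle_d))                            # settle distal
  # open-arm terminals: walk back to a closed arm to idle
  end_arm <- terminal
  if (substr(terminal, 1, 4) == "open") {
    add(c(0, 0)); add(pt(other, idle_d))
    end_arm <- other
  }
  tw <- vapply(wp, `[[`, numeric(1), "t")
  px <- vapply(wp, function(w) w$p[1], numeric(1))
  py <- vapply(wp, function(w) w$p[2], numeric(1))
  pause <- vapply(wp, `[[`, numeric(1), "pause")
  list(waypoints = data.frame(t = tw, x = px, y = py, pause = pause),
       t_end = tw[length(tw)], end_arm = end_arm,
       truth = list(type = type, t_start = t0,
                    t_center = NA_real_,  # filled after interpolation
                    t_first_risk = if (length(risk_times)) risk_times[1]
                                   else NA_real_,
                    risk_times = risk_times))
}

#' Simulate a scripted EPM trajectory
#'
#' Generates a pose track realizing each scripted bout (start in a distal
#' closed-arm zone moving toward center; NoGo/Go pause in the proximal
#' open arm and emit risk-assessment point events at pause onsets; Go/CO
#' end past the stop threshold of an open arm; CC/NoGo past the threshold
#' of the opposite closed arm), idling in a closed arm between bouts with
#' the heading turned away from the center. Kinematics are
#' piecewise-constant-speed segments between zone waypoints with small
#' Gaussian tracking jitter (SD `jitter_sd` cm).
#'
#' @param config A [sim_config()].
#' @param geom A [maze_geometry()].
#' @param jitter_sd Tracking jitter SD in cm (default 0.1).
#' @return List with elements `track` ([pose_track()]), `events`
#'   ([event_table()]), and `truth` (data.frame of scripted bouts with
#'   `type`, `t_start`, `t_center`, `t_first_risk`, `t_stop`).
#' @export
simulate_trajectory <- function(config, geom = maze_geometry(),
                                jitter_sd = 0.1) {
  local_seed(config$seed)
  fps <- config$video_rate
  time <- seq(0, config$session_duration - 1 / fps, by = 1 / fps)
  n <- length(time)
  idle_d <- (arm_threshold(geom) + arm_outer(geom)) / 2

  script <- config$sequence_script
  origin <- "closed+"
  plans <- list()
  if (!is.null(script) && nrow(script) > 0) {
    t_prev_end <- -Inf
    for (b in seq_len(nrow(script))) {
      pl <- bout_plan(script$type[b], script$start[b], origin, geom,
                      config$n_risk_events_per_sequence)
      if (script$start[b] <= t_prev_end)
        stop(sprintf("scripted bout %d overlaps the previous bout", b))
      if (pl$t_end > config$session_duration)
        stop(sprintf("scripted bout %d runs past the session end", b))
      plans[[b]] <- pl
      origin <- pl$end_arm
      t_prev_end <- pl$t_end
    }
  }

  # assemble the full waypoint path: idle -> bout -> idle ...
  start_pos <- function(arm) -arm_to_center_direction(arm, geom) * idle_d
  path_t <- 0; p0 <- start_pos("closed+")
  path_x <- p0[1]; path_y <- p0[2]
  for (pl in plans) {
    w <- pl$waypoints
    # hold position until the bout starts
    path_t <- c(path_t, w$t[1]); path_x <- c(path_x, w$x[1])
    path_y <- c(path_y, w$y[1])
    # expand pauses into hold segments
    for (k in seq_len(nrow(w))[-1]) {
      path_t <- c(path_t, w$t[k]); path_x <- c(path_x, w$x[k])
      path_y <- c(path_y, w$y[k])
      if (w$pause[k] > 0) {
        path_t <- c(path_t, w$t[k] + w$pause[k])
        path_x <- c(path_x, w$x[k]); path_y <- c(path_y, w$y[k])
      }
    }
  }
  end_t <- config$session_duration
  path_t <- c(path_t, end_t)
  path_x <- c(path_x, path_x[length(path_x)])
  path_y <- c(path_y, path_y[length(path_y)])

  cx <- stats::approx(path_t, path_x, xout = time, rule = 2)$y
  cy <- stats::approx(path_t, path_y, xout = time, rule = 2)$y

  # heading along motion; when idle, face away from center (into the arm)
  dx <- c(diff(cx), 0); dy <- c(diff(cy), 0)
  moving <- sqrt(dx^2 + dy^2) > 1e-6
  hx <- numeric(n); hy <- numeric(n)
  hx[moving] <- dx[moving]; hy[moving] <- dy[moving]
  away <- cbind(sign(cx), sign(cy))
  idle_axis_y <- abs(cy) >= abs(cx)
  hx[!moving] <- ifelse(idle_axis_y[!moving], 0, away[!moving, 1])
  hy[!moving] <- ifelse(idle_axis_y[!moving], away[!moving, 2], 0)
  nrm <- pmax(sqrt(hx^2 + hy^2), 1e-9)
  body <- 2.0                                       # centroid-to-head, cm
  head <- cbind(cx + body * hx / nrm, cy + body * hy / nrm)
  tail <- cbind(cx - 1.5 * body * hx / nrm, cy - 1.5 * body * hy / nrm)

  cen <- cbind(cx, cy) + matrix(stats::rnorm(2 * n, 0, jitter_sd), n)
  head <- head + matrix(stats::rnorm(2 * n, 0, jitter_sd / 2), n)
  tail <- tail + matrix(stats::rnorm(2 * n, 0, jitter_sd / 2), n)

  # posture: stretched (higher aspect) during risk-assessment pauses
  bw <- rep(2.8, n); bh <- rep(5.5, n)
  events_t <- numeric(0)
  truth_rows <- list()
  for (pl in plans) {
    if (length(pl$truth$risk_times) > 0) {
      events_t <- c(events_t, pl$truth$risk_times)
      for (rt in pl$truth$risk_times)
        bh[time >= rt & time < rt + 0.5] <- 7.5
    }
    # ground-truth center crossing / stop from the noise-free path
    w <- pl$waypoints
    tt <- seq(w$t[1], pl$t_end, by = 1 / (4 * fps))
    px <- stats::approx(path_t, path_x, xout = tt, rule = 2)$y
    py <- stats::approx(path_t, path_y, xout = tt, rule = 2)$y
    z <- zone_of(cbind(px, py), geom)
    t_center <- tt[match("center", z$zone)]
    origin0 <- z$arm[1]
    stop_idx <- which(z$zone %in% c("closed-distal", "open-distal") &
                        z$arm != origin0 & !is.na(z$arm))
    t_stop <- if (length(stop_idx)) tt[min(stop_idx)] else NA_real_
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      type = pl$truth$type, t_start = pl$truth$t_start,
      t_center = t_center, t_first_risk = pl$truth$t_first_risk,
      t_stop = t_stop)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(type = character(), t_start = numeric(),
               t_center = numeric(), t_first_risk = numeric(),
               t_stop = numeric())

  track <- pose_track(time, cen, head, tail, bw, bh)
  events <- event_table(events_t, rep("risk_assessment", length(events_t)),
                        source = "simulated")
  list(track = track, events = events, truth = truth)
}

# ---- photometry ------------------------------------------------------------

# double-exponential calcium transient kernel, peak-normalized
transient_kernel <- function(t, tau_rise, tau_decay) {
  k <- (1 - exp(-pmax(t, 0) / tau_rise)) * exp(-pmax(t, 0) / tau_decay)
  k[t < 0] <- 0
  tp <- tau_rise * log1p(tau_decay / tau_rise)
  kmax <- (1 - exp(-tp / tau_rise)) * exp(-tp / tau_decay)
  k / kmax
}

#' Simulate an interleaved two-channel photometry session
#'
#' Emits one record stream with a channel flag: a 470-like signal channel
#' carrying calcium transients time-locked to each scripted bout's
#' alignment event (center crossing for CC/CO, first risk assessment for
#' NoGo/Go) with per-type amplitudes, and a 415-like isosbestic reference
#' without transients. Both channels share a single-exponential bleach
#' trend and a multiplicative motion artifact (smoothed Gaussian random
#' walk); independent Gaussian noise is added per channel. Fully
#' reproducible given the config seed.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth bout table from [simulate_trajectory()].
#' @param baseline_470,baseline_415 Baseline fluorescence, raw units.
#' @return List of class `photometry_session`: `records` (data.frame
#'   `frame_counter`, `time`, `channel`, `fluor`), `rate` (per-channel),
#'   `artifact` (shared artifact series at the signal-channel times),
#'   `clean_dff` (noise-free fractional transient component, for ground
#'   truth), and metadata fields `animal`, `hemisphere`.
#' @export
simulate_photometry <- function(config, truth,
                                baseline_470 = 200, baseline_415 = 150,
                                animal = "animal1", hemisphere = "left") {
  if (config$noise_sd < 0) stop("noise_sd must be >= 0")
  if (nrow(truth) > 0) {
    anchors <- anchor_times(truth)
    if (any(stats::na.omit(anchors) > config$session_duration))
      stop("ground-truth timestamps fall outside the session")
  }
  local_seed(config$seed + 104729L)   # distinct stream from the trajectory
  fs <- config$photometry_rate
  n <- floor(config$session_duration * fs)
  t470 <- (seq_len(n) - 1) / fs
  t415 <- t470 + 1 / (2 * fs)         # interleaved half-frame offset

  # shared multiplicative artifact: smoothed Gaussian random walk,
  # normalized to unit SD then scaled by artifact_amplitude
  art <- cumsum(stats::rnorm(n))
  art <- gaussian_smooth(art, sigma = fs / 2)
  if (stats::sd(art) > 0) art <- (art - mean(art)) / stats::sd(art)
  artifact <- 1 + config$artifact_amplitude * art

  bleach <- exp(-t470 / config$bleach_tau)

  # per-type transients at alignment anchors; amplitudes are nominal z
  # units converted to fractional dF/F via the expected session dF/F SD
  dff_sd <- nominal_dff_sd(config, baseline_470)
  clean <- numeric(n)
  if (nrow(truth) > 0) {
    amps <- config$effect_amplitudes
    anchors <- anchor_times(truth)
    for (b in seq_len(nrow(truth))) {
      a <- anchors[b]
      if (is.na(a)) next
      amp <- amps[[truth$type[b]]] %||% 0
      clean <- clean + amp * dff_sd *
        transient_kernel(t470 - a, config$transient_tau_rise,
                         config$transient_tau_decay)
    }
  }

  f470 <- baseline_470 * bleach * artifact * (1 + clean) +
    stats::rnorm(n, 0, config$noise_sd)
  f415 <- baseline_415 * bleach * artifact +
    stats::rnorm(n, 0, config$noise_sd)

  records <- data.frame(
    frame_counter = seq_len(2L * n),
    time = as.vector(rbind(t470, t415)),
    channel = rep(c("signal_470", "reference_415"), times = n),
    fluor = as.vector(rbind(f470, f415)))
  structure(list(records = records, rate = fs, artifact = artifact,
                 clean_dff = clean, animal = animal,
                 hemisphere = hemisphere),
            class = "photometry_session")
}

# alignment anchor per bout: first risk assessment for NoGo/Go, center
# crossing otherwise
anchor_times <- function(truth) {
  ifelse(truth$type %in% c("NoGo", "Go"), truth$t_first_risk,
         truth$t_center)
}

# expected session dF/F SD for the default generator: the additive noise
# propagated through dF/F plus the 10-Hz lowpass. Used only to express
# scripted amplitudes in approximate z units; documented as nominal.
nominal_dff_sd <- function(config, baseline_470) {
  att <- sqrt(2 * 10 / config$photometry_rate)  # lowpass noise retention
  sdv <- config$noise_sd * att / baseline_470
  max(sdv, 1e-4)
}

#' Split a photometry session into channel vectors
#' @param session A `photometry_session` (or data.frame of records).
#' @return List with `time` (signal-channel times), `signal`, `reference`.
#' @export
photometry_channels <- function(session) {
  rec <- if (is.data.frame(session)) session else session$records
  sig <- rec[rec$channel == "signal_470", ]
  ref <- rec[rec$channel == "reference_415", ]
  m <- min(nrow(sig), nrow(ref))
  list(time = sig$time[seq_len(m)], signal = sig$fluor[seq_len(m)],
       reference = ref$fluor[seq_len(m)])
}

#' Write a Neurophotometrics-style photometry CSV
#'
#' Columns `FrameCounter`, `SystemTimestamp`, `LedState` (1 = 415 nm
#' reference, 2 = 470 nm signal), and one fluorescence column per region
#' (default `Region0G`).
#'
#' @param session A `photometry_session`.
#' @param path Output path.
#' @param region Region column name (default `"Region0G"`).
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(session, path, region = "Region0G") {
  rec <- session$records
  df <- data.frame(FrameCounter = rec$frame_counter,
                   SystemTimestamp = rec$time,
                   LedState = ifelse(rec$channel == "signal_470", 2L, 1L))
  df[[region]] <- rec$fluor
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a Neurophotometrics-style photometry CSV
#'
#' Demultiplexes records on `LedState` (or `Flags`): 1 or 415 -> reference,
#' 2 or 470 -> signal.
#'
#' @param path CSV path.
#' @param region Fluorescence column to read (default first `Region*`
#'   column).
#' @param animal,hemisphere Metadata attached to the session.
#' @return A `photometry_session`.
#' @export
read_photometry_csv <- function(path, region = NULL, animal = "animal1",
                                hemisphere = "left") {
  df <- utils::read.csv(path, check.names = FALSE)
  led <- df[["LedState"]] %||% df[["Flags"]]
  if (is.null(led)) stop("photometry CSV needs a LedState or Flags column")
  if (is.null(region)) {
    region <- grep("^Region", names(df), value = TRUE)[1]
    if (is.na(region)) stop("no Region* fluorescence column found")
  }
  channel <- ifelse(led %in% c(2, 470), "signal_470",
                    ifelse(led %in% c(1, 415), "reference_415", NA))
  keep <- !is.na(channel)
  rec <- data.frame(frame_counter = df[["FrameCounter"]][keep],
                    time = df[["SystemTimestamp"]][keep],
                    channel = channel[keep], fluor = df[[region]][keep])
  n_sig <- sum(rec$channel == "signal_470")
  dt <- stats::median(diff(rec$time[rec$channel == "signal_470"]))
  structure(list(records = rec, rate = 1 / dt, artifact = NULL,
                 clean_dff = NULL, animal = animal,
                 hemisphere = hemisphere),
            class = "photometry_session")
}

#' Simulate peri-event units directly with known ground truth
#'
#' Generates a binned peri-event table (bypassing the photometry and
#' alignment stages) for calibration and recovery studies: per unit,
#' `zdff = mu[type](t) + animal offset + animal-by-type effect + AR(1)
#' noise`. The animal offset is kept small by default because
#' within-animal session z-scoring removes additive offsets in the real
#' pipeline; the animal-by-type effect models per-mouse response
#' amplitude heterogeneity, the dependence animal-level bootstraps
#' exist to respect. The AR(1) parameter applies at the bin level.
#'
#' @param n_animals Number of animals.
#' @param units_per_type Units per animal per type.
#' @param types Sequence types to generate.
#' @param mu Named list mapping type to a mean curve: a constant, a
#'   length-`n_bins` vector, or a function of bin time; missing types
#'   default to zero.
#' @param rho Within-unit AR(1) correlation between adjacent bins.
#' @param unit_sd Marginal SD of the within-unit noise (z units).
#' @param animal_sd SD of the shared per-animal offset (default 0).
#' @param animal_type_sd SD of the per-animal, per-type effect
#'   (default 0).
#' @param seed Integer seed.
#' @param n_bins Bins per unit (default 90 on \[-3, 3)).
#' @return A `perievent_units` data.frame.
#' @export
simulate_perievent_units <- function(n_animals, units_per_type,
                                     types = c("CC", "Go"), mu = NULL,
                                     rho = 0.9, unit_sd = 1,
                                     animal_sd = 0, animal_type_sd = 0,
                                     seed = 1, n_bins = 90) {
  local_seed(seed)
  bt <- -3 + (seq_len(n_bins) - 0.5) / 15
  mu <- lapply(stats::setNames(nm = types), function(ty) {
    m <- mu[[ty]]
    if (is.null(m)) rep(0, n_bins)
    else if (is.function(m)) m(bt)
    else rep_len(m, n_bins)
  })
  rows <- vector("list", n_animals * length(types) * units_per_type)
  k <- 0; ev <- 0
  for (a in seq_len(n_animals)) {
    a_eff <- stats::rnorm(1, 0, animal_sd)
    for (ty in types) {
      at_eff <- stats::rnorm(1, 0, animal_type_sd)
      for (u in seq_len(units_per_type)) {
        ev <- ev + 1
        e <- stats::rnorm(n_bins)
        x <- numeric(n_bins)
        x[1] <- e[1]
        for (t in 2:n_bins) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * e[t]
        k <- k + 1
        rows[[k]] <- data.frame(
          animal = paste0("a", a), hemisphere = "left", event = ev,
          sequence_type = ty, bin = seq_len(n_bins), bin_time = bt,
          zdff = mu[[ty]] + a_eff + at_eff + unit_sd * x)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("perievent_units", "data.frame")
  out
}
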