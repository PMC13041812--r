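# shared fixture builders; all randomness is seeded by the caller

# straight-line pose track at constant speed (cm/s) along +y
straight_track <- function(n = 100, fps = 30, speed = 15, start = c(0, 0),
                           dir = c(0, 1)) {
  time <- (seq_len(n) - 1) / fps
  step <- speed / fps
  cen <- cbind(start[1] + dir[1] * step * (seq_len(n) - 1),
               start[2] + dir[2] * step * (seq_len(n) - 1))
  head <- sweep(cen, 2, dir * 2, `+`)
  tail <- sweep(cen, 2, dir * -2, `+`)
  pose_track(time, cen, head, tail, bbox_width = 3, bbox_height = 6)
}

stationary_track <- function(n = 100, fps = 30, at = c(0, 25)) {
  straight_track(n, fps, speed = 0, start = at)
}

# scripted synthetic session + detected features, one call
scripted_session <- function(types, seed, spacing = 25, duration = NULL,
                             geom = maze_geometry()) {
  script <- data.frame(type = types,
                       start = 20 + spacing * (seq_along(types) - 1))
  if (is.null(duration)) duration <- max(script$start) + spacing
  cfg <- sim_config(session_duration = duration, sequence_script = script,
                    seed = seed)
  sim <- simulate_trajectory(cfg, geom)
  fx <- frame_features(sim$track, geom)
  fx$centroid_x <- sim$track$centroid_x
  fx$centroid_y <- sim$track$centroid_y
  list(cfg = cfg, sim = sim, features = fx, geom = geom)
}

# thin wrapper kept for test brevity
make_units <- function(...) simulate_perievent_units(...)

# binomial 95% CI for a proportion estimate from n trials
binom_ci <- function(p0, n) p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / n)
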