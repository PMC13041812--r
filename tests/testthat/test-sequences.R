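test_that("classification rule table is exhaustive over the 2x2 cases", {
  expect_equal(classify_sequence("closed-", 0), "CC")
  expect_equal(classify_sequence("closed+", 2), "NoGo")
  expect_equal(classify_sequence("open+", 2), "Go")
  expect_equal(classify_sequence("open-", 0), "CO")
  expect_error(classify_sequence(NA, 0), "terminal arm")
})

test_that("scripted sessions are recovered exactly (types, order, count)", {
  # segmentation round trip over 5 seeds x 10 bouts
  for (seed in 1:5) {
    types <- c(rep("CC", 5), rep("NoGo", 3), rep("Go", 2))
    ss <- scripted_session(types, seed = seed)
    seqs <- detect_sequences(ss$features, ss$sim$events, ss$geom)
    expect_identical(seqs$type, types)
    # detection idempotence
    seqs2 <- detect_sequences(ss$features, ss$sim$events, ss$geom)
    expect_identical(as.data.frame(seqs), as.data.frame(seqs2))
  }
})

test_that("mixed scripts incl. CO are recovered across seeds", {
  for (seed in 6:8) {
    script <- random_script(12, seed = seed)
    ss <- scripted_session(script$type, seed = seed)
    seqs <- detect_sequences(ss$features, ss$sim$events, ss$geom)
    expect_identical(seqs$type, script$type)
  }
})

test_that("idle mouse never oriented toward center yields no sequences", {
  cfg <- sim_config(session_duration = 60, seed = 2)
  sim <- simulate_trajectory(cfg, maze_geometry())
  fx <- frame_features(sim$track, maze_geometry())
  fx$centroid_x <- sim$track$centroid_x
  fx$centroid_y <- sim$track$centroid_y
  seqs <- detect_sequences(fx, sim$events, maze_geometry())
  expect_equal(nrow(seqs), 0)
})

test_that("a 40% open-arm excursion with a risk event classifies NoGo", {
  g <- maze_geometry()
  fps <- 30
  # constructed path: closed-distal start -> center -> 40% into open arm
  # (3.9 + 0.4 * 27.8 = 15.02 < 17.8 threshold) -> back -> opposite
  # closed arm past threshold
  wp_t <- c(0, 2, 4, 6, 8, 11)
  wp_x <- c(0, 0, 15, 15, 0, 0)
  wp_y <- c(25, 0, 0, 0, 0, -20)
  time <- seq(0, 11, by = 1 / fps)
  cx <- approx(wp_t, wp_x, time)$y
  cy <- approx(wp_t, wp_y, time)$y
  dx <- c(diff(cx), 0); dy <- c(diff(cy), 0)
  nrm <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  head <- cbind(cx + 2 * dx / nrm, cy + 2 * dy / nrm)
  tr <- pose_track(time, cbind(cx, cy), head,
                   cbind(cx - 2 * dx / nrm, cy - 2 * dy / nrm), 3, 6)
  fx <- frame_features(tr, g)
  fx$centroid_x <- cx; fx$centroid_y <- cy
  ev <- event_table(5.0, "risk_assessment")   # during the pause at 15 cm
  seqs <- detect_sequences(fx, ev, g)
  expect_equal(nrow(seqs), 1)
  expect_equal(seqs$type, "NoGo")
  expect_equal(seqs$terminal_arm, "closed-")

  # same path without the risk event is a plain closed-to-closed
  seqs2 <- detect_sequences(fx, event_table(), g)
  expect_equal(seqs2$type, "CC")
})

test_that("risk events outside the proximal open arm are ignored with warning", {
  types <- c("CC", "CC")
  ss <- scripted_session(types, seed = 11)
  # add a bogus risk event inside the first bout while the mouse is
  # still in the closed arm (bout starts at 20 s)
  ev <- event_table(c(20.5), "risk_assessment")
  expect_warning(seqs <- detect_sequences(ss$features, ev, ss$geom),
                 "outside the proximal open arm")
  expect_equal(seqs$type, types)   # classification unchanged
})

test_that("events outside the session are rejected", {
  ss <- scripted_session("CC", seed = 12)
  ev <- event_table(1e6, "risk_assessment")
  expect_error(detect_sequences(ss$features, ev, ss$geom),
               "outside the session")
})

test_that("sequence metrics average over the half-open frame slice", {
  ss <- scripted_session(c("CC", "NoGo"), seed = 13)
  seqs <- detect_sequences(ss$features, ss$sim$events, ss$geom)
  m <- sequence_metrics(seqs, ss$features)
  expect_equal(m$duration, seqs$t_stop - seqs$t_start)
  expect_true(all(m$duration > 0))
  expect_true(all(m$mean_speed >= 0))
  # hand check on a constructed constant-speed slice
  fx <- ss$features[1:100, ]
  fx$speed <- 15; fx$aspect_ratio <- rep(c(1, 2), 50)
  sq <- data.frame(type = "CC", t_start = fx$time[1],
                   t_stop = fx$time[100] + 1e-6)
  mm <- sequence_metrics(sq, fx)
  expect_equal(mm$mean_speed, 15)
  expect_equal(mm$mean_aspect_ratio, 1.5)
})

test_that("risk index arithmetic and counts", {
  counts <- c(CC = 4, NoGo = 3, Go = 2, CO = 1)
  expect_equal(risk_assessment_index(counts), 0.5)
  expect_equal(risk_assessment_index(c(CC = 7)), 0)
  expect_equal(risk_assessment_index(c(Go = 5)), 1)
  tab <- data.frame(type = c("CC", "Go", "Go"))
  expect_equal(counts_by_type(tab), c(CC = 1L, NoGo = 0L, Go = 2L, CO = 0L))
  expect_equal(risk_assessment_index(tab), 2 / 3)
  expect_error(risk_assessment_index(data.frame(type = character())),
               "no sequences detected")
})

test_that("risk index monotonicity under count perturbations", {
  set.seed(21)
  for (i in 1:200) {
    cnt <- c(CC = sample(0:10, 1), NoGo = sample(0:10, 1),
             Go = sample(0:10, 1), CO = sample(0:10, 1))
    if (sum(cnt) == 0) cnt["CC"] <- 1
    idx <- risk_assessment_index(cnt)
    expect_gte(risk_assessment_index(cnt + c(0, 0, 1, 0)), idx)  # +Go
    expect_lte(risk_assessment_index(cnt + c(1, 0, 0, 0)), idx)  # +CC
    expect_true(idx >= 0 && idx <= 1)
  }
})
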