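test_that("alignment rule: 90 half-open bins on [-3, 3)", {
  r <- alignment_rule()
  expect_equal(r$n_bins, 90)                 # 6 s / (1/15 s)
  expect_equal(r$bin_edges[1], -3)
  expect_equal(r$bin_edges[91], 3)
  expect_equal(r$bin_centers[1], -3 + 1 / 30)
  expect_error(alignment_rule(window = c(1, 3)), "contain 0")
  expect_error(alignment_rule(bin_width = 0.7), "divide")
})

# a flat processed trace for alignment tests
flat_trace <- function(c0 = 0, duration = 600, rate = 40) {
  tr <- data.frame(time = seq(0, duration - 1 / rate, by = 1 / rate),
                   dff = c0, zdff = c0)
  attr(tr, "animal") <- "a1"; attr(tr, "hemisphere") <- "left"
  class(tr) <- c("processed_trace", "data.frame")
  tr
}

seq_row <- function(type = "CC", t_center = 100, t_first_risk = NA) {
  data.frame(type = type, origin_arm = "closed+", terminal_arm = "closed-",
             t_start = t_center - 3, t_center = t_center,
             t_first_risk = t_first_risk, t_stop = t_center + 3,
             duration = 6, n_risk_events = as.integer(!is.na(t_first_risk)))
}

test_that("constant zdF/F gives constant bins; anchors follow the rule", {
  u <- align_events(flat_trace(2.5), seq_row("CC", 100))
  expect_equal(nrow(u), 90)
  expect_equal(u$zdff, rep(2.5, 90))
  expect_equal(u$sequence_type, rep("CC", 90))
  # NoGo aligns to first risk assessment, not center crossing
  u2 <- align_events(flat_trace(1), seq_row("NoGo", 100, t_first_risk = 102))
  expect_equal(unique(u2$zdff), 1)
  # CO excluded by rule
  u3 <- align_events(flat_trace(1), seq_row("CO", 100))
  expect_equal(nrow(u3), 0)
  # missing anchor skipped with warning
  expect_warning(u4 <- align_events(flat_trace(1),
                                    seq_row("NoGo", 100, NA)),
                 "missing anchor")
  expect_equal(nrow(u4), 0)
})

test_that("events whose window exceeds the session are dropped and logged", {
  u <- align_events(flat_trace(0), seq_row("CC", 1))
  expect_equal(nrow(u), 0)
  expect_match(attr(u, "log"), "outside session")
})

test_that("alignment places an injected transient at the right bin", {
  rate <- 40
  tr <- flat_trace(0, duration = 200, rate = rate)
  # transient peaking 0.5 s after the anchor at t = 100
  tr$zdff <- exp(-(tr$time - 100.5)^2 / (2 * 0.05^2))
  u <- align_events(tr, seq_row("CC", 100), smooth_sigma = 0)
  peak_bin_time <- u$bin_time[which.max(u$zdff)]
  expect_lt(abs(peak_bin_time - 0.5), 1 / 15 + 1e-9)  # within one bin
})

test_that("binning conserves mass under uniform sampling", {
  # exact only when the rate fills every bin equally (30 Hz -> 2
  # samples per 1/15 s bin); at 40 Hz bins alternate 2-3 samples
  set.seed(17)
  tr <- flat_trace(0, duration = 300, rate = 30)
  tr$zdff <- rnorm(nrow(tr))
  u <- align_events(tr, seq_row("CC", 150), smooth_sigma = 0)
  sel <- tr$time >= 147 & tr$time < 153
  expect_equal(mean(u$zdff), mean(tr$zdff[sel]), tolerance = 1e-9)
})

test_that("epoch bin counts are frozen: pre 37, peri 15, post 38", {
  r <- alignment_rule()
  sp <- epoch_spec()
  counts <- vapply(sp, function(e)
    sum(r$bin_centers >= e[1] & r$bin_centers < e[2]), numeric(1))
  expect_equal(unname(counts), c(37, 15, 38))
  expect_equal(sum(counts), 90)
})

test_that("epoch means on constants and a step function", {
  u0 <- align_events(flat_trace(0), seq_row("CC", 100))
  em0 <- epoch_means(u0)
  expect_equal(em0$mean_zdff, rep(0, 3))
  # step: 0 before the event, 1 after
  tr <- flat_trace(0); tr$zdff <- as.numeric(tr$time >= 100)
  u <- align_events(tr, seq_row("CC", 100), smooth_sigma = 0)
  em <- epoch_means(u)
  expect_equal(em$mean_zdff[em$epoch == "pre"], 0)
  expect_equal(em$mean_zdff[em$epoch == "post"], 1)
  # peri epoch: 0 is a bin edge; 7 of the 15 peri bins lie right of it
  # (centers -0.5 ... -0.033 are 8 bins, 0.033 ... 0.433 are 7)
  peri <- em$mean_zdff[em$epoch == "peri"]
  expect_equal(peri, 7 / 15)
  expect_error(epoch_means(u, epoch_spec(post = c(0.5, 4))), "outside")
})

test_that("epoch comparison: null calibration, power, degenerate input", {
  # null: both types drawn from the same distribution
  set.seed(23)
  rej <- vapply(1:1000, function(i) {
    u <- make_units(4, 3, types = c("CC", "Go"), rho = 0, seed = 1000 + i)
    epoch_comparison(u, "post", mode = "unit")$p < 0.05
  }, logical(1))
  ci <- binom_ci(0.05, 1000)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
  # power: two groups separated by 5 sd
  u <- make_units(5, 5, types = c("CC", "Go"),
                  mu = list(CC = 0, Go = 5), rho = 0, seed = 7)
  expect_lt(epoch_comparison(u, "post", mode = "unit")$p, 1e-6)
  # identical constant groups: error path
  uc <- make_units(3, 2, types = c("CC", "Go"), rho = 0, unit_sd = 0,
                   seed = 1)
  expect_error(epoch_comparison(uc, "post"), "zero variance")
})
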