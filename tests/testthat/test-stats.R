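# long-format split-plot fixture generator
make_mixed <- function(n_per_group = 5, groups = c("control", "Gi", "Gq"),
                       levels = c("L1", "L2", "L3"), group_eff = 0,
                       level_eff = 0, sd = 1) {
  df <- expand.grid(animal = paste0("a", seq_len(n_per_group * length(groups))),
                    level = levels)
  df$group <- rep(rep(groups, each = n_per_group), times = length(levels))
  df$value <- rnorm(nrow(df), sd = sd) +
    group_eff * (as.integer(factor(df$group)) - 1) +
    level_eff * (as.integer(factor(df$level)) - 1)
  df
}

test_that("mixed ANOVA agrees with the frozen oracle fixture", {
  # fixture computed independently with a reference implementation
  # (pingouin.mixed_anova): F_group = 1.971571, F_level = 2.456232,
  # F_interaction = 2.319132 with dfs (2,9), (2,18), (4,18)
  set.seed(7)
  df <- expand.grid(animal = paste0("a", 1:12), level = c("L1", "L2", "L3"))
  df$group <- rep(rep(c("control", "Gi", "Gq"), each = 4), times = 3)
  df$value <- rnorm(nrow(df)) + as.numeric(df$level) * 0.5
  res <- mixed_anova(df)
  expect_equal(res$F, c(1.971571, 2.456232, 2.319132), tolerance = 1e-6)
  expect_equal(res$df1, c(2, 2, 4))
  expect_equal(res$df2, c(9, 18, 18))
  expect_equal(res$p, c(0.19494525, 0.11397419, 0.09637518),
               tolerance = 1e-6)
  expect_true(all(res$p_gg[-1] >= res$p[-1]))   # GG never anti-conservative
})

test_that("mixed ANOVA input guards", {
  df <- make_mixed()
  expect_error(mixed_anova(df[df$level != "L1" | df$animal != "a1", ]),
               "a1")
  df2 <- df; df2$value <- 1
  expect_error(mixed_anova(df2), "zero variance")
  df3 <- df; df3$group[df3$animal == "a1"] <- c("Gi", "control", "Gq")
  expect_error(mixed_anova(df3), "one group")
})

test_that("mixed ANOVA calibration and power", {
  set.seed(31)
  # null: no group or level effect; interaction rejection near alpha
  rej <- vapply(1:500, function(i) {
    df <- make_mixed()
    res <- mixed_anova(df)
    res$p[res$effect == "group:level"] < 0.05
  }, logical(1))
  ci <- binom_ci(0.05, 500)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
  # strong within effect: 3 sd steps detected essentially always
  hits <- vapply(1:50, function(i) {
    df <- make_mixed(level_eff = 3)
    res <- mixed_anova(df)
    res$p[res$effect == "level"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("one-way ANOVA with BH follow-ups", {
  set.seed(12)
  # three identical groups: p near 1 territory (not significant)
  tab0 <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                     value = rep(rnorm(4), 3))
  expect_gt(oneway_anova_fdr(tab0)$p, 0.99)
  # one group shifted 5 sd: omnibus p tiny
  tab1 <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                     value = c(rnorm(30), rnorm(30), rnorm(30) + 5))
  res <- oneway_anova_fdr(tab1)
  expect_lt(res$p, 1e-6)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_error(oneway_anova_fdr(data.frame(group = "a", value = 1:3)),
               ">= 2 groups")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  # p = {0.01, 0.02, 0.03}, m = 3: adjusted {0.03, 0.03, 0.03}
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # monotone in the raw p-values and never smaller
  set.seed(13)
  p <- sort(runif(20))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= p))
})

test_that("KS two-sample: identical, disjoint, and half-overlapping", {
  x <- rnorm(100)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(1:50, 101:150)$D, 1)
  # Uniform(0,1) vs Uniform(0.5,1.5): closed-form maximal ECDF gap 0.5
  set.seed(14)
  hits <- vapply(1:100, function(i) {
    D <- ks_two_sample(runif(1000), runif(1000) + 0.5)$D
    abs(D - 0.5) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  # invariance under a common monotone transform
  a <- runif(200); b <- runif(200) + 0.3
  expect_equal(ks_two_sample(a, b)$D, ks_two_sample(exp(a), exp(b))$D)
})

test_that("session time bins average frame features as documented", {
  tr <- straight_track(600, fps = 30, speed = 10)
  fx <- frame_features(tr, maze_geometry())
  tb <- session_time_bins(fx, bin_width = 5)
  expect_equal(nrow(tb), 4)                   # 20 s of track
  expect_equal(tb$speed, rep(10, 4), tolerance = 1e-9)
  expect_equal(sum(tb$distance), sum(fx$horizontal_movement))
})
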