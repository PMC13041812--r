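#' Two-way mixed (split-plot) ANOVA
#'
#' One between-subjects factor (`group`) and one within-subjects factor
#' (`within`), subjects nested in groups, every subject measured once at
#' every within level. Classical expected-mean-square F tests: the
#' between effect against subjects-within-groups, the within and
#' interaction effects against the within-by-subject residual.
#' Greenhouse-Geisser-adjusted p-values (epsilon from the pooled
#' within-group covariance) are reported alongside the uncorrected ones.
#'
#' @param table Long data.frame with columns `animal`, `group`, `level`
#'   (within-factor), `value`.
#' @return data.frame with one row per effect (`group`, `level`,
#'   `group:level`): `F`, `df1`, `df2`, `p`, `p_gg` (GG-adjusted where
#'   applicable), plus attribute `epsilon`.
#' @export
mixed_anova <- function(table) {
  need <- c("animal", "group", "level", "value")
  if (!all(need %in% names(table)))
    stop("mixed_anova() needs columns animal, group, level, value")
  if (any(!is.finite(table$value))) stop("values must be finite")
  table$animal <- factor(table$animal)
  table$group <- factor(table$group)
  table$level <- factor(table$level)
  a <- nlevels(table$group); b <- nlevels(table$level)
  if (a < 2) stop("need >= 2 groups")
  # one group per animal; balanced within-factor coverage
  gmap <- tapply(as.character(table$group), table$animal,
                 function(g) length(unique(g)))
  if (any(gmap > 1)) stop("animals must each belong to one group")
  cover <- table(table$animal, table$level)
  bad <- rownames(cover)[apply(cover, 1, function(r) any(r != 1))]
  if (length(bad) > 0)
    stop("animal(s) missing a within level: ", paste(bad, collapse = ", "))

  N <- nlevels(table$animal)
  y <- table$value
  grand <- mean(y)
  subj_mean <- tapply(y, table$animal, mean)
  subj_group <- tapply(as.character(table$group), table$animal, unique)
  group_mean <- tapply(y, table$group, mean)
  level_mean <- tapply(y, table$level, mean)
  cell_mean <- tapply(y, list(table$group, table$level), mean)
  n_g <- table(factor(subj_group, levels = levels(table$group)))

  ss_A <- b * sum(n_g * (group_mean - grand)^2)
  ss_S <- b * sum((subj_mean - group_mean[subj_group])^2)
  ss_B <- N * sum((level_mean - grand)^2)
  ss_cells <- sum(rep(n_g, b) * (as.vector(cell_mean) - grand)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_A - ss_S - ss_B - ss_AB

  df_A <- a - 1; df_S <- N - a
  df_B <- b - 1; df_AB <- (a - 1) * (b - 1); df_err <- (N - a) * (b - 1)
  if (ss_S <= 0 || ss_err <= 0)
    stop("zero variance in error strata: F undefined")
  F_A <- (ss_A / df_A) / (ss_S / df_S)
  F_B <- (ss_B / df_B) / (ss_err / df_err)
  F_AB <- (ss_AB / df_AB) / (ss_err / df_err)

  eps <- gg_epsilon(table)
  out <- data.frame(
    effect = c("group", "level", "group:level"),
    F = c(F_A, F_B, F_AB),
    df1 = c(df_A, df_B, df_AB),
    df2 = c(df_S, df_err, df_err),
    p = c(stats::pf(F_A, df_A, df_S, lower.tail = FALSE),
          stats::pf(F_B, df_B, df_err, lower.tail = FALSE),
          stats::pf(F_AB, df_AB, df_err, lower.tail = FALSE)),
    p_gg = c(NA,
             stats::pf(F_B, df_B * eps, df_err * eps, lower.tail = FALSE),
             stats::pf(F_AB, df_AB * eps, df_err * eps,
                       lower.tail = FALSE)))
  attr(out, "epsilon") <- eps
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the subject-by-level matrix
gg_epsilon <- function(table) {
  b <- nlevels(table$level)
  wide <- stats::reshape(
    table[, c("animal", "group", "level", "value")],
    idvar = c("animal", "group"), timevar = "level", direction = "wide")
  M <- as.matrix(wide[, -(1:2), drop = FALSE])
  covs <- lapply(split(seq_len(nrow(M)), wide$group), function(idx)
    if (length(idx) > 1) stats::cov(M[idx, , drop = FALSE]) else NULL)
  covs <- Filter(Negate(is.null), covs)
  S <- Reduce(`+`, covs) / length(covs)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (b * (dbar - sbar))^2
  den <- (b - 1) * (sum(S^2) - 2 * b * sum(rowMeans(S)^2) +
                      b^2 * sbar^2)
  eps <- if (den > 0) num / den else 1
  min(max(eps, 1 / (b - 1)), 1)
}

#' One-way ANOVA with BH-corrected pairwise follow-ups
#'
#' Omnibus F across groups and pairwise Welch t-tests adjusted by
#' Benjamini-Hochberg.
#'
#' @param table data.frame with columns `group` and `value` (an optional
#'   `animal` column is ignored).
#' @return List with `F`, `df`, `p`, and `pairwise` (data.frame with
#'   `a`, `b`, `p_raw`, `p_adj`).
#' @export
oneway_anova_fdr <- function(table) {
  grp <- factor(table$group); vals <- table$value
  if (nlevels(grp) < 2) stop("need >= 2 groups")
  if (any(tapply(vals, grp, length) < 2))
    stop("each group needs >= 2 observations")
  fit <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2)
  praw <- apply(pairs, 2, function(pp)
    stats::t.test(vals[grp == pp[1]], vals[grp == pp[2]])$p.value)
  list(F = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value,
       pairwise = data.frame(a = pairs[1, ], b = pairs[2, ],
                             p_raw = praw,
                             p_adj = stats::p.adjust(praw, "BH")))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the maximum ECDF gap; the p-value is the asymptotic
#' approximation (appropriate for the large frame-wise samples this is
#' used on).
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over the step-up BH procedure, exposed for report tables.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values, monotone in the input and never smaller.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Average frame features into fixed-width session time bins
#'
#' Builds the per-animal time-binned locomotion tables used for
#' session-course comparisons (distance, speed, acceleration, posture
#' over time). Default 5-s bins over a 600-s session give 120 bins.
#'
#' @param features A [frame_features()] table.
#' @param bin_width Bin width in seconds (default 5).
#' @param columns Feature columns to average.
#' @return data.frame with `t_bin` (bin start) and the averaged columns;
#'   `distance` is the summed horizontal movement per bin.
#' @export
session_time_bins <- function(features, bin_width = 5,
                              columns = c("speed", "acceleration",
                                          "bbox_area", "aspect_ratio",
                                          "d_aspect")) {
  tb <- floor(features$time / bin_width) * bin_width
  out <- data.frame(t_bin = sort(unique(tb)))
  for (cl in columns)
    out[[cl]] <- as.numeric(tapply(features[[cl]], tb, mean,
                                   na.rm = TRUE))
  out$distance <- as.numeric(tapply(features$horizontal_movement, tb, sum))
  out
}
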