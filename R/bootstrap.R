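#' Animal-level bootstrap confidence bands for mean time courses
#'
#' Resamples animals with replacement; each resample includes all
#' peri-event units of each drawn animal (with multiplicity) and
#' recomputes the per-type mean time course. Percentile bands are
#' reported at 95% and 99%. Deterministic given `seed`.
#'
#' @param units A `perievent_units` table.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (required; no silent nondeterminism).
#' @param types Sequence types to include (default those present).
#' @return data.frame of class `bootstrap_bands`: `sequence_type`,
#'   `bin_time`, `mean`, `lo95`, `hi95`, `lo99`, `hi99`; attributes
#'   `n_resamples`, `seed`.
#' @export
bootstrap_timecourse <- function(units, n_resamples = 1000, seed,
                                 types = NULL) {
  if (missing(seed)) stop("bootstrap_timecourse() requires a seed")
  um <- units_matrix(units)
  if (is.null(types)) types <- unique(um$type)
  animals <- unique(um$animal)
  if (length(animals) < 2) stop("cannot resample one cluster")
  sums <- resample_sums(um, types)
  local_seed(seed)
  draws <- matrix(sample.int(length(animals), n_resamples * length(animals),
                             replace = TRUE), nrow = n_resamples)
  out <- list()
  for (ty in types) {
    S <- sums$sum[[ty]]; cn <- sums$count[[ty]]
    curves <- matrix(NA_real_, n_resamples, ncol(S))
    for (r in seq_len(n_resamples)) {
      sel <- draws[r, ]
      tot <- sum(cn[sel])
      if (tot == 0) next
      curves[r, ] <- colSums(S[sel, , drop = FALSE]) / tot
    }
    ok <- stats::complete.cases(curves)
    q <- apply(curves[ok, , drop = FALSE], 2, stats::quantile,
               probs = c(0.025, 0.975, 0.005, 0.995), names = FALSE)
    out[[ty]] <- data.frame(
      sequence_type = ty, bin_time = um$bin_time,
      mean = colMeans(um$values[um$type == ty, , drop = FALSE]),
      lo95 = q[1, ], hi95 = q[2, ], lo99 = q[3, ], hi99 = q[4, ])
  }
  bands <- do.call(rbind, out)
  rownames(bands) <- NULL
  attr(bands, "n_resamples") <- n_resamples
  attr(bands, "seed") <- seed
  class(bands) <- c("bootstrap_bands", "data.frame")
  bands
}

# per-animal, per-type bin-sum matrices and unit counts
resample_sums <- function(um, types) {
  animals <- unique(um$animal)
  sum_l <- list(); cnt_l <- list()
  for (ty in types) {
    S <- matrix(0, length(animals), ncol(um$values))
    cn <- numeric(length(animals))
    for (ai in seq_along(animals)) {
      sel <- um$animal == animals[ai] & um$type == ty
      cn[ai] <- sum(sel)
      if (cn[ai] > 0)
        S[ai, ] <- colSums(um$values[sel, , drop = FALSE])
    }
    sum_l[[ty]] <- S; cnt_l[[ty]] <- cn
  }
  list(sum = sum_l, count = cnt_l, animals = animals)
}

#' Time-resolved one-sample significance from bootstrap bands
#'
#' Finds contiguous runs of bins where the band at the requested level
#' excludes zero, merging runs into intervals reported at bin centers.
#' Runs shorter than `min_run` bins are logged, not reported (noise-bin
#' suppression; set `min_run = 1` to keep isolated bins).
#'
#' @param bands A `bootstrap_bands` table.
#' @param level `"99"` (default, per time-resolved significance
#'   visualization) or `"95"`.
#' @param min_run Minimum run length in bins (default 2).
#' @return data.frame of class `significance_intervals`: `contrast`,
#'   `t_start`, `t_end` (bin centers); attribute `log` lists suppressed
#'   single-bin hits.
#' @export
one_sample_significance <- function(bands, level = c("99", "95"),
                                    min_run = 2) {
  level <- match.arg(level)
  lo <- bands[[paste0("lo", level)]]; hi <- bands[[paste0("hi", level)]]
  out <- list(); log <- character()
  for (ty in unique(bands$sequence_type)) {
    sel <- bands$sequence_type == ty
    sig <- (lo[sel] > 0) | (hi[sel] < 0)
    iv <- runs_to_intervals(sig, bands$bin_time[sel], min_run)
    log <- c(log, sprintf("%s: %d single-bin hit(s) suppressed", ty,
                          attr(iv, "suppressed")))
    if (nrow(iv) > 0)
      out[[ty]] <- cbind(contrast = ty, iv)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contrast = character(), t_start = numeric(),
               t_end = numeric())
  rownames(res) <- NULL
  attr(res, "log") <- log
  class(res) <- c("significance_intervals", "data.frame")
  res
}

runs_to_intervals <- function(sig, times, min_run) {
  r <- rle(sig)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  suppressed <- sum(r$values & r$lengths < min_run)
  iv <- data.frame(t_start = times[starts[keep]], t_end = times[ends[keep]])
  attr(iv, "suppressed") <- suppressed
  iv
}

#' Bootstrap significance intervals for a pairwise type contrast
#'
#' Both type mean time courses are recomputed within each animal-level
#' resample. With the default `method = "band_subtraction"` the two
#' types' percentile confidence bands are subtracted bin by bin
#' (`lo = lo_a - hi_b`, `hi = hi_a - lo_b`) and a bin is significant
#' where the subtracted band excludes zero, i.e. where the two bands do
#' not overlap. `method = "difference"` instead bootstraps the per-bin
#' difference of type means directly and flags bins where its percentile
#' band excludes zero; this is a pointwise test and markedly more
#' liberal across the 90-bin family. Contiguity rule as in
#' [one_sample_significance()].
#'
#' @param units A `perievent_units` table.
#' @param pair Character vector `c(type_a, type_b)`.
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param level `"95"` (default) or `"99"`.
#' @param min_run Minimum run length in bins (default 2).
#' @param method `"band_subtraction"` (default) or `"difference"`.
#' @return A `significance_intervals` data.frame with attribute `band`
#'   (the per-bin contrast band).
#' @export
pairwise_band_difference <- function(units, pair, n_resamples = 1000, seed,
                                     level = c("95", "99"), min_run = 2,
                                     method = c("band_subtraction",
                                                "difference")) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (missing(seed)) stop("pairwise_band_difference() requires a seed")
  if (length(pair) != 2) stop("pair must name two types")
  um <- units_matrix(units)
  absent <- setdiff(pair, unique(um$type))
  if (length(absent) > 0)
    stop("type(s) absent from units: ", paste(absent, collapse = ", "))
  animals <- unique(um$animal)
  if (length(animals) < 2) stop("cannot resample one cluster")
  sums <- resample_sums(um, unique(pair))
  local_seed(seed)
  draws <- matrix(sample.int(length(animals), n_resamples * length(animals),
                             replace = TRUE), nrow = n_resamples)
  nb <- ncol(um$values)
  curves_a <- matrix(NA_real_, n_resamples, nb)
  curves_b <- matrix(NA_real_, n_resamples, nb)
  Sa <- sums$sum[[pair[1]]]; ca <- sums$count[[pair[1]]]
  Sb <- sums$sum[[pair[2]]]; cb <- sums$count[[pair[2]]]
  for (r in seq_len(n_resamples)) {
    sel <- draws[r, ]
    ta <- sum(ca[sel]); tb <- sum(cb[sel])
    if (ta == 0 || tb == 0) next
    curves_a[r, ] <- colSums(Sa[sel, , drop = FALSE]) / ta
    curves_b[r, ] <- colSums(Sb[sel, , drop = FALSE]) / tb
  }
  ok <- stats::complete.cases(curves_a) & stats::complete.cases(curves_b)
  pr <- if (level == "95") c(0.025, 0.975) else c(0.005, 0.995)
  if (method == "difference") {
    q <- apply(curves_a[ok, , drop = FALSE] - curves_b[ok, , drop = FALSE],
               2, stats::quantile, probs = pr, names = FALSE)
  } else {
    qa <- apply(curves_a[ok, , drop = FALSE], 2, stats::quantile,
                probs = pr, names = FALSE)
    qb <- apply(curves_b[ok, , drop = FALSE], 2, stats::quantile,
                probs = pr, names = FALSE)
    q <- rbind(qa[1, ] - qb[2, ], qa[2, ] - qb[1, ])
  }
  sig <- (q[1, ] > 0) | (q[2, ] < 0)
  iv <- runs_to_intervals(sig, um$bin_time, min_run)
  res <- if (nrow(iv) > 0)
    cbind(contrast = paste(pair, collapse = "-"), iv)
  else data.frame(contrast = character(), t_start = numeric(),
                  t_end = numeric())
  rownames(res) <- NULL
  attr(res, "band") <- data.frame(bin_time = um$bin_time, lo = q[1, ],
                                  hi = q[2, ])
  attr(res, "suppressed") <- attr(iv, "suppressed")
  class(res) <- c("significance_intervals", "data.frame")
  res
}
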