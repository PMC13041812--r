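#' Peri-event alignment rule
#'
#' Maps each sequence type to its alignment anchor: the first
#' risk-assessment onset for NoGo/Go, the center crossing for CC.
#' CO sequences have no defined anchor and are excluded. The window is
#' `[-3, 3)` s split into 90 half-open 1/15-s bins; bin "centers" sit at
#' the left edge + 1/30 s.
#'
#' @param window Two-element window in seconds (default `c(-3, 3)`).
#' @param bin_width Bin width in seconds (default `1/15`); must divide the
#'   window span.
#' @param anchors Named map type -> anchor column.
#' @return List of class `alignment_rule` with `window`, `bin_width`,
#'   `n_bins`, `bin_edges`, `bin_centers`, `anchors`.
#' @export
alignment_rule <- function(window = c(-3, 3), bin_width = 1 / 15,
                           anchors = c(CC = "t_center",
                                       NoGo = "t_first_risk",
                                       Go = "t_first_risk")) {
  if (!(window[1] < 0 && window[2] > 0))
    stop("window must contain 0")
  n_bins <- (window[2] - window[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("bin_width must divide the window span")
  n_bins <- round(n_bins)
  edges <- window[1] + bin_width * (0:n_bins)
  structure(list(window = window, bin_width = bin_width, n_bins = n_bins,
                 bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_width / 2,
                 anchors = anchors),
            class = "alignment_rule")
}

#' Align a processed trace to sequence events and bin
#'
#' Extracts one peri-event unit per anchored sequence: zdF/F samples in
#' the window around the anchor, Gaussian-smoothed per window
#' (`smooth_sigma` samples), then averaged within each half-open bin
#' `[edge, edge + 1/15)`. Events whose window exceeds the session span are
#' dropped and logged; sequences missing their anchor are skipped with a
#' warning; types without an anchor in the rule (CO) are excluded.
#'
#' @param trace A `processed_trace` (from [preprocess_photometry()]).
#' @param sequences A `sequence_list` table.
#' @param rule An [alignment_rule()].
#' @param smooth_sigma Per-window Gaussian SD in samples (default 4).
#' @return data.frame of class `perievent_units`: columns `animal`,
#'   `hemisphere`, `event`, `sequence_type`, `bin`, `bin_time`, `zdff`
#'   (long format, 90 rows per unit). Attribute `log` records drops.
#' @export
align_events <- function(trace, sequences, rule = alignment_rule(),
                         smooth_sigma = 4) {
  tt <- trace$time
  log <- character()
  rows <- list()
  animal <- attr(trace, "animal") %||% "animal1"
  hemi <- attr(trace, "hemisphere") %||% "left"
  for (i in seq_len(nrow(sequences))) {
    type <- sequences$type[i]
    anchor_col <- rule$anchors[type]
    if (is.na(anchor_col)) next                       # excluded type (CO)
    anchor <- sequences[[anchor_col]][i]
    if (is.na(anchor)) {
      warning(sprintf("sequence %d (%s) missing anchor %s; skipped",
                      i, type, anchor_col))
      next
    }
    lo <- anchor + rule$window[1]; hi <- anchor + rule$window[2]
    if (lo < tt[1] - 1e-9 || hi > tt[length(tt)] + 1e-9) {
      log <- c(log, sprintf(
        "event %d (%s) at %.2f s: window outside session; dropped",
        i, type, anchor))
      next
    }
    sel <- tt >= lo & tt < hi
    ts <- tt[sel] - anchor
    zs <- gaussian_smooth(trace$zdff[sel], smooth_sigma)
    # epsilon-nudged floor so samples falling exactly on a bin edge (up
    # to fp rounding) land in the right-hand bin, per the half-open rule
    bin <- floor((ts - rule$window[1]) / rule$bin_width + 1e-9) + 1L
    keep <- bin >= 1 & bin <= rule$n_bins
    vals <- vapply(seq_len(rule$n_bins), function(b) {
      v <- zs[keep & bin == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      animal = animal, hemisphere = hemi, event = i,
      sequence_type = type, bin = seq_len(rule$n_bins),
      bin_time = rule$bin_centers, zdff = vals)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(), hemisphere = character(),
               event = integer(), sequence_type = character(),
               bin = integer(), bin_time = numeric(), zdff = numeric())
  attr(out, "log") <- log
  attr(out, "rule") <- rule
  class(out) <- c("perievent_units", "data.frame")
  out
}

#' Combine peri-event tables from several traces/animals
#' @param ... `perievent_units` tables (or a single list of them).
#' @return One `perievent_units` table with unique unit keys.
#' @export
bind_units <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  rule <- attr(parts[[1]], "rule")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "rule") <- rule
  class(out) <- c("perievent_units", "data.frame")
  out
}

unit_key <- function(units)
  interaction(units$animal, units$hemisphere, units$event,
              units$sequence_type, drop = TRUE)

#' Reshape peri-event units to a unit x bin matrix
#' @param units A `perievent_units` table.
#' @return List with `values` (matrix, units x bins), `animal`, `type`
#'   (per-row vectors), `bin_time`.
#' @export
units_matrix <- function(units) {
  key <- unit_key(units)
  ord <- order(key, units$bin)
  u <- units[ord, ]
  k <- key[ord]
  n_bins <- max(u$bin)
  ids <- !duplicated(k)
  m <- matrix(u$zdff, ncol = n_bins, byrow = TRUE)
  list(values = m, animal = u$animal[ids], type = u$sequence_type[ids],
       hemisphere = u$hemisphere[ids],
       bin_time = u$bin_time[u$bin <= n_bins][seq_len(n_bins)])
}

#' Epoch specification for peri-event summaries
#'
#' Default epochs: pre `[-3, -0.5)`, peri `[-0.5, 0.5)`, post `[0.5, 3)`
#' (closed-left, open-right; membership by bin center). With the default
#' 90-bin rule these contain 37, 15, and 38 bins.
#'
#' @param pre,peri,post Two-element intervals in seconds.
#' @return List of class `epoch_spec`.
#' @export
epoch_spec <- function(pre = c(-3, -0.5), peri = c(-0.5, 0.5),
                       post = c(0.5, 3)) {
  eps <- list(pre = pre, peri = peri, post = post)
  structure(eps, class = "epoch_spec")
}

#' Per-unit epoch means
#'
#' Means of zdF/F over bins whose centers fall in each epoch interval.
#'
#' @param units A `perievent_units` table.
#' @param spec An [epoch_spec()].
#' @return data.frame with `animal`, `hemisphere`, `event`,
#'   `sequence_type`, `epoch`, `mean_zdff`.
#' @export
epoch_means <- function(units, spec = epoch_spec()) {
  rng <- range(units$bin_time)
  for (e in names(spec))
    if (spec[[e]][1] < rng[1] - 1 / 30 || spec[[e]][2] > rng[2] + 1 / 30)
      stop(sprintf("epoch '%s' extends outside the peri-event window", e))
  out <- list()
  for (e in names(spec)) {
    lo <- spec[[e]][1]; hi <- spec[[e]][2]
    sub <- units[units$bin_time >= lo & units$bin_time < hi, ]
    agg <- stats::aggregate(
      zdff ~ animal + hemisphere + event + sequence_type, data = sub,
      FUN = mean)
    agg$epoch <- e
    names(agg)[names(agg) == "zdff"] <- "mean_zdff"
    out[[e]] <- agg
  }
  do.call(rbind, out)
}

#' Compare an epoch across sequence types
#'
#' One-way ANOVA of zdF/F across sequence types within one epoch, with
#' Benjamini-Hochberg-adjusted pairwise Welch t-tests. Observations are
#' bin-level samples by default (`mode = "bin"`, matching large printed
#' denominator dfs) or per-unit epoch means (`mode = "unit"`).
#'
#' @param units A `perievent_units` table.
#' @param epoch One of `"pre"`, `"peri"`, `"post"`.
#' @param spec An [epoch_spec()].
#' @param mode `"bin"` or `"unit"`.
#' @return List with `F`, `df`, `p`, and `pairwise` (data.frame with raw
#'   and BH-adjusted p-values).
#' @export
epoch_comparison <- function(units, epoch = "post", spec = epoch_spec(),
                             mode = c("bin", "unit")) {
  mode <- match.arg(mode)
  lo <- spec[[epoch]][1]; hi <- spec[[epoch]][2]
  if (mode == "bin") {
    sub <- units[units$bin_time >= lo & units$bin_time < hi, ]
    vals <- sub$zdff; grp <- sub$sequence_type
  } else {
    em <- epoch_means(units, spec)
    em <- em[em$epoch == epoch, ]
    vals <- em$mean_zdff; grp <- em$sequence_type
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2) stop("epoch comparison needs >= 2 sequence types")
  if (any(tapply(vals, grp, length) < 2))
    stop("each sequence type needs >= 2 observations")
  if (stats::var(vals) == 0)
    stop("zero variance across observations: F undefined")
  fit <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2)
  praw <- apply(pairs, 2, function(pp)
    stats::t.test(vals[grp == pp[1]], vals[grp == pp[2]])$p.value)
  list(F = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value,
       pairwise = data.frame(a = pairs[1, ], b = pairs[2, ], p_raw = praw,
                             p_adj = stats::p.adjust(praw, "BH")))
}

#' Write peri-event units as tidy CSV
#' @param units A `perievent_units` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perievent_csv <- function(units, path) {
  utils::write.csv(as.data.frame(units), path, row.names = FALSE)
  invisible(path)
}

#' Read peri-event units from tidy CSV
#' @param path CSV path.
#' @param rule Alignment rule to attach (default [alignment_rule()]).
#' @return A `perievent_units` table.
#' @export
read_perievent_csv <- function(path, rule = alignment_rule()) {
  out <- utils::read.csv(path)
  attr(out, "rule") <- rule
  class(out) <- c("perievent_units", "data.frame")
  out
}
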