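#' Preprocessing configuration for photometry
#'
#' @param lowpass_cutoff Low-pass cutoff, Hz (default 10). Must be below
#'   0.45 x the channel sampling rate.
#' @param filter_order Butterworth order (default 4).
#' @param ransac_residual_threshold Robust-scale multiplier applied to
#'   1.4826 x MAD of the initial least-squares residuals (default 1).
#' @param ransac_max_iter RANSAC iterations (default 100).
#' @param ransac_seed Integer seed for the RANSAC sampler (default 1).
#' @param smooth_sigma Gaussian smoothing SD in samples, applied per
#'   peri-event window (default 4).
#' @param inlier_floor QC floor on the RANSAC inlier fraction; a fit below
#'   it raises a warning (default 0.5).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_cutoff = 10, filter_order = 4,
                              ransac_residual_threshold = 1,
                              ransac_max_iter = 100, ransac_seed = 1,
                              smooth_sigma = 4, inlier_floor = 0.5) {
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 filter_order = filter_order,
                 ransac_residual_threshold = ransac_residual_threshold,
                 ransac_max_iter = ransac_max_iter,
                 ransac_seed = as.integer(ransac_seed),
                 smooth_sigma = smooth_sigma,
                 inlier_floor = inlier_floor),
            class = "preprocess_config")
}

# ---- Butterworth low-pass, zero phase --------------------------------------

# digital lowpass Butterworth coefficients via bilinear transform of the
# analog prototype; returns list(b, a), DC gain exactly 1
butter_lowpass <- function(order, cutoff, rate) {
  if (cutoff >= rate / 2)
    stop(sprintf("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                 cutoff, rate / 2))
  wc <- tan(pi * cutoff / rate)              # prewarped analog cutoff
  k <- seq_len(order)
  poles_a <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform s = (1 - z^-1)/(1 + z^-1)
  poles_z <- (1 + poles_a) / (1 - poles_a)
  a <- Re(poly_from_roots(poles_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))   # 'order' zeros at z = -1
  gain <- sum(a) / sum(b)                         # unit DC gain
  list(b = b * gain, a = a)
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# direct-form II transposed IIR filter with initial conditions zi
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- length(a)
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(nfilt - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(nfilt - 2))
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    z[nfilt - 1] <- b[nfilt] * x[i] - a[nfilt] * y[i]
  }
  y
}

# steady-state initial conditions for a unit step (scipy lfilter_zi)
filter_zi <- function(b, a) {
  n <- length(a) - 1
  b <- b / a[1]; a <- a / a[1]
  A <- diag(1, n) - cbind(-a[-1], rbind(diag(1, n - 1), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(A, B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs an order-`order` digital Butterworth low-pass at `cutoff` Hz and
#' applies it forward and backward (zero net phase; the effective magnitude
#' response is the squared Butterworth magnitude
#' `1 / (1 + (f/fc)^(2 * order))`). Edges use odd-reflection padding with
#' steady-state initial conditions, so a constant trace passes unchanged.
#'
#' @param x Numeric trace.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist (`rate / 2`).
#' @param rate Sampling rate, Hz.
#' @param order Filter order (default 4).
#' @return Filtered trace, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, cutoff, rate, order = 4) {
  co <- butter_lowpass(order, cutoff, rate)
  b <- co$b; a <- co$a
  ntaps <- max(length(a), length(b))
  padlen <- 3 * ntaps
  if (length(x) <= padlen)
    stop(sprintf("trace length %d too short for order-%d zero-phase filtering",
                 length(x), order))
  # odd reflection about the end points
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1, padlen + length(x))]
}

# ---- RANSAC isosbestic fit -------------------------------------------------

#' Robust linear scaling of the isosbestic reference to the signal
#'
#' Fits `signal ~ slope * reference + intercept` by RANSAC: repeatedly fit
#' a line through two random samples, count inliers within the residual
#' threshold (a `ransac_residual_threshold` multiple of 1.4826 x MAD of
#' the initial least-squares residuals), keep the largest consensus set,
#' and refit by least squares on it. Deterministic given `ransac_seed`.
#'
#' @param reference,signal Equal-length traces (>= 100 samples);
#'   the reference must have positive variance.
#' @param config A [preprocess_config()].
#' @return List with `slope`, `intercept`, `inliers` (logical mask),
#'   `inlier_fraction`, and `r_squared` (on inliers).
#' @export
fit_isosbestic <- function(reference, signal, config = preprocess_config()) {
  n <- length(reference)
  if (length(signal) != n) stop("reference and signal lengths differ")
  if (n < 100) stop("fit_isosbestic() needs at least 100 samples")
  if (stats::var(reference) == 0) stop("flat isosbestic channel")
  ls <- stats::lm.fit(cbind(1, reference), signal)
  scale0 <- 1.4826 * stats::median(abs(ls$residuals - stats::median(ls$residuals)))
  thr <- config$ransac_residual_threshold * scale0
  eps <- 1e-9 * max(1, stats::median(abs(signal)))
  thr <- max(thr, eps)

  local_seed(config$ransac_seed)
  best_mask <- NULL; best_count <- -1L
  for (it in seq_len(config$ransac_max_iter)) {
    idx <- sample.int(n, 2)
    dx <- reference[idx[2]] - reference[idx[1]]
    if (dx == 0) next
    sl <- (signal[idx[2]] - signal[idx[1]]) / dx
    ic <- signal[idx[1]] - sl * reference[idx[1]]
    res <- signal - (sl * reference + ic)
    mask <- abs(res) <= thr
    cnt <- sum(mask)
    if (cnt > best_count) { best_count <- cnt; best_mask <- mask }
  }
  if (is.null(best_mask) || best_count < 2) {
    warning("RANSAC found no consensus; falling back to least squares")
    best_mask <- rep(TRUE, n)
  }
  fit <- stats::lm.fit(cbind(1, reference[best_mask]), signal[best_mask])
  slope <- unname(fit$coefficients[2]); intercept <- unname(fit$coefficients[1])
  pred <- slope * reference + intercept
  ss_res <- sum((signal[best_mask] - pred[best_mask])^2)
  ss_tot <- sum((signal[best_mask] - mean(signal[best_mask]))^2)
  frac <- mean(best_mask)
  if (frac < config$inlier_floor)
    warning(sprintf("RANSAC inlier fraction %.2f below floor %.2f",
                    frac, config$inlier_floor))
  list(slope = slope, intercept = intercept, inliers = best_mask,
       inlier_fraction = frac,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Motion-corrected dF/F
#'
#' `dff = (signal - fitted_reference) / fitted_reference`, elementwise.
#' The denominator is the scaled reference, the standard convention for
#' isosbestic correction.
#'
#' @param signal Signal-channel trace.
#' @param fitted_reference Scaled reference trace; must be strictly
#'   positive.
#' @return dF/F trace.
#' @export
compute_dff <- function(signal, fitted_reference) {
  bad <- fitted_reference <= 0
  if (any(bad))
    stop(sprintf("fitted reference non-positive at %d sample(s)", sum(bad)))
  (signal - fitted_reference) / fitted_reference
}

#' Within-animal session z-scoring
#'
#' Subtracts the animal's session mean and divides by the session SD,
#' pooling both hemispheres of the animal so between-hemisphere offsets
#' are preserved in z units.
#'
#' @param dff_list A numeric trace, or a named list of traces (one per
#'   hemisphere) for one animal.
#' @return Same shape as the input, z-scored with pooled statistics.
#' @export
zscore_within_animal <- function(dff_list) {
  single <- is.numeric(dff_list)
  traces <- if (single) list(dff_list) else dff_list
  pooled <- unlist(traces, use.names = FALSE)
  m <- mean(pooled)
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score session")
  out <- lapply(traces, function(x) (x - m) / s)
  if (single) out[[1]] else out
}

#' One-dimensional Gaussian smoothing
#'
#' Discrete Gaussian convolution with a kernel truncated at 4 sigma and
#' normalized to unit mass, with reflection padding. `sigma = 0` returns
#' the input unchanged.
#'
#' @param x Numeric trace.
#' @param sigma Kernel SD in samples.
#' @return Smoothed trace, same length.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  idx_pre <- pmin(pmax(seq(half, 1), 1), n)
  idx_post <- pmin(pmax(seq(n, n - half + 1), 1), n)
  ext <- c(x[idx_pre], x, x[idx_post])
  y <- stats::filter(ext, k, sides = 2)
  as.numeric(y[seq(half + 1, half + n)])
}

#' Gaussian smoothing kernel (internal convention, exposed for tests)
#' @param sigma SD in samples.
#' @return Normalized kernel vector.
#' @export
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# ---- full preprocessing pipeline -------------------------------------------

#' Preprocess a photometry session to a z-scored dF/F trace
#'
#' Pipeline order: low-pass both channels (zero-phase Butterworth at the
#' native rate) -> RANSAC-fit the reference to the signal -> subtract the
#' scaled reference and divide by it (dF/F) -> z-score within animal
#' across the whole session (pooling hemispheres when several sessions
#' from one animal are passed together via [preprocess_animal()]).
#' Per-window Gaussian smoothing happens at peri-event extraction.
#'
#' @param session A `photometry_session`.
#' @param config A [preprocess_config()].
#' @param zscore Whether to z-score here (set `FALSE` when pooling
#'   hemispheres via [preprocess_animal()]).
#' @return data.frame of class `processed_trace`: `time`, `dff`, `zdff`
#'   with attributes `fit` (slope, intercept, inlier_fraction,
#'   r_squared), `session_stats` (mean, sd of dff), `animal`, `hemisphere`,
#'   `rate`.
#' @export
preprocess_photometry <- function(session, config = preprocess_config(),
                                  zscore = TRUE) {
  ch <- photometry_channels(session)
  rate <- session$rate
  if (config$lowpass_cutoff >= 0.45 * rate)
    stop(sprintf("lowpass cutoff %.3g Hz too close to the %.3g Hz channel rate",
                 config$lowpass_cutoff, rate))
  sig <- lowpass_zero_phase(ch$signal, config$lowpass_cutoff, rate,
                            config$filter_order)
  ref <- lowpass_zero_phase(ch$reference, config$lowpass_cutoff, rate,
                            config$filter_order)
  fit <- fit_isosbestic(ref, sig, config)
  fitted <- fit$slope * ref + fit$intercept
  dff <- compute_dff(sig, fitted)
  zdff <- if (zscore) zscore_within_animal(dff) else rep(NA_real_, length(dff))
  out <- data.frame(time = ch$time, dff = dff, zdff = zdff)
  attr(out, "fit") <- fit[c("slope", "intercept", "inlier_fraction",
                            "r_squared")]
  attr(out, "session_stats") <- c(mean = mean(dff), sd = stats::sd(dff))
  attr(out, "animal") <- session$animal
  attr(out, "hemisphere") <- session$hemisphere
  attr(out, "rate") <- rate
  class(out) <- c("processed_trace", "data.frame")
  out
}

#' Preprocess all hemispheres of one animal with pooled z-scoring
#'
#' @param sessions List of `photometry_session` objects from one animal
#'   (typically left and right hemispheres).
#' @param config A [preprocess_config()].
#' @return List of `processed_trace` objects, z-scored with the animal's
#'   pooled dF/F mean and SD.
#' @export
preprocess_animal <- function(sessions, config = preprocess_config()) {
  traces <- lapply(sessions, preprocess_photometry, config = config,
                   zscore = FALSE)
  z <- zscore_within_animal(lapply(traces, function(tr) tr$dff))
  for (i in seq_along(traces)) traces[[i]]$zdff <- z[[i]]
  traces
}

#' Write a processed trace as tidy CSV
#' @param trace A `processed_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(animal = attr(trace, "animal"),
                   hemisphere = attr(trace, "hemisphere"),
                   time = trace$time, dff = trace$dff, zdff = trace$zdff)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
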