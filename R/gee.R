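#' GEE model specification
#'
#' Sequence-specific zdF/F time courses are modeled as
#' `zdff ~ type + bs(time, df) + type:bs(time, df)` with a Gaussian
#' family, identity link, AR(1) working correlation over the bins of each
#' peri-event unit, and robust sandwich covariance. With the default
#' `spline_df = 4` and three sequence levels the design has
#' `1 + 2 + 4 + 8 = 15` columns.
#'
#' @param spline_df Cubic B-spline degrees of freedom over bin time
#'   (default 4; knots by quantiles, intercept excluded from the basis).
#' @param sequence_levels Sequence types entering the model
#'   (default `c("CC", "NoGo", "Go")`; CO is excluded from photometry
#'   analysis).
#' @return List of class `gee_spec`.
#' @export
gee_spec <- function(spline_df = 4,
                     sequence_levels = c("CC", "NoGo", "Go")) {
  if (spline_df < 2) stop("spline_df must be >= 2")
  if (length(sequence_levels) < 2) stop("need >= 2 sequence levels")
  structure(list(spline_df = spline_df,
                 sequence_levels = sequence_levels,
                 family = "gaussian", link = "identity",
                 correlation = "ar1", covariance = "robust"),
            class = "gee_spec")
}

#' Build the spline-by-sequence design matrix
#'
#' Columns: intercept, `levels - 1` type indicators (reference = first
#' level), `spline_df` B-spline time columns, and all type-by-spline
#' interactions. Rows are unit x bin observations grouped by unit.
#'
#' @param units A `perievent_units` table (90 bins per unit).
#' @param spec A [gee_spec()].
#' @return List with `X` (design matrix), `y` (response), `id` (unit
#'   grouping factor, rows ordered by unit then bin), `time` (bin time),
#'   `type` (per-row), and `columns` (names).
#' @export
build_design <- function(units, spec = gee_spec()) {
  u <- units[units$sequence_type %in% spec$sequence_levels, ]
  present <- unique(u$sequence_type)
  missing <- setdiff(spec$sequence_levels, present)
  if (length(missing) > 0)
    stop("sequence level(s) with zero units: ",
         paste(missing, collapse = ", "))
  key <- interaction(u$animal, u$hemisphere, u$event, u$sequence_type,
                     drop = TRUE)
  ord <- order(key, u$bin)
  u <- u[ord, ]; key <- droplevels(key[ord])
  type <- factor(u$sequence_type, levels = spec$sequence_levels)
  B <- splines::bs(u$bin_time, df = spec$spline_df, intercept = FALSE)
  colnames(B) <- paste0("s", seq_len(ncol(B)))
  Tm <- stats::model.matrix(~type)[, -1, drop = FALSE]
  colnames(Tm) <- paste0("type", spec$sequence_levels[-1])
  inter <- do.call(cbind, lapply(seq_len(ncol(Tm)), function(j) {
    M <- B * Tm[, j]
    colnames(M) <- paste0(colnames(Tm)[j], ":", colnames(B))
    M
  }))
  X <- cbind(`(Intercept)` = 1, Tm, B, inter)
  list(X = X, y = u$zdff, id = key, time = u$bin_time,
       type = as.character(type), columns = colnames(X),
       animal = u$animal)
}

# AR(1) whitening of stacked cluster data: within each cluster,
# u_1 = x_1, u_t = (x_t - rho x_{t-1}) / sqrt(1 - rho^2)
ar1_whiten <- function(M, id, rho) {
  M <- as.matrix(M)
  n <- nrow(M)
  first <- !duplicated(id)
  lag <- rbind(0, M[-n, , drop = FALSE])
  W <- (M - rho * lag) / sqrt(1 - rho^2)
  W[first, ] <- M[first, , drop = FALSE]
  W
}

#' Fit a Gaussian GEE with AR(1) working correlation
#'
#' Iterates generalized least squares with moment estimation of the
#' dispersion and the lag-1 working correlation (Liang-Zeger estimators),
#' solving each step by per-cluster AR(1) whitening. Returns robust
#' (sandwich) covariance.
#'
#' The sandwich meat uses the Mancl-DeRouen bias correction by default
#' (`correction = "md"`): within each cluster the whitened residuals are
#' inflated by the inverse of `I - H_ii` (the cluster leverage), removing
#' the downward bias of order p/K that makes the uncorrected robust
#' covariance liberal with tens of clusters. `correction = "none"` gives
#' the classical Liang-Zeger sandwich.
#'
#' @param design Output of [build_design()] (or a compatible list with
#'   `X`, `y`, `id`).
#' @param maxit,tol Iteration controls.
#' @param correction Sandwich small-sample correction, `"md"` (default)
#'   or `"none"`.
#' @return Object of class `gee_fit`: `coefficients`, `vcov` (sandwich),
#'   `vcov_model` (model-based), `rho` (working AR(1) parameter), `phi`
#'   (dispersion), `n_units`, `n_obs`, `columns`, `converged`,
#'   `iterations`.
#' @export
fit_gee <- function(design, maxit = 25, tol = 1e-8,
                    correction = c("md", "none")) {
  correction <- match.arg(correction)
  X <- design$X; y <- design$y; id <- design$id
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  rho <- 0
  n <- length(y)
  first <- !duplicated(id)
  n_units <- sum(first)
  K1 <- n - n_units                       # sum over clusters of (n_i - 1)
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    lagpair <- e[-1] * e[-n]
    lagpair[first[-1]] <- 0               # do not cross cluster boundaries
    rho_new <- sum(lagpair) / ((K1 - p) * phi)
    rho_new <- max(min(rho_new, 0.999), -0.999)
    Xw <- ar1_whiten(X, id, rho_new)
    yw <- ar1_whiten(y, id, rho_new)
    fitw <- stats::lm.fit(Xw, yw)
    beta_new <- fitw$coefficients
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new; rho <- rho_new
    if (delta < tol) { converged <- TRUE; break }
  }
  Xw <- ar1_whiten(X, id, rho)
  yw <- ar1_whiten(y, id, rho)
  ew <- yw - Xw %*% beta
  e <- y - X %*% beta
  phi <- sum(e^2) / (n - p)
  bread <- crossprod(Xw)
  bread_inv <- chol2inv(chol(bread))
  if (correction == "md") {
    # Mancl-DeRouen: inflate each cluster's whitened residuals by
    # (I - H_ii)^{-1} before forming the scores
    idx_list <- split(seq_len(n), id)
    scores <- matrix(0, length(idx_list), p)
    for (k in seq_along(idx_list)) {
      idx <- idx_list[[k]]
      Xi <- Xw[idx, , drop = FALSE]
      Hii <- Xi %*% bread_inv %*% t(Xi)
      ei_adj <- solve(diag(length(idx)) - Hii, ew[idx])
      scores[k, ] <- crossprod(Xi, ei_adj)
    }
  } else {
    scores <- rowsum(as.matrix(Xw * as.numeric(ew)), group = id)
  }
  meat <- crossprod(scores)
  vcov_rob <- bread_inv %*% meat %*% bread_inv
  dimnames(vcov_rob) <- list(colnames(X), colnames(X))
  vcov_mod <- phi * bread_inv
  dimnames(vcov_mod) <- dimnames(vcov_rob)
  structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 vcov = vcov_rob, vcov_model = vcov_mod, rho = rho,
                 phi = phi, n_units = n_units, n_obs = n,
                 columns = colnames(X), converged = converged,
                 iterations = it, design = design),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE, AR(1) working correlation: rho = %.4f, phi = %.4g\n",
              x$rho, x$phi))
  cat(sprintf("  %d observations in %d units; converged: %s (%d iterations)\n",
              x$n_obs, x$n_units, x$converged, x$iterations))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, robust_se = se))
  invisible(x)
}

#' Joint Wald chi-square test on a coefficient block
#'
#' `chi^2 = beta_s' V_s^{-1} beta_s` over the selected columns using the
#' robust sandwich covariance; df equals the block size.
#'
#' With few clusters the naive chi-square reference for a sandwich-based
#' Wald statistic is markedly liberal; by default the p-value therefore
#' uses the Hotelling-type small-sample reference
#' `W (K - p) / ((K - 1) p) ~ F(p, K - p)` (K = clusters, p = block
#' size), which converges to the chi-square reference as K grows.
#' Set `small_sample = FALSE` for the asymptotic chi-square p-value.
#'
#' @param fit A `gee_fit`.
#' @param columns Character vector of coefficient names, or one of the
#'   scopes `"interaction"` (all type-by-spline columns),
#'   `"type"` (type mains + interactions), `"all"` (all non-intercept).
#' @param small_sample Use the F-reference p-value (default TRUE).
#' @return List of class `wald_result`: `statistic`, `df`, `p`, `columns`.
#' @export
wald_joint <- function(fit, columns = "interaction", small_sample = TRUE) {
  if (length(columns) == 1 && columns %in% c("interaction", "type", "all")) {
    nm <- fit$columns
    columns <- switch(columns,
      interaction = grep("^type.*:", nm, value = TRUE),
      type = grep("^type", nm, value = TRUE),
      all = setdiff(nm, "(Intercept)"))
  }
  if (length(columns) == 0) stop("empty column selection")
  if (!all(columns %in% fit$columns))
    stop("unknown column(s): ",
         paste(setdiff(columns, fit$columns), collapse = ", "))
  b <- fit$coefficients[columns]
  V <- fit$vcov[columns, columns, drop = FALSE]
  if (fit$n_units <= length(columns) ||
      rcond(V) < .Machine$double.eps * 1e3)
    stop(sprintf(paste0(
      "robust covariance block is (near-)singular: %d clusters cannot ",
      "support a joint test of %d coefficients"),
      fit$n_units, length(columns)))
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(columns)
  K <- fit$n_units
  p <- if (small_sample && K > df + 1) {
    stats::pf(stat * (K - df) / ((K - 1) * df), df, K - df,
              lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = df, p = p, columns = columns,
                 reference = if (small_sample) "F" else "chisq"),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Joint Wald test: chi2(%d) = %.4g, p = %.4g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

#' Model-predicted time courses per sequence type
#'
#' @param fit A `gee_fit`.
#' @return data.frame with `sequence_type`, `bin_time`, `predicted`.
#' @export
predict_timecourse <- function(fit) {
  d <- fit$design
  df <- data.frame(type = d$type, time = d$time)
  pred <- as.numeric(d$X %*% fit$coefficients)
  agg <- stats::aggregate(pred, by = list(sequence_type = df$type,
                                          bin_time = df$time), FUN = mean)
  names(agg)[3] <- "predicted"
  agg[order(agg$sequence_type, agg$bin_time), ]
}
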