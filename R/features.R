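#' Detect the eCAP threshold
#'
#' The threshold is the lowest measured stimulation level whose eCAP
#' amplitude meets the criterion (5 uV or larger by default, boundary
#' inclusive). Only measured points are consulted; no interpolation or
#' fit-based extrapolation. When no point meets the criterion the result is
#' a "no threshold" record (not an exception), which downstream stages
#' propagate as a missing dependent variable.
#'
#' @param io an [io_function()].
#' @param criterion amplitude criterion in uV.
#' @param law a [device_law()] for the charge conversions.
#' @return List with `found`, `level` (native level unit), `charge_nc`,
#'   `charge_db` (dB re 1 nC), and `criterion`.
#' @export
detect_threshold <- function(io, criterion = 5, law = device_law()) {
  if (!inherits(io, "ecap_io")) stop_config("`io` must be an ecap_io")
  check_number(criterion, "criterion", 0, strict = TRUE)
  hit <- which(io$amplitudes >= criterion)
  if (length(hit) == 0)
    return(list(found = FALSE, level = NA_real_, charge_nc = NA_real_,
                charge_db = NA_real_, criterion = criterion))
  level <- io$levels[min(hit)]
  current <- if (io$level_unit == "uA") level else cl_to_current(level, law)
  charge <- current_to_charge(current, io$phase_duration)
  list(found = TRUE, level = level, charge_nc = charge,
       charge_db = to_db(charge, 1), criterion = criterion)
}

#' Maximum eCAP amplitude
#'
#' The maximum over measured amplitudes, reported in uV and dB re 1 uV.
#'
#' @param io an [io_function()].
#' @return List with `uv` and `db` (NA dB when the maximum is 0).
#' @export
max_amplitude <- function(io) {
  if (!inherits(io, "ecap_io")) stop_config("`io` must be an ecap_io")
  m <- max(io$amplitudes)
  list(uv = m, db = if (m > 0) to_db(m, 1) else NA_real_)
}

#' Dynamic range of an I/O function
#'
#' Stimulation-level span between the eCAP threshold and the maximum
#' comfortable (C) level, in native level units (CL steps).
#'
#' @param io an [io_function()].
#' @param criterion threshold criterion in uV.
#' @return The level difference, or `NA` when no threshold exists.
#' @export
dynamic_range <- function(io, criterion = 5) {
  thr <- detect_threshold(io, criterion)
  if (!thr$found) return(NA_real_)
  io$c_level - thr$level
}

# Closed-form OLS slope (covariance over variance); x must vary.
ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Overall linear slope of an I/O function
#'
#' Ordinary least-squares slope over all points measured between the
#' threshold level and the C level (both inclusive), on the working scale
#' of `sio`. Returns `NA` with a reason attribute when fewer than two
#' points fall in the window.
#'
#' @param sio a `scaled_io` from [transform_io()].
#' @param threshold_level threshold stimulation level (native level units).
#' @param c_level maximum comfortable level.
#' @export
overall_linear_slope <- function(sio, threshold_level, c_level) {
  if (!inherits(sio, "scaled_io")) stop_config("`sio` must be a scaled_io")
  if (is.na(threshold_level))
    return(structure(NA_real_, reason = "no threshold"))
  keep <- sio$level >= threshold_level & sio$level <= c_level
  if (sum(keep) < 2)
    return(structure(NA_real_, reason = "fewer than 2 points between threshold and C level"))
  ols_slope(sio$x[keep], sio$y[keep])
}

#' Resample an I/O function to equally spaced input values
#'
#' Piecewise-linear interpolation at `n` equally spaced values spanning
#' `[min(x), max(x)]`; the endpoints are reproduced exactly. Linear
#' interpolation is monotone and cannot overshoot the measured amplitudes.
#'
#' @param sio a `scaled_io`.
#' @param n number of resampled points (>= 2); 11 for the window method.
#' @return A `scaled_io` on the resampled grid.
#' @export
resample_io <- function(sio, n = 11) {
  if (!inherits(sio, "scaled_io")) stop_config("`sio` must be a scaled_io")
  if (n < 2) stop_config("`n` must be >= 2")
  if (length(sio$x) < 2) stop_config("resampling needs >= 2 points")
  xi <- seq(min(sio$x), max(sio$x), length.out = n)
  yi <- stats::approx(sio$x, sio$y, xout = xi, method = "linear",
                      ties = "ordered")$y
  out <- sio
  out$x <- xi
  out$y <- yi
  out$level <- stats::approx(sio$x, sio$level, xout = xi, method = "linear",
                             ties = "ordered")$y
  out$charge_nc <- NULL
  out$resampled <- TRUE
  out
}

#' Maximum slope by the sliding-window method
#'
#' The I/O function is resampled to `n_points` (11) equally spaced input
#' values; a linear regression is fitted in every contiguous window of
#' `window` (4) consecutive points (unit stride, so 11 points give exactly 8
#' windows); the maximum slope across windows is returned. Ties are broken
#' toward the window at lower stimulation levels. This estimator tracks the
#' growth function's first derivative at its steepest (inflection) region
#' and remains stable when the measured range stops short of saturation,
#' where sigmoidal fits can fail to converge.
#'
#' @param sio a `scaled_io`.
#' @param n_points resampling grid size.
#' @param window points per regression window.
#' @return The maximum slope, with attributes `window_index` (1-based start
#'   of the winning window) and `slopes` (all window slopes). `NA` with a
#'   reason when fewer than `window` points are available.
#' @export
max_slope_window <- function(sio, n_points = 11, window = 4) {
  if (window < 2) stop_config("`window` must be >= 2")
  if (n_points < window)
    return(structure(NA_real_, reason = "fewer resampled points than window size"))
  if (length(sio$x) < 2)
    return(structure(NA_real_, reason = "fewer than 2 measured points"))
  rs <- resample_io(sio, n_points)
  n_win <- n_points - window + 1L
  slopes <- vapply(seq_len(n_win), function(i) {
    idx <- i:(i + window - 1L)
    ols_slope(rs$x[idx], rs$y[idx])
  }, numeric(1))
  best <- which.max(slopes)  # which.max takes the first maximum: lower-level window on ties
  structure(slopes[best], window_index = best, slopes = slopes)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) * (n - 1) / (n - k - 1)` for a model with `k` parameters
#' fitted to `n` observations. Undefined (NA) when `n <= k + 1` or the
#' response is constant.
#'
#' @param residuals model residuals.
#' @param y observed response (for the total sum of squares).
#' @param k number of model parameters.
#' @export
adjusted_r2 <- function(residuals, y, k) {
  n <- length(y)
  if (n != length(residuals)) stop_config("`residuals` and `y` must match")
  if (n <= k + 1) return(NA_real_)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  r2 <- 1 - sum(residuals^2) / sst
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# Shared scaffolding for the two nonlinear growth-model fits, built on the
# Levenberg-Marquardt core (minpack.lm::nls.lm) with analytic Jacobians; the
# raw core handles exact zero-residual fits that the nls-object wrappers
# reject.
growth_fit_failed <- function(sio, par_names, reason, class) {
  out <- as.list(rep(NA_real_, length(par_names)))
  names(out) <- par_names
  out$converged <- FALSE
  out$at_bound <- FALSE
  out$adj_r2 <- NA_real_
  out$r2 <- NA_real_
  out$n <- length(sio$y)
  out$scale <- sio$spec$label
  out$reason <- reason
  structure(out, class = class)
}

finish_growth_fit <- function(fit, sio, k, upper, class) {
  x <- sio$x; y <- sio$y
  par_names <- names(upper)
  if (inherits(fit, "try-error"))
    return(growth_fit_failed(sio, par_names, as.character(fit), class))
  cf <- fit$par
  names(cf) <- par_names
  res <- fit$fvec
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  at_bound <- any(abs(cf - upper) < 1e-8 * pmax(1, abs(upper)), na.rm = TRUE)
  at_lower <- cf[["a"]] <= 2e-12 ||
    ("c" %in% par_names && cf[["c"]] <= 2e-12) ||
    (class == "exp_fit" && cf[["b"]] <= 2e-12)
  out <- as.list(cf)
  out$converged <- all(is.finite(cf)) && fit$info %in% 1:4 && !at_lower
  out$at_bound <- at_bound
  out$adj_r2 <- adjusted_r2(res, y, k)
  out$r2 <- r2
  out$n <- length(y)
  out$scale <- sio$spec$label
  out$fitted <- y - res
  out$reason <- if (fit$info %in% 1:4) NA_character_ else fit$message
  structure(out, class = class)
}

#' Fit the sigmoidal growth model
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `y = y0 + a / (1 + exp(-(x - b) / c))`. Initial values: `y0 = min(y)`,
#' `a = range(y)`, `b` = x nearest the half-range crossing,
#' `c = range(x) / 8`; `a` and `c` are bounded below by a small positive
#' value, `c` above by `50 * range(x)` and `a` above by `100 * range(y)` --
#' degenerate shapes (effectively linear or purely exponential data, which
#' the sigmoid only fits in a parameter limit) push `c` or `a` onto a bound,
#' which is flagged via `at_bound` rather than hidden.
#' Non-convergence never throws: the result carries `converged = FALSE` and
#' a reason.
#'
#' @param sio a `scaled_io` (>= 5 points; the model has 4 parameters).
#' @param max_iter,ftol Levenberg-Marquardt iteration cap and relative
#'   residual tolerance.
#' @return A `sigmoid_fit`: parameters `y0, a, b, c`, `adj_r2`, `r2`,
#'   `converged`, `at_bound`, `n`, `scale`, `fitted`.
#' @export
fit_sigmoid <- function(sio, max_iter = 500, ftol = 1e-12) {
  if (!inherits(sio, "scaled_io")) stop_config("`sio` must be a scaled_io")
  x <- sio$x; y <- sio$y
  rng <- max(y) - min(y)
  upper <- c(y0 = Inf, a = max(100 * rng, 1e-6), b = Inf,
             c = 50 * max(diff(range(x)), 1))
  if (length(x) < 5)
    return(growth_fit_failed(sio, names(upper),
                             "insufficient data: sigmoid fit needs >= 5 points",
                             "sigmoid_fit"))
  if (rng == 0)
    return(growth_fit_failed(sio, names(upper),
                             "constant response: amplitude range is degenerate",
                             "sigmoid_fit"))
  b0 <- x[which.min(abs(y - (min(y) + rng / 2)))]
  start <- c(y0 = min(y), a = rng, b = b0,
             c = max(diff(range(x)) / 8, 1e-6))
  resid_fn <- function(p) y - (p[1] + p[2] / (1 + exp(-(x - p[3]) / p[4])))
  jac_fn <- function(p) {
    z <- (x - p[3]) / p[4]
    s <- 1 / (1 + exp(-z))
    dz <- s * (1 - s)
    -cbind(1, s, -p[2] * dz / p[4], -p[2] * dz * z / p[4])
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn, jac = jac_fn,
    lower = c(-Inf, 1e-12, -Inf, 1e-12), upper = unname(upper),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = ftol, maxfev = 100000)),
    silent = TRUE)
  finish_growth_fit(fit, sio, 4, upper, "sigmoid_fit")
}

#' Fit the saturating exponential growth model
#'
#' Nonlinear least squares fit of `y = y0 + a * (1 - exp(-b * x))`, the
#' alternative model used to score whether a growth function has an
#' exponential rather than sigmoidal profile on the log/log scale.
#'
#' @param sio a `scaled_io` (>= 4 points; the model has 3 parameters).
#' @param max_iter,ftol Levenberg-Marquardt controls.
#' @return An `exp_fit`: parameters `y0, a, b`, `adj_r2`, `r2`, `converged`,
#'   `at_bound`, `n`, `scale`, `fitted`.
#' @export
fit_exponential <- function(sio, max_iter = 500, ftol = 1e-12) {
  if (!inherits(sio, "scaled_io")) stop_config("`sio` must be a scaled_io")
  x <- sio$x; y <- sio$y
  upper <- c(y0 = Inf, a = Inf, b = Inf)
  if (length(x) < 4)
    return(growth_fit_failed(sio, names(upper),
                             "insufficient data: exponential fit needs >= 4 points",
                             "exp_fit"))
  rng <- max(y) - min(y)
  if (rng == 0)
    return(growth_fit_failed(sio, names(upper),
                             "constant response: amplitude range is degenerate",
                             "exp_fit"))
  xspan <- max(abs(range(x)))
  start <- c(y0 = min(y), a = rng, b = 2 / max(xspan, 1e-6))
  resid_fn <- function(p) y - (p[1] + p[2] * (1 - exp(-p[3] * x)))
  jac_fn <- function(p) {
    e <- exp(-p[3] * x)
    -cbind(1, 1 - e, p[2] * x * e)
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn, jac = jac_fn,
    lower = c(-Inf, 1e-12, 1e-12), upper = unname(upper),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = ftol, maxfev = 100000)),
    silent = TRUE)
  finish_growth_fit(fit, sio, 3, upper, "exp_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit (%s): y0=%.4g a=%.4g b=%.4g c=%.4g, adjR2=%.4f, converged=%s%s\n",
              x$scale, x$y0, x$a, x$b, x$c, x$adj_r2, x$converged,
              if (isTRUE(x$at_bound)) " [at bound]" else ""))
  invisible(x)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit (%s): y0=%.4g a=%.4g b=%.4g, adjR2=%.4f, converged=%s%s\n",
              x$scale, x$y0, x$a, x$b, x$adj_r2, x$converged,
              if (isTRUE(x$at_bound)) " [at bound]" else ""))
  invisible(x)
}

#' Classify the log/log shape of an I/O function
#'
#' Growth functions that look sigmoidal on linear axes can transition to an
#' exponential profile when re-displayed on the log/log (S3) scale; the
#' compressive log transform of an approximately linear function is convex.
#' This classifier replaces visual inspection with an adjusted-R-squared
#' margin: the function is labelled `"exponential-transitioned"` when the
#' exponential model outperforms the sigmoid on the S3-transformed
#' coordinates by more than `margin`, `"unchanged"` otherwise, and
#' `"unclassified"` when either fit is unusable.
#'
#' @param io an [io_function()].
#' @param phase phase duration in us.
#' @param margin adjusted-R-squared margin (default 0.01).
#' @param law a [device_law()].
#' @return List with `label`, `adj_r2_sigmoid`, `adj_r2_exponential`,
#'   `margin`, and the two fits.
#' @export
classify_shape <- function(io, phase = io$phase_duration, margin = 0.01,
                           law = device_law()) {
  sio3 <- suppressWarnings(transform_io(io, scale_spec("S3"), phase, law))
  fs <- suppressWarnings(fit_sigmoid(sio3))
  fe <- suppressWarnings(fit_exponential(sio3))
  # a fit stopped at the iteration cap still carries its goodness of fit;
  # only fits without a usable score leave the function unclassified
  usable <- function(f) is.finite(f$adj_r2) && isTRUE(f$a > 0)
  if (!usable(fs) || !usable(fe))
    return(list(label = "unclassified", adj_r2_sigmoid = fs$adj_r2,
                adj_r2_exponential = fe$adj_r2, margin = margin,
                sigmoid = fs, exponential = fe))
  label <- if (fe$adj_r2 - fs$adj_r2 > margin) "exponential-transitioned" else "unchanged"
  list(label = label, adj_r2_sigmoid = fs$adj_r2,
       adj_r2_exponential = fe$adj_r2, margin = margin,
       sigmoid = fs, exponential = fe)
}

#' Extract all per-function features
#'
#' One row per I/O function: threshold (nC and dB re 1 nC), maximum
#' amplitude (uV and dB re 1 uV), dynamic range (level steps), and the
#' overall and window-method maximum slopes on each of the three analysis
#' scales, plus the log/log shape label.
#'
#' @param io an [io_function()].
#' @param phase phase duration in us.
#' @param criterion threshold criterion in uV.
#' @param law a [device_law()].
#' @return A one-row data.frame.
#' @export
io_features <- function(io, phase = io$phase_duration, criterion = 5,
                        law = device_law()) {
  thr <- detect_threshold(io, criterion, law)
  ma <- max_amplitude(io)
  out <- data.frame(subject = io$subject, electrode = io$electrode,
                    ipg_us = io$ipg,
                    threshold_level = thr$level,
                    threshold_nc = thr$charge_nc,
                    threshold_db = thr$charge_db,
                    max_amplitude_uv = ma$uv, max_amplitude_db = ma$db,
                    dynamic_range = dynamic_range(io, criterion),
                    stringsAsFactors = FALSE)
  for (lab in c("S1", "S2", "S3")) {
    sio <- suppressWarnings(transform_io(io, scale_spec(lab), phase, law))
    overall <- overall_linear_slope(sio, thr$level, io$c_level)
    mx <- max_slope_window(sio)
    out[[paste0("overall_slope_", lab)]] <- as.numeric(overall)
    out[[paste0("max_slope_", lab)]] <- as.numeric(mx)
  }
  out$shape_s3 <- classify_shape(io, phase, law = law)$label
  out
}
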