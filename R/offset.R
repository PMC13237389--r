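#' Normalize a paired-IPG set of I/O functions
#'
#' Both amplitude vectors are divided by the maximum measured amplitude of
#' the 7-us-IPG function (before any output-scale log transform), so the
#' normalized IPG-7 function peaks at exactly 1 and IPG-42 amplitudes may
#' exceed 1. The normalized functions are then re-expressed on the working
#' scale.
#'
#' @param io7,io42 [io_function()]s for the short and long IPG; same
#'   subject/electrode.
#' @param spec a [scale_spec()].
#' @param phase phase duration in us.
#' @param law a [device_law()].
#' @return A `normalized_pair`: `sio7`, `sio42` (scaled_io on normalized
#'   amplitudes), `normalizer` (uV), `spec`.
#' @export
normalize_pair <- function(io7, io42, spec, phase = io7$phase_duration,
                           law = device_law()) {
  if (!inherits(io7, "ecap_io") || !inherits(io42, "ecap_io"))
    stop_config("`io7` and `io42` must be ecap_io objects")
  if (!identical(io7$subject, io42$subject) ||
      !identical(io7$electrode, io42$electrode))
    stop_config("paired I/O functions must share subject and electrode")
  normalizer <- max(io7$amplitudes)
  if (normalizer <= 0) stop_config("IPG-7 maximum amplitude is zero; cannot normalize")
  sio7 <- transform_io(io7, spec, phase, law,
                       amplitudes = io7$amplitudes / normalizer)
  sio42 <- transform_io(io42, spec, phase, law,
                        amplitudes = io42$amplitudes / normalizer)
  structure(list(sio7 = sio7, sio42 = sio42, normalizer = normalizer,
                 spec = spec, subject = io7$subject, electrode = io7$electrode),
            class = "normalized_pair")
}

#' Invert a fitted sigmoid at a target amplitude
#'
#' Closed form: `x = b - c * log(a / (y - y0) - 1)`. The target must lie
#' strictly between the fitted baseline `y0` and ceiling `y0 + a`.
#'
#' @param fit a `sigmoid_fit` (converged).
#' @param y_target amplitude(s) on the fit's working output scale.
#' @export
invert_sigmoid <- function(fit, y_target) {
  if (!inherits(fit, "sigmoid_fit")) stop_config("`fit` must be a sigmoid_fit")
  if (!isTRUE(fit$converged)) stop_config("cannot invert a non-converged sigmoid fit")
  if (any(y_target <= fit$y0) || any(y_target >= fit$y0 + fit$a))
    stop_config("target amplitude outside the open range (y0, y0 + a)")
  fit$b - fit$c * log(fit$a / (y_target - fit$y0) - 1)
}

#' Stimulation level offset between IPG conditions
#'
#' Fits the sigmoidal growth model to the normalized functions at both
#' IPGs, finds the overlap of the two fitted amplitude ranges (each range
#' evaluated over that function's measured level span), takes amplitude
#' targets at 25/50/75% of the overlap, and inverts both sigmoids at each
#' target. The offset is the mean of the three per-target level differences
#' `level_IPG7(y) - level_IPG42(y)`: positive when the 42-us IPG reaches
#' the same normalized amplitude at a lower stimulation level (the long IPG
#' is more efficient). Quantile targets are taken on the working output
#' scale, i.e. in dB space for the dB-output variant.
#'
#' Any failure -- a non-converged fit or an empty overlap -- yields a
#' missing offset with a reason code, never an exception.
#'
#' @param pair a [normalize_pair()] result.
#' @param quantiles amplitude quantiles of the overlap interval.
#' @return An `offset_result`: `scale` (nC / dB_linear/log / dB_log/log),
#'   `offset`, `quantile_table` (target amplitude, level at each IPG,
#'   difference), `overlap` (interval endpoints), `fit7`, `fit42`,
#'   `normalizer`, `reason`.
#' @export
stimulation_level_offset <- function(pair, quantiles = c(0.25, 0.5, 0.75)) {
  if (!inherits(pair, "normalized_pair")) stop_config("`pair` must be a normalized_pair")
  miss <- function(reason, fit7 = NULL, fit42 = NULL) {
    structure(list(scale = pair$spec$offset_label, offset = NA_real_,
                   quantile_table = NULL, overlap = c(NA_real_, NA_real_),
                   fit7 = fit7, fit42 = fit42, normalizer = pair$normalizer,
                   quantiles = quantiles, reason = reason),
              class = "offset_result")
  }
  fit7 <- fit_sigmoid(pair$sio7)
  fit42 <- fit_sigmoid(pair$sio42)
  if (!isTRUE(fit7$converged)) return(miss("IPG-7 sigmoid fit did not converge", fit7, fit42))
  if (!isTRUE(fit42$converged)) return(miss("IPG-42 sigmoid fit did not converge", fit7, fit42))
  range7 <- sigmoid_growth(range(pair$sio7$x), fit7$y0, fit7$a, fit7$b, fit7$c)
  range42 <- sigmoid_growth(range(pair$sio42$x), fit42$y0, fit42$a, fit42$b, fit42$c)
  lo <- max(min(range7), min(range42))
  hi <- min(max(range7), max(range42))
  if (!(hi > lo)) return(miss("fitted amplitude ranges do not overlap", fit7, fit42))
  targets <- lo + quantiles * (hi - lo)
  x7 <- invert_sigmoid(fit7, targets)
  x42 <- invert_sigmoid(fit42, targets)
  tab <- data.frame(quantile = quantiles, target_amplitude = targets,
                    level_ipg7 = x7, level_ipg42 = x42, difference = x7 - x42)
  structure(list(scale = pair$spec$offset_label, offset = mean(tab$difference),
                 quantile_table = tab, overlap = c(lo, hi),
                 fit7 = fit7, fit42 = fit42, normalizer = pair$normalizer,
                 quantiles = quantiles, reason = NA_character_),
            class = "offset_result")
}

#' @export
print.offset_result <- function(x, ...) {
  if (is.na(x$offset)) {
    cat(sprintf("stimulation level offset (%s): missing (%s)\n", x$scale, x$reason))
  } else {
    cat(sprintf("stimulation level offset (%s): %.4g (overlap %.3g..%.3g)\n",
                x$scale, x$offset, x$overlap[1], x$overlap[2]))
    print(x$quantile_table, digits = 4)
  }
  invisible(x)
}

#' Stimulation level offsets on all three analysis scales
#'
#' Runs [normalize_pair()] + [stimulation_level_offset()] per scale, with
#' per-scale sigmoid fits on the transformed coordinates. Offsets are in nC
#' on S1 and in dB (input axis dB re 1 nC) on S2 and S3. Per-scale
#' missingness propagates independently.
#'
#' @param io7,io42 paired [io_function()]s.
#' @param phase phase duration in us.
#' @param law a [device_law()].
#' @param quantiles amplitude quantiles of the overlap interval.
#' @return Named list of three `offset_result`s (`S1`, `S2`, `S3`).
#' @export
offset_all_scales <- function(io7, io42, phase = io7$phase_duration,
                              law = device_law(),
                              quantiles = c(0.25, 0.5, 0.75)) {
  out <- lapply(c("S1", "S2", "S3"), function(lab) {
    pair <- suppressWarnings(
      normalize_pair(io7, io42, scale_spec(lab), phase, law))
    stimulation_level_offset(pair, quantiles)
  })
  names(out) <- c("S1", "S2", "S3")
  out
}
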