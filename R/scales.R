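#' Device current law
#'
#' Exponential mapping from the implant's integer current-level (CL) code to
#' current in uA: `I = coeff * base^(cl / cl_max)`. The default
#' (17.5 uA x 100^(CL/255)) is the manufacturer convention for the implant
#' family whose recordings this pipeline targets; it is configurable because
#' clinical reports state levels in CL and charge in nC without fixing the
#' law.
#'
#' @param coeff current at CL 0, in uA.
#' @param base dynamic span of the law (current multiplies by `base` from CL
#'   0 to CL `cl_max`).
#' @param cl_max top of the CL range.
#' @export
device_law <- function(coeff = 17.5, base = 100, cl_max = 255) {
  check_number(coeff, "coeff", 0, strict = TRUE)
  check_number(base, "base", 1, strict = TRUE)
  check_number(cl_max, "cl_max", 0, strict = TRUE)
  structure(list(coeff = coeff, base = base, cl_max = cl_max),
            class = "device_law")
}

#' Convert current-level code to current in uA
#'
#' @param cl current-level code(s) within `[0, cl_max]`.
#' @param law a [device_law()].
#' @export
cl_to_current <- function(cl, law = device_law()) {
  if (any(!is.finite(cl)) || any(cl < 0) || any(cl > law$cl_max))
    stop_config("CL out of device range [0, %g]", law$cl_max)
  law$coeff * law$base^(cl / law$cl_max)
}

#' Convert current to charge per phase
#'
#' Charge (nC) = current (uA) x phase duration (us) / 1000.
#'
#' @param current current in uA (>= 0).
#' @param phase phase duration in us (> 0).
#' @export
current_to_charge <- function(current, phase) {
  if (any(!is.finite(current)) || any(current < 0))
    stop_config("`current` must be finite and >= 0")
  check_number(phase, "phase", 0, strict = TRUE)
  current * phase / 1000
}

#' Amplitude-style decibel transform
#'
#' `20 * log10(value / reference)` by default; `convention = "power"` uses
#' 10 log10 for power-like quantities. Both stimulus charge and eCAP voltage
#' are amplitude-like here, so the dB re 1 nC and dB re 1 uV axes use the
#' 20-log convention.
#'
#' @param value positive quantity (vectorised).
#' @param reference positive reference in the same units.
#' @param convention `"amplitude"` (20 log10) or `"power"` (10 log10).
#' @export
to_db <- function(value, reference = 1, convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (any(!is.finite(value)) || any(value <= 0))
    stop_config("dB transform requires strictly positive values; exclude zero-amplitude points explicitly")
  check_number(reference, "reference", 0, strict = TRUE)
  k <- if (convention == "amplitude") 20 else 10
  k * log10(value / reference)
}

#' Input/output scale specification
#'
#' The three analysis scales: S1 = (nC in, uV out), S2 = (dB re 1 nC in, uV
#' out), S3 = (dB re 1 nC in, dB re 1 uV out). Constructed from a label or
#' from an input/output pair; the (nC in, dB out) combination has no
#' physiological rationale and is rejected.
#'
#' @param label one of `"S1"`, `"S2"`, `"S3"`, or `NULL` to give `input` /
#'   `output` explicitly.
#' @param input `"nC"` or `"dBC"` (dB re 1 nC).
#' @param output `"uV"` or `"dBV"` (dB re 1 uV).
#' @return A `scale_spec` with fields `input`, `output`, `label`, and
#'   `offset_label` (the naming used for stimulation-level-offset variants:
#'   nC, dB_linear/log, dB_log/log).
#' @export
scale_spec <- function(label = NULL, input = NULL, output = NULL) {
  if (!is.null(label)) {
    label <- match.arg(label, c("S1", "S2", "S3"))
    input <- switch(label, S1 = "nC", S2 = "dBC", S3 = "dBC")
    output <- switch(label, S1 = "uV", S2 = "uV", S3 = "dBV")
  } else {
    input <- match.arg(input, c("nC", "dBC"))
    output <- match.arg(output, c("uV", "dBV"))
    if (input == "nC" && output == "dBV")
      stop_config("the (nC input, dB re 1 uV output) scale is not supported")
    label <- if (input == "nC") "S1" else if (output == "uV") "S2" else "S3"
  }
  offset_label <- switch(label, S1 = "nC", S2 = "dB_linear/log", S3 = "dB_log/log")
  slope_unit <- switch(label, S1 = "uV/nC", S2 = "uV/dB re 1 nC",
                       S3 = "dB re 1 uV/dB re 1 nC")
  structure(list(input = input, output = output, label = label,
                 offset_label = offset_label, slope_unit = slope_unit),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("scale %s: input %s, output %s (offset label %s)\n",
              x$label, x$input, x$output, x$offset_label))
  invisible(x)
}

#' Re-express an I/O function on an analysis scale
#'
#' Converts the stimulation axis to charge per phase (nC) via the device law
#' (levels already in uA skip the law), applies the requested input/output
#' transforms, and returns the working coordinates that the slope, fit and
#' offset operations consume. Zero amplitudes cannot be represented on a dB
#' output axis; such points are dropped with a warning and recorded in the
#' result (`$dropped`), never silently.
#'
#' @param io an [io_function()].
#' @param spec a [scale_spec()].
#' @param phase phase duration in us; defaults to the value stored in `io`.
#' @param law a [device_law()].
#' @param amplitudes optional replacement amplitude vector (same length as
#'   `io$levels`), used by the offset module to transform normalized
#'   amplitudes while keeping the level axis of `io`.
#' @return A `scaled_io`: list with `x`, `y`, `level` (original level of each
#'   retained point), `charge_nc`, `spec`, `dropped` (data frame of excluded
#'   points), and provenance ids.
#' @export
transform_io <- function(io, spec, phase = io$phase_duration,
                         law = device_law(), amplitudes = NULL) {
  if (!inherits(io, "ecap_io")) stop_config("`io` must be an ecap_io")
  if (!inherits(spec, "scale_spec")) stop_config("`spec` must be a scale_spec")
  amp <- if (is.null(amplitudes)) io$amplitudes else as.numeric(amplitudes)
  if (length(amp) != length(io$levels))
    stop_config("`amplitudes` must match the number of levels")
  current <- if (io$level_unit == "uA") io$levels else cl_to_current(io$levels, law)
  charge <- current_to_charge(current, phase)
  x <- if (spec$input == "nC") charge else to_db(charge, 1)
  keep <- rep(TRUE, length(amp))
  if (spec$output == "dBV") keep <- amp > 0
  dropped <- data.frame(level = io$levels[!keep], amplitude_uv = amp[!keep])
  if (nrow(dropped) > 0)
    warning(sprintf("dB output scale: excluded %d zero/negative-amplitude point(s) at level(s) %s",
                    nrow(dropped), paste(dropped$level, collapse = ", ")),
            call. = FALSE)
  y <- if (spec$output == "uV") amp[keep] else to_db(amp[keep], 1)
  structure(list(x = x[keep], y = y, level = io$levels[keep],
                 charge_nc = charge[keep], spec = spec, dropped = dropped,
                 subject = io$subject, electrode = io$electrode, ipg = io$ipg),
            class = "scaled_io")
}

#' @export
print.scaled_io <- function(x, ...) {
  cat(sprintf("scaled I/O (%s): %d points, x %g..%g, y %g..%g\n",
              x$spec$label, length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}
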