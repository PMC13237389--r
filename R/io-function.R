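#' Construct an eCAP input/output (amplitude growth) function
#'
#' The central measured object of the pipeline: eCAP amplitude (uV) as a
#' function of stimulation level for one (subject, electrode, interphase gap)
#' condition. Levels are device current-level (CL) integers by default;
#' `level_unit = "uA"` admits functions defined directly on a current grid
#' (e.g. from the quadratic forward model, [brochier_forward()]).
#'
#' @param levels strictly increasing stimulation levels (CL integers, or uA
#'   when `level_unit = "uA"`).
#' @param amplitudes eCAP amplitudes in uV, same length as `levels`; must be
#'   non-negative.
#' @param c_level maximum comfortable level, upper bound of measurement;
#'   `max(levels) <= c_level`.
#' @param phase_duration pulse phase duration in us (25 or 50 in practice).
#' @param ipg interphase gap in us.
#' @param subject,electrode identifier labels.
#' @param level_unit `"CL"` (device current-level code) or `"uA"`.
#' @param truth optional list of generating parameters carried along by the
#'   simulators for recovery tests.
#' @return An object of class `ecap_io`.
#' @export
io_function <- function(levels, amplitudes, c_level = max(levels),
                        phase_duration = 25, ipg = NA_real_,
                        subject = "S1", electrode = "e1",
                        level_unit = c("CL", "uA"), truth = NULL) {
  level_unit <- match.arg(level_unit)
  levels <- as.numeric(levels)
  amplitudes <- as.numeric(amplitudes)
  if (length(levels) == 0L) stop_config("empty I/O function")
  if (length(levels) != length(amplitudes))
    stop_config("`levels` and `amplitudes` must have equal length")
  if (any(diff(levels) <= 0)) stop_config("`levels` must be strictly increasing")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop_config("`amplitudes` must be finite and >= 0")
  if (max(levels) > c_level) stop_config("max(levels) exceeds `c_level`")
  check_number(phase_duration, "phase_duration", 0, strict = TRUE)
  structure(
    list(levels = levels, amplitudes = amplitudes, c_level = c_level,
         phase_duration = phase_duration, ipg = ipg, subject = subject,
         electrode = electrode, level_unit = level_unit, truth = truth),
    class = "ecap_io")
}

#' @export
print.ecap_io <- function(x, ...) {
  cat(sprintf("eCAP I/O function: %s/%s, IPG %s us, %d levels (%g..%g %s), C level %g\n",
              x$subject, x$electrode, format(x$ipg), length(x$levels),
              min(x$levels), max(x$levels), x$level_unit, x$c_level))
  cat(sprintf("  amplitudes %.1f..%.1f uV%s\n", min(x$amplitudes),
              max(x$amplitudes), if (!is.null(x$truth)) " (ground truth attached)" else ""))
  invisible(x)
}

#' @export
as.data.frame.ecap_io <- function(x, ...) {
  data.frame(subject = x$subject, electrode = x$electrode, ipg_us = x$ipg,
             level_cl = x$levels, amplitude_uv = x$amplitudes,
             c_level = x$c_level, phase_us = x$phase_duration,
             stringsAsFactors = FALSE)
}

#' Write / read eCAP I/O functions as tidy CSV
#'
#' Columns: subject, electrode, ipg_us, level_cl, amplitude_uv, c_level,
#' phase_us. `read_io_csv` returns a list of `ecap_io` objects, one per
#' (subject, electrode, ipg_us) combination.
#'
#' @param ios a single `ecap_io` or a list of them.
#' @param path file path.
#' @export
write_io_csv <- function(ios, path) {
  if (inherits(ios, "ecap_io")) ios <- list(ios)
  tab <- do.call(rbind, lapply(ios, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_io_csv
#' @export
read_io_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "electrode", "ipg_us", "level_cl", "amplitude_uv",
            "c_level", "phase_us")
  if (!all(need %in% names(tab)))
    stop_config("I/O CSV must contain columns: %s", paste(need, collapse = ", "))
  key <- interaction(tab$subject, tab$electrode, tab$ipg_us, drop = TRUE)
  lapply(split(tab, key), function(d) {
    d <- d[order(d$level_cl), ]
    io_function(d$level_cl, d$amplitude_uv, c_level = d$c_level[1],
                phase_duration = d$phase_us[1], ipg = d$ipg_us[1],
                subject = d$subject[1], electrode = d$electrode[1])
  })
}
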