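#' Configuration for phase-locking-value analysis
#'
#' Defaults reproduce the neural-synchrony protocol for which this module
#' was built: Hanning-tapered short-time Fourier transform with a frame of
#' 26 samples (1268.8 us at the device's 48.8-us sampling resolution), a
#' pad-ratio of 2 (zero-padding each frame to 52 samples before the DFT),
#' six partially overlapping frames, and six analysis frequencies from
#' 788.2 to 4729.2 Hz in steps of 788.2 Hz. The printed frequencies are
#' nominal labels; each is evaluated at the nearest DFT bin and the realized
#' bin frequency is reported alongside. The hop of 13 samples (50% overlap)
#' makes the six frames span 91 samples (~4.44 ms), covering the window
#' where the eCAP is expected.
#'
#' @param frame_size frame length in samples (>= 2).
#' @param n_frames number of frames.
#' @param hop hop between frame starts, in samples.
#' @param pad_ratio zero-padding factor (DFT length = `pad_ratio * frame_size`).
#' @param window taper; only `"hanning"` is implemented.
#' @param frequencies nominal analysis frequencies in Hz.
#' @param analysis_start first sample (1-based) of the analysis window; the
#'   recording delay already excludes stimulus onset, so the default is 1.
#' @export
plv_config <- function(frame_size = 26, n_frames = 6, hop = 13,
                       pad_ratio = 2, window = "hanning",
                       frequencies = 788.2 * (1:6), analysis_start = 1) {
  if (frame_size < 2) stop_config("`frame_size` must be >= 2")
  if (pad_ratio < 1) stop_config("`pad_ratio` must be >= 1")
  if (n_frames < 1 || hop < 1) stop_config("`n_frames` and `hop` must be >= 1")
  if (analysis_start < 1) stop_config("`analysis_start` must be >= 1")
  if (any(frequencies <= 0)) stop_config("frequencies must be positive")
  window <- match.arg(window, "hanning")
  structure(list(frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames), hop = as.integer(hop),
                 pad_ratio = as.integer(pad_ratio), window = window,
                 frequencies = frequencies,
                 analysis_start = as.integer(analysis_start)),
            class = "plv_config")
}

hanning_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Per-trial short-time Fourier spectra
#'
#' For every trial k, frame t and analysis frequency f, computes the complex
#' spectral estimate F_k(f, t): the frame is Hanning-tapered, zero-padded to
#' `pad_ratio * frame_size` samples, discrete-Fourier-transformed, and read
#' at the bin nearest f.
#'
#' @param sweeps a [sweep_set()].
#' @param config a [plv_config()].
#' @return An `stft_spectra` object: complex array `spectra` of dimension
#'   (trials, frames, frequencies), frame start indices and center times
#'   (us), nominal and realized frequencies, and the bins used.
#' @export
stft_spectra <- function(sweeps, config = plv_config()) {
  if (!inherits(sweeps, "sweep_set")) stop_config("`sweeps` must be a sweep_set")
  if (!inherits(config, "plv_config")) stop_config("`config` must be a plv_config")
  data <- sweeps$data
  fs <- sweeps$sampling_rate
  starts <- config$analysis_start + (seq_len(config$n_frames) - 1L) * config$hop
  ends <- starts + config$frame_size - 1L
  bad <- which(ends > ncol(data))
  if (length(bad) > 0)
    stop_config("frame %d (samples %d..%d) extends past the %d-sample record",
                bad[1], starts[bad[1]], ends[bad[1]], ncol(data))
  if (any(config$frequencies >= fs / 2))
    stop_config("analysis frequencies must lie below the Nyquist frequency %g Hz", fs / 2)
  nfft <- config$pad_ratio * config$frame_size
  bins <- as.integer(round(config$frequencies * nfft / fs))  # 0-based bin index
  realized <- bins * fs / nfft
  taper <- hanning_taper(config$frame_size)
  n_trials <- nrow(data)
  spec <- array(complex(real = 0), dim = c(n_trials, config$n_frames,
                                           length(bins)))
  pad <- numeric(nfft)
  for (k in seq_len(n_trials)) {
    for (t in seq_len(config$n_frames)) {
      pad[] <- 0
      pad[seq_len(config$frame_size)] <-
        data[k, starts[t]:ends[t]] * taper
      ft <- stats::fft(pad)
      spec[k, t, ] <- ft[bins + 1L]
    }
  }
  centers <- sweeps$t0_offset +
    (starts - 1 + (config$frame_size - 1) / 2) / fs * 1e6
  structure(list(spectra = spec, frame_starts = starts,
                 frame_center_times_us = centers,
                 frequencies_nominal = config$frequencies,
                 frequencies_realized = realized, bins = bins,
                 sampling_rate = fs, config = config),
            class = "stft_spectra")
}

#' Phase locking value grid
#'
#' PLV(f, t) = | (1/N) sum_k F_k(f, t) / |F_k(f, t)| |: the modulus of the
#' mean unit phasor across the N trials. Values lie in \[0, 1\]; 1 means all
#' trials share the same phase (perfect trial-to-trial synchrony). A trial
#' whose spectral estimate has zero magnitude carries no phase and would
#' bias the mean if dropped silently, so it raises an error identifying the
#' (trial, frame, frequency) cell.
#'
#' @param spectra an [stft_spectra()] result.
#' @param config the [plv_config()] used (defaults to the one stored in
#'   `spectra`).
#' @return A `plv_grid`: `values` (frames x frequencies matrix in \[0, 1\]),
#'   frame center times, nominal/realized frequencies, and `aggregate` (the
#'   arithmetic mean of all cells).
#' @export
phase_locking_value <- function(spectra, config = spectra$config) {
  if (!inherits(spectra, "stft_spectra")) stop_config("`spectra` must be an stft_spectra")
  sp <- spectra$spectra
  if (dim(sp)[1] < 2) stop_config("PLV needs >= 2 trials")
  mag <- Mod(sp)
  if (any(mag == 0)) {
    idx <- which(mag == 0, arr.ind = TRUE)[1, ]
    stop_config("degenerate zero-magnitude spectral estimate at trial %d, frame %d, frequency %g Hz",
                idx[1], idx[2], spectra$frequencies_nominal[idx[3]])
  }
  unitph <- sp / mag
  values <- apply(unitph, c(2, 3), function(z) Mod(mean(z)))
  dimnames(values) <- list(
    frame = sprintf("t%d", seq_len(nrow(values))),
    freq = sprintf("%.1fHz", spectra$frequencies_nominal))
  structure(list(values = values,
                 frame_center_times_us = spectra$frame_center_times_us,
                 frequencies_nominal = spectra$frequencies_nominal,
                 frequencies_realized = spectra$frequencies_realized,
                 n_trials = dim(sp)[1],
                 aggregate = mean(values)),
            class = "plv_grid")
}

#' Aggregate a PLV grid into a single synchrony index
#'
#' The arithmetic mean of all time-frequency cells (6 frames x 6
#' frequencies = 36 cells under the default configuration).
#'
#' @param grid a `plv_grid` (or a bare numeric matrix of PLV cells).
#' @export
aggregate_plv <- function(grid) {
  values <- if (inherits(grid, "plv_grid")) grid$values else as.matrix(grid)
  if (length(values) == 0) stop_config("empty PLV grid")
  if (any(!is.finite(values))) stop_config("PLV grid must be finite")
  mean(values)
}

#' Full sweep-set to synchrony-index chain
#'
#' Convenience wrapper: STFT spectra, PLV grid, aggregate.
#'
#' @param sweeps a [sweep_set()].
#' @param config a [plv_config()].
#' @return The `plv_grid` (its `$aggregate` is the synchrony index).
#' @export
plv <- function(sweeps, config = plv_config()) {
  phase_locking_value(stft_spectra(sweeps, config))
}

#' @export
print.plv_grid <- function(x, ...) {
  cat(sprintf("PLV grid: %d frames x %d frequencies (N = %d trials), aggregate %.4f\n",
              nrow(x$values), ncol(x$values), x$n_trials, x$aggregate))
  print(round(x$values, 3))
  invisible(x)
}

#' Tidy export of a PLV grid
#'
#' One row per (frame, frequency) cell plus a final aggregate row, matching
#' the CSV contract of the pipeline outputs.
#'
#' @param x a `plv_grid`.
#' @param ... unused.
#' @export
as.data.frame.plv_grid <- function(x, ...) {
  cells <- expand.grid(frame = seq_len(nrow(x$values)),
                       freq_idx = seq_len(ncol(x$values)))
  out <- data.frame(
    frame = cells$frame,
    frame_center_us = x$frame_center_times_us[cells$frame],
    frequency_nominal_hz = x$frequencies_nominal[cells$freq_idx],
    frequency_realized_hz = x$frequencies_realized[cells$freq_idx],
    plv = x$values[cbind(cells$frame, cells$freq_idx)])
  rbind(out, data.frame(frame = NA, frame_center_us = NA,
                        frequency_nominal_hz = NA, frequency_realized_hz = NA,
                        plv = x$aggregate))
}
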