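#' Configuration for the eCAP sweep simulator
#'
#' Defines a sweep set of repeated single-trial eCAP recordings. The waveform
#' template is a smooth biphasic deflection: a negative Gaussian lobe (the N1
#' trough) followed by a positive Gaussian lobe (the P2 peak). Trial-to-trial
#' variability has three controllable components: per-sweep latency jitter
#' (a continuous time shift of the whole template), per-sweep multiplicative
#' amplitude jitter, and an additive white noise floor. Noise-floor magnitudes
#' of roughly 2-20 uV span the range reported for clinical recording systems.
#'
#' @param n_sweeps number of repeated sweeps (>= 2); 400 in the measurement
#'   protocol this emulates.
#' @param sampling_rate sampling rate in Hz (device resolution ~48.8 us/sample).
#' @param n_samples samples per sweep.
#' @param t0_offset recording delay in us between stimulus offset and the
#'   first sample (devices report 98-122 us).
#' @param n1_latency,n1_amplitude,n1_width N1 trough: latency (us), amplitude
#'   (uV, negative), Gaussian width (us).
#' @param p2_latency,p2_amplitude,p2_width P2 peak: latency (us), amplitude
#'   (uV, positive), Gaussian width (us).
#' @param latency_jitter_sd SD of the per-sweep latency shift in us (>= 0).
#' @param amplitude_jitter_cv coefficient of variation of the per-sweep
#'   multiplicative amplitude factor (lognormal with mean 1; 0 disables).
#' @param noise_sd SD of additive white noise in uV (>= 0).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output. `NULL` uses the current RNG stream.
#' @return A list of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_sweeps = 400, sampling_rate = 20492,
                             n_samples = 104, t0_offset = 110,
                             n1_latency = 300, n1_amplitude = -100,
                             n1_width = 80,
                             p2_latency = 650, p2_amplitude = 50,
                             p2_width = 250,
                             latency_jitter_sd = 0, amplitude_jitter_cv = 0,
                             noise_sd = 0, seed = NULL) {
  if (!is.numeric(n_sweeps) || n_sweeps < 2) stop_config("`n_sweeps` must be >= 2")
  check_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  if (!is.numeric(n_samples) || n_samples < 1) stop_config("`n_samples` must be >= 1")
  check_number(latency_jitter_sd, "latency_jitter_sd", 0)
  check_number(amplitude_jitter_cv, "amplitude_jitter_cv", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(n1_width, "n1_width", 0, strict = TRUE)
  check_number(p2_width, "p2_width", 0, strict = TRUE)
  structure(as.list(environment()), class = "sweep_sim_config")
}

# Continuous biphasic template, evaluated at times in us.
ecap_template <- function(t, config) {
  config$n1_amplitude * exp(-0.5 * ((t - config$n1_latency) / config$n1_width)^2) +
    config$p2_amplitude * exp(-0.5 * ((t - config$p2_latency) / config$p2_width)^2)
}

#' Simulate a set of repeated eCAP sweeps
#'
#' Each sweep is the continuous template time-shifted by its own latency
#' jitter draw (the template is re-evaluated at shifted times, not shifted by
#' integer samples, so sub-sample jitter is represented without quantization),
#' scaled by a multiplicative amplitude factor, plus additive white noise.
#'
#' @param config a [sweep_sim_config()].
#' @return A `sweep_set`: list with `data` (n_sweeps x n_samples uV matrix),
#'   `sampling_rate`, `t0_offset`, `times_us`, and the generating `config`.
#' @export
simulate_sweeps <- function(config) {
  if (!inherits(config, "sweep_sim_config"))
    stop_config("`config` must be a sweep_sim_config")
  with_seed(config$seed, {
    n <- as.integer(config$n_sweeps)
    t_us <- config$t0_offset + (seq_len(config$n_samples) - 1) / config$sampling_rate * 1e6
    shifts <- if (config$latency_jitter_sd > 0)
      stats::rnorm(n, 0, config$latency_jitter_sd) else numeric(n)
    scales <- if (config$amplitude_jitter_cv > 0) {
      sdlog <- sqrt(log(1 + config$amplitude_jitter_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
    } else rep(1, n)
    data <- vapply(seq_len(n), function(k) {
      scales[k] * ecap_template(t_us - shifts[k], config)
    }, numeric(config$n_samples))
    data <- t(data)
    if (config$noise_sd > 0)
      data <- data + matrix(stats::rnorm(length(data), 0, config$noise_sd),
                            nrow = n)
    sweep_set(data, sampling_rate = config$sampling_rate,
              t0_offset = config$t0_offset, config = config)
  })
}

#' Construct a sweep set
#'
#' @param data N x T matrix of uV, one row per sweep.
#' @param sampling_rate Hz.
#' @param t0_offset recording delay in us.
#' @param metadata optional list (electrode id, stimulation level, ...).
#' @param config optional generating configuration.
#' @export
sweep_set <- function(data, sampling_rate, t0_offset = 0, metadata = list(),
                      config = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop_config("a sweep set needs >= 2 sweeps")
  if (any(!is.finite(data))) stop_config("sweep data must be finite")
  check_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  times <- t0_offset + (seq_len(ncol(data)) - 1) / sampling_rate * 1e6
  structure(list(data = data, sampling_rate = sampling_rate,
                 t0_offset = t0_offset, times_us = times,
                 metadata = metadata, config = config),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("eCAP sweep set: %d sweeps x %d samples @ %g Hz (t0 = %g us)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$t0_offset))
  invisible(x)
}

#' Write a sweep set as CSV plus a JSON sidecar
#'
#' The CSV holds the raw matrix (rows = sweeps, columns = samples); the
#' sidecar `<path>.json` records sampling rate, recording delay and metadata.
#'
#' @param sweeps a `sweep_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @export
write_sweeps <- function(sweeps, path) {
  utils::write.table(sweeps$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(sampling_rate = sweeps$sampling_rate,
               t0_offset_us = sweeps$t0_offset,
               n_sweeps = nrow(sweeps$data), n_samples = ncol(sweeps$data),
               metadata = sweeps$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  data <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sweep_set(unname(data), sampling_rate = side$sampling_rate,
            t0_offset = side$t0_offset_us,
            metadata = if (is.null(side$metadata)) list() else as.list(side$metadata))
}
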