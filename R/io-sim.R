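#' Sigmoidal growth function
#'
#' `y0 + a / (1 + exp(-(x - b) / c))`: baseline `y0`, amplitude range `a`,
#' midpoint `b` (input-scale units), slope parameter `c` (larger = shallower).
#'
#' @param x input values (working input scale).
#' @param y0,a,b,c parameters.
#' @export
sigmoid_growth <- function(x, y0, a, b, c) y0 + a / (1 + exp(-(x - b) / c))

#' Saturating exponential growth function
#'
#' `y0 + a * (1 - exp(-b * x))`: `y0` is the amplitude at threshold, `a` the
#' amplitude range, `b` the slope (larger = steeper).
#'
#' @param x input values.
#' @param y0,a,b parameters.
#' @export
exp_growth <- function(x, y0, a, b) y0 + a * (1 - exp(-b * x))

#' Scenario preset table for paired-IPG growth-function simulation
#'
#' Version 1 of the illustrative preset table. Each row gives the sigmoidal
#' ground truth (on the nC input scale) for one (scenario, electrode
#' position, IPG) cell. The scenarios encode the qualitative structure the
#' simulator is meant to emulate, not patient statistics:
#' \describe{
#'   \item{CND}{cochlear nerve deficiency: few (healthy) fibers -- low
#'     maximum amplitude, shallow slope, and a large leftward level shift of
#'     the 42-us-IPG curve that grows toward apical electrodes (fiber count
#'     decreases base-to-apex in this population).}
#'   \item{NSCN}{normal-sized nerve, idiopathic SNHL: high amplitude, steep
#'     slope, small shift, no electrode gradient.}
#'   \item{GJB2}{connexin-26 mutation, many healthy fibers: like NSCN with a
#'     marginally smaller shift.}
#' }
#' @return data.frame with columns scenario, position, ipg_us, y0, a, b, c.
#' @export
scenario_presets <- function() {
  base <- expand.grid(position = c("basal", "middle", "apical"),
                      scenario = c("CND", "NSCN", "GJB2"),
                      stringsAsFactors = FALSE)
  shape <- list(
    CND  = list(a = c(basal = 120, middle = 100, apical = 80), c = 2.2,
                shift = c(basal = 1.5, middle = 2.5, apical = 4.0)),
    NSCN = list(a = c(basal = 350, middle = 350, apical = 350), c = 1.2,
                shift = c(basal = 0.7, middle = 0.7, apical = 0.7)),
    GJB2 = list(a = c(basal = 450, middle = 450, apical = 450), c = 1.0,
                shift = c(basal = 0.6, middle = 0.6, apical = 0.6)))
  rows <- lapply(seq_len(nrow(base)), function(i) {
    sc <- base$scenario[i]; pos <- base$position[i]
    p <- shape[[sc]]
    b7 <- 11
    data.frame(scenario = sc, position = pos, ipg_us = c(7, 42),
               y0 = 0, a = unname(p$a[pos]), b = c(b7, b7 - unname(p$shift[pos])),
               c = p$c, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "version") <- 1L
  out
}

#' Configuration for paired-IPG I/O function simulation
#'
#' @param level_grid strictly increasing CL integers; `max(level_grid)` must
#'   not exceed `c_level`.
#' @param c_level maximum comfortable level (CL).
#' @param phase_duration pulse phase duration in us (25 or 50).
#' @param ipg_pair the two interphase gaps in us, default `c(7, 42)`.
#' @param sigmoid_truth_per_ipg named list mapping IPG (as character) to a
#'   list with `y0, a, b, c`; filled from [scenario_presets()] unless
#'   `scenario = "custom"`.
#' @param truth_scale input scale on which the truth sigmoid is defined:
#'   `"nC"` (charge) or `"dBC"` (dB re 1 nC).
#' @param noise_sd SD of additive amplitude noise in uV.
#' @param scenario `"CND"`, `"NSCN"`, `"GJB2"`, or `"custom"`.
#' @param electrode_position `"basal"`, `"middle"` or `"apical"`.
#' @param subject,electrode identifier labels.
#' @param law a [device_law()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @export
io_sim_config <- function(level_grid = seq(120, 200, by = 5), c_level = 200,
                          phase_duration = 25, ipg_pair = c(7, 42),
                          sigmoid_truth_per_ipg = NULL, truth_scale = c("nC", "dBC"),
                          noise_sd = 3,
                          scenario = c("CND", "NSCN", "GJB2", "custom"),
                          electrode_position = c("middle", "basal", "apical"),
                          subject = "S1", electrode = "e1",
                          law = device_law(), seed = NULL) {
  scenario <- match.arg(scenario)
  electrode_position <- match.arg(electrode_position)
  truth_scale <- match.arg(truth_scale)
  if (any(diff(level_grid) <= 0)) stop_config("`level_grid` must be strictly increasing")
  if (max(level_grid) > c_level) stop_config("max(level_grid) exceeds `c_level`")
  check_number(noise_sd, "noise_sd", 0)
  if (is.null(sigmoid_truth_per_ipg)) {
    if (scenario == "custom")
      stop_config("scenario 'custom' requires `sigmoid_truth_per_ipg`")
    tab <- scenario_presets()
    tab <- tab[tab$scenario == scenario & tab$position == electrode_position, ]
    sigmoid_truth_per_ipg <- lapply(ipg_pair, function(g) {
      row <- tab[tab$ipg_us == g, ]
      if (nrow(row) != 1)
        stop_config("no preset sigmoid truth for IPG %g us", g)
      as.list(row[, c("y0", "a", "b", "c")])
    })
    names(sigmoid_truth_per_ipg) <- as.character(ipg_pair)
  }
  for (g in as.character(ipg_pair)) {
    tr <- sigmoid_truth_per_ipg[[g]]
    if (is.null(tr)) stop_config("missing sigmoid truth for IPG %s us", g)
    if (tr$a <= 0 || tr$c <= 0) stop_config("sigmoid truth needs a > 0 and c > 0")
  }
  structure(as.list(environment()), class = "io_sim_config")
}

#' Simulate a paired-IPG set of eCAP I/O functions
#'
#' Evaluates each IPG's ground-truth sigmoid at the charge (or dB-charge)
#' value of every grid level, adds Gaussian amplitude noise, and floors
#' amplitudes at 0 uV (negative voltages are not meaningful eCAP
#' amplitudes). The generating parameters ride along in `$truth` so recovery
#' tests can compare fit to truth.
#'
#' @param config an [io_sim_config()].
#' @return List with one [io_function()] per IPG, named by IPG.
#' @export
simulate_io_pair <- function(config) {
  if (!inherits(config, "io_sim_config")) stop_config("`config` must be an io_sim_config")
  charge <- current_to_charge(cl_to_current(config$level_grid, config$law),
                              config$phase_duration)
  x <- if (config$truth_scale == "nC") charge else to_db(charge, 1)
  with_seed(config$seed, {
    out <- lapply(seq_along(config$ipg_pair), function(i) {
      g <- config$ipg_pair[i]
      tr <- config$sigmoid_truth_per_ipg[[as.character(g)]]
      amp <- sigmoid_growth(x, tr$y0, tr$a, tr$b, tr$c)
      if (config$noise_sd > 0)
        amp <- amp + stats::rnorm(length(amp), 0, config$noise_sd)
      amp <- pmax(amp, 0)
      io_function(config$level_grid, amp, c_level = config$c_level,
                  phase_duration = config$phase_duration, ipg = g,
                  subject = config$subject, electrode = config$electrode,
                  truth = c(tr, list(truth_scale = config$truth_scale,
                                     scenario = config$scenario)))
    })
    names(out) <- as.character(config$ipg_pair)
    out
  })
}

#' Configuration for the quadratic eCAP forward model
#'
#' The theoretical model `V = r * n * (s * g * I)^2`: `r` captures the
#' recording electrode, `n` the number of neurons near the stimulating
#' electrode, `s` the stimulating electrode, `g` a stimulus-dependent gain
#' (IPG-specific), and `I` the input current. Under a log/log display all
#' factors become additive, so level offsets between two IPG conditions
#' depend only on the gain ratio -- the invariance the offset module
#' demonstrates numerically.
#'
#' @param r,n,s,g positive model factors.
#' @param current_grid strictly increasing currents in uA.
#' @param phase_duration phase duration in us used for charge conversion.
#' @export
brochier_config <- function(r = 1, n = 1, s = 1, g = 1,
                            current_grid = seq(100, 1000, by = 100),
                            phase_duration = 25) {
  for (nm in c("r", "n", "s", "g"))
    check_number(get(nm), nm, 0, strict = TRUE)
  if (any(current_grid <= 0)) stop_config("all currents must be > 0")
  if (any(diff(current_grid) <= 0)) stop_config("`current_grid` must be strictly increasing")
  structure(list(r = r, n = n, s = s, g = g, current_grid = current_grid,
                 phase_duration = phase_duration), class = "brochier_config")
}

#' Evaluate the quadratic forward model as a noise-free I/O function
#'
#' @param config a [brochier_config()].
#' @param ipg IPG label (us) attached to the result.
#' @return An [io_function()] on the uA level axis.
#' @export
brochier_forward <- function(config, ipg = NA_real_) {
  if (!inherits(config, "brochier_config")) stop_config("`config` must be a brochier_config")
  V <- config$r * config$n * (config$s * config$g * config$current_grid)^2
  io_function(config$current_grid, V, c_level = max(config$current_grid),
              phase_duration = config$phase_duration, ipg = ipg,
              level_unit = "uA",
              truth = list(model = "quadratic_forward", r = config$r,
                           n = config$n, s = config$s, g = config$g))
}
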