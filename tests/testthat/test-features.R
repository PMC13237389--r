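test_that("threshold is the lowest measured level meeting the 5-uV criterion", {
  io <- io_function(c(170, 175, 180, 185), c(2, 4, 6, 9), c_level = 200)
  thr <- detect_threshold(io)
  expect_true(thr$found)
  expect_equal(thr$level, 180)
  q <- current_to_charge(cl_to_current(180), 25)
  expect_equal(thr$charge_nc, q, tolerance = 1e-12)
  expect_equal(thr$charge_db, 20 * log10(q), tolerance = 1e-12)
  # boundary inclusive: exactly 5.0 uV qualifies
  io2 <- io_function(c(170, 175), c(5, 9), c_level = 200)
  expect_equal(detect_threshold(io2)$level, 170)
  # all sub-criterion: a no-threshold result, not an exception
  io3 <- io_function(c(170, 175), c(2, 4.9), c_level = 200)
  thr3 <- detect_threshold(io3)
  expect_false(thr3$found)
  expect_true(is.na(thr3$level))
})

test_that("maximum amplitude is reported in uV and dB re 1 uV", {
  io <- io_function(c(150, 160, 170), c(10, 50, 40), c_level = 200)
  ma <- max_amplitude(io)
  expect_equal(ma$uv, 50)
  expect_equal(ma$db, 20 * log10(50))
  io2 <- io_function(c(150, 160), c(1, 100), c_level = 200)
  expect_equal(max_amplitude(io2)$db, 40)
})

test_that("dynamic range spans threshold to C level and is shift-invariant", {
  io <- io_function(c(170, 180, 190), c(2, 6, 30), c_level = 200)
  expect_equal(dynamic_range(io), 20)
  io2 <- io_function(c(170, 180, 200), c(2, 3, 6), c_level = 200)
  expect_equal(dynamic_range(io2), 0)   # threshold at the C level
  io3 <- io_function(c(170, 180, 190) + 10, c(2, 6, 30), c_level = 210)
  expect_equal(dynamic_range(io3), dynamic_range(io))
  io4 <- io_function(c(170, 180), c(1, 2), c_level = 200)
  expect_true(is.na(dynamic_range(io4)))
})

test_that("overall linear slope equals the closed-form least-squares oracle", {
  sio <- mk_sio(x = c(1, 3), y = c(10, 30), level = c(1, 3))
  expect_equal(overall_linear_slope(sio, 1, 3), 10)
  sio2 <- mk_sio(x = 1:6, y = 3 * (1:6), level = 1:6)
  expect_equal(overall_linear_slope(sio2, 1, 6), 3, tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(s)
    x <- sort(runif(6, 0, 20)); y <- rnorm(6, 2 * x, 4)
    sio3 <- mk_sio(x, y, level = x)
    expect_equal(overall_linear_slope(sio3, min(x), max(x)),
                 normal_eq_slope(x, y), tolerance = 1e-10)
  }
  # window restriction: only points between threshold and C level enter
  sio4 <- mk_sio(1:5, c(100, 2, 4, 6, -50), level = 1:5)
  expect_equal(overall_linear_slope(sio4, 2, 4), 2, tolerance = 1e-12)
  expect_true(is.na(overall_linear_slope(sio4, 5, 5)))
  expect_true(is.na(overall_linear_slope(sio4, NA, 5)))
})

test_that("resampling to 11 points is linear, endpoint-exact and idempotent", {
  x <- seq(2, 12, length.out = 11)
  sio <- mk_sio(x, 5 * x - 3, level = x)
  rs <- resample_io(sio, 11)
  expect_equal(rs$x, x, tolerance = 1e-12)
  expect_equal(rs$y, 5 * x - 3, tolerance = 1e-12)
  # 2-point input gives 11 collinear points
  rs2 <- resample_io(mk_sio(c(0, 10), c(1, 21), level = c(0, 10)), 11)
  expect_equal(rs2$y, 1 + 2 * rs2$x, tolerance = 1e-12)
  expect_equal(range(rs2$x), c(0, 10))
  # mild-curvature sigmoid sampled on an uneven grid tracks the curve
  set.seed(3)
  xs <- sort(seq(0, 60, length.out = 25) + rnorm(25, 0, 0.4))
  sig <- function(x) sigmoid_growth(x, 0, 1, 30, 12)
  rs3 <- resample_io(mk_sio(xs, sig(xs), level = xs), 11)
  expect_equal(rs3$y, sig(rs3$x), tolerance = 1e-3)
  expect_error(resample_io(sio, 1), "n")
})

test_that("window method evaluates exactly 8 four-point regressions on 11 points", {
  x <- seq(0, 50, length.out = 13)
  sio <- mk_sio(x, sigmoid_growth(x, 0, 100, 25, 6), level = x)
  ms <- max_slope_window(sio)
  expect_length(attr(ms, "slopes"), 8)
  # brute force over all 8 windows with the normal-equations oracle
  rs <- resample_io(sio, 11)
  brute <- vapply(1:8, function(i) normal_eq_slope(rs$x[i:(i + 3)], rs$y[i:(i + 3)]),
                  numeric(1))
  expect_equal(as.numeric(ms), max(brute), tolerance = 1e-10)
  # the sigmoid's steepest region beats its overall slope
  expect_gt(as.numeric(ms), overall_linear_slope(sio, min(x), max(x)))
})

test_that("window method equals the overall slope exactly on a straight line", {
  x <- seq(1, 21, 2)
  sio <- mk_sio(x, 4.5 * x + 2, level = x)
  ms <- max_slope_window(sio)
  expect_equal(as.numeric(ms), 4.5, tolerance = 1e-12)
  expect_equal(as.numeric(ms), overall_linear_slope(sio, 1, 21), tolerance = 1e-12)
  expect_equal(attr(ms, "window_index"), 1L)  # ties break toward lower levels
  short <- mk_sio(c(1, 2), c(1, 2), level = c(1, 2))
  expect_true(is.na(max_slope_window(short, n_points = 3, window = 4)))
})

test_that("sigmoid fit recovers noise-free generating parameters", {
  x <- seq(10, 50, length.out = 15)
  sio <- mk_sio(x, sigmoid_growth(x, 0, 1, 30, 4), level = x)
  f <- fit_sigmoid(sio)
  expect_true(f$converged)
  expect_equal(f$a, 1, tolerance = 1e-6)
  expect_equal(f$b, 30, tolerance = 1e-6)
  expect_equal(f$c, 4, tolerance = 1e-6)
  expect_lt(abs(f$y0), 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
})

test_that("degenerate sigmoid fits are flagged, not silently returned", {
  x <- seq(1, 12, 1)
  lin <- mk_sio(x, 2 * x + 1, level = x)
  f <- fit_sigmoid(lin)
  expect_true(!f$converged || f$at_bound || f$c > 100 * diff(range(x)))
  few <- mk_sio(1:4, c(1, 2, 3, 4), level = 1:4)
  f2 <- fit_sigmoid(few)
  expect_false(f2$converged)
  expect_match(f2$reason, "insufficient")
})

test_that("exponential fit recovers noise-free parameters and flags constants", {
  x <- seq(1, 40, length.out = 12)
  sio <- mk_sio(x, exp_growth(x, 5, 40, 0.1), level = x)
  f <- fit_exponential(sio)
  expect_true(f$converged)
  expect_equal(f$y0, 5, tolerance = 1e-6)
  expect_equal(f$a, 40, tolerance = 1e-6)
  expect_equal(f$b, 0.1, tolerance = 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  const <- mk_sio(x, rep(7, 12), level = x)
  fc <- fit_exponential(const)
  expect_false(fc$converged)
})

test_that("saturating curves favor the exponential model over a straight line", {
  x <- seq(2, 30, length.out = 12)
  y <- exp_growth(x, 0, 50, 0.15)
  sio <- mk_sio(x, y, level = x)
  fe <- fit_exponential(sio)
  lm_fit <- stats::lm(y ~ x)
  adj_line <- adjusted_r2(stats::residuals(lm_fit), y, 2)
  expect_gt(fe$adj_r2, adj_line)
})

test_that("adjusted R-squared follows its defining formula", {
  y <- c(-sqrt(5), sqrt(5), rep(0, 9))      # n = 11, SStot = 10
  res0 <- rep(0, 11)
  expect_equal(adjusted_r2(res0, y, 4), 1)
  res <- c(1, rep(0, 10))                   # SSres = 1 -> R2 = 0.9
  expect_equal(adjusted_r2(res, y, 4), 1 - 0.1 * 10 / 6, tolerance = 1e-12)
  # an extra useless parameter lowers adjusted R2 for identical residuals
  expect_lt(adjusted_r2(res, y, 5), adjusted_r2(res, y, 4))
  expect_true(is.na(adjusted_r2(res[1:5], y[1:5], 4)))
})

test_that("shape classification follows the adjusted-R2 margin and is scale-invariant", {
  lv <- seq(120, 200, 5)
  q <- current_to_charge(cl_to_current(lv), 25)
  # noise-free sigmoid spanning threshold to plateau: no transition
  io_sig <- io_function(lv, sigmoid_growth(q, 0, 100, 11, 2.2), c_level = 200)
  expect_equal(classify_shape(io_sig)$label, "unchanged")
  # noisy data whose log/log profile is exponential-truth: the parsimonious
  # exponential model wins once noise makes the raw fits comparable
  xdb <- 20 * log10(q)
  set.seed(4)
  ydb <- exp_growth(xdb, -20, 45, 0.09) + rnorm(length(xdb), 0, 1.5)
  io_exp <- io_function(lv, 10^(ydb / 20), c_level = 200)
  cls <- classify_shape(io_exp)
  expect_equal(cls$label, "exponential-transitioned")
  expect_gt(cls$adj_r2_exponential, cls$adj_r2_sigmoid + cls$margin)
  # uniform amplitude scaling shifts dB intercepts only: label unchanged
  io_scaled <- io_function(lv, 3.7 * io_exp$amplitudes, c_level = 200)
  expect_equal(classify_shape(io_scaled)$label, cls$label)
  expect_equal(classify_shape(io_function(lv, 3.7 * io_sig$amplitudes,
                                          c_level = 200))$label, "unchanged")
})

test_that("slopes scale with amplitude on uV outputs and are invariant on dB outputs", {
  pr <- simulate_io_pair(io_sim_config(scenario = "NSCN", noise_sd = 0))
  io <- pr[["7"]]
  k <- 2.5
  io_k <- io_function(io$levels, k * io$amplitudes, c_level = io$c_level,
                      phase_duration = io$phase_duration, ipg = io$ipg)
  thr <- detect_threshold(io)
  for (lab in c("S1", "S2")) {
    s <- transform_io(io, scale_spec(lab)); sk <- transform_io(io_k, scale_spec(lab))
    expect_equal(as.numeric(max_slope_window(sk)),
                 k * as.numeric(max_slope_window(s)), tolerance = 1e-9)
    # same regression window: scaling acts on amplitudes only
    expect_equal(overall_linear_slope(sk, thr$level, io$c_level),
                 k * overall_linear_slope(s, thr$level, io$c_level),
                 tolerance = 1e-9)
  }
  s3 <- transform_io(io, scale_spec("S3")); s3k <- transform_io(io_k, scale_spec("S3"))
  expect_equal(as.numeric(max_slope_window(s3k)),
               as.numeric(max_slope_window(s3)), tolerance = 1e-9)
  expect_equal(overall_linear_slope(s3k, thr$level, io$c_level),
               overall_linear_slope(s3, thr$level, io$c_level), tolerance = 1e-9)
})

test_that("io_features assembles one row with every dependent variable", {
  pr <- simulate_io_pair(io_sim_config(scenario = "CND", noise_sd = 0))
  row <- io_features(pr[["42"]])
  expect_equal(nrow(row), 1)
  expect_true(all(c("threshold_nc", "threshold_db", "max_amplitude_uv",
                    "max_amplitude_db", "dynamic_range", "overall_slope_S1",
                    "max_slope_S3", "shape_s3") %in% names(row)))
  expect_false(any(is.na(unlist(row[, c("threshold_nc", "max_amplitude_uv",
                                        "overall_slope_S1", "max_slope_S1")]))))
  # max amplitude of the noise-free simulation matches the truth sigmoid top
  q_top <- current_to_charge(cl_to_current(200), 25)
  tr <- pr[["42"]]$truth
  expect_equal(row$max_amplitude_uv,
               sigmoid_growth(q_top, tr$y0, tr$a, tr$b, tr$c), tolerance = 1e-6)
})
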