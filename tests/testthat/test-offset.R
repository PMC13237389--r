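test_that("normalization divides both curves by the IPG-7 maximum", {
  io7 <- io_function(c(150, 160, 170), c(100, 300, 500), c_level = 200, ipg = 7)
  io42 <- io_function(c(150, 160, 170), c(200, 450, 620), c_level = 200, ipg = 42)
  pair <- normalize_pair(io7, io42, scale_spec("S1"))
  expect_equal(pair$normalizer, 500)
  expect_equal(max(pair$sio7$y), 1)
  expect_equal(pair$sio42$y, c(200, 450, 620) / 500)
  expect_gt(max(pair$sio42$y), 1)  # exceeding 1 is allowed
  zero <- io_function(c(150, 160), c(0, 0), c_level = 200, ipg = 7)
  expect_error(normalize_pair(zero, io42, scale_spec("S1")), "zero")
  other <- io_function(c(150, 160), c(1, 2), c_level = 200, subject = "S9")
  expect_error(normalize_pair(io7, other, scale_spec("S1")), "share")
})

test_that("sigmoid inversion follows the closed form and round-trips", {
  x <- seq(0, 60, length.out = 20)
  sio <- mk_sio(x, sigmoid_growth(x, 0.1, 0.9, 30, 5), level = x)
  f <- fit_sigmoid(sio)
  expect_equal(invert_sigmoid(f, f$y0 + f$a / 2), f$b, tolerance = 1e-6)
  expect_equal(invert_sigmoid(f, f$y0 + 3 * f$a / 4), f$b + f$c * log(3),
               tolerance = 1e-6)
  for (s in 1:5) {
    set.seed(s)
    y0 <- runif(1, -1, 1); a <- runif(1, 0.5, 3)
    b <- runif(1, 5, 40); cc <- runif(1, 1, 8)
    fit <- structure(list(y0 = y0, a = a, b = b, c = cc, converged = TRUE),
                     class = "sigmoid_fit")
    xs <- runif(10, b - 3 * cc, b + 3 * cc)
    expect_equal(invert_sigmoid(fit, sigmoid_growth(xs, y0, a, b, cc)), xs,
                 tolerance = 1e-10)
  }
  expect_error(invert_sigmoid(f, f$y0), "outside")
  expect_error(invert_sigmoid(f, f$y0 + f$a), "outside")
})

test_that("a constructed level shift is recovered exactly on the charge scale", {
  tr7 <- list(y0 = 0, a = 400, b = 11, c = 1.8)
  tr42 <- list(y0 = 0, a = 400, b = 11 - 2.5, c = 1.8)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 0)
  res <- stimulation_level_offset(normalize_pair(pr[["7"]], pr[["42"]],
                                                 scale_spec("S1")))
  expect_equal(res$offset, 2.5, tolerance = 1e-6)
  expect_equal(res$quantile_table$difference, rep(2.5, 3), tolerance = 1e-6)
  expect_equal(res$quantile_table$quantile, c(0.25, 0.5, 0.75))
})

test_that("identical functions at both IPGs give zero offset everywhere", {
  tr <- list(y0 = 0, a = 300, b = 11, c = 2)
  pr <- mk_truth_pair(tr, tr, noise_sd = 0)
  for (res in offset_all_scales(pr[["7"]], pr[["42"]]))
    expect_equal(res$offset, 0, tolerance = 1e-6)
})

test_that("offset is independent of the uV normalizer on the charge scale", {
  tr7 <- list(y0 = 0, a = 250, b = 11, c = 2)
  tr42 <- list(y0 = 0, a = 250, b = 9.5, c = 2)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 0)
  res <- stimulation_level_offset(normalize_pair(pr[["7"]], pr[["42"]],
                                                 scale_spec("S1")))
  # same data, amplitudes rescaled wholesale: the level axis is untouched
  k <- 4.2
  io7k <- io_function(pr[["7"]]$levels, k * pr[["7"]]$amplitudes,
                      c_level = pr[["7"]]$c_level, ipg = 7)
  io42k <- io_function(pr[["42"]]$levels, k * pr[["42"]]$amplitudes,
                       c_level = pr[["42"]]$c_level, ipg = 42)
  resk <- stimulation_level_offset(normalize_pair(io7k, io42k, scale_spec("S1")))
  expect_equal(resk$offset, res$offset, tolerance = 1e-9)
})

test_that("swapping the IPG roles negates the offset", {
  tr7 <- list(y0 = 0, a = 350, b = 11, c = 1.5)
  tr42 <- list(y0 = 0, a = 350, b = 10, c = 1.5)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 0)
  fwd <- stimulation_level_offset(normalize_pair(pr[["7"]], pr[["42"]],
                                                 scale_spec("S1")))
  rev <- stimulation_level_offset(normalize_pair(pr[["42"]], pr[["7"]],
                                                 scale_spec("S1")))
  expect_equal(rev$offset, -fwd$offset, tolerance = 1e-6)
})

test_that("translating the IPG-42 input axis shifts the offset exactly", {
  tr7 <- list(y0 = 0, a = 300, b = 21, c = 1.1)
  tr42 <- list(y0 = 0, a = 300, b = 20, c = 1.1)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 0, truth_scale = "dBC")
  pair <- normalize_pair(pr[["7"]], pr[["42"]], scale_spec("S2"))
  base <- stimulation_level_offset(pair)
  delta <- 0.8
  pair2 <- pair
  pair2$sio42$x <- pair2$sio42$x + delta
  shifted <- stimulation_level_offset(pair2)
  expect_equal(shifted$offset, base$offset - delta, tolerance = 1e-6)
})

test_that("reported quantile rows are self-consistent with the stored fits", {
  tr7 <- list(y0 = 0, a = 280, b = 11, c = 2.2)
  tr42 <- list(y0 = 0, a = 310, b = 9.8, c = 1.9)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 2, seed = 9)
  res <- stimulation_level_offset(normalize_pair(pr[["7"]], pr[["42"]],
                                                 scale_spec("S1")))
  tab <- res$quantile_table
  expect_equal(res$offset, mean(tab$difference), tolerance = 1e-12)
  for (i in 1:3) {
    expect_equal(tab$level_ipg7[i], invert_sigmoid(res$fit7, tab$target_amplitude[i]),
                 tolerance = 1e-12)
    expect_equal(tab$level_ipg42[i], invert_sigmoid(res$fit42, tab$target_amplitude[i]),
                 tolerance = 1e-12)
    expect_gte(tab$target_amplitude[i], res$overlap[1])
    expect_lte(tab$target_amplitude[i], res$overlap[2])
  }
})

test_that("failures yield missing offsets with reasons, never exceptions", {
  # too few points for the sigmoid fit
  io7 <- io_function(c(150, 160, 170), c(10, 50, 100), c_level = 200, ipg = 7)
  io42 <- io_function(c(150, 160, 170), c(12, 60, 110), c_level = 200, ipg = 42)
  res <- stimulation_level_offset(normalize_pair(io7, io42, scale_spec("S1")))
  expect_true(is.na(res$offset))
  expect_match(res$reason, "converge")
  out <- offset_all_scales(io7, io42)
  expect_true(all(vapply(out, function(o) is.na(o$offset), logical(1))))
})

test_that("a multiplicative gain ratio appears as 20 log10(k) dB on log-input scales", {
  k <- 1.5
  shift <- 20 * log10(k)
  tr7 <- list(y0 = 0, a = 1, b = 21, c = 1.2)
  tr42 <- list(y0 = 0, a = 1, b = 21 - shift, c = 1.2)
  pr <- mk_truth_pair(tr7, tr42, noise_sd = 0, truth_scale = "dBC")
  res2 <- stimulation_level_offset(normalize_pair(pr[["7"]], pr[["42"]],
                                                  scale_spec("S2")))
  expect_equal(res2$offset, shift, tolerance = 1e-6)
  # S3: construct amplitudes whose dB values are exact translates in dB-charge
  lv <- seq(120, 200, 5)
  xdb <- 20 * log10(current_to_charge(cl_to_current(lv), 25))
  mk_db_io <- function(b, ipg) io_function(
    lv, 10^(sigmoid_growth(xdb, -18, 16, b, 1.2) / 20), c_level = 200, ipg = ipg)
  res3 <- stimulation_level_offset(normalize_pair(mk_db_io(21, 7),
                                                  mk_db_io(21 - shift, 42),
                                                  scale_spec("S3")))
  expect_equal(res3$offset, shift, tolerance = 1e-6)
})

test_that("quadratic forward-model offsets ignore the shared non-neural factors", {
  k <- 1.6
  mk <- function(r, n, s, g) brochier_forward(brochier_config(r, n, s, g), ipg = 7)
  set.seed(11)
  # exactly representable scale factors isolate the algebraic invariance
  pow2 <- replicate(5, {
    e <- sample(-20:20, 3, replace = TRUE)
    o <- offset_all_scales(mk(2^e[1], 2^e[2], 2^e[3], 1),
                           mk(2^e[1], 2^e[2], 2^e[3], k))
    c(o$S2$offset, o$S3$offset)
  })
  expect_lt(diff(range(pow2[1, ])), 1e-9)
  expect_lt(diff(range(pow2[2, ])), 1e-9)
  # arbitrary continuous factors: invariant to the level set by input
  # rounding (~1e-15 relative) times the constrained fit's conditioning
  cont <- replicate(5, {
    r <- exp(runif(1, -3, 3)); n <- exp(runif(1, 0, 8)); s <- exp(runif(1, -4, 1))
    o <- offset_all_scales(mk(r, n, s, 1), mk(r, n, s, k))
    c(o$S2$offset, o$S3$offset)
  })
  expect_lt(diff(range(cont[1, ])), 1e-8)
  expect_lt(diff(range(cont[2, ])), 1e-8)
  # and the offsets sit at the gain ratio's dB value
  o <- offset_all_scales(mk(1, 1, 1, 1), mk(1, 1, 1, k))
  expect_equal(o$S3$offset, 20 * log10(k), tolerance = 0.05)
  expect_equal(o$S2$offset, 20 * log10(k), tolerance = 0.05)
})
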