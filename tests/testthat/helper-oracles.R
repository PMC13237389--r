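# Independent oracles and small fixture builders used across the suite.

# Brute-force DFT by summation: X[bin] = sum_n x[n] exp(-2 pi i bin n / nfft),
# 0-based bin, x implicitly zero-padded to nfft.
dft_oracle <- function(x, bin, nfft) {
  n <- seq_along(x) - 1
  sum(x * exp(-2i * pi * bin * n / nfft))
}

# Closed-form least-squares slope from the normal equations.
normal_eq_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  unname(beta[2, 1])
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# assignments of the pooled ranks to group A (midranks for ties).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_stat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_stat(seq_len(na))
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2, u_stat)
  mu <- na * length(b) / 2
  # two-sided: as extreme or more extreme in |U - E[U]|
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Bare scaled_io fixture on explicit working coordinates.
mk_sio <- function(x, y, level = x, label = "S1") {
  structure(list(x = x, y = y, level = level, charge_nc = NULL,
                 spec = scale_spec(label),
                 dropped = data.frame(level = numeric(0),
                                      amplitude_uv = numeric(0)),
                 subject = "S1", electrode = "e1", ipg = NA_real_),
            class = "scaled_io")
}

# Paired I/O functions from custom sigmoid truths (no scenario presets).
mk_truth_pair <- function(tr7, tr42, noise_sd = 0, seed = NULL,
                          truth_scale = "nC", ...) {
  cfg <- io_sim_config(scenario = "custom",
                       sigmoid_truth_per_ipg = list(`7` = tr7, `42` = tr42),
                       noise_sd = noise_sd, truth_scale = truth_scale,
                       seed = seed, ...)
  simulate_io_pair(cfg)
}
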