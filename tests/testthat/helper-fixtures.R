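# Shared fixtures: the published parameter sets and a noiseless synthetic
# LFP/rate pair built from them (computed once per test run).

published_ln_filter <- function() {
  ln_filter(c0 = -109.2, coefficients = c(85.8, 18.3), taus = c(0.031, 0.635))
}

published_transduction <- function() {
  transduction_params(convention = "odor_activation")
}

# Noiseless LFP (2 s pulse at the modelled concentration, 1 s baseline)
# and the LN-model rate derived from it; memoized.
.fixture_env <- new.env()

synthetic_pair <- function() {
  if (is.null(.fixture_env$pair)) {
    params <- published_transduction()
    stim <- stimulus_protocol(matrix(c(0, 2), 1), concentration = 1e-11)
    sim <- simulate_transduction(params, stim, t_end = 3, dt = 1e-3,
                                 t_start = -1, method = "exact")
    filt <- published_ln_filter()
    .fixture_env$pair <- list(lfp = sim$lfp,
                              rate = predict_rate(sim$lfp, filt),
                              filt = filt, stim = stim)
  }
  .fixture_env$pair
}

# Direct O(N*M) causal convolution oracle for the gamma filter.
direct_gamma_convolution <- function(x, tau, alpha, dt) {
  w <- ornpulse:::gamma_kernel_weights(tau, alpha, dt, length(x))
  vapply(seq_along(x), function(i) {
    j <- seq_len(min(i, length(w)))
    sum(w[j] * x[i - j + 1])
  }, numeric(1))
}

# Brute-force response-end oracle: scan all ISIs (interval after the last
# spike unbounded) for the first that ends after the offset and exceeds
# the threshold.
response_end_oracle <- function(times, offset, thr = 0.1) {
  if (!length(times)) return(NA_real_)
  ends <- c(times[-1], Inf)
  for (i in seq_along(times)) {
    if (ends[i] > offset && (ends[i] - times[i]) > thr) return(times[i])
  }
  NA_real_
}

# Exact two-tailed signed-rank p by enumeration of all sign assignments:
# the conventional doubled smaller tail of the positive-rank-sum null
# distribution, capped at 1.
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s == 1]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Seeded evaluation that restores the session RNG state afterwards.
with_local_seed_test <- function(seed, code) {
  ornpulse:::with_local_seed(seed, code)
}
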