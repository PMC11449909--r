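#' Antennal-lobe glomerulus parameters
#'
#' Parameters of the single-glomerulus model: 10 projection neurons (PNs)
#' and 6 local neurons (LNs) as leaky integrate-and-fire units with
#' nondimensional potentials (leak `E_L = 0`, threshold `V_thr = 1`,
#' excitatory reversal `14/3`, inhibitory/SK reversal `-2/3`). PNs carry a
#' slow SK (calcium-activated potassium) conductance driven by their own
#' spikes, producing spike-frequency adaptation; LNs provide fast
#' (GABA-A-like) and slow (GABA-B-like) inhibition. Synaptic amplitudes
#' are per postsynaptic population: `S_exc = 0.01/0.006`,
#' `S_inh = 0.0169/0.015`, `S_slow = 0.0338/0.04`,
#' `S_stim = 0.004/0.0031` (PN/LN), and connection probabilities are
#' `PN->PN = 0.75, PN->LN = 0.75, LN->PN = 0.38, LN->LN = 0.25`.
#'
#' The membrane, synaptic, refractory and SK time constants are not fixed
#' by the nondimensionalization; they are mandatory configuration fields
#' with defaults (in seconds) from the standard glomerulus-model
#' literature, and every analysis reads them from this configuration.
#'
#' @param n_pn,n_ln numbers of projection and local neurons.
#' @param tau_v membrane time constant (s).
#' @param tau_ref absolute refractory period (s).
#' @param tau_exc,tau_inh,tau_slow,tau_stim synaptic time constants (s).
#' @param tau_rise,tau_sk SK conductance rise and decay time constants (s).
#' @param S_exc,S_inh,S_slow,S_stim length-2 amplitudes `(PN, LN)` per
#'   postsynaptic population.
#' @param sk_mean,sk_sd per-PN SK gain distribution (normal, negative
#'   draws floored at 0).
#' @param p_pn_pn,p_pn_ln,p_ln_pn,p_ln_ln connection probabilities.
#' @param background background ORN input rate in spikes/ms.
#' @param e_l,e_exc,e_inh,v_thr nondimensional potentials.
#' @return An object of class `al_params`.
#' @export
al_params <- function(n_pn = 10, n_ln = 6,
                      tau_v = 0.020, tau_ref = 0.002,
                      tau_exc = 0.002, tau_inh = 0.010,
                      tau_slow = 0.200, tau_stim = 0.002,
                      tau_rise = 0.035, tau_sk = 0.100,
                      S_exc = c(0.01, 0.006), S_inh = c(0.0169, 0.015),
                      S_slow = c(0.0338, 0.04), S_stim = c(0.004, 0.0031),
                      sk_mean = 0.5, sk_sd = 0.2,
                      p_pn_pn = 0.75, p_pn_ln = 0.75,
                      p_ln_pn = 0.38, p_ln_ln = 0.25,
                      background = 3,
                      e_l = 0, e_exc = 14 / 3, e_inh = -2 / 3, v_thr = 1) {
  probs <- c(p_pn_pn, p_pn_ln, p_ln_pn, p_ln_ln)
  if (any(probs < 0 | probs > 1)) stop("al_params: probabilities must be in [0, 1]")
  taus <- c(tau_v, tau_ref, tau_exc, tau_inh, tau_slow, tau_stim,
            tau_rise, tau_sk)
  if (any(taus <= 0)) stop("al_params: time constants must be positive")
  amps <- c(S_exc, S_inh, S_slow, S_stim)
  if (any(amps < 0)) stop("al_params: synaptic amplitudes must be >= 0")
  structure(list(
    n_pn = n_pn, n_ln = n_ln, tau_v = tau_v, tau_ref = tau_ref,
    tau_exc = tau_exc, tau_inh = tau_inh, tau_slow = tau_slow,
    tau_stim = tau_stim, tau_rise = tau_rise, tau_sk = tau_sk,
    S_exc = S_exc, S_inh = S_inh, S_slow = S_slow, S_stim = S_stim,
    sk_mean = sk_mean, sk_sd = sk_sd,
    p_pn_pn = p_pn_pn, p_pn_ln = p_pn_ln, p_ln_pn = p_ln_pn,
    p_ln_ln = p_ln_ln, background = background,
    e_l = e_l, e_exc = e_exc, e_stim = e_exc, e_inh = e_inh, e_sk = e_inh,
    v_thr = v_thr
  ), class = "al_params")
}

#' Build a random glomerulus network instance
#'
#' Draws Bernoulli connectivity per connection class at the configured
#' probabilities (self-connections excluded) and the per-PN SK gains from
#' a normal distribution with negative draws set to 0. The instance is
#' reproducible from the seed.
#'
#' @param params an [al_params()].
#' @param seed integer RNG seed.
#' @return An object of class `glomerulus_net` with boolean adjacency
#'   matrices `A_pp`, `A_pl`, `A_lp`, `A_ll` (row = presynaptic neuron),
#'   per-PN `s_sk` draws, the `params` and the `seed`.
#' @export
build_glomerulus <- function(params = al_params(), seed = 1) {
  stopifnot(inherits(params, "al_params"))
  with_local_seed(seed, {
    bern <- function(nr, nc, p, no_self = FALSE) {
      m <- matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
      if (no_self) diag(m) <- 0L
      m
    }
    A_pp <- bern(params$n_pn, params$n_pn, params$p_pn_pn, no_self = TRUE)
    A_pl <- bern(params$n_pn, params$n_ln, params$p_pn_ln)
    A_lp <- bern(params$n_ln, params$n_pn, params$p_ln_pn)
    A_ll <- bern(params$n_ln, params$n_ln, params$p_ln_ln, no_self = TRUE)
    s_sk <- pmax(0, stats::rnorm(params$n_pn, params$sk_mean, params$sk_sd))
    structure(list(A_pp = A_pp, A_pl = A_pl, A_lp = A_lp, A_ll = A_ll,
                   s_sk = s_sk, params = params, seed = seed),
              class = "glomerulus_net")
  })
}

#' @export
print.glomerulus_net <- function(x, ...) {
  cat(sprintf("<glomerulus_net> %d PN + %d LN, %d edges, seed %s\n",
              x$params$n_pn, x$params$n_ln,
              sum(x$A_pp) + sum(x$A_pl) + sum(x$A_lp) + sum(x$A_ll),
              as.character(x$seed)))
  invisible(x)
}

#' Simulate the glomerulus network
#'
#' Leaky integrate-and-fire dynamics with conductance-based synapses and
#' SK adaptation. Every neuron receives an independent Poisson ORN event
#' stream at rate `background + stimulus(t)` (spikes/ms) feeding the
#' stimulus conductance. Conductances decay exponentially between events
#' (exact update); membrane potentials use explicit Euler at step `dt`.
#'
#' @param net a [glomerulus_net()].
#' @param orn_rate stimulus ORN rate on top of the background, as a
#'   [time_series()] in spikes/ms (or a constant); sampled on the
#'   simulation grid starting at `t = 0`.
#' @param duration simulated time in seconds.
#' @param dt integration step in seconds (must be `<= 1e-4`; default
#'   1e-5).
#' @param seed integer RNG seed for the Poisson input streams.
#' @param record optionally record the state trace of one neuron
#'   (1-based index) for diagnostics.
#' @return list with `pn` and `ln`: lists of [spike_train()] objects
#'   (times in seconds); with `record`, also `trace` (matrix of V and
#'   conductances at every step).
#' @export
simulate_al <- function(net, orn_rate = 0, duration, dt = 1e-5, seed = 1,
                        record = NULL) {
  stopifnot(inherits(net, "glomerulus_net"))
  if (dt > 1e-4) stop("simulate_al: dt must be <= 1e-4 s")
  p <- net$params
  n_steps <- ceiling(duration / dt)
  t_grid <- (seq_len(n_steps) - 1) * dt
  stim <- if (inherits(orn_rate, "time_series")) {
    pmax(0, ts_at(orn_rate, t_grid))
  } else {
    rep(max(0, orn_rate), n_steps)
  }
  rate <- p$background + stim          # spikes/ms per neuron
  ms <- 1e3
  pars <- list(tau_v = p$tau_v * ms, tau_ref = p$tau_ref * ms,
               tau_exc = p$tau_exc * ms, tau_inh = p$tau_inh * ms,
               tau_slow = p$tau_slow * ms, tau_stim = p$tau_stim * ms,
               tau_rise = p$tau_rise * ms, tau_sk = p$tau_sk * ms,
               e_l = p$e_l, e_exc = p$e_exc, e_inh = p$e_inh,
               e_stim = p$e_stim, e_sk = p$e_sk, v_thr = p$v_thr,
               S_exc = p$S_exc, S_inh = p$S_inh, S_slow = p$S_slow,
               S_stim = p$S_stim)
  res <- with_local_seed(seed,
    al_sim_cpp(net$A_pp, net$A_pl, net$A_lp, net$A_ll, net$s_sk,
               rate, dt * ms, n_steps, pars,
               record = !is.null(record),
               record_idx = if (is.null(record)) 0L else as.integer(record) - 1L))
  win <- c(0, duration)
  to_train <- function(v, id) spike_train(v / ms, window = win, sensillum = id)
  spikes <- res$spikes
  out <- list(
    pn = lapply(seq_len(p$n_pn), function(i) to_train(spikes[[i]], paste0("PN", i))),
    ln = lapply(seq_len(p$n_ln), function(i)
      to_train(spikes[[p$n_pn + i]], paste0("LN", i)))
  )
  if (!is.null(record)) {
    colnames(res$trace) <- c("V", "g_stim", "g_exc", "g_inh", "g_slow",
                             "g_sk", "z")
    out$trace <- res$trace
    out$trace_dt <- dt
  }
  out
}

#' Smooth an ORN rate profile with an exponential kernel
#'
#' Causal convolution with a unit-area exponential kernel of the given
#' mean (the mean of an exponential kernel equals its time constant); used
#' to ask whether duration encoding survives when the sharp ORN dynamics
#' are artificially slowed.
#'
#' @param rate a [time_series()] of firing rate (non-negative).
#' @param mean kernel mean in seconds (default 0.150).
#' @return a smoothed [time_series()]; the total integral is preserved.
#' @export
smooth_orn_input <- function(rate, mean = 0.150) {
  stopifnot(inherits(rate, "time_series"))
  if (any(rate$values < 0)) stop("smooth_orn_input: rate must be >= 0")
  gamma_filter(rate, tau = mean, alpha = 1)
}

#' Pooled PN population rate over repeated simulations
#'
#' Pools the PN spike trains of several network simulations and bins them
#' into a population rate in Hz per PN (count / (n_runs * n_pn * bin)).
#'
#' @param runs list of [simulate_al()] outputs.
#' @param bin bin width in seconds (default 0.020).
#' @return a [time_series()] of the average PN firing rate in Hz.
#' @export
pn_population_rate <- function(runs, bin = 0.020) {
  if (!length(runs)) stop("pn_population_rate: empty input")
  all_spikes <- unlist(lapply(runs, function(r)
    unlist(lapply(r$pn, function(tr) tr$times))))
  t_max <- max(vapply(runs, function(r) r$pn[[1]]$window[2], numeric(1)))
  n_pn <- length(runs[[1]]$pn)
  edges <- seq(0, t_max + bin, by = bin)
  counts <- tabulate(findInterval(all_spikes, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  rate <- counts / (length(runs) * n_pn * bin)
  time_series(rate, dt = bin, t_start = bin / 2, unit = "Hz")
}
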