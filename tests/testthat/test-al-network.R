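test_that("glomerulus construction follows the configured statistics", {
  p0 <- al_params(p_pn_pn = 0, p_pn_ln = 0, p_ln_pn = 0, p_ln_ln = 0)
  net0 <- build_glomerulus(p0, seed = 1)
  expect_equal(sum(net0$A_pp) + sum(net0$A_pl) + sum(net0$A_lp) +
                 sum(net0$A_ll), 0)

  # expected PN->PN edge count: 0.75 * 10 * 9 (self-edges excluded)
  counts <- vapply(1:10000, function(s)
    sum(build_glomerulus(al_params(), seed = s)$A_pp), numeric(1))
  expect_equal(mean(counts), 0.75 * 10 * 9, tolerance = 1 / 67.5)
  expect_true(all(vapply(1:10000, function(s) {
    net <- build_glomerulus(al_params(), seed = s)
    all(diag(net$A_pp) == 0) && all(diag(net$A_ll) == 0)
  }, logical(1))[1:50]))

  # SK gains are non-negative for any seed
  sks <- unlist(lapply(1:200, function(s)
    build_glomerulus(al_params(), seed = s)$s_sk))
  expect_true(all(sks >= 0))
  # truncation at zero actually occurs at mean 0.5, sd 0.2
  expect_gt(mean(sks == 0), 0)

  # identical seed reproduces the instance
  expect_identical(build_glomerulus(al_params(), seed = 7),
                   build_glomerulus(al_params(), seed = 7))
})

test_that("network dynamics respect refractoriness, determinism and silence", {
  net <- build_glomerulus(al_params(), seed = 3)

  run1 <- simulate_al(net, 5, duration = 0.5, dt = 2e-5, seed = 11)
  run2 <- simulate_al(net, 5, duration = 0.5, dt = 2e-5, seed = 11)
  expect_identical(lapply(c(run1$pn, run1$ln), `[[`, "times"),
                   lapply(c(run2$pn, run2$ln), `[[`, "times"))

  isis <- unlist(lapply(c(run1$pn, run1$ln), function(tr) diff(tr$times)))
  expect_true(length(isis) > 0)
  expect_gte(min(isis), net$params$tau_ref - 1e-9)

  # zero background and zero stimulus: no spikes, V stays at rest
  silent_net <- build_glomerulus(al_params(background = 0), seed = 3)
  r0 <- simulate_al(silent_net, 0, duration = 0.2, dt = 2e-5, seed = 1,
                    record = 1)
  expect_equal(sum(lengths(lapply(c(r0$pn, r0$ln), `[[`, "times"))), 0)
  expect_true(all(r0$trace[, "V"] == silent_net$params$e_l))

  expect_error(simulate_al(net, 0, duration = 0.1, dt = 1e-3), "dt")
})

test_that("conductances decay exponentially between input events", {
  p <- al_params(background = 0.02, p_pn_pn = 0, p_pn_ln = 0, p_ln_pn = 0,
                 p_ln_ln = 0, sk_mean = 0, sk_sd = 0)
  net <- build_glomerulus(p, seed = 2)
  run <- simulate_al(net, 0, duration = 0.5, dt = 5e-5, seed = 4, record = 1)
  g <- run$trace[, "g_stim"]
  decay <- exp(-5e-5 / p$tau_stim)
  ratio_ok <- abs(g[-1] - g[-length(g)] * decay) < 1e-12
  nz <- g[-length(g)] > 1e-12
  # between events the trace follows the exact exponential; the rest are
  # event steps (jumps above the decayed value)
  jumps <- g[-1] > g[-length(g)] * decay + 1e-12
  expect_true(all(ratio_ok[nz] | jumps[nz]))
  expect_gt(mean(ratio_ok[nz]), 0.9)
  expect_gt(sum(jumps), 0)
})

test_that("near-constant drive produces near-periodic firing at the LIF period", {
  # strong high-rate ORN input with small kicks approximates a constant
  # conductance; compare the ISI against the closed-form LIF period
  p <- al_params(background = 200, S_stim = c(0.0005, 0.0005),
                 p_pn_pn = 0, p_pn_ln = 0, p_ln_pn = 0, p_ln_ln = 0,
                 sk_mean = 0, sk_sd = 0)
  net <- build_glomerulus(p, seed = 1)
  run <- simulate_al(net, 0, duration = 0.5, dt = 1e-5, seed = 9)
  isis <- diff(run$pn[[1]]$times)
  expect_gt(length(isis), 10)
  g <- 200 * p$S_stim[1] * p$tau_stim[1] * 1e3   # mean conductance (1/ms)
  tau_v_ms <- p$tau_v * 1e3
  a <- 1 / tau_v_ms + g
  b <- g * p$e_exc
  v_inf <- b / a
  period_ms <- p$tau_ref * 1e3 + log(v_inf / (v_inf - 1)) / a
  expect_equal(mean(isis) * 1e3, period_ms, tolerance = 0.1 * period_ms)
  expect_lt(sd(isis) / mean(isis), 0.2)
})

test_that("removing inhibition cannot reduce PN output", {
  net <- build_glomerulus(al_params(), seed = 5)
  p_free <- net$params
  p_free$S_inh <- c(0, 0)
  p_free$S_slow <- c(0, 0)
  net_free <- net
  net_free$params <- p_free
  drive <- time_series(rep(10, 100), dt = 5e-3)
  intact <- simulate_al(net, drive, duration = 0.5, dt = 2e-5, seed = 31)
  free <- simulate_al(net_free, drive, duration = 0.5, dt = 2e-5, seed = 31)
  n_intact <- sum(lengths(lapply(intact$pn, `[[`, "times")))
  n_free <- sum(lengths(lapply(free$pn, `[[`, "times")))
  expect_gte(n_free, n_intact)
})

test_that("exponential smoothing of the ORN input preserves mass", {
  const <- time_series(rep(4, 3000), dt = 1e-3)
  sm <- smooth_orn_input(const)
  expect_equal(tail(sm$values, 1), 4, tolerance = 1e-4)

  imp <- time_series(c(100, numeric(4999)), dt = 1e-3)
  sm2 <- smooth_orn_input(imp, mean = 0.150)
  t <- ts_times(sm2)
  tail_idx <- t > 0.05 & t < 0.6
  fit <- lm(log(sm2$values[tail_idx]) ~ t[tail_idx])
  expect_equal(-1 / unname(coef(fit)[2]), 0.150, tolerance = 0.01)
  expect_equal(sum(sm2$values), sum(imp$values), tolerance = 1)

  expect_error(smooth_orn_input(time_series(c(-1, 1), dt = 1)), ">= 0")
})

test_that("PN population rate pools runs and shows duration-encoding dynamics", {
  net <- build_glomerulus(al_params(), seed = 3)
  one <- simulate_al(net, 5, duration = 0.5, dt = 2e-5, seed = 2)
  pr1 <- pn_population_rate(list(one), bin = 0.05)
  pr2 <- pn_population_rate(list(one, one), bin = 0.05)
  expect_equal(pr1$values, pr2$values)
  expect_error(pn_population_rate(list()), "empty")

  # phasi-tonic ORN drive for a 2 s pulse: post-offset dip below 20% of
  # the pre-offset level; 20 ms input: PN response outlasts the stimulus
  phen <- orn_phenotype()
  mk_drive <- function(dur) {
    stim <- stimulus_protocol(matrix(c(0, dur), 1),
                              concentration = dose_concentration("100 pg"))
    sim <- simulate_transduction(phen$transduction, stim, t_end = dur + 2,
                                 dt = 1e-3, t_start = -0.5, method = "exact")
    orn <- ornpulse:::phenotype_rate(phen, sim$lfp, stim)
    drive <- orn
    drive$values <- orn$values / max(orn$values) * 25
    drive$t_start <- orn$t_start + 0.5
    drive
  }
  drive2 <- mk_drive(2)
  runs <- lapply(1:36, function(r)
    simulate_al(net, drive2, duration = 4.5, dt = 2e-5, seed = 300 + r))
  pr <- pn_population_rate(runs, bin = 0.1)
  t <- ts_times(pr)
  pre_offset <- mean(pr$values[t > 2 & t < 2.5])    # stimulus at 0.5-2.5
  dip <- min(pr$values[t > 2.5 & t < 2.85])         # inhibitory phase
  expect_gt(pre_offset, 0)
  expect_lt(dip, 0.2 * pre_offset)

  drive02 <- mk_drive(0.02)
  runs02 <- lapply(1:12, function(r)
    simulate_al(net, drive02, duration = 2, dt = 2e-5, seed = 400 + r))
  pr02 <- pn_population_rate(runs02, bin = 0.02)
  t02 <- ts_times(pr02)
  base <- mean(pr02$values[t02 < 0.5])
  resp <- pr02$values[t02 > 0.5 & t02 < 1.2]
  # response persists well beyond the 20 ms stimulus (0.50-0.52 s)
  above <- t02[t02 > 0.5 & t02 < 1.2][resp > 2 * base]
  expect_gt(max(above) - 0.5, 0.1)
})
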