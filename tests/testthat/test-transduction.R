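test_that("resting state is a fixed point and receptor mass is conserved", {
  # with the concentration on the binding step, [O] = 0 freezes the
  # all-unbound initial state
  p_bind <- transduction_params(convention = "swapped")
  none <- stimulus_protocol(matrix(numeric(0), ncol = 2), concentration = 0)
  sim <- simulate_transduction(p_bind, none, t_end = 0.5, dt = 1e-3)
  expect_true(all(sim$R$values == 1))
  expect_true(all(sim$OR$values == 0))
  expect_true(all(sim$OR_star$values == 0))
  expect_true(all(sim$lfp$values == 0))

  # with the concentration on the activation step, binding equilibrates
  # but no activation (and no LFP) develops without odor
  sim_oa <- simulate_transduction(published_transduction(), none,
                                  t_end = 0.5, dt = 1e-3)
  expect_lt(max(abs(sim_oa$OR_star$values)), 1e-9)
  expect_lt(max(abs(sim_oa$lfp$values)), 1e-9)

  for (p in list(p_bind, published_transduction())) {
    stim <- stimulus_protocol(matrix(c(0, 0.3), 1), concentration = 1e-12)
    for (method in c("ode45", "exact")) {
      sim <- simulate_transduction(p, stim, t_end = 1, dt = 1e-3,
                                   method = method)
      dev <- max(abs(sim$R$values + sim$OR$values + sim$OR_star$values - 1))
      expect_lt(dev, 1e-8)
    }
  }
  expect_error(
    simulate_transduction(p_bind, time_series(-1e-12, dt = 1), t_end = 0.5),
    "negative")
})

test_that("the two integration paths agree", {
  p <- published_transduction()
  stim <- stimulus_protocol(matrix(c(0, 0.2), 1), concentration = 1e-11)
  a <- simulate_transduction(p, stim, t_end = 0.4, dt = 1e-3)
  b <- simulate_transduction(p, stim, t_end = 0.4, dt = 1e-3,
                             method = "exact")
  expect_lt(max(abs(a$lfp$values - b$lfp$values)), 1e-6)
  expect_lt(max(abs(a$OR_star$values - b$OR_star$values)), 1e-6)
})

test_that("steady-state activation matches the closed form and is monotone", {
  p <- published_transduction()
  stim <- stimulus_protocol(matrix(c(0, 3), 1), concentration = 1e-12)
  sim <- simulate_transduction(p, stim, t_end = 3, dt = 1e-3,
                               method = "exact")
  expect_equal(tail(sim$OR_star$values, 1),
               steady_state_activation(p, 1e-12), tolerance = 1e-6)

  concs <- 10^seq(-15, -10, by = 0.5)
  ss <- steady_state_activation(p, concs)
  expect_true(all(diff(ss) > 0))

  # linear small-signal regime: peak OR* doubles when [O] doubles
  peak <- function(conc) {
    stim <- stimulus_protocol(matrix(c(0, 0.1), 1), concentration = conc)
    max(simulate_transduction(p, stim, t_end = 0.3, dt = 1e-3,
                              method = "exact")$OR_star$values)
  }
  expect_equal(peak(2e-16) / peak(1e-16), 2, tolerance = 0.01)
})

test_that("activation decays with the receptor time constant 1/s_a after a pulse", {
  p <- published_transduction()
  stim <- stimulus_protocol(matrix(c(0, 0.02), 1), concentration = 1e-12)
  sim <- simulate_transduction(p, stim, t_end = 1, dt = 1e-3,
                               method = "exact")
  t <- ts_times(sim$OR_star)
  tail_idx <- t > 0.15 & t < 0.6
  fit <- lm(log(sim$OR_star$values[tail_idx]) ~ t[tail_idx])
  tau_fit <- -1 / coef(fit)[2]
  expect_equal(unname(tau_fit), 1 / p$s_a, tolerance = 0.05)
})

test_that("LFP filter has the first-order fixed point and step response", {
  const <- time_series(rep(0.5, 3000), dt = 1e-4)
  lfp <- lfp_from_activation(const, beta = -5.67, tau_lfp = 0.010)
  expect_equal(tail(lfp$values, 1), -2.835, tolerance = 1e-4)

  # 63.2% of asymptote after one time constant
  step <- time_series(c(0, rep(1, 3000)), dt = 1e-4)
  resp <- lfp_from_activation(step, beta = 1, tau_lfp = 0.010)
  expect_equal(ts_at(resp, 0.010), 1 - exp(-1), tolerance = 0.01)

  # relaxation to zero from OR* = 0 with the configured time constant
  zero <- time_series(numeric(2000), dt = 1e-4)
  relax <- lfp_from_activation(zero, beta = -5.67, tau_lfp = 0.010, lfp0 = -3)
  expect_equal(ts_at(relax, 0.010), -3 * exp(-1), tolerance = 0.01)

  expect_error(lfp_from_activation(const, beta = 1, tau_lfp = 0), "tau_lfp")
})

test_that("generating parameters are a local optimum of the fitting loss", {
  p <- published_transduction()
  mk <- function(dur) {
    stim <- stimulus_protocol(matrix(c(0, dur), 1), concentration = 1e-11)
    simulate_transduction(p, stim, t_end = 0.4, dt = 1e-3,
                          method = "exact")$lfp
  }
  lfp20 <- mk(0.02)
  lfp200 <- mk(0.2)
  loss_at <- function(q) {
    tot <- 0
    for (i in 1:2) {
      dur <- c(0.02, 0.2)[i]
      obs <- list(lfp20, lfp200)[[i]]
      stim <- stimulus_protocol(matrix(c(0, dur), 1), concentration = 1e-11)
      sim <- simulate_transduction(q, stim, t_end = 0.4, dt = 1e-3,
                                   method = "exact")
      tot <- tot + sum((sim$lfp$values - obs$values)^2)
    }
    tot
  }
  base <- loss_at(p)
  set.seed(21)
  for (i in 1:100) {
    f <- exp(rnorm(5, 0, 0.05))
    q <- transduction_params(k_a = p$k_a * f[1], s_a = p$s_a * f[2],
                             k_b = p$k_b * f[3], s_b = p$s_b * f[4],
                             beta = p$beta * f[5], convention = "odor_activation")
    expect_gte(loss_at(q), base)
  }
})

test_that("odor-to-rate composition is phasi-tonic with an inhibitory phase", {
  p <- published_transduction()
  filt <- published_ln_filter()
  stim <- stimulus_protocol(matrix(c(0, 2), 1), concentration = 1e-12)
  res <- odor_to_rate(p, filt, stim, t_end = 4, t_start = -1, dt = 1e-3)
  t <- ts_times(res$rate)
  v <- res$rate$values
  expect_true(all(v >= 0))
  # peak within 100 ms of onset, steady level below the peak
  expect_lt(t[which.max(v)], 0.1)
  steady <- mean(v[t > 1.5 & t < 2])
  expect_lt(steady, 0.5 * max(v))
  expect_gt(steady, 0)
  # rectifier pins the rate at 0 for > 100 ms after offset
  expect_true(all(v[t > 2.1 & t < 2.3] == 0))

  # zero stimulus -> zero rate; gain scales pointwise
  none <- stimulus_protocol(matrix(numeric(0), ncol = 2), concentration = 0)
  expect_true(all(odor_to_rate(p, filt, none, t_end = 1)$rate$values == 0))
  res77 <- odor_to_rate(p, filt, stim, t_end = 4, t_start = -1, dt = 1e-3,
                        gain = 0.77)
  expect_equal(res77$rate$values, 0.77 * v, tolerance = 1e-12)
})
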