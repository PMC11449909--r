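test_that("the resting state is an exact equilibrium that holds over time", {
  cp <- compartment_params()
  cur <- compartment_currents(compartment_rest(cp), cp)
  expect_identical(unname(max(abs(cur))), 0)

  sim <- simulate_compartments(cp, t_end = 1, dt = 1e-3)
  drift <- max(abs(sim$V_ed$values + 35), abs(sim$V_ea$values + 35),
               abs(sim$V_id$values + 62), abs(sim$V_is$values + 62))
  expect_lt(drift, 1e-6)
  # max |dV/dt| below 1e-9 mV/ms at the end state
  d_end <- ornpulse:::compartment_deriv(
    c(V_id = tail(sim$V_id$values, 1), V_ed = tail(sim$V_ed$values, 1),
      V_is = tail(sim$V_is$values, 1), V_ea = tail(sim$V_ea$values, 1)),
    cp, 0, 0)
  expect_lt(max(abs(d_end)) / 1e3, 1e-9)

  # off-equilibrium offsets are flagged
  bad <- compartment_params(E_ls = -60)
  expect_warning(simulate_compartments(bad, t_end = 0.01), "equilibrium")
})

test_that("node equations match a hand-coded oracle at random states", {
  cp <- compartment_params(G_e = 1.3, G_i = 0.8, G_ls = 0.21, G_ld = 0.17,
                           G_a = 1.1, C_md = 0.012, C_ma = 0.004,
                           C_ms = 0.025)
  oracle <- function(st, p, I_R, I_ad) {
    I_ls <- p$G_ls * (st["V_is"] - p$E_ls)
    I_ld <- p$G_ld * (st["V_ed"] - st["V_id"] + p$E_ld)
    I_i <- p$G_i * (st["V_id"] - st["V_is"])
    I_a <- -p$G_a * (st["V_ea"] + p$E_a)
    I_e <- p$G_e * (st["V_ea"] - st["V_ed"])
    den <- p$G_e + p$G_i
    c(V_id = p$G_e / (p$C_md * den) * (I_R + I_ld - I_e) +
        p$G_e / (p$C_ma * den) * (I_a - I_e) +
        p$G_i / (p$C_ms * den) * (I_i - I_ls - I_ad),
      V_ed = p$G_i / (p$C_md * den) * (I_e - I_R - I_ld) +
        p$G_e / (p$C_ma * den) * (I_a - I_e) +
        p$G_i / (p$C_ms * den) * (I_i - I_ls - I_ad),
      V_is = (I_i - I_ls - I_ad) / p$C_ms,
      V_ea = (I_a - I_e) / p$C_ma)
  }
  set.seed(8)
  for (i in 1:50) {
    st <- c(V_id = runif(1, -80, -40), V_ed = runif(1, -50, -20),
            V_is = runif(1, -80, -40), V_ea = runif(1, -50, -20))
    ir <- rnorm(1); iad <- rnorm(1)
    expect_equal(ornpulse:::compartment_deriv(st, cp, ir, iad),
                 unname(oracle(st, cp, ir, iad)) |>
                   stats::setNames(c("V_id", "V_ed", "V_is", "V_ea")),
                 tolerance = 1e-12)
  }
})

test_that("receptor current drives the recorded potential downward", {
  cp <- compartment_params()
  t <- seq(0, 0.3, 1e-4)
  ir <- time_series(pmax(0, 1 - exp(-t / 0.02)) * 2, dt = 1e-4)
  fwd <- simulate_compartments(cp, I_R = ir, t_end = 0.3, dt = 1e-4)
  expect_lt(tail(fwd$V_ed$values, 1), -35)   # LFP deflects negative
  expect_gt(tail(fwd$V_is$values, 1), -62)   # soma depolarizes

  # hyperpolarizing somatic adaptation current pushes the LFP further down
  iad <- time_series(pmax(0, 1 - exp(-t / 0.05)) * 0.5, dt = 1e-4)
  fwd2 <- simulate_compartments(cp, I_R = ir, I_ad = iad, t_end = 0.3,
                                dt = 1e-4)
  expect_lt(tail(fwd2$V_ed$values, 1), tail(fwd$V_ed$values, 1))
  expect_lt(tail(fwd2$V_is$values, 1), tail(fwd$V_is$values, 1))
})

test_that("inverse problems are exact inverses of the forward model", {
  cp <- compartment_params()
  t <- seq(0, 0.3, 1e-4)
  ir <- time_series(pmax(0, 1 - exp(-t / 0.02)) * 2 *
                      (1 + 0.3 * sin(2 * pi * 5 * t)), dt = 1e-4)
  fwd <- simulate_compartments(cp, I_R = ir, t_end = 0.3, dt = 1e-4)

  ir_rec <- infer_receptor_current(fwd$V_ed, cp)
  expect_lt(max(abs(ir_rec$values - ir$values)) / max(ir$values), 0.01)

  # constant resting target -> zero receptor current
  flat <- time_series(rep(-35, 1001), dt = 1e-4, unit = "mV")
  ir0 <- infer_receptor_current(flat, cp)
  expect_lt(max(abs(ir0$values)), 1e-9)

  iad <- time_series(pmax(0, 1 - exp(-t / 0.05)) * 0.4, dt = 1e-4)
  fwd2 <- simulate_compartments(cp, I_R = ir, I_ad = iad, t_end = 0.3,
                                dt = 1e-4)
  iad_rec <- infer_adaptation_current(ir, fwd2$V_is, cp)
  expect_lt(max(abs(iad_rec$values - iad$values)) / max(iad$values), 0.01)

  # resting somatic target with no receptor current -> zero adaptation
  flat_is <- time_series(rep(-62, 1001), dt = 1e-4, unit = "mV")
  iad0 <- infer_adaptation_current(NULL, flat_is, cp)
  expect_lt(max(abs(iad0$values)), 1e-9)

  coarse <- time_series(rep(-35, 100), dt = 1e-3)
  expect_error(infer_receptor_current(coarse, cp), "coarse")
  expect_error(infer_adaptation_current(NULL, coarse, cp), "coarse")
})

test_that("ramp target implies a constant capacitive receptor-current term", {
  cp <- compartment_params()
  slope <- -20   # mV/s
  t <- seq(0, 0.2, 1e-4)
  ramp <- time_series(-35 + slope * t, dt = 1e-4, unit = "mV")
  ir <- infer_receptor_current(ramp, cp)
  # initial instant: all other node potentials still at rest, so
  # I_R = -dVed/dt * C_md (G_e + G_i) / G_i
  expected0 <- -slope * cp$C_md * (cp$G_e + cp$G_i) / cp$G_i
  expect_equal(ir$values[2], expected0, tolerance = 0.02 * abs(expected0))
})

test_that("the model is linear in the input currents", {
  cp <- compartment_params()
  t <- seq(0, 0.2, 1e-4)
  ir1 <- time_series(pmax(0, sin(2 * pi * 10 * t)), dt = 1e-4)
  ir2 <- time_series(rep(0.7, length(t)), dt = 1e-4)
  base <- compartment_rest(cp)
  dev <- function(sim) cbind(sim$V_id$values - base["V_id"],
                             sim$V_ed$values - base["V_ed"],
                             sim$V_is$values - base["V_is"],
                             sim$V_ea$values - base["V_ea"])
  s1 <- simulate_compartments(cp, I_R = ir1, t_end = 0.2, dt = 1e-4)
  s2 <- simulate_compartments(cp, I_R = ir2, t_end = 0.2, dt = 1e-4)
  both <- ir1; both$values <- ir1$values + ir2$values
  s12 <- simulate_compartments(cp, I_R = both, t_end = 0.2, dt = 1e-4)
  expect_equal(dev(s12), dev(s1) + dev(s2), tolerance = 1e-6)
})

test_that("the effective LFP kernel is recovered and has the right sign", {
  set.seed(2)
  irn <- time_series(rnorm(4000, 1, 0.5), dt = 1e-4)

  # synthetic construction: exact 10 ms exponential kernel
  v_syn <- gamma_filter(irn, 0.010, 1)
  v_syn$values <- -3 * v_syn$values - 35
  k <- estimate_lfp_kernel(irn, v_syn)
  expect_equal(k$tau, 0.010, tolerance = 0.01 * 0.010)
  expect_equal(k$gain, -3, tolerance = 0.01 * 3)

  # through the full compartment model with reference parameters the
  # fitted constant is of order 10 ms and the gain negative
  fwd <- simulate_compartments(compartment_params(), I_R = irn,
                               t_end = 0.3999, dt = 1e-4)
  k2 <- estimate_lfp_kernel(irn, fwd$V_ed)
  expect_gt(k2$tau, 0.002)
  expect_lt(k2$tau, 0.05)
  expect_lt(k2$gain, 0)

  expect_error(estimate_lfp_kernel(time_series(rep(1, 10), dt = 1e-4),
                                   time_series(rep(1, 10), dt = 1e-4)),
               "zero-variance")
})
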