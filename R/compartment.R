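#' Passive multicompartmental sensillum parameters
#'
#' Electrical constants of the passive four-node model of the sensillum
#' circuit (hemolymph reference, auxiliary cells, sensillar lymph,
#' dendrite, soma). The state consists of the four potentials `V_id`
#' (inner dendrite), `V_ed` (outer dendrite = recording electrode, the
#' LFP), `V_is` (inner soma) and `V_ea` (outer auxiliary). Five passive
#' currents connect the nodes; their offset potentials are forced by the
#' requirement that the resting state `V_ed = V_ea = -35 mV`,
#' `V_id = V_is = -62 mV` is an equilibrium with zero receptor and
#' adaptation currents: `E_ls = -62`, `E_ld = -27`, `E_a = +35` mV. The
#' conductance and capacitance magnitudes are not constrained by that
#' equilibrium; the defaults are reference values (relative units chosen
#' so that the dendritic node integrates with a ~10 ms time constant) and
#' are fully configurable.
#'
#' @param G_e,G_i,G_ls,G_ld,G_a conductances (relative siemens units).
#' @param C_md,C_ma,C_ms capacitances (relative farad units; `C/G` is in
#'   seconds).
#' @param E_ls,E_ld,E_a offset potentials in mV.
#' @return An object of class `compartment_params`.
#' @export
compartment_params <- function(G_e = 1, G_i = 1, G_ls = 0.2, G_ld = 0.2,
                               G_a = 1, C_md = 0.010, C_ma = 0.005,
                               C_ms = 0.020, E_ls = -62, E_ld = -27,
                               E_a = 35) {
  if (any(c(G_e, G_i, G_ls, G_ld, G_a, C_md, C_ma, C_ms) <= 0))
    stop("compartment_params: conductances and capacitances must be positive")
  structure(list(G_e = G_e, G_i = G_i, G_ls = G_ls, G_ld = G_ld, G_a = G_a,
                 C_md = C_md, C_ma = C_ma, C_ms = C_ms,
                 E_ls = E_ls, E_ld = E_ld, E_a = E_a),
            class = "compartment_params")
}

#' Resting state of the compartment model
#' @param params a [compartment_params()] (unused beyond the convention;
#'   kept for symmetry).
#' @return named numeric state `c(V_id, V_ed, V_is, V_ea)` in mV.
#' @export
compartment_rest <- function(params = compartment_params()) {
  c(V_id = -62, V_ed = -35, V_is = -62, V_ea = -35)
}

#' Passive currents at a given state
#'
#' Evaluates the five passive currents from the node potentials:
#' soma leak `I_ls = G_ls (V_is - E_ls)`, dendrite leak
#' `I_ld = G_ld (V_ed - V_id + E_ld)`, axial `I_i = G_i (V_id - V_is)`,
#' auxiliary `I_a = -G_a (V_ea + E_a)` and epithelial
#' `I_e = G_e (V_ea - V_ed)`.
#'
#' @param state named numeric with `V_id`, `V_ed`, `V_is`, `V_ea` in mV.
#' @param params a [compartment_params()].
#' @return named numeric `c(I_ls, I_ld, I_i, I_a, I_e)`.
#' @export
compartment_currents <- function(state, params = compartment_params()) {
  with(c(as.list(state), params), c(
    I_ls = G_ls * (V_is - E_ls),
    I_ld = G_ld * (V_ed - V_id + E_ld),
    I_i  = G_i * (V_id - V_is),
    I_a  = -G_a * (V_ea + E_a),
    I_e  = G_e * (V_ea - V_ed)
  ))
}

# Node derivatives given state and input currents. The three shared
# coefficient blocks of the potential equations.
compartment_deriv <- function(state, params, I_R, I_ad) {
  cur <- compartment_currents(state, params)
  p <- params
  denom <- p$G_e + p$G_i
  term_a <- (p$G_e / (p$C_ma * denom)) * (cur["I_a"] - cur["I_e"])
  term_s <- (p$G_i / (p$C_ms * denom)) *
    (cur["I_i"] - cur["I_ls"] - I_ad)
  d_vid <- (p$G_e / (p$C_md * denom)) * (I_R + cur["I_ld"] - cur["I_e"]) +
    term_a + term_s
  d_ved <- (p$G_i / (p$C_md * denom)) * (cur["I_e"] - I_R - cur["I_ld"]) +
    term_a + term_s
  d_vis <- (cur["I_i"] - cur["I_ls"] - I_ad) / p$C_ms
  d_vea <- (cur["I_a"] - cur["I_e"]) / p$C_ma
  c(V_id = unname(d_vid), V_ed = unname(d_ved), V_is = unname(d_vis),
    V_ea = unname(d_vea))
}

#' Simulate the passive compartment model
#'
#' Integrates the four node potentials under given receptor (`I_R`,
#' entering the dendrite from the sensillar lymph) and somatic adaptation
#' (`I_ad`) current time courses with an adaptive explicit Runge-Kutta
#' 5(4) pair, maximum step 0.1 ms, from the resting state. A warning is
#' issued when the provided parameters violate the zero-input equilibrium
#' at the resting potentials (the model then drifts).
#'
#' @param params a [compartment_params()].
#' @param I_R receptor current: a [time_series()], a constant, or `NULL`
#'   for 0.
#' @param I_ad adaptation current, same conventions.
#' @param t_end end time in seconds.
#' @param dt output step in seconds (default 1e-4).
#' @return list with [time_series()] entries `V_id`, `V_ed`, `V_is`,
#'   `V_ea` (mV) and a matrix `currents` (columns `I_ls`, `I_ld`, `I_i`,
#'   `I_a`, `I_e`) on the output grid.
#' @export
simulate_compartments <- function(params = compartment_params(), I_R = NULL,
                                  I_ad = NULL, t_end, dt = 1e-4) {
  stopifnot(inherits(params, "compartment_params"))
  rest <- compartment_rest(params)
  eq <- compartment_currents(rest, params)
  if (max(abs(eq)) > 1e-9)
    warning("simulate_compartments: parameters violate the resting ",
            "equilibrium (max |I| = ", format(max(abs(eq))),
            "); the model will drift")
  ir_fun <- current_fun(I_R)
  iad_fun <- current_fun(I_ad)
  rhs <- function(t, y, parms) {
    list(compartment_deriv(y, params, ir_fun(t), iad_fun(t)))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = rest, times = times, func = rhs, parms = NULL,
                      method = "ode45", hmax = 1e-4, rtol = 1e-8,
                      atol = 1e-10)
  states <- sol[, -1, drop = FALSE]
  cur <- t(apply(states, 1, compartment_currents, params = params))
  mk <- function(col) time_series(states[, col], dt = dt, t_start = 0,
                                  unit = "mV")
  list(V_id = mk("V_id"), V_ed = mk("V_ed"), V_is = mk("V_is"),
       V_ea = mk("V_ea"), currents = cur, times = times)
}

# Coerce a current specification (time_series | constant | NULL) into a
# function of time.
current_fun <- function(x) {
  if (is.null(x)) return(function(t) 0)
  if (inherits(x, "time_series")) return(function(t) ts_at(x, t))
  if (is.numeric(x) && length(x) == 1L) return(function(t) x)
  stop("currents must be a time_series, a constant, or NULL")
}

#' Infer the receptor current reproducing a target LFP
#'
#' Replaces the LFP node equation by the numerical derivative of the
#' target `V_ed` trace and solves it for `I_R` at every step while
#' integrating the remaining three node equations (classical RK4 on the
#' target grid). Forward simulation with the inferred current reproduces
#' the target trace.
#'
#' @param lfp_target a [time_series()] of `V_ed` in mV on a grid with
#'   `dt <= 1e-4` s (pre-smooth noisy targets before inverting:
#'   differentiation amplifies high-frequency noise).
#' @param params a [compartment_params()].
#' @param I_ad adaptation current ([time_series()], constant or `NULL`).
#' @return a [time_series()] of `I_R` on the target grid.
#' @export
infer_receptor_current <- function(lfp_target, params = compartment_params(),
                                   I_ad = NULL) {
  stopifnot(inherits(lfp_target, "time_series"))
  if (lfp_target$dt > 1e-4 + 1e-12)
    stop("infer_receptor_current: grid too coarse (need dt <= 0.1 ms)")
  p <- params
  denom <- p$G_e + p$G_i
  a_coef <- p$G_i / (p$C_md * denom)
  iad_fun <- current_fun(I_ad)
  t <- ts_times(lfp_target)
  n <- length(t)
  dt <- lfp_target$dt
  ved <- lfp_target$values
  # central differences, one-sided at the ends
  dved <- numeric(n)
  dved[1] <- (ved[2] - ved[1]) / dt
  dved[n] <- (ved[n] - ved[n - 1]) / dt
  if (n > 2) dved[2:(n - 1)] <- (ved[3:n] - ved[1:(n - 2)]) / (2 * dt)
  ved_at <- function(tt) ts_at(lfp_target, tt)
  dved_at <- function(tt) stats::approx(t, dved, xout = tt, rule = 2)$y

  solve_ir <- function(state, tt) {
    cur <- compartment_currents(state, p)
    term_a <- (p$G_e / (p$C_ma * denom)) * (cur["I_a"] - cur["I_e"])
    term_s <- (p$G_i / (p$C_ms * denom)) *
      (cur["I_i"] - cur["I_ls"] - iad_fun(tt))
    # dVed/dt = a_coef (I_e - I_R - I_ld) + term_a + term_s
    unname(cur["I_e"] - cur["I_ld"] -
             (dved_at(tt) - term_a - term_s) / a_coef)
  }
  # integrate V_id, V_is, V_ea with V_ed pinned to the target
  deriv3 <- function(state3, tt) {
    state <- c(V_id = unname(state3[1]), V_ed = ved_at(tt),
               V_is = unname(state3[2]), V_ea = unname(state3[3]))
    ir <- solve_ir(state, tt)
    d <- compartment_deriv(state, p, ir, iad_fun(tt))
    list(d = d[c("V_id", "V_is", "V_ea")], ir = ir)
  }
  rest <- compartment_rest(p)
  s <- unname(c(rest["V_id"], rest["V_is"], rest["V_ea"]))
  ir_out <- numeric(n)
  ir_out[1] <- deriv3(s, t[1])$ir
  for (i in seq_len(n - 1)) {
    h <- dt
    k1 <- deriv3(s, t[i])$d
    k2 <- deriv3(s + h / 2 * k1, t[i] + h / 2)$d
    k3 <- deriv3(s + h / 2 * k2, t[i] + h / 2)$d
    k4 <- deriv3(s + h * k3, t[i] + h)$d
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ir_out[i + 1] <- deriv3(s, t[i + 1])$ir
  }
  time_series(ir_out, dt = dt, t_start = lfp_target$t_start, unit = "1")
}

#' Infer the somatic adaptation current for a target somatic potential
#'
#' Fixes the somatic potential `V_is` to a target time course (e.g. shaped
#' like the firing rate), eliminates its node equation via the numerical
#' derivative, and computes the adaptation current
#' `I_ad = I_i - I_ls - C_ms dV_is/dt` while integrating the remaining
#' node equations under the given receptor current.
#'
#' @param I_R receptor current ([time_series()], constant or `NULL`).
#' @param v_is_target a [time_series()] of `V_is` in mV, `dt <= 1e-4` s.
#' @param params a [compartment_params()].
#' @return a [time_series()] of `I_ad` on the target grid.
#' @export
infer_adaptation_current <- function(I_R, v_is_target,
                                     params = compartment_params()) {
  stopifnot(inherits(v_is_target, "time_series"))
  if (v_is_target$dt > 1e-4 + 1e-12)
    stop("infer_adaptation_current: grid too coarse (need dt <= 0.1 ms)")
  p <- params
  ir_fun <- current_fun(I_R)
  t <- ts_times(v_is_target)
  n <- length(t)
  dt <- v_is_target$dt
  vis <- v_is_target$values
  dvis <- numeric(n)
  dvis[1] <- (vis[2] - vis[1]) / dt
  dvis[n] <- (vis[n] - vis[n - 1]) / dt
  if (n > 2) dvis[2:(n - 1)] <- (vis[3:n] - vis[1:(n - 2)]) / (2 * dt)
  vis_at <- function(tt) ts_at(v_is_target, tt)
  dvis_at <- function(tt) stats::approx(t, dvis, xout = tt, rule = 2)$y

  iad_of <- function(state, tt) {
    cur <- compartment_currents(state, p)
    unname(cur["I_i"] - cur["I_ls"] - p$C_ms * dvis_at(tt))
  }
  deriv3 <- function(state3, tt) {
    state <- c(V_id = unname(state3[1]), V_ed = unname(state3[2]),
               V_is = vis_at(tt), V_ea = unname(state3[3]))
    iad <- iad_of(state, tt)
    d <- compartment_deriv(state, p, ir_fun(tt), iad)
    list(d = d[c("V_id", "V_ed", "V_ea")], iad = iad)
  }
  rest <- compartment_rest(p)
  s <- unname(c(rest["V_id"], rest["V_ed"], rest["V_ea"]))
  iad_out <- numeric(n)
  iad_out[1] <- deriv3(s, t[1])$iad
  for (i in seq_len(n - 1)) {
    h <- dt
    k1 <- deriv3(s, t[i])$d
    k2 <- deriv3(s + h / 2 * k1, t[i] + h / 2)$d
    k3 <- deriv3(s + h / 2 * k2, t[i] + h / 2)$d
    k4 <- deriv3(s + h * k3, t[i] + h)$d
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    iad_out[i + 1] <- deriv3(s, t[i + 1])$iad
  }
  time_series(iad_out, dt = dt, t_start = v_is_target$t_start, unit = "1")
}

#' Effective exponential LFP kernel from paired traces
#'
#' Fits `V_ed(t) ~ offset + gain * (g_tau * I_R)(t)` where `g_tau` is a
#' unit-area causal exponential kernel, by one-dimensional optimization
#' over the time constant with inner least squares for gain and offset.
#' The LFP acts as a low-pass filtered image of the receptor current; for
#' the reference parameters the fitted time constant is of order 10 ms
#' (the value depends on the passive constants).
#'
#' @param I_R a [time_series()] of receptor current.
#' @param V_ed a [time_series()] of the recorded LFP from the same
#'   simulation.
#' @param tau_range search interval in seconds.
#' @return list with `tau` (seconds), `gain` (negative: depolarizing
#'   receptor current deflects the LFP downward) and `offset` (mV).
#' @export
estimate_lfp_kernel <- function(I_R, V_ed, tau_range = c(1e-4, 0.5)) {
  stopifnot(inherits(I_R, "time_series"), inherits(V_ed, "time_series"))
  if (stats::sd(I_R$values) == 0 || stats::sd(V_ed$values) == 0)
    stop("estimate_lfp_kernel: zero-variance input")
  fit_at <- function(tau) {
    x <- gamma_filter(I_R, tau, 1)$values
    X <- cbind(1, x)
    f <- stats::lm.fit(X, V_ed$values)
    list(rss = sum(f$residuals^2), coef = f$coefficients)
  }
  opt <- stats::optimize(function(tau) fit_at(tau)$rss,
                         interval = tau_range, tol = 1e-7)
  best <- fit_at(opt$minimum)
  list(tau = opt$minimum, gain = unname(best$coef[2]),
       offset = unname(best$coef[1]))
}
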