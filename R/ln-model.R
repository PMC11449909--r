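#' Linear-nonlinear LFP-to-firing-rate filter
#'
#' The firing rate is predicted as a rectified linear functional of the
#' LFP: `f(t) = max(0, c0 * LFP(t) + sum_k c_k * (g_k * LFP)(t))`, where
#' each `g_k` is a unit-area gamma kernel with time constant `tau_k` and
#' shape `alpha_k` (shape 1 gives the exponential kernel). `tau = 0`
#' denotes the delta kernel, i.e. the unfiltered LFP; the `c0` field is
#' that delta-kernel coefficient. The typical fitted filter has `c0 < 0`
#' (rapid response to the negative LFP deflection) and positive adaptation
#' coefficients on two timescales (tens and hundreds of ms).
#'
#' @param c0 coefficient on the unfiltered LFP (Hz per mV).
#' @param coefficients numeric vector of coefficients `c_k` (Hz per mV).
#' @param taus numeric vector of kernel time constants in seconds
#'   (`>= 0`; 0 entries are folded into `c0`).
#' @param alphas gamma shape parameters (`>= 1`), recycled to the length
#'   of `taus`; default 1 (exponential kernels).
#' @return An object of class `ln_filter`. Components are stored sorted by
#'   `tau`.
#' @examples
#' filt <- ln_filter(c0 = -109.2, coefficients = c(85.8, 18.3),
#'                   taus = c(0.031, 0.635))
#' @export
ln_filter <- function(c0 = 0, coefficients = numeric(), taus = numeric(),
                      alphas = 1) {
  if (length(coefficients) != length(taus))
    stop("ln_filter: coefficients and taus must have equal length")
  alphas <- rep_len(alphas, length(taus))
  if (any(taus < 0)) stop("ln_filter: taus must be >= 0")
  if (any(alphas < 1)) stop("ln_filter: alphas must be >= 1")
  zero <- taus == 0
  if (any(zero)) {
    c0 <- c0 + sum(coefficients[zero])
    coefficients <- coefficients[!zero]
    alphas <- alphas[!zero]
    taus <- taus[!zero]
  }
  o <- order(taus)
  structure(list(c0 = as.numeric(c0), coefficients = as.numeric(coefficients[o]),
                 taus = as.numeric(taus[o]), alphas = as.numeric(alphas[o])),
            class = "ln_filter")
}

#' @export
print.ln_filter <- function(x, ...) {
  cat("<ln_filter> rectified linear LFP filter\n")
  cat(sprintf("  c0 (unfiltered LFP): %.4g\n", x$c0))
  for (k in seq_along(x$taus))
    cat(sprintf("  c%d = %.4g @ tau = %.4g s (alpha = %g)\n",
                k, x$coefficients[k], x$taus[k], x$alphas[k]))
  invisible(x)
}

# Discrete unit-area gamma kernel on a grid with step dt. Weights are bin
# integrals of the continuous kernel (pgamma differences), truncated at
# coverage 1 - 1e-10 and renormalized so the DC gain is exactly 1. tau at
# or below `delta_tol` denotes the delta kernel.
gamma_kernel_weights <- function(tau, alpha, dt, n_max, delta_tol = 1e-9) {
  if (tau <= delta_tol) return(1)
  # length covering essentially all kernel mass, capped at the signal length
  k_len <- min(n_max, max(2L, ceiling(
    stats::qgamma(1 - 1e-10, shape = alpha, scale = tau) / dt) + 1L))
  edges <- dt * (0:k_len)
  w <- diff(stats::pgamma(edges, shape = alpha, scale = tau))
  w / sum(w)
}

#' Causal convolution with a unit-area gamma kernel
#'
#' Convolves the signal with the gamma-density kernel
#' `s^(alpha-1) exp(-s/tau) / (Gamma(alpha) tau^alpha)` (causal, unit
#' area); `alpha = 1` is the exponential kernel and `tau = 0` the delta
#' kernel (identity). The signal is assumed at zero before its first
#' sample (zero initial history).
#'
#' @param series a [time_series()].
#' @param tau kernel time constant in seconds (`>= 0`).
#' @param alpha gamma shape (`>= 1`).
#' @return a [time_series()] on the same grid.
#' @export
gamma_filter <- function(series, tau, alpha = 1) {
  stopifnot(inherits(series, "time_series"))
  if (tau < 0) stop("gamma_filter: tau must be >= 0")
  if (alpha < 1) stop("gamma_filter: alpha must be >= 1")
  x <- series$values
  w <- gamma_kernel_weights(tau, alpha, series$dt, length(x))
  if (length(w) == 1L && w[1] == 1) return(series)
  # causal convolution y_i = sum_j w_j x_{i-j}, FFT-based with the
  # operands zero-padded to a 2-3-5-smooth length (arbitrary lengths can
  # hit slow mixed-radix transforms)
  n <- length(x)
  L <- stats::nextn(n + length(w) - 1, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(w, numeric(L - length(w)))),
                     inverse = TRUE)) / L
  y <- y[seq_len(n)]
  time_series(y, dt = series$dt, t_start = series$t_start, unit = series$unit)
}

# Design matrix of gamma-filtered LFP copies; column 1 is the unfiltered
# LFP (delta kernel).
ln_design <- function(lfp, taus, alphas = rep(1, length(taus))) {
  cols <- c(list(lfp$values),
            lapply(seq_along(taus), function(k)
              gamma_filter(lfp, taus[k], alphas[k])$values))
  do.call(cbind, cols)
}

#' Predict firing rate from the LFP with an LN filter
#'
#' Applies the linear kernel (delta component plus gamma-filtered
#' components) and the rectifying nonlinearity `N(x) = max(0, x)`.
#'
#' @param lfp a [time_series()] of the LFP.
#' @param filt an [ln_filter()].
#' @param rectify logical; set `FALSE` to return the pre-rectifier linear
#'   output (used for fitting and diagnostics).
#' @return a [time_series()] of firing rate in Hz (non-negative when
#'   `rectify = TRUE`).
#' @export
predict_rate <- function(lfp, filt, rectify = TRUE) {
  stopifnot(inherits(lfp, "time_series"), inherits(filt, "ln_filter"))
  X <- ln_design(lfp, filt$taus, filt$alphas)
  lin <- as.numeric(X %*% c(filt$c0, filt$coefficients))
  if (rectify) lin <- pmax(0, lin)
  time_series(lin, dt = lfp$dt, t_start = lfp$t_start, unit = "Hz")
}

#' Least-squares fit of LN coefficients at fixed timescales
#'
#' Ordinary least squares of the firing rate on the unfiltered LFP and its
#' gamma-filtered copies; the rectifier takes part only at prediction, not
#' in the fit. By convention the rate is the kernel estimate with a 30 ms
#' fixed width and the fit window is the stimulus plus the preceding
#' second of spontaneous activity; the function fits whatever window the
#' input traces cover, optionally restricted by `window`.
#'
#' @param lfp a [time_series()] of the LFP.
#' @param rate a [time_series()] of the observed firing rate on the same
#'   grid.
#' @param taus fixed kernel time constants in seconds (0 entries are
#'   redundant with the always-present unfiltered-LFP regressor and are
#'   rejected).
#' @param alphas gamma shapes, recycled; default 1.
#' @param window optional length-2 numeric restricting the fit to
#'   `[window[1], window[2]]` seconds.
#' @param subtract_baseline subtract the mean LFP over the pre-stimulus
#'   second (`t < 0`) before fitting; default `TRUE`.
#' @return an [ln_filter()] with fitted coefficients.
#' @export
fit_ln_coefficients <- function(lfp, rate, taus, alphas = 1, window = NULL,
                                subtract_baseline = TRUE) {
  stopifnot(inherits(lfp, "time_series"), inherits(rate, "time_series"))
  if (length(lfp$values) != length(rate$values) ||
      abs(lfp$dt - rate$dt) > 1e-12)
    stop("fit_ln_coefficients: LFP and rate must share one grid")
  taus <- as.numeric(taus)
  alphas <- rep_len(alphas, length(taus))
  if (any(taus <= 0)) stop("fit_ln_coefficients: taus must be positive")
  if (anyDuplicated(cbind(taus, alphas)))
    stop("fit_ln_coefficients: duplicate (tau, alpha) pairs give a singular design")
  if (subtract_baseline) {
    pre <- ts_times(lfp) < 0
    if (any(pre)) lfp$values <- lfp$values - mean(lfp$values[pre])
  }
  X <- ln_design(lfp, taus, alphas)
  keep <- rep(TRUE, length(rate$values))
  if (!is.null(window)) {
    t <- ts_times(lfp)
    keep <- t >= window[1] & t <= window[2]
  }
  fit <- stats::lm.fit(X[keep, , drop = FALSE], rate$values[keep])
  beta <- fit$coefficients
  if (anyNA(beta)) stop("fit_ln_coefficients: singular design matrix")
  ln_filter(c0 = beta[1], coefficients = beta[-1], taus = taus, alphas = alphas)
}

#' Timescale/shape candidate grid for feature selection
#'
#' The default grid spans 20 time constants log-spaced from 1 ms to 3 s and
#' 17 gamma shapes linearly spaced from 1 to 5, i.e. 340 candidate
#' features.
#'
#' @param n_tau,tau_range number and range (seconds) of time constants.
#' @param n_alpha,alpha_range number and range of gamma shapes.
#' @return An object of class `feature_grid` with fields `taus`, `alphas`.
#' @export
feature_grid <- function(n_tau = 20, tau_range = c(0.001, 3),
                         n_alpha = 17, alpha_range = c(1, 5)) {
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau))
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  structure(list(taus = taus, alphas = alphas), class = "feature_grid")
}

#' Lasso scan over the (tau, alpha) feature grid
#'
#' Fits the firing rate on all gamma-filtered LFP copies of the grid with
#' L1-penalized regression; the penalty is chosen by seeded k-fold
#' cross-validation (`glmnet::cv.glmnet`, `lambda.1se`). Nonzero
#' coefficients concentrate around the informative timescales and seed the
#' subsequent refinement.
#'
#' @param lfp,rate [time_series()] pair on one grid.
#' @param grid a [feature_grid()].
#' @param nfolds cross-validation folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param standardize standardize features before penalization (default
#'   `TRUE`).
#' @return data frame with columns `tau`, `alpha`, `coefficient` for the
#'   nonzero coefficients (zero rows if the target is constant at 0).
#' @export
lasso_scan <- function(lfp, rate, grid = feature_grid(), nfolds = 5,
                       seed = 1, standardize = TRUE) {
  stopifnot(inherits(lfp, "time_series"), inherits(rate, "time_series"),
            inherits(grid, "feature_grid"))
  if (stats::sd(lfp$values) == 0)
    stop("lasso_scan: constant LFP is degenerate")
  combos <- expand.grid(tau = grid$taus, alpha = grid$alphas,
                        KEEP.OUT.ATTRS = FALSE)
  X <- do.call(cbind, lapply(seq_len(nrow(combos)), function(i)
    gamma_filter(lfp, combos$tau[i], combos$alpha[i])$values))
  cv <- with_local_seed(seed,
    glmnet::cv.glmnet(X, rate$values, alpha = 1, nfolds = nfolds,
                      standardize = standardize))
  beta <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
  nz <- which(beta != 0)
  data.frame(tau = combos$tau[nz], alpha = combos$alpha[nz],
             coefficient = beta[nz])
}

#' Bounded quasi-Newton refinement of the kernel timescales
#'
#' Starting from initial time constants (typically the clusters of the
#' lasso scan), minimizes the squared prediction error over the
#' timescales with `L-BFGS-B`, solving for the coefficients by ordinary
#' least squares at every step (shapes fixed at `alpha = 1`). The lower
#' bound of every timescale is 0, where the kernel degenerates to the
#' delta function (unfiltered LFP); timescales refined to 0 are therefore
#' folded into the `c0` coefficient of the returned filter.
#'
#' @param lfp,rate [time_series()] pair on one grid.
#' @param init_taus initial time constants in seconds.
#' @param window optional fit window, as in [fit_ln_coefficients()].
#' @param subtract_baseline as in [fit_ln_coefficients()].
#' @param control passed to [stats::optim()]; defaults set a tight
#'   tolerance (`factr = 1e4`).
#' @return an [ln_filter()]; attributes `converged` and `message` carry the
#'   optimizer diagnostics (best-so-far parameters are returned either
#'   way).
#' @export
refine_timescales <- function(lfp, rate, init_taus, window = NULL,
                              subtract_baseline = TRUE, control = list()) {
  stopifnot(inherits(lfp, "time_series"), inherits(rate, "time_series"))
  init_taus <- sort(as.numeric(init_taus))
  if (any(init_taus < 0)) stop("refine_timescales: taus must be >= 0")
  if (subtract_baseline) {
    pre <- ts_times(lfp) < 0
    if (any(pre)) lfp$values <- lfp$values - mean(lfp$values[pre])
  }
  keep <- rep(TRUE, length(rate$values))
  if (!is.null(window)) {
    t <- ts_times(lfp)
    keep <- t >= window[1] & t <= window[2]
  }
  y <- rate$values[keep]
  # design of the refined filter: one kernel column per component; a tau
  # at the 0 bound degenerates to the delta kernel (unfiltered LFP), so no
  # separate delta column is added. lm.fit handles the rank deficiency
  # arising when two taus coincide.
  design <- function(taus)
    do.call(cbind, lapply(taus, function(tk)
      gamma_filter(lfp, tk, 1)$values))[keep, , drop = FALSE]
  rss <- function(taus) sum(stats::lm.fit(design(pmax(taus, 0)), y)$residuals^2)
  # finite-difference step sized for timescales measured in seconds
  ctrl <- utils::modifyList(
    list(factr = 1e4, maxit = 500, ndeps = rep(1e-5, length(init_taus))),
    control)
  opt <- stats::optim(init_taus, rss, method = "L-BFGS-B",
                      lower = rep(0, length(init_taus)),
                      upper = rep(10, length(init_taus)),
                      control = ctrl)
  taus <- pmax(opt$par, 0)
  beta <- stats::lm.fit(design(taus), y)$coefficients
  beta[is.na(beta)] <- 0
  # taus below the grid resolution act as delta kernels; fold them into c0
  delta <- taus < lfp$dt / 2
  filt <- ln_filter(c0 = sum(beta[delta]), coefficients = beta[!delta],
                    taus = taus[!delta])
  attr(filt, "converged") <- opt$convergence == 0
  attr(filt, "message") <- opt$message
  attr(filt, "rss") <- opt$value
  if (opt$convergence != 0)
    warning("refine_timescales: optimizer did not converge (",
            opt$message, "); returning best-so-far parameters")
  filt
}
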