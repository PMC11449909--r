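#' Kernel-density rate estimation configuration
#'
#' Parameters of the adaptive kernel width used for firing-rate estimation.
#' Each spike is replaced by a normal density with standard deviation
#' `sigma = bw / 2`; the width `bw` is time dependent (see
#' [bandwidth_at()]): narrow (`bw_min`) before stimulus onset to resolve
#' the sharp transient, widening towards the plateau with time constant
#' `tau_kde` to suppress noise at low rates. A `fixed_bw` overrides the
#' adaptive schedule.
#'
#' @param bw_min minimum kernel width in seconds (default 0.010).
#' @param bw_max width scale after onset in seconds (default 0.100).
#' @param tau_kde widening time constant in seconds (default 0.500).
#' @param fixed_bw optional fixed kernel width in seconds.
#' @param smooth logical; if `TRUE` use the continuous variant
#'   `bw_min + (bw_max - bw_min) * (1 - exp(-t / tau_kde))` instead of the
#'   literature form, which jumps from `bw_min` to `bw_max` at `t = 0` and
#'   tends to `bw_max + bw_min` (see [bandwidth_at()]).
#' @return An object of class `kde_config`.
#' @export
kde_config <- function(bw_min = 0.010, bw_max = 0.100, tau_kde = 0.500,
                       fixed_bw = NULL, smooth = FALSE) {
  if (!(bw_min > 0 && bw_min <= bw_max)) stop("kde_config: need 0 < bw_min <= bw_max")
  if (tau_kde <= 0) stop("kde_config: tau_kde must be positive")
  if (!is.null(fixed_bw) && fixed_bw <= 0) stop("kde_config: fixed_bw must be positive")
  structure(list(bw_min = bw_min, bw_max = bw_max, tau_kde = tau_kde,
                 fixed_bw = fixed_bw, smooth = isTRUE(smooth)),
            class = "kde_config")
}

#' Time-dependent kernel width
#'
#' Implements the published adaptive bandwidth exactly as printed:
#' `bw(t) = bw_min` for `t < 0` and
#' `bw(t) = bw_max - bw_min * exp(-t / tau_kde) + bw_min` for `t > 0`
#' (stimulus onset at 0). As printed the schedule jumps to `bw_max` at
#' `t = 0+` and tends to `bw_max + bw_min` for large `t`; a smooth variant
#' growing from `bw_min` to `bw_max` is available via
#' `kde_config(smooth = TRUE)`.
#'
#' @param t numeric vector of times in seconds.
#' @param cfg a [kde_config()].
#' @return numeric vector of kernel widths in seconds.
#' @export
bandwidth_at <- function(t, cfg = kde_config()) {
  stopifnot(inherits(cfg, "kde_config"))
  if (!is.null(cfg$fixed_bw)) return(rep(cfg$fixed_bw, length(t)))
  bw <- if (cfg$smooth) {
    cfg$bw_min + (cfg$bw_max - cfg$bw_min) * (1 - exp(-pmax(t, 0) / cfg$tau_kde))
  } else {
    cfg$bw_max - cfg$bw_min * exp(-t / cfg$tau_kde) + cfg$bw_min
  }
  bw[t < 0] <- cfg$bw_min
  bw
}

#' Firing rate by kernel density estimation
#'
#' Each spike contributes a normal probability density centred on the
#' spike time with standard deviation `bw(t) / 2`, where the width is
#' evaluated at the grid time (adaptive schedule) or fixed. The resulting
#' trace has units of Hz and, for a fixed width, integrates to the spike
#' count.
#'
#' @param train a [spike_train()].
#' @param cfg a [kde_config()].
#' @param grid a [time_series()] whose grid is used for evaluation, or a
#'   numeric vector of times.
#' @return a [time_series()] of firing rate in Hz on the grid.
#' @export
kde_rate <- function(train, cfg = kde_config(), grid) {
  stopifnot(inherits(train, "spike_train"), inherits(cfg, "kde_config"))
  if (inherits(grid, "time_series")) {
    t <- ts_times(grid); dt <- grid$dt; t0 <- grid$t_start
  } else {
    t <- as.numeric(grid)
    if (length(t) < 1L) stop("kde_rate: empty grid")
    dt <- if (length(t) > 1) t[2] - t[1] else 1
    t0 <- t[1]
  }
  if (length(t) < 1L) stop("kde_rate: empty grid")
  sigma <- bandwidth_at(t, cfg) / 2
  rate <- numeric(length(t))
  for (s in train$times) rate <- rate + stats::dnorm(t, mean = s, sd = sigma)
  time_series(rate, dt = dt, t_start = t0, unit = "Hz")
}

#' Response-end detection from the terminating inter-spike interval
#'
#' The response end is the spike initiating the first inter-spike interval
#' that (a) finishes after stimulus offset and (b) exceeds
#' `isi_threshold`. The interval following the last spike is treated as
#' unbounded, so a neuron that stops firing during the stimulus has its
#' response end before the stimulus offset. The response end is only
#' computed for responders, i.e. trains with at least `min_onset_spikes`
#' spikes in the first 100 ms after stimulus onset; `NA` marks a
#' non-responder.
#'
#' @param train a [spike_train()].
#' @param stim a [stimulus_protocol()] with a single pulse (onset at 0).
#' @param isi_threshold terminating ISI threshold in seconds (default 0.100).
#' @param min_onset_spikes responder criterion: minimum number of spikes in
#'   the first 100 ms after onset (default 5; set 0 to disable).
#' @param onset_window length of the onset window for the responder
#'   criterion in seconds (default 0.100).
#' @return response-end time in seconds, or `NA_real_` for a non-responder.
#' @export
response_end <- function(train, stim, isi_threshold = 0.100,
                         min_onset_spikes = 5, onset_window = 0.100) {
  stopifnot(inherits(train, "spike_train"), inherits(stim, "stimulus_protocol"))
  onset <- min(stim$intervals[, 1])
  offset <- protocol_offset(stim)
  times <- train$times
  if (sum(times >= onset & times <= onset + onset_window) < min_onset_spikes)
    return(NA_real_)
  if (!length(times)) return(NA_real_)
  isi_start <- times
  isi_end <- c(times[-1], Inf)
  qualifying <- (isi_end > offset) & ((isi_end - isi_start) > isi_threshold)
  idx <- which(qualifying)
  if (!length(idx)) return(NA_real_)
  isi_start[idx[1]]
}

#' Median response end over a cohort
#'
#' Median of the individual response ends over responders only.
#'
#' @param trains list of [spike_train()] objects.
#' @param stim a [stimulus_protocol()].
#' @param ... passed to [response_end()].
#' @return median response-end time in seconds.
#' @export
median_response_end <- function(trains, stim, ...) {
  ends <- vapply(trains, response_end, numeric(1), stim = stim, ...)
  ends <- ends[!is.na(ends)]
  if (!length(ends)) stop("median_response_end: no responders in cohort")
  stats::median(ends)
}

#' Inhibitory- and rebound-phase windows
#'
#' Windows relative to the response end in which firing rates are compared:
#' the inhibitory phase (default 0.1-0.4 s after the response end) and the
#' rebound phase (default 1-3 s after the response end).
#'
#' @param inhibitory length-2 numeric, inhibitory window in seconds
#'   relative to the response end.
#' @param rebound length-2 numeric, rebound window in seconds relative to
#'   the response end.
#' @return An object of class `phase_windows`.
#' @export
phase_windows <- function(inhibitory = c(0.1, 0.4), rebound = c(1, 3)) {
  inhibitory <- as.numeric(inhibitory); rebound <- as.numeric(rebound)
  if (diff(inhibitory) <= 0 || diff(rebound) <= 0)
    stop("phase_windows: windows must have positive length")
  if (inhibitory[2] > rebound[1] && rebound[2] > inhibitory[1])
    stop("phase_windows: windows must not overlap")
  structure(list(inhibitory = inhibitory, rebound = rebound),
            class = "phase_windows")
}

#' Firing rates in the inhibitory and rebound phases
#'
#' Spike counts in each window (placed relative to the response end)
#' divided by the window length.
#'
#' @param train a [spike_train()].
#' @param end response-end time in seconds (finite).
#' @param win a [phase_windows()].
#' @return named numeric vector `c(inhibitory = , rebound = )` in Hz.
#' @export
phase_rates <- function(train, end, win = phase_windows()) {
  stopifnot(inherits(train, "spike_train"), inherits(win, "phase_windows"))
  if (!is.finite(end)) stop("phase_rates: response end must be finite")
  rate_in <- function(w) {
    lo <- end + w[1]; hi <- end + w[2]
    if (length(train$times) && (hi > train$window[2] + 1e-9))
      stop("phase_rates: window extends beyond the recording")
    sum(train$times >= lo & train$times < hi) / (hi - lo)
  }
  c(inhibitory = rate_in(win$inhibitory), rebound = rate_in(win$rebound))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed paired signed-rank test reporting the statistic `T` (the
#' smaller of the positive/negative rank sums over nonzero differences;
#' zero differences are dropped). The p-value is exact (from the signed-rank
#' distribution) for `n <= 25` without ties in the absolute differences,
#' and uses the tie-corrected normal approximation otherwise.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `T` (statistic), `p` (two-tailed p-value), `n` (number
#'   of nonzero differences).
#' @export
paired_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired_signed_rank: unequal lengths")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("paired_signed_rank: all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  T_stat <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # P(W <= T) for the smaller rank sum, doubled; psignrank is the CDF of
    # the positive rank sum under H0.
    p <- 2 * stats::psignrank(T_stat, n)
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (T_stat - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(T = T_stat, p = p, n = n)
}

#' Spearman rank correlation
#'
#' Rank correlation with tie correction, as used to relate stimulus dose to
#' the rebound-minus-inhibitory rate contrast.
#'
#' @param dose,contrast numeric vectors of equal length (>= 3).
#' @return list with `r` (Spearman correlation) and `p` (two-tailed).
#' @export
rank_correlation <- function(dose, contrast) {
  if (length(dose) != length(contrast)) stop("rank_correlation: unequal lengths")
  if (length(dose) < 3) stop("rank_correlation: need at least 3 pairs")
  if (stats::sd(dose) == 0 || stats::sd(contrast) == 0)
    stop("rank_correlation: constant input")
  ct <- suppressWarnings(
    stats::cor.test(dose, contrast, method = "spearman", exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Normalize a rate profile to its peak
#'
#' @param rate a [time_series()] with positive maximum.
#' @return a dimensionless [time_series()] with peak 1.
#' @export
normalize_profile <- function(rate) {
  stopifnot(inherits(rate, "time_series"))
  m <- max(rate$values)
  if (m <= 0) stop("normalize_profile: non-positive maximum")
  time_series(rate$values / m, dt = rate$dt, t_start = rate$t_start, unit = "1")
}
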