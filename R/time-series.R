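#' Uniformly sampled signal
#'
#' Container for a uniformly sampled trace: an LFP in mV, a firing rate in
#' Hz, an odor concentration in M, or a dimensionless signal. Time is in
#' seconds; by package convention stimulus onset is at `t = 0`, so traces
#' usually start at a negative `t_start` (pre-stimulus baseline).
#'
#' @param values numeric vector of samples; must be finite, length >= 1.
#' @param dt sampling step in seconds (> 0).
#' @param t_start time of the first sample in seconds.
#' @param unit unit tag, one of `"mV"`, `"Hz"`, `"M"`, `"1"`.
#' @return An object of class `time_series` with fields `t_start`, `dt`,
#'   `values`, `unit`.
#' @examples
#' ts <- time_series(sin(seq(0, 1, by = 0.01)), dt = 0.01)
#' ts_times(ts)[1:3]
#' @export
time_series <- function(values, dt, t_start = 0, unit = "1") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time_series: need at least one sample")
  if (!all(is.finite(values))) stop("time_series: all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("time_series: dt must be a single positive number")
  unit <- match.arg(unit, c("1", "mV", "Hz", "M"))
  structure(
    list(t_start = as.numeric(t_start), dt = dt, values = values, unit = unit),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %d samples @ dt = %g s, t = [%g, %g] s, unit = %s\n",
    length(x$values), x$dt, x$t_start, ts_end(x), x$unit
  ))
  invisible(x)
}

#' Sample times of a time series
#' @param x a [time_series()].
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t_start + x$dt * (seq_along(x$values) - 1)
}

#' Time of the last sample
#' @param x a [time_series()].
#' @return time of the last sample in seconds.
#' @export
ts_end <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t_start + x$dt * (length(x$values) - 1)
}

#' Linear interpolation of a time series at arbitrary times
#'
#' Values outside the sampled window take the nearest endpoint value.
#'
#' @param x a [time_series()].
#' @param t numeric vector of times in seconds.
#' @return numeric vector of interpolated values.
#' @export
ts_at <- function(x, t) {
  stopifnot(inherits(x, "time_series"))
  if (length(x$values) == 1L) return(rep(x$values, length(t)))
  stats::approx(ts_times(x), x$values, xout = t, rule = 2)$y
}

#' Resample a time series onto a new uniform grid
#'
#' Linear interpolation onto a grid with the same start time and step
#' `new_dt`; the new grid spans the original window (the last grid point is
#' the last one not exceeding the original end time). Resampling onto the
#' current `dt` returns the series unchanged.
#'
#' @param series a [time_series()].
#' @param new_dt new sampling step in seconds (> 0).
#' @return a [time_series()] on the new grid.
#' @export
resample <- function(series, new_dt) {
  stopifnot(inherits(series, "time_series"))
  if (!is.numeric(new_dt) || length(new_dt) != 1L || !is.finite(new_dt) ||
      new_dt <= 0)
    stop("resample: new_dt must be a single positive number")
  if (isTRUE(all.equal(new_dt, series$dt))) return(series)
  n_new <- floor((ts_end(series) - series$t_start) / new_dt + 1e-9) + 1L
  t_new <- series$t_start + new_dt * (seq_len(n_new) - 1)
  time_series(ts_at(series, t_new), dt = new_dt, t_start = series$t_start,
              unit = series$unit)
}

#' Two-pole Butterworth low-pass filter
#'
#' The filter used to separate the slow LFP from spike transients in
#' single-sensillum recordings (15 Hz cutoff) and for display filtering
#' (49 Hz). DC gain is 1 and the magnitude response at the cutoff is
#' 1/sqrt(2). The default is a causal (forward-only) filter matching online
#' acquisition; `zero_phase = TRUE` applies the filter forward and backward
#' (`signal::filtfilt`), which doubles the attenuation and removes the
#' phase lag.
#'
#' @param series a [time_series()].
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * dt)`.
#' @param zero_phase logical; apply forward-backward filtering.
#' @return a filtered [time_series()] with the same grid.
#' @export
lowpass_2pole <- function(series, cutoff, zero_phase = FALSE) {
  stopifnot(inherits(series, "time_series"))
  nyquist <- 1 / (2 * series$dt)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyquist)
    stop(sprintf("lowpass_2pole: cutoff must be in (0, %g) Hz", nyquist))
  bf <- signal::butter(2, cutoff / nyquist, type = "low")
  y <- if (zero_phase) {
    signal::filtfilt(bf, series$values)
  } else {
    as.numeric(signal::filter(bf, series$values))
  }
  time_series(y, dt = series$dt, t_start = series$t_start, unit = series$unit)
}

#' Write a trace to delimited text
#'
#' Two tab-separated columns `t` (seconds) and `value`, with a header row.
#' Values are written with full double precision so that a write/read round
#' trip is lossless.
#'
#' @param series a [time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(series, path) {
  stopifnot(inherits(series, "time_series"))
  df <- data.frame(t = sprintf("%.17g", ts_times(series)),
                   value = sprintf("%.17g", series$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Expects two columns `t` and `value` as written by [write_trace()]. The
#' time column must form a uniform ascending grid.
#'
#' @param path input file path.
#' @param unit unit tag passed to [time_series()].
#' @return a [time_series()].
#' @export
read_trace <- function(path, unit = "1") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t", "value") %in% names(df)))
    stop("read_trace: expected columns 't' and 'value' in ", path)
  t <- as.numeric(df$t)
  if (anyNA(t) || anyNA(df$value))
    stop("read_trace: non-numeric entries in ", path)
  if (length(t) > 1L) {
    dts <- diff(t)
    if (any(dts <= 0) || (max(dts) - min(dts)) > 1e-9 * max(dts))
      stop("read_trace: time column is not a uniform ascending grid")
    dt <- stats::median(dts)
  } else {
    dt <- 1
  }
  time_series(as.numeric(df$value), dt = dt, t_start = t[1], unit = unit)
}

# Run code with a deterministic, locally scoped RNG state. Used by every
# stochastic operation that takes a `seed` argument so that global RNG
# state is never clobbered.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
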