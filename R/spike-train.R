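#' Spike train
#'
#' Ascending spike times within a recording window. Duplicate times (ties)
#' are possible at 10 kHz quantization and are kept with a warning;
#' strictly descending input is rejected.
#'
#' @param times numeric vector of spike times in seconds, ascending
#'   (ties allowed).
#' @param window length-2 numeric, recording window `(t_min, t_max)`;
#'   defaults to the span of `times` (or `c(0, 0)` for an empty train).
#' @param sensillum,trial optional identifiers kept as attributes for
#'   bookkeeping.
#' @return An object of class `spike_train` with fields `times`, `window`.
#' @export
spike_train <- function(times, window = NULL, sensillum = NA, trial = NA) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike_train: non-numeric spike times")
  if (is.unsorted(times, strictly = FALSE))
    stop("spike_train: spike times must be ascending")
  if (anyDuplicated(times))
    warning("spike_train: duplicate spike times kept")
  if (is.null(window)) {
    window <- if (length(times)) range(times) else c(0, 0)
  }
  window <- as.numeric(window)
  if (length(window) != 2L || window[2] < window[1])
    stop("spike_train: window must be (t_min, t_max) with t_max >= t_min")
  if (length(times) && (times[1] < window[1] || times[length(times)] > window[2]))
    stop("spike_train: spike times outside the recording window")
  structure(
    list(times = times, window = window, sensillum = sensillum, trial = trial),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in [%g, %g] s (sensillum %s, trial %s)\n",
              length(x$times), x$window[1], x$window[2],
              as.character(x$sensillum), as.character(x$trial)))
  invisible(x)
}

#' Stimulus protocol
#'
#' A set of disjoint, ascending valve-open intervals with the odorant
#' concentration delivered while the valve is open. Stimulus onset is at
#' `t = 0` by package convention.
#'
#' @param intervals two-column matrix (or list of length-2 vectors) of
#'   `(on, off)` times in seconds; `off > on`, intervals disjoint and
#'   ascending.
#' @param concentration odorant concentration in M while the valve is open.
#' @param dose optional dose label (e.g. `"100 pg"`) for bookkeeping.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(intervals, concentration = 1e-11, dose = NA) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (nrow(intervals) > 0) {
    if (any(intervals[, 2] <= intervals[, 1]))
      stop("stimulus_protocol: each interval needs off > on")
    if (nrow(intervals) > 1) {
      flat <- as.vector(t(intervals))
      if (is.unsorted(flat, strictly = TRUE))
        stop("stimulus_protocol: intervals must be disjoint and ascending")
    }
  }
  if (concentration < 0) stop("stimulus_protocol: negative concentration")
  structure(
    list(intervals = intervals, concentration = concentration, dose = dose),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d interval(s), [O] = %g M, dose = %s\n",
              nrow(x$intervals), x$concentration, as.character(x$dose)))
  invisible(x)
}

#' Odor concentration trace implied by a protocol
#'
#' Square-wave concentration: `concentration` M while the valve is open,
#' 0 otherwise.
#'
#' @param stim a [stimulus_protocol()].
#' @param t numeric vector of times in seconds.
#' @return numeric vector of concentrations in M.
#' @export
protocol_concentration <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  conc <- numeric(length(t))
  for (i in seq_len(nrow(stim$intervals))) {
    on <- stim$intervals[i, 1]; off <- stim$intervals[i, 2]
    conc[t >= on & t < off] <- stim$concentration
  }
  conc
}

#' End of the last stimulus interval
#' @param stim a [stimulus_protocol()].
#' @return offset time of the final interval in seconds.
#' @export
protocol_offset <- function(stim) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  if (nrow(stim$intervals) == 0) stop("protocol_offset: empty protocol")
  max(stim$intervals[, 2])
}

#' Read spike trains from delimited text
#'
#' One spike per row with columns `sensillum_id`, `trial_id`, `time_s`
#' (tab-separated, header row). Rows are grouped per (sensillum, trial)
#' pair; ascending order within each train is enforced.
#'
#' @param path input file path.
#' @param window optional recording window applied to all trains; defaults
#'   to each train's own span.
#' @return list of [spike_train()] objects (empty list for an empty file).
#' @export
read_spike_trains <- function(path, window = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"))
  if (!all(c("sensillum_id", "trial_id", "time_s") %in% names(df)))
    stop("read_spike_trains: expected columns sensillum_id, trial_id, time_s")
  if (nrow(df) == 0) return(list())
  t <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop(sprintf("read_spike_trains: non-numeric time '%s' at data line %d",
                 df$time_s[bad], bad))
  }
  key <- paste(df$sensillum_id, df$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    ti <- t[idx]
    if (is.unsorted(ti, strictly = FALSE))
      stop(sprintf(
        "read_spike_trains: descending spike times for sensillum %s trial %s",
        df$sensillum_id[idx[1]], df$trial_id[idx[1]]))
    spike_train(ti, window = window,
                sensillum = df$sensillum_id[idx[1]],
                trial = df$trial_id[idx[1]])
  })
}

#' Write spike trains to delimited text
#'
#' Inverse of [read_spike_trains()]: tab-separated columns
#' `sensillum_id`, `trial_id`, `time_s` with full double precision.
#'
#' @param trains list of [spike_train()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  rows <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    stopifnot(inherits(tr, "spike_train"))
    if (!length(tr$times)) return(NULL)
    data.frame(
      sensillum_id = as.character(if (is.na(tr$sensillum)) i else tr$sensillum),
      trial_id = as.character(if (is.na(tr$trial)) 1 else tr$trial),
      time_s = sprintf("%.17g", tr$times)
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(sensillum_id = character(), trial_id = character(),
                     time_s = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
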