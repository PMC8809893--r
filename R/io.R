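#' Read spike times from a delimited file
#'
#' Expects a comma-separated file with a header row and columns `unit_id`
#' and `time_s`.  Times are seconds from session start.  Rows are grouped by
#' unit; unsorted times are sorted (with a warning) and exact duplicate times
#' within a unit are collapsed (with a warning).
#'
#' @param path Path to a CSV file.
#' @return A named list of [spike_train] objects, one per unit.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "time_s")
  if (!all(need %in% names(df)))
    stop("spike file must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$time_s)) stop("time_s must be numeric")
  session <- if ("session_id" %in% names(df)) df$session_id[1] else "s1"
  out <- lapply(split(df$time_s, df$unit_id), function(tt) {
    if (is.unsorted(tt)) {
      warning("spike times not sorted in input; sorting")
      tt <- sort(tt)
    }
    dup <- duplicated(tt)
    if (any(dup)) {
      warning(sprintf("collapsed %d duplicate spike time(s)", sum(dup)))
      tt <- tt[!dup]
    }
    tt
  })
  mapply(function(tt, uid) spike_train(tt, unit_id = uid, session_id = session),
         out, names(out), SIMPLIFY = FALSE)
}

#' Write spike trains to a delimited file
#'
#' @param trains A [spike_train] or list of them.
#' @param path Output CSV path.
#' @export
write_spikes <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(st)
    data.frame(unit_id = st$unit_id, time_s = st$times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pupil trace from a delimited file
#'
#' Expects columns `time_s` and `diameter`.  Timestamps must be
#' non-decreasing and approximately regular at the declared rate; samples are
#' snapped to the uniform grid `t0 + k/rate` (jitter below half a sample
#' period is absorbed).  Missing samples and `NA`/`NaN` diameters are filled
#' by linear interpolation for gaps up to `max_gap` seconds (blinks and brief
#' tracking losses); longer gaps or more than 20% missing samples raise an
#' error.  The interpolated fraction is reported via `message()`.
#'
#' @param path Path to a CSV file.
#' @param rate Declared sampling rate in Hz.
#' @param units Units of the stored diameters (`"mm"` or `"z"`).
#' @param max_gap Longest gap, in seconds, to fill by interpolation.
#' @return A [pupil_trace].
#' @export
read_pupil <- function(path, rate, units = "mm", max_gap = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "diameter")
  if (!all(need %in% names(df)))
    stop("pupil file must have columns: ", paste(need, collapse = ", "))
  t <- df$time_s
  if (is.unsorted(t)) stop("time_s must be non-decreasing")
  t0 <- t[1]
  k <- round((t - t0) * rate)
  if (any(abs((t - t0) * rate - k) > 0.5 + 1e-9))
    stop("timestamps deviate from the declared rate by more than half a sample")
  if (anyDuplicated(k)) stop("two samples snap to the same grid point")
  n <- k[length(k)] + 1
  vals <- rep(NA_real_, n)
  vals[k + 1] <- df$diameter
  vals[!is.finite(vals)] <- NA_real_
  miss <- is.na(vals)
  if (mean(miss) > 0.2)
    stop(sprintf("%.1f%% of samples missing (> 20%%)", 100 * mean(miss)))
  if (any(miss)) {
    runs <- rle(miss)
    if (any(runs$lengths[runs$values] / rate > max_gap))
      stop("gap longer than max_gap; split the recording instead")
    if (miss[1] || miss[n]) stop("trace must not start or end with a gap")
    vals <- stats::approx(which(!miss), vals[!miss], xout = seq_len(n))$y
    message(sprintf("interpolated %.2f%% of samples", 100 * mean(miss)))
  }
  pupil_trace(vals, rate = rate, t0 = t0, units = units)
}

#' Write a pupil trace to a delimited file
#'
#' @param trace A [pupil_trace].
#' @param path Output CSV path.
#' @export
write_pupil <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace_times(trace), diameter = trace$values),
    path, row.names = FALSE)
  invisible(path)
}

#' Read and write lick times
#'
#' Lick files have a single `time_s` column.
#'
#' @param path CSV path.
#' @return `read_licks()`: a sorted numeric vector of lick times (seconds).
#' @export
read_licks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("lick file must have column time_s")
  sort(as.numeric(df$time_s))
}

#' @rdname read_licks
#' @param licks Numeric vector of lick times.
#' @export
write_licks <- function(licks, path) {
  utils::write.csv(data.frame(time_s = as.numeric(licks)), path,
                   row.names = FALSE)
  invisible(path)
}

.outcomes <- c("hit", "miss", "fa", "cr")

# outcome implied by (stim_present, response) in a Go/NoGo task
implied_outcome <- function(stim_present, response) {
  ifelse(stim_present,
         ifelse(response, "hit", "miss"),
         ifelse(response, "fa", "cr"))
}

#' Read a Go/NoGo trial table
#'
#' Expects columns `trial_id`, `stim_present`, `response`, `outcome`.
#' Outcomes must be consistent with (`stim_present`, `response`):
#' hit/miss on go (stimulus) trials, fa/cr on nogo trials.
#'
#' @param path CSV path.
#' @return A data.frame of class `trial_table`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "stim_present", "response", "outcome")
  if (!all(need %in% names(df)))
    stop("trial file must have columns: ", paste(need, collapse = ", "))
  df$stim_present <- as.logical(df$stim_present)
  df$response <- as.logical(df$response)
  validate_trials(df)
}

validate_trials <- function(df) {
  if (!all(df$outcome %in% .outcomes))
    stop("outcome must be one of: ", paste(.outcomes, collapse = ", "))
  bad <- df$outcome != implied_outcome(df$stim_present, df$response)
  if (any(bad))
    stop(sprintf("%d trial(s) have outcomes inconsistent with stim/response",
                 sum(bad)))
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname read_trials
#' @param trials A trial table data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("trial_id", "stim_present",
                                             "response", "outcome")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an optogenetic stimulation trial table
#'
#' Expects columns `onset_s`, `pulse_ms`, `n_pulses`, `freq_hz`.  Onsets must
#' be increasing with inter-trial intervals of at least `min_iti` seconds
#' (stimulation patterns are delivered tens of seconds apart so evoked pupil
#' responses do not overlap).
#'
#' @param path CSV path.
#' @param min_iti Minimum allowed inter-trial interval in seconds.
#' @return A data.frame of class `stim_trial_table`.
#' @export
read_stim_trials <- function(path, min_iti = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "pulse_ms", "n_pulses", "freq_hz")
  if (!all(need %in% names(df)))
    stop("stim trial file must have columns: ", paste(need, collapse = ", "))
  validate_stim_trials(df, min_iti = min_iti)
}

validate_stim_trials <- function(df, min_iti = 10) {
  if (is.unsorted(df$onset_s, strictly = TRUE))
    stop("stimulation onsets must be strictly increasing")
  if (nrow(df) > 1 && any(diff(df$onset_s) < min_iti))
    stop(sprintf("inter-trial interval below %g s", min_iti))
  class(df) <- c("stim_trial_table", "data.frame")
  df
}

#' @rdname read_stim_trials
#' @param stim A stim trial table data.frame.
#' @export
write_stim_trials <- function(stim, path) {
  utils::write.csv(as.data.frame(stim)[, c("onset_s", "pulse_ms",
                                           "n_pulses", "freq_hz")],
                   path, row.names = FALSE)
  invisible(path)
}
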