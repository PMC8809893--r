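#' Construct a spike train
#'
#' A spike train holds the ordered spike times (seconds from session start)
#' of one single unit within one recording session.
#'
#' @param times Numeric vector of spike times in seconds, strictly increasing.
#' @param unit_id Identifier of the unit.
#' @param session_id Identifier of the recording session.
#' @param t_start,t_end Session bounds in seconds.  Defaults cover the spikes.
#' @return An object of class `spike_train` with fields `unit_id`, `times`,
#'   `session_id`, `t_start`, `t_end`.
#' @examples
#' st <- spike_train(c(0.5, 1.2, 3.4))
#' n_spikes(st)
#' @export
spike_train <- function(times, unit_id = "u1", session_id = "s1",
                        t_start = 0, t_end = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must be finite, non-missing numbers")
  if (is.null(t_end)) t_end <- if (length(times)) max(times) else t_start
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < t_start || times[length(times)] > t_end))
    stop("spike times must lie within [t_start, t_end]")
  structure(
    list(unit_id = as.character(unit_id), times = times,
         session_id = as.character(session_id),
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "spike_train")
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s, session %s: %d spikes in [%.2f, %.2f] s\n",
              x$unit_id, x$session_id, n_spikes(x), x$t_start, x$t_end))
  invisible(x)
}

#' Construct a pupil diameter trace
#'
#' A regularly sampled pupil diameter time series.  Samples are interpreted
#' as interval-start timestamps: sample `k` (1-based) is the value at time
#' `t0 + (k - 1) / rate`.
#'
#' @param values Numeric vector of diameters.  Units are given by `units`:
#'   `"mm"` for raw diameters, `"z"` for session z-scored values, `"pct"`
#'   for percent change from baseline.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units One of `"mm"`, `"z"`, `"pct"`.
#' @param session_id Session identifier.
#' @return An object of class `pupil_trace`.
#' @examples
#' tr <- pupil_trace(sin(seq(0, 20, by = 0.02)), rate = 50)
#' trace_duration(tr)
#' @export
pupil_trace <- function(values, rate, t0 = 0, units = c("mm", "z", "pct"),
                        session_id = "s1") {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  if (length(values) < 2) stop("a pupil trace needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("pupil trace values must be finite; fill gaps before construction")
  structure(
    list(t0 = as.numeric(t0), rate = as.numeric(rate), values = values,
         units = units, session_id = as.character(session_id)),
    class = "pupil_trace")
}

#' @rdname pupil_trace
#' @param x A `pupil_trace`.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$rate

#' @rdname pupil_trace
#' @export
trace_duration <- function(x) (length(x$values) - 1) / x$rate

#' @rdname pupil_trace
#' @export
trace_end <- function(x) x$t0 + trace_duration(x)

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace> session %s: %d samples at %g Hz (%s), t = [%.2f, %.2f] s\n",
              x$session_id, length(x$values), x$rate, x$units,
              x$t0, trace_end(x)))
  invisible(x)
}

# value of the trace at arbitrary times (nearest-sample lookup)
trace_at <- function(x, t) {
  idx <- round((t - x$t0) * x$rate) + 1
  idx[idx < 1 | idx > length(x$values)] <- NA_integer_
  x$values[idx]
}

# sample indices covering a closed time window [from, to]
window_index <- function(x, from, to) {
  i0 <- max(1L, ceiling((from - x$t0) * x$rate - 1e-9) + 1L)
  i1 <- min(length(x$values), floor((to - x$t0) * x$rate + 1e-9) + 1L)
  if (i0 > i1) integer(0) else i0:i1
}
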