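#' Z-score a pupil trace
#'
#' Standardizes the whole-session trace to mean 0 and sample SD 1 (n - 1
#' denominator) and sets the units flag to `"z"`.
#'
#' @param trace A [pupil_trace].
#' @return A z-scored [pupil_trace].
#' @export
zscore_trace <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  s <- stats::sd(trace$values)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant trace")
  trace$values <- (trace$values - mean(trace$values)) / s
  trace$units <- "z"
  trace
}

#' Smooth a pupil trace with a centered moving average
#'
#' Boxcar smoothing applied before slope estimation to suppress
#' false-positive slope zero-crossings.  The window is rounded to an odd
#' number of samples; edges use shrinking (partial) windows so the trace
#' length is preserved.
#'
#' @param trace A [pupil_trace].
#' @param window Window length in seconds (default 0.5).
#' @return A smoothed [pupil_trace].
#' @export
smooth_trace <- function(trace, window = 0.5) {
  stopifnot(inherits(trace, "pupil_trace"))
  w <- round(window * trace$rate)
  if (w <= 1) {
    if (window * trace$rate < 1)
      warning("smoothing window shorter than one sample; returning input")
    return(trace)
  }
  if (w %% 2 == 0) w <- w + 1
  trace$values <- zoo::rollapply(trace$values, width = w, FUN = mean,
                                 align = "center", partial = TRUE)
  trace
}

#' Estimate pupil slopes on a coarse time step
#'
#' The trace is averaged into consecutive bins of `step` seconds and the
#' slope between adjacent bins is their mean difference divided by the step.
#' Slope `k` is timestamped at the boundary between bins `k` and `k + 1`.
#'
#' @param trace A (smoothed) [pupil_trace].
#' @param step Slope estimation step in seconds (default 0.2); must be at
#'   least one sample period.
#' @return An object of class `slope_series`: list with `t` (boundary times,
#'   seconds), `slopes` (z-units/s), `step`, `t0`.
#' @export
compute_slopes <- function(trace, step = 0.2) {
  stopifnot(inherits(trace, "pupil_trace"))
  m <- round(step * trace$rate)
  if (m < 1) stop("step must be at least one sample period")
  nb <- floor(length(trace$values) / m)
  if (nb < 2) stop("trace shorter than two slope steps")
  step_actual <- m / trace$rate
  bins <- colMeans(matrix(trace$values[seq_len(nb * m)], nrow = m))
  slopes <- diff(bins) / step_actual
  structure(list(t = trace$t0 + step_actual * seq_len(nb - 1),
                 slopes = slopes, step = step_actual, t0 = trace$t0),
            class = "slope_series")
}

#' @export
print.slope_series <- function(x, ...) {
  cat(sprintf("<slope_series> %d slopes every %g s, t = [%.2f, %.2f] s\n",
              length(x$slopes), x$step, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Detect pupil dilation events
#'
#' A positive zero-crossing is a transition of the slope series from <= 0 to
#' > 0 (the onset of a dilation).  For each pair of sequential positive
#' zero-crossings, the dilation event is the maximum of the trace between
#' them; its amplitude is the trace value at that maximum, in SD units when
#' the trace is z-scored.
#'
#' @param trace A z-scored, smoothed [pupil_trace].
#' @param slopes A `slope_series` from [compute_slopes()]; computed from
#'   `trace` with `step` when omitted.
#' @param step Slope step passed to [compute_slopes()] when `slopes` is
#'   missing.
#' @return A data.frame of class `dilation_events` with columns `time_s`
#'   (location of the maximum), `amplitude_sd` (trace value there) and
#'   `rise_start_s` (the preceding positive zero-crossing).  Zero rows when
#'   fewer than two positive zero-crossings exist.
#' @export
detect_dilation_events <- function(trace, slopes = NULL, step = 0.2) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (is.null(slopes)) slopes <- compute_slopes(trace, step = step)
  s <- slopes$slopes
  cross <- which(s[-length(s)] <= 0 & s[-1] > 0) + 1L  # index of first > 0
  empty <- data.frame(time_s = numeric(0), amplitude_sd = numeric(0),
                      rise_start_s = numeric(0))
  class(empty) <- c("dilation_events", "data.frame")
  if (length(cross) < 2) return(empty)
  t_cross <- slopes$t[cross]
  out <- lapply(seq_len(length(cross) - 1), function(i) {
    idx <- window_index(trace, t_cross[i], t_cross[i + 1])
    if (!length(idx) || anyNA(trace$values[idx])) return(NULL)
    j <- idx[which.max(trace$values[idx])]
    data.frame(time_s = trace$t0 + (j - 1) / trace$rate,
               amplitude_sd = trace$values[j],
               rise_start_s = t_cross[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  class(out) <- c("dilation_events", "data.frame")
  out
}

#' Percent change from a pre-event baseline
#'
#' Expresses a (mm) trace as percent change relative to the mean over the
#' baseline window `[t_ref - baseline_window, t_ref)`.
#'
#' @param trace A [pupil_trace] (typically `units = "mm"`).
#' @param t_ref Reference time in seconds.
#' @param baseline_window Baseline window length in seconds.
#' @return A [pupil_trace] with `units = "pct"`.
#' @export
percent_change <- function(trace, t_ref, baseline_window) {
  stopifnot(inherits(trace, "pupil_trace"), baseline_window > 0)
  idx <- window_index(trace, t_ref - baseline_window,
                      t_ref - 1 / trace$rate)
  if (!length(idx)) stop("baseline window outside the recording")
  b <- mean(trace$values[idx])
  if (abs(b) < .Machine$double.eps^0.5) stop("baseline mean is zero")
  trace$values <- 100 * (trace$values - b) / b
  trace$units <- "pct"
  trace
}
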