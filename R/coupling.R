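#' Cluster-triggered peak pupil response
#'
#' The peak pupil dilation for a spike cluster is the maximum value of the
#' (z-scored) trace in a window after cluster onset (default 6 s), reported
#' with its latency from onset.  The maximum is taken over signed values: a
#' deep constriction is not a dilation peak.  Set `absolute = TRUE` to take
#' the maximum of |z| instead.
#'
#' @param trace A z-scored [pupil_trace].
#' @param onset Cluster onset (time of its first spike), seconds.
#' @param window Search window length in seconds (default 6).
#' @param absolute If `TRUE`, use the maximum absolute value.
#' @return A list with `peak` (z-units), `latency` (seconds) and `excluded`
#'   (`TRUE`, with `NA` peak, when the window extends past the recording).
#' @export
triggered_peak <- function(trace, onset, window = 6, absolute = FALSE) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (onset < trace$t0 || onset + window > trace_end(trace) + 1e-9)
    return(list(peak = NA_real_, latency = NA_real_, excluded = TRUE))
  idx <- window_index(trace, onset, onset + window)
  v <- trace$values[idx]
  j <- if (absolute) which.max(abs(v)) else which.max(v)
  list(peak = v[j],
       latency = trace$t0 + (idx[j] - 1) / trace$rate - onset,
       excluded = FALSE)
}

#' Peak pupil responses for a set of clusters
#'
#' Applies [triggered_peak()] to every cluster onset; clusters whose window
#' leaves the recording are flagged `excluded`.
#'
#' @param trace A z-scored [pupil_trace].
#' @param clusters A `spike_clusters` data.frame (see [cluster_spikes()]).
#' @param window Peak search window in seconds.
#' @param absolute Passed to [triggered_peak()].
#' @return A data.frame with `onset_s`, `size`, `peak`, `latency`,
#'   `excluded`.
#' @export
triggered_peaks <- function(trace, clusters, window = 6, absolute = FALSE) {
  res <- lapply(clusters$onset_s, triggered_peak, trace = trace,
                window = window, absolute = absolute)
  data.frame(onset_s = clusters$onset_s, size = clusters$size,
             peak = vapply(res, `[[`, numeric(1), "peak"),
             latency = vapply(res, `[[`, numeric(1), "latency"),
             excluded = vapply(res, `[[`, logical(1), "excluded"))
}

#' Coupling curve: mean peak pupil response by cluster size
#'
#' Groups triggered responses by cluster size and summarizes mean, SEM and
#' occurrence per size.  Sizes observed fewer than 5 times are flagged
#' `low_n`.  Excluded responses (window past the recording end) are dropped.
#'
#' @param peaks A data.frame from [triggered_peaks()].
#' @return An object of class `coupling_curve`: data.frame with `size`, `n`,
#'   `mean_peak`, `sem`, `occurrence`, `low_n`.
#' @export
coupling_curve <- function(peaks) {
  peaks <- peaks[!peaks$excluded & is.finite(peaks$peak), , drop = FALSE]
  if (!nrow(peaks)) stop("no usable triggered responses")
  sp <- split(peaks$peak, peaks$size)
  out <- data.frame(
    size = as.integer(names(sp)),
    n = vapply(sp, length, integer(1)),
    mean_peak = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)))
  out$occurrence <- out$n / sum(out$n)
  out$low_n <- out$n < 5
  rownames(out) <- NULL
  class(out) <- c("coupling_curve", "data.frame")
  out
}

#' @export
print.coupling_curve <- function(x, ...) {
  cat("<coupling_curve>\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Linear fit of the pupil--LC coupling curve
#'
#' Ordinary least squares of the per-size mean peak on cluster size.  At
#' least 3 distinct sizes are required; recordings with fewer cluster sizes
#' are not suitable for linear regression and raise an error.
#'
#' @param curve A `coupling_curve`.
#' @return A list with `slope` (z-units per spike), `intercept`, `r2`.
#' @export
fit_linear <- function(curve) {
  stopifnot(inherits(curve, "coupling_curve"))
  if (nrow(curve) < 3)
    stop("linear fit needs at least 3 distinct cluster sizes")
  fit <- stats::lm(mean_peak ~ size, data = curve)
  tss <- sum((curve$mean_peak - mean(curve$mean_peak))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2)
}

#' Cluster-level coupling slope with standard error
#'
#' Regression of the individual cluster-triggered peaks (not the per-size
#' means) on cluster size.  With one observation per cluster the slope
#' standard error reflects the true per-cluster variability, which makes
#' this the appropriate statistic for null calibration (`|slope| < 2 SE`
#' under zero coupling).
#'
#' @param peaks A data.frame from [triggered_peaks()].
#' @return A list with `slope`, `se`, `t`, `p`, `n`.
#' @export
coupling_slope <- function(peaks) {
  peaks <- peaks[!peaks$excluded & is.finite(peaks$peak), , drop = FALSE]
  if (length(unique(peaks$size)) < 2)
    stop("cluster-level slope needs at least 2 distinct sizes")
  fit <- summary(stats::lm(peak ~ size, data = peaks))$coefficients
  list(slope = fit["size", "Estimate"], se = fit["size", "Std. Error"],
       t = fit["size", "t value"], p = fit["size", "Pr(>|t|)"],
       n = nrow(peaks))
}

#' Count LC spikes preceding a dilation event
#'
#' Spikes are counted in a window before the event time, by default
#' `[-4, -2)` seconds relative to the event: the lower bound is included,
#' the upper excluded.
#'
#' @param train A [spike_train].
#' @param event_time Dilation event time in seconds.
#' @param window Two-element window in seconds relative to the event,
#'   `window[1] < window[2] < 0`.
#' @return A list with `count` and `excluded` (`TRUE` when the window starts
#'   before the recording).
#' @export
spikes_before_event <- function(train, event_time, window = c(-4, -2)) {
  stopifnot(inherits(train, "spike_train"), window[1] < window[2])
  from <- event_time + window[1]
  to <- event_time + window[2]
  if (from < train$t_start)
    return(list(count = NA_integer_, excluded = TRUE))
  list(count = sum(train$times >= from & train$times < to), excluded = FALSE)
}

#' Spike counts for a set of dilation events
#'
#' Vectorized [spikes_before_event()] over a `dilation_events` table.
#'
#' @param train A [spike_train].
#' @param events A `dilation_events` data.frame.
#' @param window Pre-event counting window (see [spikes_before_event()]).
#' @return A data.frame with `time_s`, `amplitude_sd`, `count`, `excluded`.
#' @export
spikes_before_events <- function(train, events, window = c(-4, -2)) {
  res <- lapply(events$time_s, spikes_before_event, train = train,
                window = window)
  data.frame(time_s = events$time_s, amplitude_sd = events$amplitude_sd,
             count = vapply(res, `[[`, numeric(1), "count"),
             excluded = vapply(res, `[[`, logical(1), "excluded"))
}

#' Bin dilation events by amplitude
#'
#' Events are binned every `bin` SD from 0 to `max` SD (default ten bins
#' `[0, 0.3), ..., [2.7, 3)`).  Events with amplitude outside `[0, max)` are
#' excluded from the bins but tallied in the `underflow`/`overflow`
#' attributes.
#'
#' @param counts A data.frame from [spikes_before_events()] (columns
#'   `amplitude_sd`, `count`, `excluded`).
#' @param bin Bin width in SD units (default 0.3).
#' @param max Upper edge of the binned range in SD units (default 3).
#' @return A data.frame of class `event_bins` with `bin_index` (0-based),
#'   `lo`, `hi`, `n`, `mean_count`, `occurrence` (fraction of in-range
#'   events), plus attributes `underflow` and `overflow`.
#' @export
bin_events <- function(counts, bin = 0.3, max = 3) {
  counts <- counts[!counts$excluded & is.finite(counts$count), , drop = FALSE]
  amp <- counts$amplitude_sd
  in_range <- amp >= 0 & amp < max
  idx <- floor(amp[in_range] / bin)
  nb <- ceiling(max / bin)
  n <- tabulate(idx + 1L, nbins = nb)
  mean_count <- vapply(seq_len(nb) - 1L, function(b) {
    v <- counts$count[in_range][idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- data.frame(bin_index = seq_len(nb) - 1L,
                    lo = bin * (seq_len(nb) - 1L), hi = bin * seq_len(nb),
                    n = n, mean_count = mean_count,
                    occurrence = if (sum(n)) n / sum(n) else rep(NA_real_, nb))
  attr(out, "underflow") <- sum(amp < 0)
  attr(out, "overflow") <- sum(amp >= max)
  class(out) <- c("event_bins", "data.frame")
  out
}

#' Exclude clusters near licking events
#'
#' Drops clusters whose onset falls within the closed interval
#' `[lick - halfwidth, lick + halfwidth]` of any lick, removing
#' movement-locked LC activity from the pupil--LC analysis.
#'
#' @param clusters A `spike_clusters` data.frame.
#' @param licks Sorted numeric vector of lick times (seconds).
#' @param halfwidth Exclusion half-width in seconds (default 0.5).
#' @return The filtered `spike_clusters` data.frame (occurrence fractions
#'   recomputed over the survivors).
#' @export
exclude_licking <- function(clusters, licks, halfwidth = 0.5) {
  if (!length(licks)) return(clusters)
  licks <- sort(licks)
  near <- vapply(clusters$onset_s, function(on) {
    i <- findInterval(on, licks)
    (i >= 1 && on - licks[i] <= halfwidth) ||
      (i < length(licks) && licks[i + 1] - on <= halfwidth)
  }, logical(1))
  out <- clusters[!near, , drop = FALSE]
  if (nrow(out))
    out$occurrence <- as.numeric(table(out$size)[as.character(out$size)]) /
      nrow(out)
  mem <- attr(clusters, "members")
  if (!is.null(mem)) attr(out, "members") <- mem[!near]
  attr(out, "threshold") <- attr(clusters, "threshold")
  class(out) <- class(clusters)
  out
}

#' Peak of the pupil time-derivative after an onset
#'
#' Variant of [triggered_peak()] computed on the slope series instead of the
#' trace: the maximum pupil derivative in the window after onset.  For a
#' unimodal impulse response this derivative peak precedes the value peak.
#'
#' @param trace A [pupil_trace].
#' @param onset Onset time in seconds.
#' @param window Search window in seconds.
#' @param step Slope estimation step (see [compute_slopes()]).
#' @return A list with `peak` (z-units/s), `latency` (seconds), `excluded`.
#' @export
derivative_response <- function(trace, onset, window = 6, step = 0.2) {
  sl <- compute_slopes(trace, step = step)
  sel <- sl$t >= onset & sl$t <= onset + window
  if (onset + window > trace_end(trace) + 1e-9 || !any(sel))
    return(list(peak = NA_real_, latency = NA_real_, excluded = TRUE))
  v <- sl$slopes[sel]
  j <- which.max(v)
  list(peak = v[j], latency = sl$t[sel][j] - onset, excluded = FALSE)
}
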