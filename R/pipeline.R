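#' Forward pipeline: spike clusters to pupil responses
#'
#' Runs the cluster -> pupil direction end to end on one paired recording:
#' z-scores the trace, groups spikes into clusters at the unit's median ISI
#' (or a supplied threshold), optionally removes clusters near licks,
#' measures cluster-triggered peak pupil responses, and summarizes the
#' coupling curve with its linear fit and per-size ideal-observer AUCs.
#'
#' @param trace A [pupil_trace] (z-scored internally if not already).
#' @param train A [spike_train].
#' @param licks Optional lick times for exclusion.
#' @param config An [analysis_config()].
#' @param threshold Clustering threshold; default the unit's median ISI.
#' @return A list with `clusters`, `peaks`, `curve`, `fit` (`NULL` when
#'   fewer than 3 sizes), `slope` (cluster-level, with SE), `roc` (AUC by
#'   size), `crossing` (smallest size reaching the AUC threshold).
#' @export
forward_coupling <- function(trace, train, licks = NULL,
                             config = analysis_config(),
                             threshold = NULL) {
  if (trace$units != "z") trace <- zscore_trace(trace)
  if (is.null(threshold)) threshold <- median_isi(train)
  clusters <- cluster_spikes(train, threshold)
  if (!is.null(licks) && length(licks))
    clusters <- exclude_licking(clusters, licks,
                                halfwidth = config$lick_halfwidth)
  peaks <- triggered_peaks(trace, clusters, window = config$peak_window)
  curve <- coupling_curve(peaks)
  fit <- if (nrow(curve) >= 3) fit_linear(curve) else NULL
  slope <- if (length(unique(curve$size)) >= 2) coupling_slope(peaks)
           else NULL
  roc <- roc_by_size(peaks, trace, n_repeats = config$n_boot,
                     seed = config$seed)
  list(clusters = clusters, peaks = peaks, curve = curve, fit = fit,
       slope = slope, roc = roc,
       crossing = threshold_crossing(roc, thr = config$auc_threshold))
}

#' Reverse pipeline: pupil dilation events to spike counts
#'
#' Runs the pupil -> spike direction: z-scores and smooths the trace,
#' estimates slopes, detects dilation events at positive zero-crossings,
#' counts LC spikes in the pre-event window, bins events by amplitude, and
#' computes per-bin ideal-observer AUCs against spike counts at random
#' times.
#'
#' @param trace A [pupil_trace].
#' @param train A [spike_train].
#' @param config An [analysis_config()].
#' @param n_pool Size of the random-time spike-count pool.
#' @return A list with `events`, `counts`, `bins`, `roc` (AUC by bin),
#'   `crossing` (lower edge, in SD, of the smallest bin reaching the AUC
#'   threshold).
#' @export
reverse_coupling <- function(trace, train, config = analysis_config(),
                             n_pool = 1000) {
  if (trace$units != "z") trace <- zscore_trace(trace)
  sm <- smooth_trace(trace, window = config$smooth_window)
  slopes <- compute_slopes(sm, step = config$slope_step)
  events <- detect_dilation_events(sm, slopes)
  counts <- spikes_before_events(train, events,
                                 window = config$pre_event_window)
  bins <- bin_events(counts, bin = config$event_bin,
                     max = config$event_bin_max)
  pool <- sample_spike_counts(train, n_pool,
                              window = config$pre_event_window,
                              seed = config$seed)
  roc <- roc_by_bin(counts, pool, bin = config$event_bin,
                    max = config$event_bin_max, n_repeats = config$n_boot,
                    seed = config$seed)
  crossing <- threshold_crossing(
    data.frame(condition = roc$lo, auc = roc$auc, low_n = roc$low_n),
    thr = config$auc_threshold)
  list(events = events, counts = counts, bins = bins, roc = roc,
       crossing = crossing)
}
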