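#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen value from `pos` exceeds a
#' randomly chosen value from `neg`, ties counted one half (the normalized
#' Mann-Whitney U / concordance statistic).  0.5 is chance.
#'
#' @param pos,neg Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 3), c(1, 2))  # 4/6
#' @export
auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (!n1 || !n2) stop("auc needs non-empty pos and neg")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Null standard error of the AUC
#'
#' Standard deviation of the Mann-Whitney AUC under the null hypothesis of
#' exchangeable groups: `sqrt((n1 + n2 + 1) / (12 n1 n2))`.  Used to form
#' the chance band `0.5 +/- k * SE`.
#'
#' @param n1,n2 Group sizes.
#' @return The null SE.
#' @export
auc_null_se <- function(n1, n2) sqrt((n1 + n2 + 1) / (12 * n1 * n2))

#' Ideal-observer AUC for one cluster size: pupil predicting spiking
#'
#' How well peak pupil diameter discriminates clusters of a given size from
#' chance: per repeat, a number-matched set of pupil samples is drawn at
#' random from the session trace and the AUC between the cluster-associated
#' peaks and the random draws is computed; the mean over repeats is
#' reported.
#'
#' @param peaks Peak pupil values (z) associated with clusters of one size.
#' @param trace The session's z-scored [pupil_trace]; the random baseline is
#'   drawn from all of its samples.
#' @param n_repeats Number of random baseline draws (default 100).
#' @param seed Integer seed or `NULL`.
#' @param replace Draw baseline samples with replacement (default `FALSE`;
#'   forced `TRUE` when more samples than trace values are requested).
#' @return A list of class `roc_result`: `auc` (mean over repeats),
#'   `auc_sd`, `n_pos` (= `n_neg` per repeat), `n_repeats`, `low_n` (`TRUE`
#'   when fewer than 3 peaks).
#' @export
roc_cluster <- function(peaks, trace, n_repeats = 100, seed = NULL,
                        replace = FALSE) {
  stopifnot(inherits(trace, "pupil_trace"))
  peaks <- peaks[is.finite(peaks)]
  if (!length(peaks)) stop("no peaks supplied")
  local_seed(seed)
  pool <- trace$values
  if (length(peaks) > length(pool)) replace <- TRUE
  aucs <- vapply(seq_len(n_repeats), function(i)
    auc(peaks, sample(pool, length(peaks), replace = replace)), numeric(1))
  structure(list(auc = mean(aucs), auc_sd = stats::sd(aucs),
                 n_pos = length(peaks), n_repeats = n_repeats,
                 low_n = length(peaks) < 3),
            class = "roc_result")
}

#' Ideal-observer AUC for one event bin: spiking predicting pupil events
#'
#' How well pre-event LC spike counts discriminate dilation events of a
#' given amplitude bin from chance: the counts are compared against
#' number-matched draws from a pool of spike counts taken at randomly
#' selected times (see [sample_spike_counts()]).
#'
#' @param counts Spike counts associated with events of one amplitude bin.
#' @param pool Pool of null spike counts at random times.
#' @param n_repeats,seed,replace As in [roc_cluster()].
#' @return A `roc_result` (see [roc_cluster()]).
#' @export
roc_event <- function(counts, pool, n_repeats = 100, seed = NULL,
                      replace = FALSE) {
  counts <- counts[is.finite(counts)]
  if (!length(counts)) stop("no counts supplied")
  if (!length(pool)) stop("empty null pool")
  local_seed(seed)
  if (length(counts) > length(pool)) replace <- TRUE
  aucs <- vapply(seq_len(n_repeats), function(i)
    auc(counts, sample(pool, length(counts), replace = replace)), numeric(1))
  structure(list(auc = mean(aucs), auc_sd = stats::sd(aucs),
                 n_pos = length(counts), n_repeats = n_repeats,
                 low_n = length(counts) < 3),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (sd %.3f over %d repeats), n = %d%s\n",
              x$auc, x$auc_sd, x$n_repeats, x$n_pos,
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Null pool of spike counts at random times
#'
#' Spike counts in the pre-event window anchored at uniformly random times
#' within the recording (restricted so the window fits), forming the
#' "randomly selected" baseline for [roc_event()].
#'
#' @param train A [spike_train].
#' @param n Number of random times.
#' @param window Counting window relative to each time (default `c(-4, -2)`).
#' @param seed Integer seed or `NULL`.
#' @return An integer vector of length `n`.
#' @export
sample_spike_counts <- function(train, n, window = c(-4, -2), seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  local_seed(seed)
  t <- stats::runif(n, train$t_start - window[1], train$t_end)
  from <- t + window[1]
  to <- t + window[2]
  findInterval(to, train$times, left.open = TRUE) -
    findInterval(from, train$times, left.open = TRUE)
}

#' AUC by cluster size
#'
#' Runs [roc_cluster()] for every cluster size in a triggered-peaks table.
#'
#' @param peaks A data.frame from [triggered_peaks()].
#' @param trace The session's z-scored [pupil_trace].
#' @param n_repeats,seed Passed to [roc_cluster()] (the seed is advanced
#'   deterministically across sizes).
#' @return A data.frame with `size`, `n`, `auc`, `auc_sd`, `low_n`.
#' @export
roc_by_size <- function(peaks, trace, n_repeats = 100, seed = NULL) {
  peaks <- peaks[!peaks$excluded & is.finite(peaks$peak), , drop = FALSE]
  sp <- split(peaks$peak, peaks$size)
  res <- mapply(function(v, i)
    roc_cluster(v, trace, n_repeats = n_repeats,
                seed = if (is.null(seed)) NULL else seed + i),
    sp, seq_along(sp), SIMPLIFY = FALSE)
  data.frame(size = as.integer(names(sp)),
             n = vapply(res, `[[`, numeric(1), "n_pos"),
             auc = vapply(res, `[[`, numeric(1), "auc"),
             auc_sd = vapply(res, `[[`, numeric(1), "auc_sd"),
             low_n = vapply(res, `[[`, logical(1), "low_n"),
             row.names = NULL)
}

#' AUC by dilation-event amplitude bin
#'
#' Runs [roc_event()] for every amplitude bin of a pre-event spike-count
#' table.
#'
#' @param counts A data.frame from [spikes_before_events()].
#' @param pool Null spike-count pool from [sample_spike_counts()].
#' @param bin,max Binning as in [bin_events()].
#' @param n_repeats,seed Passed to [roc_event()].
#' @return A data.frame with `bin_index`, `lo`, `hi`, `n`, `auc`, `auc_sd`,
#'   `low_n` (bins with no events are dropped).
#' @export
roc_by_bin <- function(counts, pool, bin = 0.3, max = 3, n_repeats = 100,
                       seed = NULL) {
  counts <- counts[!counts$excluded & is.finite(counts$count), , drop = FALSE]
  amp <- counts$amplitude_sd
  keep <- amp >= 0 & amp < max
  idx <- floor(amp[keep] / bin)
  cc <- counts$count[keep]
  bins <- sort(unique(idx))
  res <- lapply(seq_along(bins), function(i)
    roc_event(cc[idx == bins[i]], pool, n_repeats = n_repeats,
              seed = if (is.null(seed)) NULL else seed + i))
  data.frame(bin_index = bins, lo = bins * bin, hi = (bins + 1) * bin,
             n = vapply(res, `[[`, numeric(1), "n_pos"),
             auc = vapply(res, `[[`, numeric(1), "auc"),
             auc_sd = vapply(res, `[[`, numeric(1), "auc_sd"),
             low_n = vapply(res, `[[`, logical(1), "low_n"),
             row.names = NULL)
}

#' Window maxima of the trace at random onsets
#'
#' Peak pupil values computed exactly as cluster-triggered peaks but at
#' uniformly random onsets, forming the matched null for the peak-based ROC
#' construction.
#'
#' @param trace A z-scored [pupil_trace].
#' @param n Number of random onsets.
#' @param window Peak search window in seconds (default 6).
#' @param seed Integer seed or `NULL`.
#' @return A numeric vector of `n` window maxima.
#' @export
random_onset_peaks <- function(trace, n, window = 6, seed = NULL) {
  stopifnot(inherits(trace, "pupil_trace"))
  local_seed(seed)
  onsets <- stats::runif(n, trace$t0, trace_end(trace) - window)
  vapply(onsets, function(on)
    triggered_peak(trace, on, window = window)$peak, numeric(1))
}

#' Chance band for the peak-based ideal-observer AUC
#'
#' The AUC of window-maximum peaks against single random samples is above
#' 0.5 even for a completely uncoupled spike train, because the maximum
#' over a window of an autocorrelated trace stochastically dominates a
#' point sample.  The chance band is therefore calibrated by the same
#' construction at random onsets: per null draw, `n_pos` random-onset
#' window maxima are compared (mean AUC over `n_repeats` baseline draws)
#' with number-matched random samples; the band is the null mean plus or
#' minus `k_sd` null standard deviations (default 3, about 99.7% coverage
#' per condition).  An observed per-size AUC inside this band is
#' indistinguishable from chance.
#'
#' @param trace A z-scored [pupil_trace].
#' @param n_pos Number of peaks in the observed condition.
#' @param window Peak search window in seconds (default 6).
#' @param n_draws Number of null draws (default 200).
#' @param n_repeats Baseline draws averaged per null draw (default 10).
#' @param k_sd Half-width of the band in null standard deviations
#'   (default 3).
#' @param pool Optional precomputed [random_onset_peaks()] pool (reused
#'   across sizes for speed).
#' @param seed Integer seed or `NULL`.
#' @return A list with `lo`, `hi` (band edges) and `center` (mean null
#'   AUC).
#' @export
roc_null_band <- function(trace, n_pos, window = 6, n_draws = 200,
                          n_repeats = 10, k_sd = 3, pool = NULL,
                          seed = NULL) {
  local_seed(seed)
  if (is.null(pool))
    pool <- random_onset_peaks(trace, max(1000, 4 * n_pos), window = window)
  vals <- trace$values
  null_auc <- vapply(seq_len(n_draws), function(i) {
    pos <- sample(pool, n_pos, replace = n_pos > length(pool))
    mean(vapply(seq_len(n_repeats), function(j)
      auc(pos, sample(vals, n_pos, replace = n_pos > length(vals))),
      numeric(1)))
  }, numeric(1))
  m <- mean(null_auc)
  s <- stats::sd(null_auc)
  list(lo = m - k_sd * s, hi = m + k_sd * s, center = m)
}

#' Convert d-prime to AUC under the equal-variance Gaussian observer
#'
#' For two unit-variance Gaussians separated by `d`, the probability that a
#' signal draw exceeds a noise draw is `pnorm(d / sqrt(2))`.  A performance
#' threshold of d-prime = 1 therefore corresponds to an AUC of about 0.76
#' (commonly quoted as ~0.75).
#'
#' @param d d-prime (finite, any sign).
#' @return AUC in (0, 1), strictly increasing in `d`.
#' @examples
#' dprime_to_auc(1)   # 0.7602
#' auc_to_dprime(0.75)
#' @export
dprime_to_auc <- function(d) {
  stopifnot(all(is.finite(d)))
  stats::pnorm(d / sqrt(2))
}

#' @rdname dprime_to_auc
#' @param a AUC in (0, 1).
#' @export
auc_to_dprime <- function(a) {
  stopifnot(all(a > 0 & a < 1))
  sqrt(2) * stats::qnorm(a)
}

#' First condition reaching the AUC performance threshold
#'
#' Given per-condition AUCs ordered by condition (cluster size or event
#' amplitude bin), returns the smallest condition whose AUC reaches the
#' threshold (default 0.75, the d-prime = 1 level), or `NA` if none does.
#'
#' @param results A data.frame with a condition column (first column or
#'   `condition`) and an `auc` column, ordered by condition.
#' @param thr AUC threshold (default 0.75).
#' @param skip_low_n Drop rows flagged `low_n` before searching.
#' @return The condition value, or `NA` when the threshold is never met.
#' @export
threshold_crossing <- function(results, thr = 0.75, skip_low_n = FALSE) {
  cond <- if ("condition" %in% names(results)) results$condition
          else results[[1]]
  keep <- rep(TRUE, nrow(results))
  if (skip_low_n && "low_n" %in% names(results)) keep <- !results$low_n
  hit <- which(keep & results$auc >= thr)
  if (!length(hit)) return(NA)
  cond[hit[1]]
}
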