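#' Median interspike interval of a unit
#'
#' The clustering threshold of the pipeline: the median of the successive
#' spike-time differences of the unit.  With an even number of intervals the
#' usual mean of the two central values is taken.
#'
#' @param train A [spike_train] with at least 3 spikes (2 intervals).
#' @return Median ISI in seconds.
#' @examples
#' median_isi(spike_train(c(0, 1, 2, 3)))
#' @export
median_isi <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (n_spikes(train) < 3)
    stop("median_isi needs at least 3 spikes")
  stats::median(diff(train$times))
}

#' Group adjacent spikes into clusters
#'
#' Left-to-right scan: a spike joins the current cluster iff its interval to
#' the previous spike is strictly shorter than `threshold`; otherwise it
#' starts a new cluster.  Ties (ISI exactly equal to the threshold) split.
#' The clusters partition the train; single-spike clusters are valid.
#'
#' @param train A [spike_train].
#' @param threshold Grouping threshold in seconds (> 0).  Defaults to the
#'   unit's median ISI.
#' @return An object of class `spike_clusters`: a data.frame with columns
#'   `onset_s` (time of the first spike), `size` (spike count) and
#'   `occurrence` (fraction of clusters of that size), with the member spike
#'   times in attribute `members` and the threshold in attribute
#'   `threshold`.  An empty train yields zero rows.
#' @examples
#' st <- spike_train(c(0, 0.05, 0.15, 4.95, 9.95, 10))
#' cluster_spikes(st, threshold = 0.1)$size
#' @export
cluster_spikes <- function(train, threshold = median_isi(train)) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number of seconds")
  tt <- train$times
  if (!length(tt)) {
    out <- data.frame(onset_s = numeric(0), size = integer(0),
                      occurrence = numeric(0))
  } else {
    # new cluster wherever the ISI to the previous spike is >= threshold;
    # ties split, with a tiny tolerance so e.g. 0.15 - 0.05 counts as 0.1
    cut <- if (is.finite(threshold))
      diff(tt) >= threshold - 1e-9 * max(1, threshold)
    else rep(FALSE, length(tt) - 1L)
    id <- cumsum(c(TRUE, cut))
    size <- tabulate(id)
    onset <- tt[!duplicated(id)]
    out <- data.frame(onset_s = onset, size = size)
    out$occurrence <- as.numeric(table(size)[as.character(size)]) / nrow(out)
    attr(out, "members") <- split(tt, id)
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("spike_clusters", "data.frame")
  out
}

#' Per-size cluster occurrence table
#'
#' @param clusters A `spike_clusters` object.
#' @return A data.frame with `size`, `n` and `occurrence` (fractions summing
#'   to 1 over observed sizes), ordered by size.
#' @export
cluster_occurrence <- function(clusters) {
  if (!nrow(clusters))
    return(data.frame(size = integer(0), n = integer(0),
                      occurrence = numeric(0)))
  tab <- table(clusters$size)
  data.frame(size = as.integer(names(tab)), n = as.integer(tab),
             occurrence = as.integer(tab) / nrow(clusters))
}

#' Clustering robustness across thresholds
#'
#' Repeats [cluster_spikes()] over a set of grouping thresholds (the
#' analysis is expected to be insensitive over roughly 0.1--0.5 s for
#' well-separated bursts) and tabulates the size distribution per threshold.
#'
#' @param train A [spike_train].
#' @param thresholds Positive grouping thresholds in seconds.
#' @return A data.frame with columns `threshold`, `size`, `n`, `occurrence`.
#' @export
cluster_sensitivity <- function(train, thresholds = seq(0.1, 0.5, by = 0.1)) {
  stopifnot(all(thresholds > 0))
  do.call(rbind, lapply(thresholds, function(th) {
    occ <- cluster_occurrence(cluster_spikes(train, th))
    if (!nrow(occ)) return(NULL)
    cbind(threshold = th, occ)
  }))
}
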