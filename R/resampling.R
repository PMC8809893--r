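#' Paired stimulation sessions
#'
#' Per-trial evoked peak pupil responses from two sessions recorded under
#' the identical stimulation protocol, for resampling comparison.
#'
#' @param responses_1,responses_2 Numeric vectors of per-trial evoked peak
#'   pupil responses (at least 5 trials each).
#' @param baseline_1,baseline_2 Session baseline pupil diameters (mm when
#'   `units = "mm"`, in which case they must be positive).
#' @param label Pair label.
#' @param units `"mm"` or `"z"`.
#' @return An object of class `session_pair`.
#' @export
session_pair <- function(responses_1, responses_2,
                         baseline_1 = NA_real_, baseline_2 = NA_real_,
                         label = "pair", units = c("mm", "z")) {
  units <- match.arg(units)
  responses_1 <- as.numeric(responses_1)
  responses_2 <- as.numeric(responses_2)
  if (length(responses_1) < 5 || length(responses_2) < 5)
    stop("each session needs at least 5 trials")
  if (units == "mm" &&
      ((is.finite(baseline_1) && baseline_1 <= 0) ||
       (is.finite(baseline_2) && baseline_2 <= 0)))
    stop("mm baselines must be positive")
  structure(list(label = label, responses_1 = responses_1,
                 responses_2 = responses_2, baseline_1 = baseline_1,
                 baseline_2 = baseline_2, units = units),
            class = "session_pair")
}

#' @export
print.session_pair <- function(x, ...) {
  cat(sprintf(
    "<session_pair> %s: n = %d / %d trials, means %.3f / %.3f %s\n",
    x$label, length(x$responses_1), length(x$responses_2),
    mean(x$responses_1), mean(x$responses_2), x$units))
  invisible(x)
}

#' Are two sessions baseline-matched?
#'
#' Sessions are considered baseline pupil-matched when their baseline
#' diameters differ by at most `tol` mm (default 0.05 mm; e.g. 0.71 vs
#' 0.75 mm qualifies).
#'
#' @param pair A [session_pair] with mm baselines.
#' @param tol Tolerance in mm.
#' @return Logical.
#' @export
baseline_matched <- function(pair, tol = 0.05) {
  stopifnot(inherits(pair, "session_pair"))
  abs(pair$baseline_1 - pair$baseline_2) <= tol
}

#' Bootstrap mean and percentile confidence interval
#'
#' Resamples `x` with replacement `n_boot` times (default 100) and reports
#' the sample mean together with the percentile interval of the bootstrap
#' means.
#'
#' @param x Numeric vector (length >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed or `NULL`.
#' @return A list with `mean`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 100, level = 0.95, seed = NULL) {
  if (length(x) < 2) stop("need at least 2 values")
  if (n_boot < 2) warning("n_boot < 2 gives a degenerate interval")
  local_seed(seed)
  means <- colMeans(matrix(sample(x, length(x) * n_boot, replace = TRUE),
                           nrow = length(x)))
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(mean = mean(x), ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Resampling test for a session-pair difference
#'
#' Tests whether mean evoked responses differ between two sessions.  The
#' observed statistic is the absolute difference of session means.  Under
#' the null, trials are pooled across both sessions and, per iteration,
#' pseudo-sessions of the original trial counts are drawn from the pool
#' *with replacement* (set `method = "permutation"` for a classical
#' without-replacement shuffle); the p value is the add-one-corrected
#' proportion of iterations whose null difference is at least the observed
#' one, so p is never 0 and never below `1 / (n_iter + 1)`.
#'
#' @param pair A [session_pair], or a numeric vector (with `y` supplied).
#' @param y Second response vector when `pair` is numeric.
#' @param n_iter Number of iterations (default 1000; < 100 warns).
#' @param seed Integer seed or `NULL`.
#' @param method `"bootstrap"` (with replacement, default) or
#'   `"permutation"`.
#' @return A list of class `permutation_result`: `observed_diff`,
#'   `null_diffs`, `p`, `n_iter`, `method`.
#' @export
permutation_test <- function(pair, y = NULL, n_iter = 1000, seed = NULL,
                             method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  if (inherits(pair, "session_pair")) {
    x <- pair$responses_1; y <- pair$responses_2
  } else {
    x <- as.numeric(pair)
    if (is.null(y)) stop("supply a session_pair or two numeric vectors")
  }
  if (!length(x) || !length(y)) stop("both response lists must be non-empty")
  if (n_iter < 100) warning("fewer than 100 iterations; p is coarse")
  local_seed(seed)
  obs <- abs(mean(x) - mean(y))
  pool <- sort(c(x, y))  # label-order independent pooling
  n1 <- length(x); n2 <- length(y)
  null_diffs <- if (method == "bootstrap") {
    m1 <- colMeans(matrix(sample(pool, n1 * n_iter, replace = TRUE),
                          nrow = n1))
    m2 <- colMeans(matrix(sample(pool, n2 * n_iter, replace = TRUE),
                          nrow = n2))
    abs(m1 - m2)
  } else {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n1 + n2, n1)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    }, numeric(1))
  }
  p <- (1 + sum(null_diffs >= obs)) / (n_iter + 1)
  structure(list(observed_diff = obs, null_diffs = null_diffs, p = p,
                 n_iter = n_iter, method = method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> |diff| = %.4f, p = %.4g (%d %s iterations)\n",
              x$observed_diff, x$p, x$n_iter, x$method))
  invisible(x)
}

#' Across-session variability by pooled resampling
#'
#' Estimates the standard deviation of session means expected if all trials
#' came from one exchangeable pool: trials from all sessions are pooled and
#' pseudo-sessions matching the real sessions' trial counts are drawn with
#' replacement (as many pseudo-sessions per iteration as real sessions); the
#' SD of pseudo-session means is averaged over `n_rep` iterations.
#'
#' @param sessions A list of numeric vectors (>= 2 sessions).
#' @param n_rep Number of resampling iterations to average (default 100).
#' @param seed Integer seed or `NULL`.
#' @return A list with `across_sd` (observed SD of real session means),
#'   `resampled_sd` (pooled-resampling expectation), `ratio`
#'   (observed / resampled) and `n_sessions`.
#' @export
across_session_sd <- function(sessions, n_rep = 100, seed = NULL) {
  if (!is.list(sessions) || length(sessions) < 2)
    stop("need a list of at least 2 sessions")
  local_seed(seed)
  pool <- unlist(sessions)
  ns <- lengths(sessions)
  sds <- vapply(seq_len(n_rep), function(i) {
    stats::sd(vapply(ns, function(n) mean(sample(pool, n, replace = TRUE)),
                     numeric(1)))
  }, numeric(1))
  obs <- stats::sd(vapply(sessions, mean, numeric(1)))
  list(across_sd = obs, resampled_sd = mean(sds), ratio = obs / mean(sds),
       n_sessions = length(sessions))
}

#' Is a session's variability outside the pooled 5% band?
#'
#' For a session pair, builds the null distribution of session-level SDs by
#' resampling trials (with replacement) from the pooled trials of both
#' sessions for `n_iter` iterations, and flags each session whose observed
#' trial SD falls outside the central 95% of its null distribution.
#'
#' @param pair A [session_pair].
#' @param n_iter Number of resampling iterations (default 1000).
#' @param seed Integer seed or `NULL`.
#' @return A list with logical `flag_1`, `flag_2`, the observed `sd_1`,
#'   `sd_2`, and the null band quantiles per session.
#' @export
within_outside_5pct <- function(pair, n_iter = 1000, seed = NULL) {
  stopifnot(inherits(pair, "session_pair"))
  local_seed(seed)
  pool <- c(pair$responses_1, pair$responses_2)
  one <- function(resp) {
    n <- length(resp)
    null_sd <- vapply(seq_len(n_iter), function(i)
      stats::sd(sample(pool, n, replace = TRUE)), numeric(1))
    band <- stats::quantile(null_sd, c(0.025, 0.975), names = FALSE)
    s <- stats::sd(resp)
    list(flag = s < band[1] || s > band[2], sd = s, band = band)
  }
  r1 <- one(pair$responses_1)
  r2 <- one(pair$responses_2)
  list(flag_1 = r1$flag, flag_2 = r2$flag, sd_1 = r1$sd, sd_2 = r2$sd,
       band_1 = r1$band, band_2 = r2$band)
}

#' Waveform similarity (Pearson correlation)
#'
#' Pearson correlation coefficient between two equal-length spike waveforms
#' (or any amplitude vectors), the similarity measure used to track
#' putatively same units across sessions.
#'
#' @param w1,w2 Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
waveform_similarity <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("waveforms must have equal length")
  if (length(w1) < 3) stop("waveforms must have length >= 3")
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0)
    stop("waveforms must have nonzero variance")
  stats::cor(w1, w2)
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact p for small samples
#' without ties, normal approximation with tie correction otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return The two-tailed p value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                      correct = TRUE))$p.value
}
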