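#' Signal-detection summary of a Go/NoGo session
#'
#' Computes hit rate (hits / go trials), false-alarm rate (false alarms /
#' nogo trials) and the signal-detection decision criterion
#' `c = -(z(H) + z(FA)) / 2`, where `z` is the standard normal quantile.
#' Before the quantile, rates are clamped to
#' `[1 / (2n), 1 - 1 / (2n)]` (n = trials of that type) so perfect rates
#' stay finite.  Lower (more negative) bias means more liberal licking.
#'
#' @param trials A trial table (see [read_trials()] /
#'   [generate_behavior_session()]); needs at least one go and one nogo
#'   trial.
#' @return A list of class `behavior_summary`: `hit_rate`, `fa_rate`,
#'   `bias`, `dprime`, `n_go`, `n_nogo`.
#' @examples
#' tr <- generate_behavior_session(0.9, 0.2, 200, seed = 1)
#' summarize_behavior(tr)
#' @export
summarize_behavior <- function(trials) {
  n_go <- sum(trials$stim_present)
  n_nogo <- sum(!trials$stim_present)
  if (n_go < 1 || n_nogo < 1)
    stop("need at least one go and one nogo trial")
  hit_rate <- sum(trials$outcome == "hit") / n_go
  fa_rate <- sum(trials$outcome == "fa") / n_nogo
  zh <- stats::qnorm(clamp_rate(hit_rate, n_go))
  zf <- stats::qnorm(clamp_rate(fa_rate, n_nogo))
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 bias = -(zh + zf) / 2, dprime = zh - zf,
                 n_go = n_go, n_nogo = n_nogo),
            class = "behavior_summary")
}

# clamp a rate to [1/(2n), 1 - 1/(2n)] before the normal quantile
clamp_rate <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> hit %.3f (n=%d go), fa %.3f (n=%d nogo), bias %.3f, d' %.3f\n",
    x$hit_rate, x$n_go, x$fa_rate, x$n_nogo, x$bias, x$dprime))
  invisible(x)
}

#' Correlate per-session coupling slopes with a behavioral metric
#'
#' Pearson correlation (with the two-tailed t-distribution p value) between
#' per-session pupil--LC coupling slopes and a per-session behavioral metric
#' such as hit rate or decision bias.
#'
#' @param slopes,metric Equal-length numeric vectors, one value per session
#'   (>= 3 sessions, finite values).
#' @return A list with `r`, `p`, `n`.
#' @export
correlate_slope_behavior <- function(slopes, metric) {
  if (length(slopes) != length(metric))
    stop("slopes and metric must have equal length")
  if (length(slopes) < 3) stop("need at least 3 sessions")
  if (!all(is.finite(slopes) & is.finite(metric)))
    stop("values must be finite")
  ct <- stats::cor.test(slopes, metric, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(slopes))
}

#' Does a session qualify for the slope-behavior correlation?
#'
#' Quality gate for entering the across-session correlation: at least
#' `min_trials` behavioral trials and a coupling-curve linear fit with
#' `r2 > min_r2`.
#'
#' @param n_trials Number of behavioral trials in the session.
#' @param r2 Coupling-curve linear-regression R^2.
#' @param min_trials,min_r2 Gate values (defaults 100 and 0.6).
#' @return Logical.
#' @export
session_qualifies <- function(n_trials, r2, min_trials = 100, min_r2 = 0.6) {
  n_trials >= min_trials & r2 > min_r2
}

#' Coupling slope restricted to non-licking periods
#'
#' Re-runs the forward coupling pipeline after removing spike clusters
#' within the lick exclusion window, testing that the pupil--LC slope is not
#' an artifact of lick-locked LC activity.
#'
#' @param trace A z-scored [pupil_trace].
#' @param clusters A `spike_clusters` data.frame.
#' @param licks Numeric vector of lick times (seconds).
#' @param config An [analysis_config()].
#' @return As [fit_linear()], plus `n_clusters` (survivors).
#' @export
nonlick_slope <- function(trace, clusters, licks,
                          config = analysis_config()) {
  kept <- exclude_licking(clusters, licks,
                          halfwidth = config$lick_halfwidth)
  if (!nrow(kept)) stop("no clusters survive lick exclusion")
  peaks <- triggered_peaks(trace, kept, window = config$peak_window)
  fit <- fit_linear(coupling_curve(peaks))
  fit$n_clusters <- nrow(kept)
  fit
}
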