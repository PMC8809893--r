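#' Analysis configuration
#'
#' Bundles the constants of the pupil--LC analysis pipeline.  Defaults are the
#' values used throughout: a 6-s window for cluster-triggered peak pupil
#' responses, 0.5-s pupil smoothing before slope estimation, slopes every
#' 0.2 s, spike counting in the \[-4, -2\] s window before each dilation
#' event, 0.3-SD event bins from 0 to 3 SD, 100 bootstrap resamples, 1000
#' permutation iterations, +/- 0.5 s lick exclusion, and an AUC performance
#' threshold of 0.75 (d-prime of 1).
#'
#' @param peak_window Seconds after cluster onset searched for the peak pupil
#'   response (default 6).
#' @param smooth_window Moving-average smoothing window in seconds applied to
#'   the pupil trace before slope estimation (default 0.5).
#' @param slope_step Slope estimation step in seconds (default 0.2).
#' @param pre_event_window Two-element window, in seconds relative to a
#'   dilation event, in which preceding LC spikes are counted
#'   (default `c(-4, -2)`).
#' @param event_bin Dilation-event amplitude bin width in SD units
#'   (default 0.3).
#' @param event_bin_max Upper edge of the binned amplitude range in SD units
#'   (default 3).
#' @param lick_halfwidth Half-width in seconds of the exclusion window around
#'   each lick (default 0.5).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param n_perm Number of permutation iterations (default 1000).
#' @param auc_threshold Ideal-observer performance threshold as an AUC
#'   (default 0.75, approximately d-prime = 1).
#' @param seed Integer seed for the randomized stages, or `NULL`.
#' @return A list of class `analysis_config`.
#' @seealso [load_config()]
#' @export
analysis_config <- function(peak_window = 6,
                            smooth_window = 0.5,
                            slope_step = 0.2,
                            pre_event_window = c(-4, -2),
                            event_bin = 0.3,
                            event_bin_max = 3,
                            lick_halfwidth = 0.5,
                            n_boot = 100,
                            n_perm = 1000,
                            auc_threshold = 0.75,
                            seed = NULL) {
  cfg <- list(peak_window = peak_window, smooth_window = smooth_window,
              slope_step = slope_step, pre_event_window = pre_event_window,
              event_bin = event_bin, event_bin_max = event_bin_max,
              lick_halfwidth = lick_halfwidth, n_boot = n_boot,
              n_perm = n_perm, auc_threshold = auc_threshold, seed = seed)
  for (key in c("peak_window", "smooth_window", "slope_step", "event_bin",
                "event_bin_max", "lick_halfwidth")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("invalid value for '", key, "': must be a positive number")
  }
  pw <- cfg$pre_event_window
  if (!is.numeric(pw) || length(pw) != 2 || !(pw[1] < pw[2]) || pw[2] >= 0)
    stop("invalid value for 'pre_event_window': need w[1] < w[2] < 0")
  for (key in c("n_boot", "n_perm")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("invalid value for '", key, "': must be a positive integer")
  }
  if (!is.numeric(cfg$auc_threshold) || cfg$auc_threshold <= 0 ||
      cfg$auc_threshold >= 1)
    stop("invalid value for 'auc_threshold': must be in (0, 1)")
  if (!is.null(seed) && (!is.numeric(seed) || seed != round(seed)))
    stop("invalid value for 'seed': must be an integer or NULL")
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file take their defaults (see [analysis_config()]);
#' unknown keys raise an error so typos do not silently fall back to
#' defaults.  An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain key: value pairs")
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-17s %s\n", key,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

# Set the RNG locally for the calling function when a seed is given;
# global RNG state is restored when the caller exits.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}
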