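#' Evoked pupil response to one stimulation trial
#'
#' Baseline is the trace mean over `[onset - baseline_window, onset)`;
#' the evoked peak is the maximum over `[onset, onset + response_window]`
#' minus that baseline, reported with its latency.
#'
#' @param trace A [pupil_trace] (mm or z).
#' @param onset Stimulation onset in seconds.
#' @param baseline_window Pre-stimulus baseline window in seconds
#'   (default 2).
#' @param response_window Post-onset search window in seconds (default 6).
#' @return A list with `baseline`, `peak` (baseline-subtracted), `latency`
#'   and `excluded` (windows outside the recording).
#' @export
evoked_pupil <- function(trace, onset, baseline_window = 2,
                         response_window = 6) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (onset - baseline_window < trace$t0 ||
      onset + response_window > trace_end(trace) + 1e-9)
    return(list(baseline = NA_real_, peak = NA_real_, latency = NA_real_,
                excluded = TRUE))
  base_idx <- window_index(trace, onset - baseline_window,
                           onset - 1 / trace$rate)
  resp_idx <- window_index(trace, onset, onset + response_window)
  b <- mean(trace$values[base_idx])
  v <- trace$values[resp_idx]
  j <- which.max(v)
  list(baseline = b, peak = v[j] - b,
       latency = trace$t0 + (resp_idx[j] - 1) / trace$rate - onset,
       excluded = FALSE)
}

#' Evoked pupil responses for a stimulation session
#'
#' Applies [evoked_pupil()] to every trial of a stimulation table.
#'
#' @param trace A [pupil_trace].
#' @param stim A stim trial table (see [read_stim_trials()]).
#' @param baseline_window,response_window See [evoked_pupil()].
#' @return A data.frame with `onset_s`, `baseline`, `peak`, `latency`,
#'   `excluded`.
#' @export
evoked_pupil_trials <- function(trace, stim, baseline_window = 2,
                                response_window = 6) {
  res <- lapply(stim$onset_s, evoked_pupil, trace = trace,
                baseline_window = baseline_window,
                response_window = response_window)
  data.frame(onset_s = stim$onset_s,
             baseline = vapply(res, `[[`, numeric(1), "baseline"),
             peak = vapply(res, `[[`, numeric(1), "peak"),
             latency = vapply(res, `[[`, numeric(1), "latency"),
             excluded = vapply(res, `[[`, logical(1), "excluded"))
}

#' Evoked spike counts per stimulation trial
#'
#' Counts spikes from each trial's first pulse onset to its last pulse
#' offset plus a 50-ms tail, covering single-pulse and pulse-train
#' protocols.
#'
#' @param train A [spike_train].
#' @param stim A stim trial table with `onset_s`, `pulse_ms`, `n_pulses`,
#'   `freq_hz`.
#' @param tail_s Extra time after the last pulse offset (default 0.05).
#' @return An integer vector of counts, one per trial.
#' @export
evoked_spikes <- function(train, stim, tail_s = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  from <- stim$onset_s
  to <- from + ifelse(stim$n_pulses > 1,
                      (stim$n_pulses - 1) / stim$freq_hz, 0) +
    stim$pulse_ms / 1000 + tail_s
  findInterval(to, train$times) - findInterval(from, train$times,
                                               left.open = TRUE)
}

#' Normalize a session pair to the session-1 mean
#'
#' Divides all responses of both sessions by the mean of session 1, so the
#' session-1 mean maps to 1 and the session-2 mean is expressed relative to
#' it.
#'
#' @param pair A [session_pair] whose session-1 mean is nonzero.
#' @return The normalized [session_pair].
#' @export
normalize_sessions <- function(pair) {
  stopifnot(inherits(pair, "session_pair"))
  m1 <- mean(pair$responses_1)
  if (abs(m1) < .Machine$double.eps^0.5)
    stop("session 1 mean is zero; cannot normalize")
  pair$responses_1 <- pair$responses_1 / m1
  pair$responses_2 <- pair$responses_2 / m1
  pair
}

#' Optical fiber model for the excitable-volume estimate
#'
#' Geometric-scattering model of light spreading from a flat fiber tip into
#' brain tissue.  Irradiance at depth `z` below the tip is
#' `I(z) = I0 * rho^2 / ((S z + 1) (z + rho)^2)` with
#' `rho = radius * sqrt((n/NA)^2 - 1)` and `I0 = power / (pi radius^2)`:
#' the `1/(S z + 1)` factor is scattering loss and the remaining factor the
#' geometric spread of the emission cone.
#'
#' @param power Light power at the fiber tip, mW.
#' @param radius Fiber core radius, mm.
#' @param na Fiber numerical aperture (must be below `n_tissue`).
#' @param n_tissue Tissue refractive index (default 1.4).
#' @param scatter Scattering coefficient S in 1/mm (default 11.2, mouse
#'   cortex).
#' @param threshold Opsin activation threshold, mW/mm^2 (default 2.5).
#' @param cone_full_angle Full apex angle, in degrees, of the cylindrical
#'   cone over which the excited tissue volume is accumulated (default 30).
#' @return A list of class `fiber_model`.
#' @export
fiber_model <- function(power = 10, radius = 0.1, na = 0.39, n_tissue = 1.4,
                        scatter = 11.2, threshold = 2.5,
                        cone_full_angle = 30) {
  stopifnot(power >= 0, radius > 0, na > 0, n_tissue > 0, scatter > 0,
            threshold > 0, cone_full_angle > 0, cone_full_angle < 180)
  if (na >= n_tissue) stop("numerical aperture must be below n_tissue")
  structure(list(power = power, radius = radius, na = na,
                 n_tissue = n_tissue, scatter = scatter,
                 threshold = threshold, cone_full_angle = cone_full_angle),
            class = "fiber_model")
}

#' @rdname fiber_model
#' @param model A `fiber_model`.
#' @param z Depths below the fiber tip in mm (vectorized).
#' @return `fiber_irradiance()`: irradiance in mW/mm^2 at each depth.
#' @export
fiber_irradiance <- function(model, z) {
  rho <- model$radius * sqrt((model$n_tissue / model$na)^2 - 1)
  i0 <- model$power / (pi * model$radius^2)
  i0 * rho^2 / ((model$scatter * z + 1) * (z + rho)^2)
}

#' Excitable tissue volume below an optical fiber
#'
#' Finds the threshold depth `z*` where the modeled irradiance falls to the
#' opsin activation threshold (bisection to `tol` mm) and returns the volume
#' of the conical frustum from the fiber tip radius `r0` to
#' `r1 = r0 + z* tan(half angle)`:
#' `V = pi z* / 3 * (r0^2 + r0 r1 + r1^2)`.
#'
#' @param model A [fiber_model()].
#' @param tol Bisection tolerance on `z*` in mm (default 1e-6).
#' @param z_max Upper bracket for the depth search in mm.
#' @return A list with `z_star` (mm), `volume` (mm^3), `i0` (tip irradiance,
#'   mW/mm^2) and `r1` (cone radius at `z*`, mm).  When the tip irradiance
#'   is already below threshold, depth and volume are 0 with a warning.
#' @examples
#' excitable_volume(fiber_model())$volume
#' @export
excitable_volume <- function(model, tol = 1e-6, z_max = 100) {
  stopifnot(inherits(model, "fiber_model"))
  i0 <- model$power / (pi * model$radius^2)
  if (i0 <= model$threshold) {
    warning("tip irradiance at or below threshold; excitable volume is 0")
    return(list(z_star = 0, volume = 0, i0 = i0, r1 = model$radius))
  }
  f <- function(z) fiber_irradiance(model, z) - model$threshold
  if (f(z_max) > 0) stop("irradiance above threshold at z_max; increase z_max")
  z_star <- stats::uniroot(f, c(0, z_max), tol = tol)$root
  r0 <- model$radius
  r1 <- r0 + z_star * tan(model$cone_full_angle / 2 * pi / 180)
  list(z_star = z_star,
       volume = pi * z_star / 3 * (r0^2 + r0 * r1 + r1^2),
       i0 = i0, r1 = r1)
}
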