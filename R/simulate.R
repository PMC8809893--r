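#' Gamma-shaped pupil impulse-response kernel
#'
#' The per-spike pupil response is modeled as a gamma-shaped impulse
#' response: nonnegative, zero at the spike time, rising to a unique maximum
#' at `peak_latency` and decaying with time constant `decay`.  The default
#' 3-s peak sits in the middle of the 2.5--4 s latency range observed for
#' peak pupil dilation after LC spike clusters.
#'
#' @param peak_latency Latency of the kernel maximum in seconds.
#' @param decay Decay time constant in seconds.
#' @param amplitude Kernel maximum in z-units per spike.
#' @return An object of class `coupling_kernel`.
#' @examples
#' k <- coupling_kernel()
#' kernel_eval(k, c(0, 3, 10))
#' @export
coupling_kernel <- function(peak_latency = 3, decay = 1.5, amplitude = 0.15) {
  stopifnot(peak_latency > 0, decay > 0, amplitude >= 0)
  structure(list(family = "gamma", peak_latency = peak_latency,
                 decay = decay, amplitude = amplitude),
            class = "coupling_kernel")
}

#' @rdname coupling_kernel
#' @param kernel A `coupling_kernel`.
#' @param t Times in seconds since the spike (vectorized).
#' @export
kernel_eval <- function(kernel, t) {
  a <- kernel$peak_latency / kernel$decay
  out <- numeric(length(t))
  pos <- t > 0
  # t^a * exp(-t/decay), normalized so the value at peak_latency is amplitude
  out[pos] <- kernel$amplitude * (t[pos] / kernel$peak_latency)^a *
    exp((kernel$peak_latency - t[pos]) / kernel$decay)
  out
}

# kernel sampled on the trace grid, truncated where it becomes negligible
# (below ~1e-15 of the peak)
kernel_samples <- function(kernel, rate) {
  t_max <- kernel$peak_latency + 40 * kernel$decay
  kernel_eval(kernel, seq(0, t_max, by = 1 / rate))
}

#' Simulation configuration for paired LC/pupil recordings
#'
#' Defines the generative model: spike clusters arrive as a homogeneous
#' Poisson process; each cluster's size (spike count) is geometric, so the
#' occurrence of sizes decays monotonically; within-cluster interspike
#' intervals are a fixed short burst interval; the pupil is an
#' Ornstein-Uhlenbeck slow drift plus the summed per-spike kernel (scaled by
#' a session gain) plus white measurement noise.
#'
#' Defaults describe a session of a tonically active LC unit (about 0.9
#' spikes/s from 0.5 clusters/s of mean size 1.8) whose pupil trace is
#' dominated by slow spontaneous fluctuations, so that — as in awake
#' recordings — only the infrequent large clusters are decodable from pupil.
#'
#' @param duration Session length in seconds.
#' @param cluster_rate Cluster (burst) rate in events/s.
#' @param cluster_size_dist Geometric success parameter in (0, 1); cluster
#'   size is `1 + rgeom(., 1 - p ... )` i.e. `P(size = k) = p (1-p)^(k-1)`
#'   with `p = cluster_size_dist`, mean `1/p`.
#' @param intra_cluster_isi Within-cluster interspike interval in seconds.
#' @param kernel A [coupling_kernel()].
#' @param gain Unitless session coupling gain multiplying the kernel.
#' @param noise_sd White measurement noise SD in z-units.
#' @param drift_sd Stationary SD of the slow Ornstein-Uhlenbeck drift.
#' @param drift_tau Drift time constant in seconds.
#' @param rate_hz Pupil sampling rate in Hz.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 600,
                       cluster_rate = 0.5,
                       cluster_size_dist = 0.55,
                       intra_cluster_isi = 0.03,
                       kernel = coupling_kernel(),
                       gain = 1,
                       noise_sd = 0.05,
                       drift_sd = 1,
                       drift_tau = 100,
                       rate_hz = 50,
                       seed = NULL) {
  stopifnot(duration > 0, cluster_rate >= 0, intra_cluster_isi > 0,
            gain >= 0, noise_sd >= 0, drift_sd >= 0, drift_tau > 0,
            rate_hz > 0)
  if (!(cluster_size_dist > 0 && cluster_size_dist <= 1))
    stop("cluster_size_dist must be in (0, 1]")
  if (!inherits(kernel, "coupling_kernel")) stop("kernel must be a coupling_kernel")
  if (duration <= 10 * kernel$peak_latency)
    stop("duration must exceed 10 x kernel peak latency")
  if (cluster_rate > 0 && intra_cluster_isi >= log(2) / cluster_rate)
    stop("intra_cluster_isi >= median inter-cluster gap: clusters would merge")
  structure(list(duration = duration, cluster_rate = cluster_rate,
                 cluster_size_dist = cluster_size_dist,
                 intra_cluster_isi = intra_cluster_isi, kernel = kernel,
                 gain = gain, noise_sd = noise_sd, drift_sd = drift_sd,
                 drift_tau = drift_tau, rate_hz = rate_hz, seed = seed),
            class = "sim_config")
}

#' Generate a bursty LC spike train
#'
#' Cluster onsets are a homogeneous Poisson process at `cluster_rate`;
#' each cluster contributes `size` spikes separated by `intra_cluster_isi`,
#' with sizes drawn from the geometric law of `cluster_size_dist`.  The
#' generating cluster onsets and sizes are attached as attributes
#' `gt_onsets` / `gt_sizes` (ground truth before any boundary truncation).
#'
#' @param cfg A [sim_config()].
#' @param unit_id,session_id Identifiers for the returned train.
#' @return A [spike_train] spanning `[0, duration]`.
#' @export
generate_spike_train <- function(cfg, unit_id = "sim", session_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed)
  n_cl <- stats::rpois(1, cfg$cluster_rate * cfg$duration)
  if (n_cl == 0)
    return(structure(spike_train(numeric(0), unit_id, session_id,
                                 t_end = cfg$duration),
                     gt_onsets = numeric(0), gt_sizes = integer(0)))
  onsets <- sort(stats::runif(n_cl, 0, cfg$duration))
  sizes <- 1L + stats::rgeom(n_cl, cfg$cluster_size_dist)
  times <- rep(onsets, sizes) +
    cfg$intra_cluster_isi * (sequence(sizes) - 1)
  times <- sort(times[times <= cfg$duration])
  times <- times[!duplicated(times)]
  st <- spike_train(times, unit_id, session_id, t_end = cfg$duration)
  attr(st, "gt_onsets") <- onsets
  attr(st, "gt_sizes") <- sizes
  st
}

# AR(1)-discretized Ornstein-Uhlenbeck process with stationary sd `sd`
ou_drift <- function(n, sd, tau, dt) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  eps <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  eps[1] <- stats::rnorm(1, sd = sd)  # start at stationarity
  as.numeric(stats::filter(eps, phi, method = "recursive"))
}

#' Generate a pupil trace from a spike train
#'
#' The trace is `drift + gain * sum_i kernel(t - t_i) + noise`, sampled at
#' `rate_hz`: an Ornstein-Uhlenbeck slow drift, the per-spike gamma kernel
#' summed over spikes (each spike assigned to its enclosing sample bin), and
#' white measurement noise.  Values are in mm-free z-units (the trace is a
#' fluctuation around an arbitrary mean diameter), so the units flag is
#' `"z"`; no re-standardization is applied here — use [zscore_trace()] as in
#' the analysis pipeline.
#'
#' @param spikes A [spike_train] within `[0, duration]`.
#' @param cfg A [sim_config()].  Its `seed` governs drift and noise; pass the
#'   same config used for [generate_spike_train()] for a reproducible pair
#'   (spike generation and pupil generation consume the RNG sequentially).
#' @param seed Optional seed overriding `cfg$seed` for the pupil noise.
#' @return A [pupil_trace] with `units = "z"`.
#' @export
generate_pupil <- function(spikes, cfg, seed = cfg$seed) {
  stopifnot(inherits(spikes, "spike_train"), inherits(cfg, "sim_config"))
  if (n_spikes(spikes) &&
      (spikes$times[1] < 0 || spikes$times[n_spikes(spikes)] > cfg$duration))
    stop("spikes must lie within [0, duration]")
  local_seed(seed)
  n <- floor(cfg$duration * cfg$rate_hz) + 1
  dt <- 1 / cfg$rate_hz
  drift <- ou_drift(n, cfg$drift_sd, cfg$drift_tau, dt)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else 0
  signal <- numeric(n)
  if (cfg$gain > 0 && n_spikes(spikes) > 0) {
    counts <- tabulate(floor(spikes$times * cfg$rate_hz) + 1L, nbins = n)
    ker <- kernel_samples(cfg$kernel, cfg$rate_hz)
    # linear convolution via FFT on a highly composite padded length
    len <- stats::nextn(n + length(ker) - 1)
    conv <- Re(stats::fft(stats::fft(c(counts, numeric(len - n))) *
                          stats::fft(c(ker, numeric(len - length(ker)))),
               inverse = TRUE)) / len
    signal <- cfg$gain * conv[seq_len(n)]
  }
  pupil_trace(drift + signal + noise, rate = cfg$rate_hz, t0 = 0,
              units = "z", session_id = spikes$session_id)
}

#' Generate a pair of optogenetic stimulation sessions
#'
#' Two sessions receive the identical stimulation protocol: each trial
#' injects `n_pulses` spikes at `freq_hz` into the spontaneous generative
#' train (one evoked spike per pulse), and the pupil is generated with each
#' session's own gain and noise.  Per-trial evoked pupil responses (peak over
#' the response window minus the pre-trial baseline mean) form a
#' [session_pair] for resampling comparisons.
#'
#' @param cfg_a,cfg_b [sim_config()]s that may differ only in `gain`,
#'   `noise_sd` and `seed`.
#' @param stim A stim trial table (see [read_stim_trials()]) whose trials fit
#'   inside the session with the response window.
#' @param baseline_window,response_window Seconds before/after each trial
#'   onset over which baseline mean and evoked peak are taken.
#' @return A [session_pair] with attribute `trials` (the stim table).
#' @export
generate_session_pair <- function(cfg_a, cfg_b, stim,
                                  baseline_window = 2, response_window = 6) {
  stopifnot(inherits(cfg_a, "sim_config"), inherits(cfg_b, "sim_config"))
  same <- setdiff(names(cfg_a), c("gain", "noise_sd", "seed"))
  if (!isTRUE(all.equal(cfg_a[same], cfg_b[same])))
    stop("session configs may differ only in gain, noise_sd and seed")
  stim <- validate_stim_trials(as.data.frame(stim))
  if (max(stim$onset_s) + response_window > cfg_a$duration ||
      min(stim$onset_s) - baseline_window < 0)
    stop("stimulation trials do not fit inside the session")
  one <- function(cfg) {
    local_seed(cfg$seed)
    spont <- generate_spike_train(sim_config_unseeded(cfg))
    evoked <- unlist(lapply(seq_len(nrow(stim)), function(i)
      stim$onset_s[i] + (seq_len(stim$n_pulses[i]) - 1) / stim$freq_hz[i]))
    times <- sort(unique(c(spont$times, evoked)))
    train <- spike_train(times, "sim", "sim", t_end = cfg$duration)
    trace <- generate_pupil(train, sim_config_unseeded(cfg), seed = NULL)
    ev <- evoked_pupil_trials(trace, stim, baseline_window = baseline_window,
                              response_window = response_window)
    list(responses = ev$peak, baseline = mean(ev$baseline))
  }
  a <- one(cfg_a)
  b <- one(cfg_b)
  sp <- session_pair(a$responses, b$responses,
                     baseline_1 = a$baseline, baseline_2 = b$baseline,
                     units = "z")
  attr(sp, "trials") <- stim
  sp
}

# copy of a sim_config with the seed removed (RNG already positioned)
sim_config_unseeded <- function(cfg) {
  cfg$seed <- NULL
  cfg
}

#' Generate a Go/NoGo behavioral session
#'
#' Trial types are assigned go (stimulus present) with probability `p_go`;
#' go trials are hits with probability `hit_rate`, nogo trials false alarms
#' with probability `fa_rate`.  Licks are placed shortly after the stimulus
#' on every response trial.
#'
#' @param hit_rate,fa_rate Response probabilities in (0, 1) (degenerate 0/1
#'   allowed for exact constructions).
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param p_go Probability of a go trial.
#' @param iti Inter-trial onset spacing in seconds.
#' @param rt Lick latency after trial onset, seconds.
#' @return A `trial_table` data.frame with columns `trial_id`, `onset_s`,
#'   `stim_present`, `response`, `outcome`, `lick_s` (NA when no response).
#' @export
generate_behavior_session <- function(hit_rate, fa_rate, n_trials,
                                      seed = NULL, p_go = 0.5, iti = 10,
                                      rt = 0.4) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  if (n_trials < 1) stop("n_trials must be >= 1")
  local_seed(seed)
  go <- stats::runif(n_trials) < p_go
  resp <- ifelse(go, stats::runif(n_trials) < hit_rate,
                 stats::runif(n_trials) < fa_rate)
  onset <- iti * (seq_len(n_trials) - 1) + 2
  df <- data.frame(trial_id = seq_len(n_trials), onset_s = onset,
                   stim_present = go, response = resp,
                   outcome = implied_outcome(go, resp),
                   lick_s = ifelse(resp, onset + rt, NA_real_))
  validate_trials(df)
}

#' @rdname generate_behavior_session
#' @param trials A trial table with a `lick_s` column.
#' @return `trial_licks()`: sorted lick times of the response trials.
#' @export
trial_licks <- function(trials) {
  sort(trials$lick_s[!is.na(trials$lick_s)])
}
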