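# Small in-code fixtures shared across test files.

# trace holding given values at `rate`, declared z units (no re-scaling)
z_trace <- function(values, rate = 50, t0 = 0)
  pupil_trace(values, rate = rate, t0 = t0, units = "z")

# time-sampled trace from a function of t over [0, dur]
fun_trace <- function(f, dur, rate = 50, units = "z") {
  t <- seq(0, dur, by = 1 / rate)
  pupil_trace(f(t), rate = rate, t0 = 0, units = units)
}

# write a data.frame to a temporary csv, return path
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# brute-force cluster splitter: cut at every ISI >= threshold
oracle_clusters <- function(times, threshold) {
  if (!length(times)) return(list())
  groups <- list()
  cur <- times[1]
  for (tt in times[-1]) {
    if (tt - cur[length(cur)] < threshold) cur <- c(cur, tt)
    else { groups[[length(groups) + 1]] <- cur; cur <- tt }
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

# brute-force AUC by exhaustive pair counting with half ties
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# random spike train with bursty structure for property tests
random_train <- function(n_max = 20, t_max = 30) {
  n <- sample(2:n_max, 1)
  times <- sort(stats::runif(n, 0, t_max))
  times <- times[!duplicated(times)]
  spike_train(times, t_end = t_max)
}
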