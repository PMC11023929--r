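# Shared synthetic sessions, generated once per test run and cached.
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, params, lfp = TRUE) {
  if (!exists(key, .session_cache)) {
    assign(key, generate_session(params, lfp = lfp), .session_cache)
  }
  get(key, .session_cache)
}

# small all-purpose session with LFP (fast)
small_session <- function() {
  cached_session("small", sim_params(duration = 240, rng_seed = 42))
}

# spike-rich session without LFP for decoding tests
spike_session <- function() {
  cached_session("spikes", sim_params(duration = 600, rng_seed = 5),
                 lfp = FALSE)
}

# homogeneous Poisson spike table (vectorized)
poisson_units <- function(n_units, rate_hz, duration, region = "X") {
  k <- rpois(n_units, rate_hz * duration)
  spike_table(rep(seq_len(n_units), k), runif(sum(k), 0, duration),
              region)
}

# random event table of one kind, away from the session edges
random_events <- function(n, duration, kind = "DS2", margin = 1) {
  event_table(kind = rep(kind, n),
              peak_time = sort(runif(n, margin, duration - margin)),
              amplitude = 2)
}

# units with an event-locked Hann rate gain (peak rate = gain x base)
gain_units <- function(n_units, base_hz, gain, event_times, duration,
                       half_width_s = 0.05, region = "X") {
  id <- integer(0); st <- numeric(0)
  for (u in seq_len(n_units)) {
    t_u <- runif(rpois(1, base_hz * duration), 0, duration)
    lam <- (gain - 1) * base_hz * half_width_s  # Hann kernel integral
    for (tp in event_times) {
      k <- rpois(1, lam)
      acc <- numeric(0)
      while (length(acc) < k) {
        x <- runif(max(k, 4), -half_width_s, half_width_s)
        keep <- runif(length(x)) < 0.5 + 0.5 * cos(pi * x / half_width_s)
        acc <- c(acc, x[keep])
      }
      t_u <- c(t_u, tp + acc[seq_len(k)])
    }
    t_u <- t_u[t_u >= 0 & t_u < duration]
    id <- c(id, rep(u, length(t_u))); st <- c(st, t_u)
  }
  spike_table(id, st, region)
}

# brute-force plug-in MI from an explicit joint table (bits)
brute_mi <- function(P) {
  pa <- rowSums(P); pb <- colSums(P)
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    if (P[i, j] > 0)
      s <- s + P[i, j] * log2(P[i, j] / (pa[i] * pb[j]))
  s
}

# brute-force Bayesian decoder: explicit Poisson product over bins
brute_decode <- function(counts, rate, tau, floor_hz = 0.01) {
  r <- pmax(rate, floor_hz)
  p <- vapply(seq_len(ncol(r)), function(x)
    prod(dpois(counts, r[, x] * tau)), numeric(1))
  p / sum(p)
}
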