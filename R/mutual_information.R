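# Time-resolved coupling between brain regions around LFP events:
# plug-in mutual information on discretized pooled spike counts, with a
# Monte-Carlo trial-shuffle null and a significant-coupling graph.

#' Discretize regional spike counts around events
#'
#' Pools the spikes of all units in a region, bins them in 5 ms bins
#' over +/- 200 ms around each event (trial), and maps counts to
#' `n_states` states by uniform-count (quantile) binning computed over
#' all trials and bins; ties go to the lower state.
#'
#' @param spikes a [spike_table()].
#' @param events an [event_table()].
#' @param region region label to pool.
#' @param bin_ms bin width (default 5).
#' @param n_states number of states (default 4).
#' @param window_ms half-window (default 200).
#' @return integer matrix trials x time bins with entries in
#'   `0:(n_states-1)`; attribute `"time_ms"` holds bin centres.
#' @export
discretize_counts <- function(spikes, events, region, bin_ms = 5,
                              n_states = 4, window_ms = 200) {
  st <- sort(spikes$spike_time[spikes$region == region])
  if (length(st) == 0 && !region %in% spikes$region)
    stop("region not present: ", region)
  w <- window_ms / 1000
  bw <- bin_ms / 1000
  nb <- as.integer(2 * window_ms / bin_ms)
  counts <- matrix(0L, nrow(events), nb)
  for (i in seq_len(nrow(events))) {
    lo <- findInterval(events$peak_time[i] - w, st) + 1
    hi <- findInterval(events$peak_time[i] + w, st)
    if (hi >= lo) {
      rel <- st[lo:hi] - events$peak_time[i]
      bin <- pmin(nb, floor((rel + w) / bw) + 1)
      counts[i, ] <- tabulate(bin, nbins = nb)
    }
  }
  qs <- quantile(counts, probs = seq_len(n_states - 1) / n_states,
                 type = 1, names = FALSE)
  # state = number of quantile boundaries strictly below the count
  states <- matrix(0L, nrow(counts), ncol(counts))
  for (q in qs) states <- states + (counts > q)
  attr(states, "time_ms") <- seq(-window_ms + bin_ms / 2,
                                 window_ms - bin_ms / 2, by = bin_ms)
  states
}

# plug-in MI (bits) between two integer state vectors
plugin_mi <- function(a, b, n_states) {
  n <- length(a)
  j <- tabulate(a + n_states * b + 1L, nbins = n_states^2) / n
  pj <- matrix(j, n_states, n_states)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Mutual-information timecourse between two regions
#'
#' Per time bin, the plug-in mutual information (log base 2) across
#' trials between the two regions' states; the mean over the baseline
#' bins (-200 to -100 ms) is subtracted to give the delta-MI
#' timecourse.
#'
#' @param states_a,states_b trial x bin state matrices from
#'   [discretize_counts()] (same trials and bins).
#' @param n_states alphabet size (default 4).
#' @return list: `mi` (bits per bin), `delta_mi`, `delta_mi_max`,
#'   `time_ms`, `baseline`.
#' @export
mutual_info_timecourse <- function(states_a, states_b, n_states = 4) {
  stopifnot(all(dim(states_a) == dim(states_b)))
  if (nrow(states_a) < 2) stop("need at least 2 trials")
  tm <- attr(states_a, "time_ms")
  if (is.null(tm))
    tm <- seq_len(ncol(states_a))
  mi <- vapply(seq_len(ncol(states_a)), function(k)
    plugin_mi(states_a[, k], states_b[, k], n_states), numeric(1))
  base_idx <- which(tm >= -200 & tm < -100)
  if (length(base_idx) == 0) base_idx <- seq_len(max(1, ncol(states_a) %/% 4))
  baseline <- mean(mi[base_idx])
  dmi <- mi - baseline
  list(mi = mi, delta_mi = dmi, delta_mi_max = max(dmi),
       time_ms = tm, baseline = baseline)
}

#' Monte-Carlo significance of event-locked mutual information
#'
#' Null by permuting whole trials (rows) of one region, preserving each
#' region's temporal structure; the statistic is the maximum delta-MI
#' over bins. `p = (1 + #{null >= observed}) / (1 + n_shuffles)`.
#'
#' @param states_a,states_b trial x bin state matrices.
#' @param n_shuffles Monte-Carlo permutations (default 5000).
#' @param alpha significance level (default 0.01).
#' @param n_states alphabet size (default 4).
#' @param seed RNG seed for the shuffle substream.
#' @return list: `delta_mi_max`, `p_value`, `significant`, `n_trials`,
#'   `timecourse`.
#' @export
mi_significance <- function(states_a, states_b, n_shuffles = 5000,
                            alpha = 0.01, n_states = 4, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  obs <- mutual_info_timecourse(states_a, states_b, n_states)
  nt <- nrow(states_a); nb <- ncol(states_a)
  tm <- obs$time_ms
  base_idx <- which(tm >= -200 & tm < -100)
  if (length(base_idx) == 0) base_idx <- seq_len(max(1, nb %/% 4))
  null_max <- with_substream(seed, "mi_null", {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(nt)
      jj <- states_a + n_states * states_b[perm, , drop = FALSE] + 1L
      cnt <- matrix(tabulate(jj + n_states^2 * (col(jj) - 1L),
                             nbins = n_states^2 * nb),
                    n_states^2, nb) / nt
      mi_b <- vapply(seq_len(nb), function(k) {
        pj <- matrix(cnt[, k], n_states, n_states)
        pa <- rowSums(pj); pb <- colSums(pj)
        nz <- pj > 0
        sum(pj[nz] * log2(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
      }, numeric(1))
      max(mi_b - mean(mi_b[base_idx]))
    }, numeric(1))
  })
  p <- (1 + sum(null_max >= obs$delta_mi_max)) / (1 + n_shuffles)
  list(delta_mi_max = obs$delta_mi_max, p_value = p,
       significant = p < alpha, n_trials = nt, timecourse = obs)
}

#' Brain-wide coupling graph from MI results
#'
#' Nodes are regions; an edge joins a pair if the pair is significant
#' and has results from at least `min_sessions` sessions. Edge weight
#' is the maximum delta-MI.
#'
#' @param results data.frame with columns `region_a`, `region_b`,
#'   `session`, `delta_mi_max`, `significant` (one row per pair x
#'   session).
#' @param min_sessions minimum session count per pair (default 5).
#' @return list: `graph` (igraph, weighted), `percent_significant`
#'   (of pairs meeting the session minimum), `sum_delta_mi` (over
#'   significant pairs), `pairs` summary data.frame.
#' @export
coupling_graph <- function(results, min_sessions = 5) {
  key <- paste(pmin(results$region_a, results$region_b),
               pmax(results$region_a, results$region_b), sep = "|")
  agg <- lapply(split(results, key), function(d) {
    data.frame(region_a = pmin(d$region_a[1], d$region_b[1]),
               region_b = pmax(d$region_a[1], d$region_b[1]),
               n_sessions = length(unique(d$session)),
               weight = max(d$delta_mi_max),
               significant = any(d$significant))
  })
  pairs <- do.call(rbind, agg)
  rownames(pairs) <- NULL
  eligible <- pairs[pairs$n_sessions >= min_sessions, , drop = FALSE]
  sig <- eligible[eligible$significant, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sig[, c("region_a", "region_b", "weight")], directed = FALSE,
    vertices = data.frame(name = sort(unique(c(results$region_a,
                                               results$region_b)))))
  list(graph = g,
       percent_significant = if (nrow(eligible) == 0) 0
       else 100 * nrow(sig) / nrow(eligible),
       sum_delta_mi = if (nrow(sig) == 0) 0 else sum(sig$weight),
       pairs = pairs)
}
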