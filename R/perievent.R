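# Peri-event firing-rate standardization, shuffle modulation tests,
# brain-wide high-firing peaks, behaviour-change tests with +/-2 s
# shuffle nulls, motion-state segmentation, and dF/F baselining.

peri_bins <- function(config) {
  w <- config$peri_window_ms; b <- config$peri_bin_ms
  n <- 2 * w / b
  list(n = as.integer(n), edges_ms = seq(-w, w, by = b),
       centers_ms = seq(-w + b / 2, w - b / 2, by = b))
}

# relative spike times (s) within +/- window of each event, per unit;
# returns list(rel = times, event = event index)
peri_spike_times <- function(st, event_times, window_s) {
  rel <- numeric(0); evi <- integer(0)
  for (i in seq_along(event_times)) {
    lo <- findInterval(event_times[i] - window_s, st) + 1
    hi <- findInterval(event_times[i] + window_s, st)
    if (hi >= lo) {
      rel <- c(rel, st[lo:hi] - event_times[i])
      evi <- c(evi, rep(i, hi - lo + 1))
    }
  }
  list(rel = rel, event = evi)
}

#' Session firing statistics per unit
#'
#' Whole-session rate in 100 ms bins, smoothed with a Gaussian filter
#' (sigma 5 bins); returns each unit's mean and SD in Hz — the
#' standardization used for peri-event z-scores.
#'
#' @param spikes a [spike_table()].
#' @param duration session duration, seconds.
#' @param config a [pipeline_config()].
#' @return data.frame with `unit_id`, `mean_hz`, `sd_hz`.
#' @export
session_rate_stats <- function(spikes, duration, config = pipeline_config()) {
  units <- sort(unique(spikes$unit_id))
  bw <- config$session_bin_ms / 1000
  nb <- max(1L, floor(duration / bw))
  by_unit <- split_units(spikes, units)
  out <- lapply(units, function(u) {
    st <- by_unit[[as.character(u)]]
    cnt <- tabulate(pmin(nb, floor(st / bw) + 1), nbins = nb)
    r <- gauss_smooth(cnt / bw, config$session_smooth_sigma_bins)
    data.frame(unit_id = u, mean_hz = mean(r), sd_hz = sd(r))
  })
  do.call(rbind, out)
}

#' Peri-event z-scored firing rates
#'
#' Per unit: spike counts in 10 ms bins over the 400 ms peri-event
#' window centred on each event peak, converted to Hz and z-scored with
#' the unit's session mean and SD (from [session_rate_stats()]); the
#' event-averaged trace and its maximum (`peak_z`) are returned. Units
#' with zero session SD are excluded.
#'
#' @param spikes a [spike_table()].
#' @param events an [event_table()] of a single kind (events with
#'   multiple kinds within the peri window should be pre-excluded).
#' @param duration session duration, seconds.
#' @param config a [pipeline_config()].
#' @return list of per-unit results: `unit_id`, `rate_z` (events x
#'   bins), `trace_z` (bin average), `peak_z`, `peak_bin_time_ms`,
#'   `session_mean`, `session_sd`.
#' @export
perievent_zscores <- function(spikes, events, duration,
                              config = pipeline_config()) {
  if (length(unique(events$kind)) > 1)
    stop("events must be of a single kind")
  pb <- peri_bins(config)
  w <- config$peri_window_ms / 1000
  bw <- config$peri_bin_ms / 1000
  stats <- session_rate_stats(spikes, duration, config)
  by_unit <- split_units(spikes)
  out <- list()
  for (k in seq_len(nrow(stats))) {
    u <- stats$unit_id[k]
    if (stats$sd_hz[k] <= 0) {
      message("unit ", u, " excluded: zero session rate SD")
      next
    }
    ps <- peri_spike_times(by_unit[[as.character(u)]],
                           events$peak_time, w)
    counts <- matrix(0, nrow(events), pb$n)
    if (length(ps$rel) > 0) {
      bin <- pmin(pb$n, floor((ps$rel + w) / bw) + 1)
      for (j in seq_along(bin))
        counts[ps$event[j], bin[j]] <- counts[ps$event[j], bin[j]] + 1
    }
    rate_z <- (counts / bw - stats$mean_hz[k]) / stats$sd_hz[k]
    trace <- colMeans(rate_z)
    out[[length(out) + 1]] <- list(
      unit_id = u, rate_z = rate_z, trace_z = trace,
      peak_z = max(trace),
      peak_bin_time_ms = pb$centers_ms[which.max(trace)],
      session_mean = stats$mean_hz[k], session_sd = stats$sd_hz[k])
  }
  out
}

#' Shuffle test for event-locked rate modulation
#'
#' Null built by redrawing each peri-event spike's time uniformly
#' within the window (preserving per-event counts), `n_shuffles` times;
#' a unit is significantly modulated if the maximal bin of its observed
#' event-averaged rate exceeds the given percentile of the shuffled
#' maxima. The comparison is done on averaged counts; z-scoring is an
#' affine per-unit transform and does not change the outcome.
#'
#' @param spikes a [spike_table()].
#' @param events single-kind [event_table()].
#' @param n_shuffles shuffles (default 100; the threshold estimate is
#'   anticonservative at small values — see the methods vignette).
#' @param percentile null percentile (default 99.5).
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the shuffle substream.
#' @return data.frame: `unit_id`, `significant`, `peak_bin_time_ms`,
#'   `observed_max`, `null_threshold`.
#' @export
modulation_test <- function(spikes, events, n_shuffles = 100,
                            percentile = 99.5,
                            config = pipeline_config(), seed = 1L) {
  pb <- peri_bins(config)
  w <- config$peri_window_ms / 1000
  bw <- config$peri_bin_ms / 1000
  units <- sort(unique(spikes$unit_id))
  by_unit <- split_units(spikes, units)
  ne <- nrow(events)
  with_substream(seed, "modulation", {
    rows <- lapply(units, function(u) {
      ps <- peri_spike_times(by_unit[[as.character(u)]],
                             events$peak_time, w)
      n_tot <- length(ps$rel)
      if (n_tot < 2)
        return(data.frame(unit_id = u, significant = FALSE,
                          peak_bin_time_ms = NA_real_,
                          observed_max = NA_real_,
                          null_threshold = NA_real_))
      bin <- pmin(pb$n, floor((ps$rel + w) / bw) + 1)
      obs <- tabulate(bin, nbins = pb$n) / ne
      # uniform redraw within the window; the event-averaged trace
      # depends only on the pooled spikes, so each shuffle is one
      # multinomial draw of the pooled count over the bins
      m <- stats::rmultinom(n_shuffles, n_tot, rep(1 / pb$n, pb$n))
      null_max <- m[cbind(max.col(t(m), ties.method = "first"),
                          seq_len(n_shuffles))] / ne
      thr <- quantile(null_max, percentile / 100, names = FALSE)
      data.frame(unit_id = u, significant = max(obs) > thr,
                 peak_bin_time_ms = pb$centers_ms[which.max(obs)],
                 observed_max = max(obs), null_threshold = thr)
    })
    do.call(rbind, rows)
  })
}

#' High brain-wide firing peaks
#'
#' Population-average rate (all spikes pooled, averaged across cells)
#' in 10 ms bins; peaks exceeding the 99.9th percentile of this trace
#' are returned as `HIGH_FIRING` events (one per supra-threshold run,
#' at the run's maximum).
#'
#' @param spikes a [spike_table()] (>= 1 unit).
#' @param duration session duration, seconds.
#' @param config a [pipeline_config()].
#' @return an [event_table()]; attribute `"fraction_bins_above"` gives
#'   the flagged-bin fraction.
#' @export
high_firing_peaks <- function(spikes, duration, config = pipeline_config()) {
  if (nrow(spikes) == 0) stop("empty spike table")
  n_units <- length(unique(spikes$unit_id))
  bw <- config$peri_bin_ms / 1000
  nb <- max(1L, floor(duration / bw))
  cnt <- tabulate(pmin(nb, floor(spikes$spike_time / bw) + 1), nbins = nb)
  trace <- cnt / bw / n_units
  thr <- quantile(trace, config$high_firing_percentile / 100, names = FALSE)
  above <- trace > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  pk_t <- vapply(keep, function(i) {
    seg <- starts[i]:ends[i]
    (seg[which.max(trace[seg])] - 0.5) * bw
  }, numeric(1))
  out <- event_table(kind = rep("HIGH_FIRING", length(pk_t)),
                     peak_time = pk_t)
  attr(out, "fraction_bins_above") <- mean(above)
  out
}

#' Event-locked behaviour change with a shifted-event null
#'
#' Per event, change = mean of the signal in the post window minus the
#' pre window (windows in ms relative to the event peak; defaults are
#' the pupil windows). The null pools changes recomputed at event times
#' shifted by uniform draws in +/- `shift_s`; events whose change
#' exceeds the pooled 97.5th percentile are flagged (one-sided increase
#' at two-sided P < 0.05).
#'
#' @param behavior a [behavior_trace()].
#' @param events an [event_table()].
#' @param signal column of `behavior` to test.
#' @param pre_ms,post_ms window bounds, ms relative to the peak.
#' @param n_draws null draws per event (default 200).
#' @param shift_s maximum shift, seconds (default 2).
#' @param percentile null percentile (default 97.5).
#' @param seed RNG seed for the shuffle substream.
#' @return list: `change` (per event, NA if clipped at the trace edge),
#'   `significant`, `cutoff`, `fraction_significant`.
#' @export
behavior_change_test <- function(behavior, events,
                                 signal = "pupil_diameter",
                                 pre_ms = c(-290, -85),
                                 post_ms = c(-20, 85),
                                 n_draws = 200, shift_s = 2,
                                 percentile = 97.5, seed = 1L) {
  x <- behavior[[signal]]
  stopifnot(!is.null(x))
  t0 <- behavior$t[1]
  dt <- behavior$t[2] - behavior$t[1]
  n <- length(x)
  cs <- cumsum(x)
  win_mean <- function(times, win_ms) {
    i0 <- floor((times + win_ms[1] / 1000 - t0) / dt) + 1
    i1 <- floor((times + win_ms[2] / 1000 - t0) / dt) + 1
    bad <- i0 < 1 | i1 > n | i1 < i0
    i0c <- pmax(1L, pmin(n, i0)); i1c <- pmax(1L, pmin(n, i1))
    m <- (cs[i1c] - c(0, cs)[i0c]) / (i1c - i0c + 1)
    m[bad] <- NA_real_
    m
  }
  change_at <- function(times)
    win_mean(times, post_ms) - win_mean(times, pre_ms)
  obs <- change_at(events$peak_time)
  if (anyNA(obs))
    message(sum(is.na(obs)), " event(s) skipped: window outside trace")
  null_pool <- with_substream(seed, "behavior_null", {
    sh <- runif(n_draws * nrow(events), -shift_s, shift_s)
    change_at(rep(events$peak_time, n_draws) + sh)
  })
  cutoff <- quantile(null_pool, percentile / 100, na.rm = TRUE,
                     names = FALSE)
  sig <- !is.na(obs) & obs > cutoff
  list(change = obs, significant = sig, cutoff = cutoff,
       fraction_significant = mean(sig[!is.na(obs)]))
}

#' Segment immobility and locomotion
#'
#' Maximal intervals with speed below (immobility) or at/above
#' (locomotion) the threshold; the intervals tile the sampled time
#' span, half-open.
#'
#' @param behavior a [behavior_trace()].
#' @param threshold_cm_s speed cutoff, default 1 cm/s.
#' @return list of data.frames `immobility` and `locomotion`
#'   (`start`, `end`).
#' @export
segment_motion_state <- function(behavior, threshold_cm_s = 1) {
  dt <- behavior$t[2] - behavior$t[1]
  im <- behavior$speed < threshold_cm_s
  r <- rle(im)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- data.frame(start = behavior$t[starts],
                   end = behavior$t[ends] + dt,
                   immobile = r$values)
  list(immobility = iv[iv$immobile, c("start", "end"), drop = FALSE],
       locomotion = iv[!iv$immobile, c("start", "end"), drop = FALSE])
}

#' Fluorescence dF/F with a polynomial baseline
#'
#' Least-squares cubic polynomial in time fitted to the raw trace is
#' the time-dependent baseline B(t); the result is (F - B)/B.
#'
#' @param f fluorescence trace.
#' @param t sample times (default sample index).
#' @return dF/F trace.
#' @export
dff <- function(f, t = seq_along(f)) {
  if (length(f) < 4) stop("trace must have at least 4 samples")
  fit <- lm(f ~ poly(t, 3, raw = TRUE))
  b <- as.numeric(stats::fitted(fit))
  if (any(b <= 0)) stop("polynomial baseline crosses zero; dF/F undefined")
  (f - b) / b
}

#' Event-aligned z-scores of a continuous trace
#'
#' Windows around each event standardized by the mean and SD of the
#' preceding 1 s of data.
#'
#' @param x trace (e.g. dF/F); `fs` its sampling rate.
#' @param fs sampling rate, Hz.
#' @param event_times seconds.
#' @param window_s window around each event, default c(-1, 1).
#' @param baseline_s length of the preceding standardization window.
#' @return matrix events x samples (NA rows where windows clip).
#' @export
event_aligned_z <- function(x, fs, event_times, window_s = c(-1, 1),
                            baseline_s = 1) {
  i_win <- round(window_s[1] * fs):round(window_s[2] * fs)
  out <- matrix(NA_real_, length(event_times), length(i_win))
  for (e in seq_along(event_times)) {
    c0 <- round(event_times[e] * fs) + 1
    base <- (c0 - round(baseline_s * fs)):(c0 - 1)
    idx <- c0 + i_win
    if (min(base) < 1 || max(idx) > length(x)) next
    mu <- mean(x[base]); s <- sd(x[base])
    if (s > 0) out[e, ] <- (x[idx] - mu) / s
  }
  out
}
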