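# Dentate spike and sharp-wave ripple detection from laminar LFP,
# plus cross-probe synchrony, evoked latency and event rates.

#' Detect dentate spikes
#'
#' Bandpass-filters the hilus channel (5-100 Hz, zero phase) and keeps
#' local maxima exceeding `ds_threshold_sd` standard deviations of the
#' filtered trace. The timepoint at the maximum of each peak is the DS
#' time; amplitude is the filtered-trace value there and half-width the
#' width at half that amplitude on the filtered trace. Super-threshold
#' peaks closer than one template width are merged, keeping the larger.
#'
#' @param lfp an [lfp_recording()].
#' @param hilus_channel channel index (1-based) of the hilus trace.
#' @param config a [pipeline_config()] (fields `ds_band`,
#'   `ds_threshold_sd`, `ds_merge_ms`).
#' @return an [event_table()] of kind `DS_unclassified`.
#' @export
detect_ds <- function(lfp, hilus_channel, config = pipeline_config()) {
  stopifnot(hilus_channel >= 1, hilus_channel <= nrow(lfp$voltage))
  x <- lfp$voltage[hilus_channel, ]
  min_len <- 6 * ceiling(lfp$fs / config$ds_band[1])
  if (length(x) < min_len)
    stop("trace too short for the detection filter settling span")
  filt <- bandpass(x, config$ds_band, lfp$fs)
  thr <- config$ds_threshold_sd * sd(filt)
  pk <- local_maxima(filt)
  pk <- pk[filt[pk] > thr]
  if (length(pk) == 0) return(event_table())
  # merge peaks closer than one template width, keep the larger
  merge_n <- config$ds_merge_ms / 1000 * lfp$fs
  keep <- logical(length(pk))
  ord <- order(filt[pk], decreasing = TRUE)
  taken <- numeric(0)
  for (i in ord) {
    if (length(taken) == 0 || min(abs(taken - pk[i])) >= merge_n) {
      keep[i] <- TRUE
      taken <- c(taken, pk[i])
    }
  }
  pk <- sort(pk[keep])
  amp <- filt[pk]
  hw <- half_width_ms(filt, pk, amp, lfp$fs)
  tms <- lfp_times(lfp)
  event_table(kind = rep("DS_unclassified", length(pk)),
              peak_time = tms[pk], amplitude = amp, half_width = hw,
              channel_index = rep(hilus_channel, length(pk)))
}

# width (ms) at half amplitude around each peak on the filtered trace,
# with linear interpolation at the crossings
half_width_ms <- function(filt, pk, amp, fs) {
  n <- length(filt)
  vapply(seq_along(pk), function(i) {
    h <- amp[i] / 2
    l <- pk[i]
    while (l > 1 && filt[l] > h) l <- l - 1
    r <- pk[i]
    while (r < n && filt[r] > h) r <- r + 1
    lfrac <- if (filt[l] <= h && l < pk[i])
      (h - filt[l]) / (filt[l + 1] - filt[l]) else 0
    rfrac <- if (filt[r] <= h && r > pk[i])
      (filt[r - 1] - h) / (filt[r - 1] - filt[r]) else 0
    ((r - 1 + rfrac) - (l + lfrac)) / fs * 1000
  }, numeric(1))
}

#' Detect sharp-wave ripples
#'
#' Bandpass 120-180 Hz (zero phase) on the CA1 pyramidal channel; the
#' envelope is the modulus of the analytic (Hilbert) signal. Excursions
#' above `swr_sustain_sd` SD lasting at least `swr_sustain_ms` ms that
#' contain an envelope peak above `swr_peak_sd` SD are kept (one event
#' per excursion); the ripple time is the maximum positive value of the
#' filtered trace within the excursion.
#'
#' @param lfp an [lfp_recording()].
#' @param pyramidal_channel channel index of the CA1 pyramidal trace.
#' @param config a [pipeline_config()].
#' @return an [event_table()] of kind `SPWR`.
#' @export
detect_swr <- function(lfp, pyramidal_channel, config = pipeline_config()) {
  stopifnot(pyramidal_channel >= 1, pyramidal_channel <= nrow(lfp$voltage))
  x <- lfp$voltage[pyramidal_channel, ]
  min_len <- 6 * ceiling(lfp$fs / config$swr_band[1])
  if (length(x) < min_len)
    stop("trace too short for the detection filter settling span")
  filt <- bandpass(x, config$swr_band, lfp$fs)
  env <- envelope(filt)
  mu <- mean(env); s <- sd(env)
  hi <- mu + config$swr_peak_sd * s
  lo <- mu + config$swr_sustain_sd * s
  above <- env > lo
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= config$swr_sustain_ms / 1000 * lfp$fs)
  starts <- starts[keep]; ends <- ends[keep]
  tms <- lfp_times(lfp)
  out_t <- numeric(0); out_a <- numeric(0)
  for (i in seq_along(starts)) {
    seg <- starts[i]:ends[i]
    if (max(env[seg]) < hi) next
    j <- seg[which.max(filt[seg])]
    out_t <- c(out_t, tms[j])
    out_a <- c(out_a, filt[j])
  }
  event_table(kind = rep("SPWR", length(out_t)), peak_time = out_t,
              amplitude = out_a,
              channel_index = rep(pyramidal_channel, length(out_t)))
}

#' Cross-probe event coincidence
#'
#' Greedy nearest-neighbour matching of two event tables within a
#' window (each event matched at most once); events are synchronous if
#' they fall within `window_ms`. The synchrony fraction uses the probe
#' with fewer events as the reference, applied automatically.
#'
#' @param events_a,events_b [event_table()]s.
#' @param window_ms synchrony window, default 100 ms.
#' @return list with `fraction` and a `pairs` data.frame (times and
#'   index into each table).
#' @export
coincidence <- function(events_a, events_b, window_ms = 100) {
  ta <- events_a$peak_time; tb <- events_b$peak_time
  if (length(ta) == 0 || length(tb) == 0)
    return(list(fraction = 0,
                pairs = data.frame(index_a = integer(0), index_b = integer(0),
                                   time_a = numeric(0), time_b = numeric(0))))
  w <- window_ms / 1000
  cand <- do.call(rbind, lapply(seq_along(ta), function(i) {
    j <- which(abs(tb - ta[i]) <= w)
    if (length(j) == 0) return(NULL)
    data.frame(i = i, j = j, d = abs(tb[j] - ta[i]))
  }))
  pairs <- data.frame(index_a = integer(0), index_b = integer(0))
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
    used_a <- logical(length(ta)); used_b <- logical(length(tb))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
        sel[k] <- TRUE
        used_a[cand$i[k]] <- TRUE; used_b[cand$j[k]] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    pairs <- data.frame(index_a = cand$i, index_b = cand$j,
                        time_a = ta[cand$i], time_b = tb[cand$j])
  }
  n_ref <- min(length(ta), length(tb))
  list(fraction = nrow(pairs) / n_ref, pairs = pairs)
}

#' Latency of evoked events after stimulus onsets
#'
#' For each stimulus onset, the first event peak strictly within the
#' post-onset search window.
#'
#' @param events an [event_table()] (typically classified DS2).
#' @param stimuli a [stimulus_log()].
#' @param window_ms post-onset search window.
#' @return list with `latency_ms` (per stimulus, `NA` if none),
#'   `fraction_evoked`, and `mean_latency_ms`.
#' @export
evoked_latency <- function(events, stimuli, window_ms = 200) {
  w <- window_ms / 1000
  lat <- vapply(stimuli$onset_time, function(on) {
    hit <- events$peak_time[events$peak_time > on &
                              events$peak_time <= on + w]
    if (length(hit) == 0) NA_real_ else (hit[1] - on) * 1000
  }, numeric(1))
  list(latency_ms = lat,
       fraction_evoked = if (length(lat) == 0) 0 else mean(!is.na(lat)),
       mean_latency_ms = if (all(is.na(lat))) NA_real_
       else mean(lat, na.rm = TRUE))
}

#' Event rate within a behavioural state mask
#'
#' @param events an [event_table()].
#' @param intervals data.frame with `start`, `end` (disjoint, half-open).
#' @return events per second of mask time.
#' @export
event_rate <- function(events, intervals) {
  dur <- intervals_duration(intervals)
  if (dur <= 0) stop("zero-duration state mask")
  sum(in_intervals(events$peak_time, intervals)) / dur
}
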