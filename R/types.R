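# Shared data types. Lightweight S3: validated lists / data.frames, the
# way field packages carry recordings and event tables.

EVENT_KINDS <- c("SPWR", "DS1", "DS2", "DS_unclassified", "HIGH_FIRING")
STIM_KINDS <- c("tone", "puff")

#' Laminar LFP recording
#'
#' @param voltage channels x samples matrix, millivolts. Row 1 is the
#'   most superficial channel.
#' @param fs sampling rate, Hz.
#' @param channel_depth per-channel depth in micrometres, strictly
#'   increasing along the probe (deeper = larger).
#' @param channel_label per-channel anatomical label (free text).
#' @param t0 recording start time, seconds.
#' @return an `lfp_recording` object.
#' @export
lfp_recording <- function(voltage, fs, channel_depth, channel_label,
                          t0 = 0) {
  voltage <- as.matrix(voltage)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (nrow(voltage) != length(channel_depth))
    stop("channel_depth length must match channel count")
  if (nrow(voltage) != length(channel_label))
    stop("channel_label length must match channel count")
  if (any(diff(channel_depth) <= 0))
    stop("channel_depth must be strictly monotonic along the probe")
  if (anyNA(voltage)) stop("voltage must have no missing samples")
  structure(list(voltage = voltage, fs = fs,
                 channel_depth = as.numeric(channel_depth),
                 channel_label = as.character(channel_label),
                 t0 = as.numeric(t0)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$voltage), ncol(x$voltage), x$fs,
              ncol(x$voltage) / x$fs))
  invisible(x)
}

lfp_times <- function(lfp) lfp$t0 + (seq_len(ncol(lfp$voltage)) - 1) / lfp$fs

#' Spike table
#'
#' @param unit_id integer unit ids, one row per spike.
#' @param spike_time spike times in seconds, sorted within unit.
#' @param region brain-area label per spike's unit.
#' @param session_id session label.
#' @return a `spike_table` data.frame with attributes.
#' @export
spike_table <- function(unit_id = integer(0), spike_time = numeric(0),
                        region = character(0), session_id = "session") {
  stopifnot(length(unit_id) == length(spike_time),
            length(region) %in% c(1L, length(unit_id)))
  if (length(unit_id) > 0 && length(region) == 1L)
    region <- rep(region, length(unit_id))
  if (any(spike_time < 0)) stop("spike times must be non-negative")
  df <- data.frame(unit_id = as.integer(unit_id),
                   spike_time = as.numeric(spike_time),
                   region = as.character(region),
                   stringsAsFactors = FALSE)
  df <- df[order(df$unit_id, df$spike_time), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "session_id") <- session_id
  class(df) <- c("spike_table", "data.frame")
  df
}

# list of spike-time vectors by unit (named by unit id)
split_units <- function(spikes, units = NULL) {
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  out <- split(spikes$spike_time, factor(spikes$unit_id, levels = units))
  lapply(out, function(v) if (is.null(v)) numeric(0) else v)
}

unit_regions <- function(spikes) {
  u <- !duplicated(spikes$unit_id)
  stats::setNames(spikes$region[u], spikes$unit_id[u])
}

#' Behaviour trace
#'
#' Uniformly sampled behavioural signals: position on a circular track,
#' locomotion speed, pupil and facial-motion signals.
#'
#' @param t time, seconds, uniform step.
#' @param position cm along the track, in `[0, track_length)`.
#' @param speed cm/s.
#' @param pupil_diameter,pupil_speed,facial_motion arbitrary units.
#' @param track_length cm (default 120).
#' @return a `behavior_trace` data.frame.
#' @export
behavior_trace <- function(t, position, speed,
                           pupil_diameter = rep(0, length(t)),
                           pupil_speed = rep(0, length(t)),
                           facial_motion = rep(0, length(t)),
                           track_length = 120) {
  dt <- diff(t)
  if (length(dt) > 0 &&
      (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1]))
    stop("t must be strictly increasing with a uniform step")
  if (any(position < 0 | position >= track_length))
    stop("position must lie in [0, track_length)")
  df <- data.frame(t = t, position = position, speed = speed,
                   pupil_diameter = pupil_diameter,
                   pupil_speed = pupil_speed,
                   facial_motion = facial_motion)
  attr(df, "track_length") <- track_length
  class(df) <- c("behavior_trace", "data.frame")
  df
}

track_length <- function(behavior) attr(behavior, "track_length")

#' Event table
#'
#' Detected (or injected) LFP events with per-event features.
#'
#' @param kind event kinds from `SPWR, DS1, DS2, DS_unclassified,
#'   HIGH_FIRING`.
#' @param peak_time event peak times, seconds; stored sorted.
#' @param amplitude filtered-trace value at the peak, millivolts.
#' @param half_width width at half amplitude, milliseconds.
#' @param channel_index channel the event was measured on (1-based).
#' @param ... further per-event columns (kept in the table).
#' @return an `event_table` data.frame.
#' @export
event_table <- function(kind = character(0), peak_time = numeric(0),
                        amplitude = rep(NA_real_, length(peak_time)),
                        half_width = rep(NA_real_, length(peak_time)),
                        channel_index = rep(NA_integer_, length(peak_time)),
                        ...) {
  if (!all(kind %in% EVENT_KINDS))
    stop("unknown event kind: ",
         paste(setdiff(kind, EVENT_KINDS), collapse = ", "))
  if (any(kind %in% c("DS1", "DS2", "DS_unclassified") & is.na(amplitude)))
    stop("amplitude must be present for DS events")
  df <- data.frame(kind = as.character(kind),
                   peak_time = as.numeric(peak_time),
                   amplitude = as.numeric(amplitude),
                   half_width = as.numeric(half_width),
                   channel_index = as.integer(channel_index),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df <- df[order(df$peak_time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events\n", nrow(x)))
  if (nrow(x) > 0) print(table(x$kind))
  invisible(x)
}

#' Subset an event table by kind
#' @param events an [event_table()].
#' @param kind one or more event kinds.
#' @return the matching rows.
#' @export
events_of_kind <- function(events, kind) {
  out <- events[events$kind %in% kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stimulus log
#'
#' @param onset_time onset times, seconds (sorted).
#' @param kind `"tone"` or `"puff"`.
#' @param duration seconds.
#' @return a `stimulus_log` data.frame.
#' @export
stimulus_log <- function(onset_time = numeric(0),
                         kind = character(0),
                         duration = rep(0.1, length(onset_time))) {
  if (!all(kind %in% STIM_KINDS))
    stop("unknown stimulus kind: ",
         paste(setdiff(kind, STIM_KINDS), collapse = ", "))
  df <- data.frame(onset_time = as.numeric(onset_time),
                   kind = as.character(kind),
                   duration = as.numeric(duration))
  df <- df[order(df$onset_time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("stimulus_log", "data.frame")
  df
}

#' Pipeline configuration
#'
#' All detection and statistics parameters, with defaults equal to the
#' study values the pipeline implements; plus the session seed from
#' which every shuffle substream is derived.
#'
#' @param ... overrides of the defaults (see `default_config()`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$ds_threshold_sd > 0, cfg$swr_peak_sd > 0,
            cfg$swr_sustain_sd > 0,
            cfg$modulation_percentile > 0, cfg$modulation_percentile < 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @export
default_config <- function() {
  list(
    # detection
    ds_band = c(5, 100), ds_threshold_sd = 4.5,
    swr_band = c(120, 180), swr_peak_sd = 5, swr_sustain_sd = 3,
    swr_sustain_ms = 25, ds_merge_ms = 25,
    sync_window_ms = 100, evoked_window_ms = 200,
    # classification
    csd_window_ms = 50, dbscan_eps = NULL, dbscan_min_samples = 5,
    # peri-event
    peri_window_ms = 200, peri_bin_ms = 10,
    session_bin_ms = 100, session_smooth_sigma_bins = 5,
    n_shuffles = 100, modulation_percentile = 99.5,
    high_firing_percentile = 99.9, high_firing_window_ms = 60,
    pupil_pre_ms = c(-290, -85), pupil_post_ms = c(-20, 85),
    facial_pre_ms = c(-140, -40), facial_post_ms = c(40, 115),
    behavior_shift_s = 2, behavior_null_draws = 1000,
    immobility_cm_s = 1,
    # mutual information
    mi_bin_ms = 5, mi_n_states = 4, mi_n_shuffles = 5000,
    mi_alpha = 0.01, mi_min_sessions = 5,
    # decoding
    n_position_bins = 24, decode_window_ms = 20, decode_step_ms = 5,
    tuning_smooth_sigma_bins = 1, rate_floor_hz = 0.01,
    shift_range_cm = 60, n_shifts = 1000,
    mua_smooth_ms = 21, candidate_min_s = 0.05, candidate_max_s = 2,
    slope_grid_max = 3, slope_grid_step = 0.01, r2_min = 0.3,
    # population patterns
    pv_window_ms = 200, pv_max_rate_hz = 5,
    similarity_n_shuffles = 1000, perceptron_epochs = 100,
    n_folds = 10, n_permutations = 1000,
    rng_seed = 1L
  )
}
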