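# Synthetic sessions with full ground truth: laminar LFP with injected
# DS1/DS2/SPW-R events, place-tuned Poisson spike trains with
# event-locked modulation and replay content, and arousal-coupled
# behaviour traces.

#' Simulation parameters
#'
#' Defaults are the study conditions the pipeline is validated under:
#' 600 s sessions, 0.3 Hz DS2 / 0.05 Hz DS1 / 0.3 Hz SPW-R during
#' immobility, 2 mV DS transients of 25 ms full width over 0.1 mV 1/f
#' noise, 150 Hz ripples, a 120 cm circular track with 5 cm decoding
#' bins, and ~50 place cells with >= 10 Hz peak rates.
#'
#' @param ... overrides of any default listed in the function body.
#' @return a `sim_params` list.
#' @export
sim_params <- function(...) {
  p <- list(
    n_channels = 16L, fs = 1250, duration = 600,
    event_rates = c(SPWR = 0.3, DS1 = 0.05, DS2 = 0.3),  # Hz, immobility
    min_separation_s = 0.25, event_margin_s = 0.5,
    ds_amplitude_mv = 2, ds_width_ms = 25,
    ripple_freq_hz = 150, ripple_duration_ms = 60,
    ripple_amplitude_mv = 0.25, sharp_wave_mv = 0.25,
    noise_sd_mv = 0.1, noise_exponent = 1, common_noise_frac = 0.3,
    # behaviour
    behavior_fs = 50, track_length = 120,
    loco_speed_cm_s = 15, loco_duration_s = c(8, 12),
    immobile_duration_s = c(12, 18), ramp_s = 1,
    pupil_dilation = 0.5, pupil_tau_s = 2, pupil_noise_sd = 0.2,
    facial_amplitude = 0.5, transient_decay_s = 1,
    # units
    n_units = 60L, fraction_place = 50 / 60,
    tuning_width_cm = 10, peak_rate_hz = c(10, 25),
    baseline_rate_hz = c(0.5, 2),
    ds2_gain = 5, ds2_gain_fraction = 0.5,
    swr_gain = 3, swr_gain_fraction = 0.3,
    event_kernel_ms = 100,
    react_peak_hz = 40, react_width_cm = 10,
    replay_peak_hz = 50, replay_duration_ms = 150,
    replay_speed_cm_s = c(100, 400),
    # stimuli (0 = none)
    n_stimuli = 0L, stim_interval_s = 10, evoked_latency_ms = 40,
    evoked_prob = 1,
    rng_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0)
    stop("unknown sim parameter: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(p$event_rates >= 0), p$duration > 0, p$n_channels >= 12)
  class(p) <- "sim_params"
  p
}

#' Default laminar probe layout
#'
#' 50 um spacing, superficial to deep: CA1 pyramidal layer at the top,
#' hippocampal fissure, dentate molecular layers (outer = DS1 sink,
#' middle = DS2 sink), granule layer and hilus below.
#'
#' @param n_channels number of channels (>= 12).
#' @return list with `depth_um`, `label`, and the role indices
#'   `pyramidal`, `fissure`, `ds1_sink`, `ds2_sink`, `hilus`,
#'   `deep_dentate` (1-based, 1 = most superficial).
#' @export
default_probe <- function(n_channels = 16L) {
  stopifnot(n_channels >= 12)
  label <- rep("CA3", n_channels)
  label[1] <- "CA1 pyramidal"
  label[2:3] <- "CA1 radiatum"
  label[4] <- "fissure"
  label[5:6] <- "outer molecular layer"
  label[7:8] <- "middle molecular layer"
  label[9] <- "granule layer"
  label[10:min(12, n_channels)] <- "hilus"
  list(depth_um = 50 * (seq_len(n_channels) - 1), label = label,
       pyramidal = 1L, fissure = 4L, ds1_sink = 5L, ds2_sink = 7L,
       hilus = 10L, deep_dentate = 12L)
}

# Laminar voltage profile of a DS transient, specified in CSD space
# (Gaussian sink at the target channel, balancing source two channels
# below, toward the granule layer) and integrated twice to voltage with
# zero superficial boundary. The double integration leaves a positive
# plateau on all channels below the dipole -- the hilus-positive
# signature -- and the profile is normalized so the hilus channel is 1.
ds_voltage_profile <- function(n_channels, sink_channel, hilus_channel,
                               source_offset = 2, sigma = 0.8) {
  k <- seq_len(n_channels)
  csd <- -exp(-(k - sink_channel)^2 / (2 * sigma^2)) +
    exp(-(k - (sink_channel + source_offset))^2 / (2 * sigma^2))
  v <- numeric(n_channels)
  # estimator convention csd_k = 2 v_k - v_{k-1} - v_{k+1} (sinks < 0)
  for (i in 2:(n_channels - 1))
    v[i + 1] <- -csd[i] + 2 * v[i] - v[i - 1]
  v / v[hilus_channel]
}

# Hann (raised-cosine) temporal bump of given full width; unit peak.
# Width at half amplitude = width/2.
ds_temporal_bump <- function(width_s, fs) {
  n <- max(3L, round(width_s * fs))
  if (n %% 2 == 0) n <- n + 1L
  hanning(n)
}

# position at arbitrary times, wrap-aware (interpolates the circular
# phase through sin/cos)
position_at <- function(behavior, t) {
  L <- track_length(behavior)
  th <- 2 * pi * behavior$position / L
  s <- approx(behavior$t, sin(th), t, rule = 2)$y
  c_ <- approx(behavior$t, cos(th), t, rule = 2)$y
  wrap_pos(atan2(s, c_) / (2 * pi) * L, L)
}

speed_at <- function(behavior, t) {
  approx(behavior$t, behavior$speed, t, rule = 2)$y
}

#' Generate the behaviour trace
#'
#' Laps on a circular track interleaved with immobility bouts; pupil
#' diameter is slow mean-reverting (Ornstein-Uhlenbeck) noise plus a
#' dilation transient at each DS2, and facial motion receives a
#' transient just after DS2 onset. Event-locked transients are added by
#' [generate_session()] once event times exist; this function lays down
#' the locomotion structure and baseline arousal signals.
#'
#' @param params a [sim_params()] object.
#' @return a [behavior_trace()].
#' @export
generate_behavior <- function(params) {
  with_substream(params$rng_seed, "behavior", {
    dt <- 1 / params$behavior_fs
    t <- seq(0, params$duration - dt, by = dt)
    n <- length(t)
    # alternating immobility / locomotion bouts with speed ramps
    speed <- numeric(n)
    pos_t <- 0
    state_immobile <- TRUE
    while (pos_t < params$duration) {
      dur <- if (state_immobile)
        runif(1, params$immobile_duration_s[1], params$immobile_duration_s[2])
      else
        runif(1, params$loco_duration_s[1], params$loco_duration_s[2])
      i0 <- which(t >= pos_t)[1]
      i1 <- max(which(t < min(pos_t + dur, params$duration)))
      if (!state_immobile && !is.na(i0) && i1 >= i0) {
        seg <- t[i0:i1] - pos_t
        ramp <- pmin(1, pmin(seg, dur - seg) / params$ramp_s)
        speed[i0:i1] <- params$loco_speed_cm_s * pmax(0, ramp)
      }
      pos_t <- pos_t + dur
      state_immobile <- !state_immobile
    }
    # immobility jitter well below the 1 cm/s threshold
    speed <- speed + abs(rnorm(n, 0, 0.03))
    position <- wrap_pos(cumsum(speed * dt), params$track_length)
    # Ornstein-Uhlenbeck pupil baseline
    pupil <- numeric(n)
    sig <- params$pupil_noise_sd * sqrt(2 / params$pupil_tau_s)
    innov <- rnorm(n, 0, sig * sqrt(dt))
    for (i in 2:n)
      pupil[i] <- pupil[i - 1] * (1 - dt / params$pupil_tau_s) + innov[i]
    facial <- abs(rnorm(n, 0, 0.1)) + 0.5 * speed / params$loco_speed_cm_s
    pupil_speed <- c(0, abs(diff(pupil))) / dt
    behavior_trace(t, position, speed, pupil, pupil_speed, facial,
                   track_length = params$track_length)
  })
}

# maximal intervals with speed < threshold, shrunk by the event margin
immobile_event_windows <- function(behavior, params, threshold = 1) {
  states <- segment_motion_state(behavior, threshold)
  im <- states$immobility
  im$start <- im$start + params$event_margin_s
  im$end <- im$end - params$event_margin_s
  im[im$end > im$start, , drop = FALSE]
}

# uniform draw over a union of intervals
runif_intervals <- function(n, intervals) {
  w <- intervals$end - intervals$start
  pick <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  intervals$start[pick] + runif(n) * w[pick]
}

#' Simulate ground truth for a session
#'
#' Draws per-kind Poisson event counts over the immobile time, places
#' events uniformly in immobility with a minimum separation between any
#' two events, and attaches the latent structure: per-unit tuning,
#' event-kind rate gains, replay trajectories for SPW-Rs, the animal's
#' position at each DS2, injected arousal amplitudes, and (optionally)
#' stimulus onsets with evoked DS2s.
#'
#' @param params a [sim_params()] object.
#' @param behavior trace from [generate_behavior()].
#' @return a `ground_truth` list (see fields in the implementation).
#' @export
simulate_ground_truth <- function(params, behavior) {
  windows <- immobile_event_windows(behavior, params)
  immobile_time <- intervals_duration(windows)
  with_substream(params$rng_seed, "events", {
    rates <- params$event_rates
    need <- sum(rates) * params$min_separation_s * 2
    if (immobile_time <= 0 || need > 0.8 * immobile_time)
      stop("immobility too scarce for the requested event rates")
    times <- numeric(0); kinds <- character(0)
    for (kind in names(rates)) {
      nk <- rpois(1, rates[[kind]] * immobile_time)
      for (j in seq_len(nk)) {
        for (try in 1:1000) {
          cand <- runif_intervals(1, windows)
          if (length(times) == 0 ||
              min(abs(times - cand)) >= params$min_separation_s) break
          if (try == 1000) stop("could not place events at min separation")
        }
        times <- c(times, cand); kinds <- c(kinds, kind)
      }
    }
    # optional stimuli with evoked DS2s
    stimuli <- stimulus_log()
    if (params$n_stimuli > 0) {
      onsets <- numeric(0)
      for (j in seq_len(params$n_stimuli)) {
        for (try in 1:1000) {
          cand <- runif_intervals(1, windows)
          ok <- (length(times) == 0 ||
                   min(abs(times - cand)) >= params$min_separation_s +
                     params$evoked_latency_ms / 1000) &&
            (length(onsets) == 0 || min(abs(onsets - cand)) >= 1)
          if (ok) break
          if (try == 1000) stop("could not place stimuli")
        }
        onsets <- c(onsets, cand)
      }
      onsets <- sort(onsets)
      skind <- rep(c("tone", "puff"), length.out = length(onsets))
      stimuli <- stimulus_log(onsets, skind,
                              ifelse(skind == "tone", 0.35, 0.1))
      evoked <- runif(length(onsets)) < params$evoked_prob
      ev_t <- onsets[evoked] + params$evoked_latency_ms / 1000
      times <- c(times, ev_t)
      kinds <- c(kinds, rep("DS2", length(ev_t)))
    }
    ord <- order(times)
    times <- times[ord]; kinds <- kinds[ord]
    events <- event_table(kind = kinds, peak_time = times,
                          amplitude = ifelse(kinds == "SPWR",
                                             params$ripple_amplitude_mv,
                                             params$ds_amplitude_mv))
    # unit tuning
    n_place <- round(params$n_units * params$fraction_place)
    is_place <- c(rep(TRUE, n_place),
                  rep(FALSE, params$n_units - n_place))
    tuning <- data.frame(
      unit_id = seq_len(params$n_units),
      is_place = is_place,
      preferred_cm = ifelse(is_place,
                            runif(params$n_units, 0, params$track_length),
                            NA_real_),
      width_cm = rep(params$tuning_width_cm, params$n_units),
      peak_hz = ifelse(is_place,
                       runif(params$n_units, params$peak_rate_hz[1],
                             params$peak_rate_hz[2]), 0),
      baseline_hz = runif(params$n_units, params$baseline_rate_hz[1],
                          params$baseline_rate_hz[2]),
      region = ifelse(is_place, "CA1",
                      rep_len(c("DG", "CTX"), params$n_units))
    )
    # event-kind gains (multiplicative on baseline at the kernel peak)
    modulation <- data.frame(
      unit_id = tuning$unit_id,
      DS1 = rep(1, params$n_units),
      DS2 = ifelse(runif(params$n_units) < params$ds2_gain_fraction,
                   params$ds2_gain, 1),
      SPWR = ifelse(runif(params$n_units) < params$swr_gain_fraction,
                    params$swr_gain, 1)
    )
    # replay trajectories for every SPW-R
    swr_idx <- which(events$kind == "SPWR")
    sl <- runif(length(swr_idx), params$replay_speed_cm_s[1],
                params$replay_speed_cm_s[2]) *
      sample(c(-1, 1), length(swr_idx), replace = TRUE)
    replay <- data.frame(
      peak_time = events$peak_time[swr_idx],
      slope_cm_s = sl,
      start_cm = runif(length(swr_idx), 0, params$track_length),
      duration_s = rep(params$replay_duration_ms / 1000, length(swr_idx))
    )
    ds2_idx <- which(events$kind == "DS2")
    ds2 <- data.frame(
      peak_time = events$peak_time[ds2_idx],
      position_cm = position_at(behavior, events$peak_time[ds2_idx])
    )
    arousal <- data.frame(
      peak_time = events$peak_time[ds2_idx],
      pupil_amplitude = rep(params$pupil_dilation, length(ds2_idx)),
      facial_amplitude = rep(params$facial_amplitude, length(ds2_idx)))
    structure(list(injected_events = events, stimuli = stimuli,
                   unit_tuning = tuning, unit_modulation = modulation,
                   replay = replay, ds2_position = ds2, arousal = arousal),
              class = "ground_truth")
  })
}

# add DS2-locked pupil/facial transients to a behaviour trace
add_arousal_transients <- function(behavior, truth, params) {
  dt <- behavior$t[2] - behavior$t[1]
  dec <- params$transient_decay_s
  for (i in seq_len(nrow(truth$arousal))) {
    tp <- truth$arousal$peak_time[i]
    # pupil dilation begins just before the LFP peak (during the rising
    # phase of the event), so the (-20, +85) ms window sees the plateau
    # while the (-290, -85) ms window stays clear of it
    idx <- which(behavior$t >= tp - 0.04)
    if (length(idx) > 0) {
      tt <- behavior$t[idx] - (tp - 0.04)
      behavior$pupil_diameter[idx] <- behavior$pupil_diameter[idx] +
        truth$arousal$pupil_amplitude[i] * exp(-tt / dec)
    }
    idx <- which(behavior$t >= tp + 0.03)
    if (length(idx) > 0) {
      tt <- behavior$t[idx] - (tp + 0.03)
      behavior$facial_motion[idx] <- behavior$facial_motion[idx] +
        truth$arousal$facial_amplitude[i] * exp(-tt / dec)
    }
  }
  behavior$pupil_speed <- c(0, abs(diff(behavior$pupil_diameter))) / dt
  behavior
}

#' Generate the laminar LFP
#'
#' Spectrally shaped (1/f) Gaussian background noise per channel plus a
#' common-mode term; each DS adds a Hann transient whose laminar profile
#' is defined in CSD space (sink at the configured molecular-layer
#' channel) and integrated to voltage, giving the hilus-positive peak;
#' each SPW-R adds a Hann-enveloped ripple-frequency oscillation on the
#' CA1 pyramidal channel and a slow sharp-wave deflection below it.
#'
#' @param params a [sim_params()] object.
#' @param truth from [simulate_ground_truth()].
#' @return an [lfp_recording()].
#' @export
generate_lfp <- function(params, truth) {
  probe <- default_probe(params$n_channels)
  events <- truth$injected_events
  if (nrow(events) > 0 &&
      (min(events$peak_time) < 0 || max(events$peak_time) >= params$duration))
    stop("event times must fit in [0, duration)")
  with_substream(params$rng_seed, "lfp", {
    nch <- params$n_channels
    ns <- round(params$duration * params$fs)
    v <- matrix(0, nch, ns)
    common <- shaped_noise(ns, params$noise_exponent)
    for (ch in seq_len(nch)) {
      x <- shaped_noise(ns, params$noise_exponent)
      z <- sqrt(1 - params$common_noise_frac^2) * x +
        params$common_noise_frac * common
      v[ch, ] <- params$noise_sd_mv * z
    }
    # DS transients
    prof <- list(
      DS1 = ds_voltage_profile(nch, probe$ds1_sink, probe$hilus),
      DS2 = ds_voltage_profile(nch, probe$ds2_sink, probe$hilus)
    )
    bump <- ds_temporal_bump(params$ds_width_ms / 1000, params$fs)
    half <- (length(bump) - 1) / 2
    for (i in seq_len(nrow(events))) {
      kind <- events$kind[i]
      if (!kind %in% c("DS1", "DS2")) next
      c0 <- round(events$peak_time[i] * params$fs) + 1
      sl <- (c0 - half):(c0 + half)
      keep <- sl >= 1 & sl <= ns
      v[, sl[keep]] <- v[, sl[keep]] +
        params$ds_amplitude_mv * outer(prof[[kind]], bump[keep])
    }
    # ripples + sharp waves
    nrip <- round(params$ripple_duration_ms / 1000 * params$fs)
    if (nrip %% 2 == 0) nrip <- nrip + 1
    hrip <- (nrip - 1) / 2
    env <- hanning(nrip)
    tt <- (-hrip:hrip) / params$fs
    carrier <- cos(2 * pi * params$ripple_freq_hz * tt)
    for (tp in events$peak_time[events$kind == "SPWR"]) {
      c0 <- round(tp * params$fs) + 1
      sl <- (c0 - hrip):(c0 + hrip)
      keep <- sl >= 1 & sl <= ns
      v[probe$pyramidal, sl[keep]] <- v[probe$pyramidal, sl[keep]] +
        params$ripple_amplitude_mv * (env * carrier)[keep]
      v[2:3, sl[keep]] <- v[2:3, sl[keep]] -
        params$sharp_wave_mv * rep(env[keep], each = 2)
    }
    lfp_recording(v, params$fs, probe$depth_um, probe$label)
  })
}

# 1/f^alpha shaped unit-variance Gaussian noise via FFT filtering
shaped_noise <- function(n, alpha) {
  w <- rnorm(n)
  if (alpha == 0) return(w)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index, DC guarded
  shape <- f^(-alpha / 2)
  x <- Re(fft(W * shape, inverse = TRUE) / n)
  (x - mean(x)) / sd(x)
}

#' Generate spike trains
#'
#' Inhomogeneous Poisson per unit on a 1 ms rate grid: baseline +
#' place-field term (circular Gaussian bump, active during locomotion)
#' + event-kind gain kernels around injected events. During SPW-Rs the
#' place cells additionally fire along the injected replay trajectory;
#' during DS2s, place cells whose preferred position is near the
#' animal's current position receive the reactivation gain.
#'
#' @param params a [sim_params()] object.
#' @param truth from [simulate_ground_truth()].
#' @param behavior trace covering `[0, duration)`.
#' @return a [spike_table()].
#' @export
generate_spikes <- function(params, truth, behavior) {
  if (params$n_units == 0) return(spike_table())
  with_substream(params$rng_seed, "spikes", {
    dt <- 0.001
    tg <- seq(0, params$duration - dt, by = dt) + dt / 2
    ng <- length(tg)
    L <- params$track_length
    pos <- position_at(behavior, tg)
    loco <- speed_at(behavior, tg) >= 1
    tun <- truth$unit_tuning
    mod <- truth$unit_modulation
    ev <- truth$injected_events
    kern_half_s <- params$event_kernel_ms / 2000
    all_id <- integer(0); all_t <- numeric(0)
    for (u in seq_len(nrow(tun))) {
      rate <- rep(tun$baseline_hz[u], ng)
      if (tun$is_place[u]) {
        d <- circ_diff(pos, tun$preferred_cm[u], L)
        rate <- rate + loco * tun$peak_hz[u] *
          exp(-d^2 / (2 * tun$width_cm[u]^2))
      }
      # generic event gains (Hann kernel, peak gain x baseline)
      for (kind in c("DS1", "DS2", "SPWR")) {
        g <- mod[[kind]][u]
        if (g <= 1) next
        for (tp in ev$peak_time[ev$kind == kind]) {
          sl <- which(tg >= tp - kern_half_s & tg <= tp + kern_half_s)
          if (length(sl) == 0) next
          k <- 0.5 + 0.5 * cos(pi * (tg[sl] - tp) / kern_half_s)
          rate[sl] <- rate[sl] + (g - 1) * tun$baseline_hz[u] * k
        }
      }
      if (tun$is_place[u]) {
        # DS2 current-location reactivation
        for (i in seq_len(nrow(truth$ds2_position))) {
          tp <- truth$ds2_position$peak_time[i]
          dpr <- circ_diff(tun$preferred_cm[u],
                           truth$ds2_position$position_cm[i], L)
          amp <- params$react_peak_hz *
            exp(-dpr^2 / (2 * params$react_width_cm^2))
          if (amp < 0.05) next
          sl <- which(tg >= tp - kern_half_s & tg <= tp + kern_half_s)
          if (length(sl) == 0) next
          k <- 0.5 + 0.5 * cos(pi * (tg[sl] - tp) / kern_half_s)
          rate[sl] <- rate[sl] + amp * k
        }
        # SPW-R replay sequence
        for (i in seq_len(nrow(truth$replay))) {
          tp <- truth$replay$peak_time[i]
          dur <- truth$replay$duration_s[i]
          sl <- which(tg >= tp - dur / 2 & tg <= tp + dur / 2)
          if (length(sl) == 0) next
          traj <- wrap_pos(truth$replay$start_cm[i] +
                             truth$replay$slope_cm_s[i] *
                             (tg[sl] - (tp - dur / 2)), L)
          d <- circ_diff(tun$preferred_cm[u], traj, L)
          rate[sl] <- rate[sl] + params$replay_peak_hz *
            exp(-d^2 / (2 * tun$width_cm[u]^2))
        }
      }
      n_sp <- rpois(ng, rate * dt)
      hit <- which(n_sp > 0)
      if (length(hit) > 0) {
        reps <- rep(hit, n_sp[hit])
        st <- tg[reps] - dt / 2 + runif(length(reps)) * dt
        all_id <- c(all_id, rep(u, length(st)))
        all_t <- c(all_t, st)
      }
    }
    region <- tun$region[all_id]
    spike_table(all_id, all_t, region)
  })
}

#' Generate and write a complete synthetic session
#'
#' Draws the ground truth, synthesizes behaviour (with DS2-locked
#' arousal transients), LFP and spikes, writes everything (plus the
#' ground-truth tables) to `dir` via the package's session format, and
#' returns the in-memory objects.
#'
#' @param params a [sim_params()] object.
#' @param dir output directory; `NULL` keeps the session in memory only.
#' @param lfp generate the LFP matrix (set `FALSE` for spike-only
#'   studies to save time).
#' @return list with `lfp`, `spikes`, `behavior`, `stimuli`, `truth`,
#'   and `dir`.
#' @export
generate_session <- function(params, dir = NULL, lfp = TRUE) {
  behavior <- generate_behavior(params)
  truth <- simulate_ground_truth(params, behavior)
  behavior <- add_arousal_transients(behavior, truth, params)
  rec <- if (lfp) generate_lfp(params, truth) else NULL
  spikes <- generate_spikes(params, truth, behavior)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(rec)) write_lfp(rec, dir)
    write_session_tables(spikes, behavior, truth$stimuli, dir)
    gt <- file.path(dir, "ground_truth")
    dir.create(gt, showWarnings = FALSE)
    write_events(truth$injected_events, file.path(gt, "injected_events.tsv"))
    write_tsv(truth$unit_tuning, file.path(gt, "unit_tuning.tsv"))
    write_tsv(truth$unit_modulation, file.path(gt, "unit_modulation.tsv"))
    write_tsv(truth$replay, file.path(gt, "replay.tsv"))
    write_tsv(truth$ds2_position, file.path(gt, "ds2_position.tsv"))
    write_tsv(truth$arousal, file.path(gt, "arousal.tsv"))
  }
  list(lfp = rec, spikes = spikes, behavior = behavior,
       stimuli = truth$stimuli, truth = truth, dir = dir)
}
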