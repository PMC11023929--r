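# Place tuning, Bayesian position decoding with a Poisson likelihood,
# circular-shift decoding-error nulls, MUA candidate events, and
# circular-linear trajectory-slope fitting.

#' Position tuning curves
#'
#' Occupancy-normalized firing rate by position bin (5 cm bins on the
#' 120 cm track by default), restricted to locomotion intervals, with
#' optional circular Gaussian smoothing across bins.
#'
#' @param spikes a [spike_table()].
#' @param behavior a [behavior_trace()].
#' @param intervals locomotion intervals (data.frame `start`, `end`).
#' @param config a [pipeline_config()] (`n_position_bins`,
#'   `tuning_smooth_sigma_bins`).
#' @return list: `rate` (units x bins matrix, Hz), `occupancy_s`,
#'   `unit_id`, `bin_centers_cm`.
#' @export
tuning_curves <- function(spikes, behavior, intervals,
                          config = pipeline_config()) {
  L <- track_length(behavior)
  nb <- config$n_position_bins
  bw <- L / nb
  dt <- behavior$t[2] - behavior$t[1]
  in_loco <- in_intervals(behavior$t, intervals)
  pos_bin <- pmin(nb, floor(behavior$position / bw) + 1)
  occ <- tabulate(pos_bin[in_loco], nbins = nb) * dt
  if (any(occ <= 0))
    stop("empty occupancy in position bin(s) ",
         paste(which(occ <= 0), collapse = ", "))
  units <- sort(unique(spikes$unit_id))
  keep_sp <- in_intervals(spikes$spike_time, intervals)
  sp <- spikes[keep_sp, , drop = FALSE]
  sp_bin <- pmin(nb, floor(position_at(behavior, sp$spike_time) / bw) + 1)
  rate <- t(vapply(units, function(u) {
    cnt <- tabulate(sp_bin[sp$unit_id == u], nbins = nb)
    r <- cnt / occ
    circ_gauss_smooth(r, config$tuning_smooth_sigma_bins)
  }, numeric(nb)))
  list(rate = rate, occupancy_s = occ, unit_id = units,
       bin_centers_cm = (seq_len(nb) - 0.5) * bw)
}

# circular (wrapped) Gaussian smoothing across position bins
circ_gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  n <- length(x)
  k <- exp(-((0:(n - 1)) - floor(n / 2))^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  # circular convolution via FFT
  ks <- c(k[(floor(n / 2) + 1):n], k[1:floor(n / 2)])
  Re(fft(fft(x) * Conj(fft(ks)), inverse = TRUE)) / n
}

#' Select place cells by spatial information
#'
#' Skaggs spatial information (bits/spike) against a position-shuffle
#' null: each unit's spikes are circularly shifted in time by uniform
#' draws, tuning recomputed, and the unit kept if its observed
#' information exceeds the null 95th percentile (and its peak rate a
#' minimum).
#'
#' @param spikes,behavior,intervals as for [tuning_curves()].
#' @param n_shuffles null draws per unit (default 100).
#' @param min_peak_hz minimum tuning-curve peak (default 1).
#' @param config a [pipeline_config()].
#' @param seed RNG seed.
#' @return integer vector of selected unit ids.
#' @export
select_place_cells <- function(spikes, behavior, intervals,
                               n_shuffles = 100, min_peak_hz = 1,
                               config = pipeline_config(), seed = 1L) {
  tc <- tuning_curves(spikes, behavior, intervals, config)
  occ_p <- tc$occupancy_s / sum(tc$occupancy_s)
  si <- function(r) {
    mr <- sum(occ_p * r)
    if (mr <= 0) return(0)
    nz <- r > 0
    sum(occ_p[nz] * r[nz] / mr * log2(r[nz] / mr))
  }
  obs <- apply(tc$rate, 1, si)
  dur <- max(behavior$t) + behavior$t[2] - behavior$t[1]
  with_substream(seed, "place_null", {
    keep <- vapply(seq_along(tc$unit_id), function(k) {
      u <- tc$unit_id[k]
      st <- spikes$spike_time[spikes$unit_id == u]
      if (length(st) < 10 || max(tc$rate[k, ]) < min_peak_hz)
        return(FALSE)
      null <- vapply(seq_len(n_shuffles), function(s) {
        sh <- (st + runif(1, 0.1 * dur, 0.9 * dur)) %% dur
        shf <- spike_table(rep(u, length(sh)), sort(sh), "x")
        si(tuning_curves(shf, behavior, intervals, config)$rate[1, ])
      }, numeric(1))
      obs[k] > quantile(null, 0.95, names = FALSE)
    }, logical(1))
    tc$unit_id[keep]
  })
}

#' Bayesian position decoding of one spike-count vector
#'
#' Poisson-likelihood decoder with a uniform prior: for counts `n` in a
#' window of length tau, `log P(x|n) = sum_u [ n_u log(r_u(x) tau) -
#' r_u(x) tau ] + const`, normalized so the posterior sums to 1. The
#' decoded position is the maximum-probability bin. Computed in log
#' space with a floor rate for stability.
#'
#' @param counts spike counts per unit (aligned with `curves$unit_id`).
#' @param curves from [tuning_curves()].
#' @param tau_s window length, seconds (default 0.02).
#' @param rate_floor_hz floor applied to tuning rates (default 0.01).
#' @return list: `posterior` (per bin, sums to 1), `map_bin`,
#'   `map_cm`.
#' @export
decode <- function(counts, curves, tau_s = 0.02, rate_floor_hz = 0.01) {
  r <- pmax(curves$rate, rate_floor_hz)
  if (all(curves$rate == 0)) stop("all-zero tuning curves")
  stopifnot(length(counts) == nrow(r), all(counts >= 0))
  lp <- colSums(counts * log(r * tau_s)) - tau_s * colSums(r)
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  mb <- which.max(p)
  list(posterior = p, map_bin = mb, map_cm = curves$bin_centers_cm[mb])
}

# counts per unit in [t0, t0+tau) from a list of per-unit spike vectors
window_counts <- function(by_unit, t0, tau) {
  vapply(by_unit, function(st)
    findInterval(t0 + tau, st) - findInterval(t0, st), numeric(1))
}

#' Sliding-window posterior matrix
#'
#' Decodes successive windows of length `window_ms` advanced by
#' `step_ms`, e.g. 20 ms windows shifted 5 ms for candidate replay
#' events.
#'
#' @param spikes a [spike_table()] (restricted to the decoding units).
#' @param curves from [tuning_curves()].
#' @param t_start,t_end span to decode, seconds.
#' @param window_ms,step_ms window and step (default 20 / 5).
#' @param rate_floor_hz floor rate.
#' @return list: `p` (steps x bins, rows sum to 1), `window_start_s`,
#'   `window_ms`, `step_ms`.
#' @export
decode_sliding <- function(spikes, curves, t_start, t_end,
                           window_ms = 20, step_ms = 5,
                           rate_floor_hz = 0.01) {
  tau <- window_ms / 1000
  starts <- seq(t_start, t_end - tau, by = step_ms / 1000)
  if (length(starts) == 0) stop("span shorter than one window")
  by_unit <- split_units(spikes, curves$unit_id)
  p <- t(vapply(starts, function(t0) {
    decode(window_counts(by_unit, t0, tau), curves, tau,
           rate_floor_hz)$posterior
  }, numeric(ncol(curves$rate))))
  list(p = p, window_start_s = starts, window_ms = window_ms,
       step_ms = step_ms)
}

#' Decoding-error histogram with a circular-shift null
#'
#' Per event, decodes the 20 ms window centred on the event and takes
#' the signed circular distance between decoded and actual position,
#' histogrammed in 5 cm bins. Null: the decoded positions are
#' circularly shifted by uniform draws in +/- `shift_range_cm`
#' (multiples of the bin), `n_shifts` times; each iteration's maximum
#' bin proportion forms the null, and observed bins above its 97.5th
#' percentile are over-represented.
#'
#' @param events an [event_table()].
#' @param spikes a [spike_table()] restricted to the decoding units.
#' @param curves from [tuning_curves()].
#' @param behavior a [behavior_trace()] (actual positions).
#' @param config a [pipeline_config()].
#' @param seed RNG seed.
#' @return list: `error_cm` (per event), `bin_centers_cm`,
#'   `proportion`, `over_represented` (logical per bin), `cutoff`,
#'   `decoded_cm`, `actual_cm`.
#' @export
decoding_error_test <- function(events, spikes, curves, behavior,
                                config = pipeline_config(), seed = 1L) {
  if (nrow(events) == 0) stop("no events to decode")
  L <- track_length(behavior)
  nb <- config$n_position_bins
  bw <- L / nb
  tau <- config$decode_window_ms / 1000
  by_unit <- split_units(spikes, curves$unit_id)
  decoded <- vapply(events$peak_time, function(tp)
    decode(window_counts(by_unit, tp - tau / 2, tau), curves, tau,
           config$rate_floor_hz)$map_cm, numeric(1))
  actual <- position_at(behavior, events$peak_time)
  err <- circ_diff(decoded, actual, L)
  hist_prop <- function(e) {
    # signed-error bins centred on multiples of bw, 0-error bin first
    idx <- (round(e / bw) %% nb) + 1
    tabulate(idx, nbins = nb) / length(e)
  }
  obs <- hist_prop(err)
  n_ev <- length(decoded)
  n_steps <- 2 * config$shift_range_cm / bw
  null_max <- with_substream(seed, "decode_null", {
    vapply(seq_len(config$n_shifts), function(s) {
      # independent circular shift per event
      shift <- (sample.int(n_steps, n_ev, replace = TRUE) -
                  n_steps / 2) * bw
      max(hist_prop(circ_diff(wrap_pos(decoded + shift, L), actual, L)))
    }, numeric(1))
  })
  cutoff <- quantile(null_max, 0.975, names = FALSE)
  centers <- ((seq_len(nb) - 1) * bw)
  centers[centers > L / 2] <- centers[centers > L / 2] - L
  ord <- order(centers)
  list(error_cm = err, bin_centers_cm = centers[ord],
       proportion = obs[ord], over_represented = obs[ord] > cutoff,
       cutoff = cutoff, decoded_cm = decoded, actual_cm = actual)
}

#' Candidate population events from multi-unit activity
#'
#' Pooled spike counts in 1 ms bins, convolved with a 21 ms Hanning
#' window; maximal runs where the smoothed MUA exceeds its mean over
#' the analysis intervals become candidates. Boundaries are adjusted
#' inwards to the first/last bin containing a raw spike, and events
#' outside the 50 ms - 2 s duration range (or with < 2 spikes) are
#' discarded.
#'
#' @param spikes a [spike_table()].
#' @param intervals analysis intervals (e.g. immobility); the MUA mean
#'   is computed over these.
#' @param config a [pipeline_config()].
#' @return data.frame: `start`, `end`, `duration_s`, `n_spikes`.
#' @export
candidate_events <- function(spikes, intervals,
                             config = pipeline_config()) {
  if (nrow(spikes) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration_s = numeric(0), n_spikes = integer(0)))
  t_end <- max(intervals$end)
  nb <- ceiling(t_end * 1000)
  cnt <- tabulate(pmin(nb, floor(spikes$spike_time * 1000) + 1),
                  nbins = nb)
  k <- hanning(config$mua_smooth_ms)
  k <- k / sum(k)
  mua <- as.numeric(stats::filter(cnt, k, sides = 2))
  mua[is.na(mua)] <- 0
  bin_t <- (seq_len(nb) - 0.5) / 1000
  in_mask <- in_intervals(bin_t, intervals)
  thr <- mean(mua[in_mask])
  above <- mua > thr & in_mask
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  st <- sort(spikes$spike_time)
  rows <- lapply(keep, function(i) {
    t0 <- (starts[i] - 1) / 1000; t1 <- ends[i] / 1000
    lo <- findInterval(t0, st) + 1
    hi <- findInterval(t1, st)
    if (hi < lo) return(NULL)
    # shrink to first/last spike-containing 1 ms bin
    t0 <- floor(st[lo] * 1000) / 1000
    t1 <- floor(st[hi] * 1000) / 1000 + 0.001
    n_sp <- hi - lo + 1
    dur <- t1 - t0
    if (dur < config$candidate_min_s || dur > config$candidate_max_s ||
        n_sp < 2) return(NULL)
    data.frame(start = t0, end = t1, duration_s = dur, n_spikes = n_sp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = numeric(0), end = numeric(0),
                      duration_s = numeric(0), n_spikes = integer(0))
  rownames(out) <- NULL
  out
}

#' Circular-linear trajectory fit on a posterior matrix
#'
#' Grid search over slopes (position bins per time step): for each
#' candidate slope the best phase has a closed form through the
#' posterior-weighted complex resultant `R(s) = |sum_{t,x} p[t,x]
#' exp(i a (x - s t))| / sum p` (a = 2 pi / n_bins), maximized over
#' `s`. Goodness of fit is `R^2 = R(s*)^2`: 1 for a posterior
#' concentrated on any line (including a stationary one), ~0 for a
#' uniform posterior. Callers apply the `R^2 >= 0.3` filter.
#'
#' @param posterior list from [decode_sliding()] (or a steps x bins
#'   matrix).
#' @param slope_grid_max,slope_grid_step grid bounds (bins/step).
#' @return list: `slope_bins_per_step`, `slope_cm_s` (using the
#'   posterior's step and 5 cm bins when available), `phase_bin`,
#'   `r_squared`.
#' @export
fit_trajectory <- function(posterior, slope_grid_max = 3,
                           slope_grid_step = 0.01) {
  p <- if (is.list(posterior)) posterior$p else posterior
  if (nrow(p) < 3) stop("need at least 3 time steps")
  nb <- ncol(p)
  a <- 2 * pi / nb
  tt <- seq_len(nrow(p)) - 1
  xx <- seq_len(nb) - 1
  ct <- as.vector(p %*% exp(1i * a * xx))  # per-step resultant
  slopes <- seq(-slope_grid_max, slope_grid_max, by = slope_grid_step)
  R <- vapply(slopes, function(s)
    Mod(sum(ct * exp(-1i * a * s * tt))), numeric(1)) / sum(p)
  best <- which.max(R)
  s <- slopes[best]
  # parabolic refinement around the grid maximum (sub-grid resolution)
  if (best > 1 && best < length(slopes)) {
    y0 <- R[best - 1]; y1 <- R[best]; y2 <- R[best + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      s <- s + 0.5 * slope_grid_step * (y0 - y2) / den
      R[best] <- Mod(sum(ct * exp(-1i * a * s * tt))) / sum(p)
    }
  }
  phase <- Arg(sum(ct * exp(-1i * a * s * tt))) / a %% nb
  step_s <- if (is.list(posterior)) posterior$step_ms / 1000 else NA_real_
  list(slope_bins_per_step = s,
       slope_cm_s = if (is.na(step_s)) NA_real_ else s * 5 / step_s,
       phase_bin = phase, r_squared = R[best]^2)
}

#' Fit replay slopes for a set of candidate events
#'
#' Decodes each candidate span in sliding 20 ms / 5 ms windows and fits
#' the trajectory slope; fits with `R^2 < r2_min` are marked excluded.
#'
#' @param candidates data.frame from [candidate_events()].
#' @param spikes,curves decoding inputs.
#' @param config a [pipeline_config()].
#' @return data.frame: `start`, `end`, `slope_bins_per_step`,
#'   `slope_cm_s`, `r_squared`, `included`.
#' @export
fit_candidate_slopes <- function(candidates, spikes, curves,
                                 config = pipeline_config()) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    t0 <- candidates$start[i]; t1 <- candidates$end[i]
    if (t1 - t0 < config$decode_window_ms / 1000 * 3)
      return(NULL)
    ps <- decode_sliding(spikes, curves, t0, t1,
                         config$decode_window_ms, config$decode_step_ms,
                         config$rate_floor_hz)
    fit <- fit_trajectory(ps, config$slope_grid_max,
                          config$slope_grid_step)
    data.frame(start = t0, end = t1,
               slope_bins_per_step = fit$slope_bins_per_step,
               slope_cm_s = fit$slope_cm_s,
               r_squared = fit$r_squared,
               included = fit$r_squared >= config$r2_min)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = numeric(0), end = numeric(0),
                      slope_bins_per_step = numeric(0),
                      slope_cm_s = numeric(0), r_squared = numeric(0),
                      included = logical(0))
  rownames(out) <- NULL
  out
}
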