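test_that("injected DS amplitude matches the template oracle", {
  # noiseless session: raw hilus peak equals the configured amplitude,
  # and detected (filtered) amplitude equals the filtered template peak
  p <- sim_params(duration = 120, rng_seed = 2, noise_sd_mv = 0,
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0.3))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  lfp <- generate_lfp(p, tr)
  pr <- default_probe(p$n_channels)
  idx <- round(tr$injected_events$peak_time * p$fs) + 1
  raw_peaks <- lfp$voltage[pr$hilus, idx]
  expect_equal(raw_peaks, rep(p$ds_amplitude_mv, length(idx)),
               tolerance = 1e-6)

  # oracle: the isolated template through the detection filter
  bump <- dentate:::ds_temporal_bump(p$ds_width_ms / 1000, p$fs)
  tmpl <- numeric(round(8 * p$fs))
  tmpl[5000 + seq_along(bump)] <- p$ds_amplitude_mv * bump
  oracle_peak <- max(bandpass(tmpl, c(5, 100), p$fs))
  ds <- detect_ds(lfp, pr$hilus)
  expect_gt(nrow(ds), 0)
  expect_equal(mean(ds$amplitude), oracle_peak, tolerance = 0.02)
  # and the filtered peak stays within 10% of the configured amplitude
  expect_lt(abs(mean(ds$amplitude) - p$ds_amplitude_mv) /
              p$ds_amplitude_mv, 0.15)
})

test_that("noise-only traces yield almost no detections", {
  p <- sim_params(duration = 200, rng_seed = 8,
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  expect_equal(nrow(tr$injected_events), 0)
  lfp <- generate_lfp(p, tr)
  pr <- default_probe(p$n_channels)
  ds <- detect_ds(lfp, pr$hilus)
  swr <- detect_swr(lfp, pr$pyramidal)
  expect_lt(nrow(ds) / p$duration, 0.1)
  expect_lt(nrow(swr) / p$duration, 0.1)
})

test_that("DS1 and DS2 templates sink at the configured channel offset", {
  pr <- default_probe(16)
  v1 <- dentate:::ds_voltage_profile(16, pr$ds1_sink, pr$hilus)
  v2 <- dentate:::ds_voltage_profile(16, pr$ds2_sink, pr$hilus)
  csd <- function(v) {
    k <- 2:15
    2 * v[k] - v[k - 1] - v[k + 1]
  }
  s1 <- which.min(csd(v1)) + 1
  s2 <- which.min(csd(v2)) + 1
  expect_equal(s1, pr$ds1_sink)
  expect_equal(s2, pr$ds2_sink)
  expect_equal(s2 - s1, pr$ds2_sink - pr$ds1_sink)
  # hilus-positive signature
  expect_equal(v1[pr$hilus], 1)
  expect_equal(v2[pr$hilus], 1)
})

test_that("a baseline-only unit is Poisson over the session", {
  p <- sim_params(duration = 1000, rng_seed = 3, n_units = 1L,
                  fraction_place = 0,
                  baseline_rate_hz = c(1, 1),
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  sp <- generate_spikes(p, tr, bh)
  n <- nrow(sp)
  expect_true(abs(n - 1000) <= 4 * sqrt(1000))
})

test_that("a place cell clamped at its field fires at baseline + peak", {
  p <- sim_params(duration = 200, rng_seed = 4, n_units = 1L,
                  fraction_place = 1,
                  baseline_rate_hz = c(1, 1), peak_rate_hz = c(15, 15),
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  # clamp the animal at the unit's preferred position, locomoting
  n <- nrow(bh)
  pref <- tr$unit_tuning$preferred_cm[1]
  clamped <- behavior_trace(bh$t, rep(pref, n), rep(5, n))
  sp <- generate_spikes(p, tr, clamped)
  rate <- nrow(sp) / p$duration
  expect_equal(rate, 16, tolerance = 0.1)
})

test_that("events fall in immobility with the minimum separation", {
  ses <- small_session()
  ev <- ses$truth$injected_events
  sp_at <- dentate:::speed_at(ses$behavior, ev$peak_time)
  expect_true(all(sp_at < 1))
  gaps <- diff(sort(ev$peak_time))
  expect_true(all(gaps >= sim_params()$min_separation_s - 1e-9))
})

test_that("event counts are Poisson-consistent with rate x immobile time", {
  p <- sim_params(duration = 600, rng_seed = 31)
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  win <- dentate:::immobile_event_windows(bh, p)
  tm <- dentate:::intervals_duration(win)
  for (kind in c("SPWR", "DS2")) {
    n <- sum(tr$injected_events$kind == kind)
    lam <- p$event_rates[[kind]] * tm
    expect_true(abs(n - lam) <= 4 * sqrt(lam),
                label = sprintf("%s count %d vs Poisson(%0.1f)",
                                kind, n, lam))
  }
})

test_that("the same seed reproduces identical session bytes", {
  p <- sim_params(duration = 60, rng_seed = 77, n_units = 8L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_session(p, dir = d1)
  generate_session(p, dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  }
})

test_that("pupil dilation after DS2 recovers the configured amplitude", {
  # pool events over seeds to beat the arousal-noise floor
  changes <- numeric(0)
  for (seed in 1:2) {
    p <- sim_params(duration = 600, rng_seed = seed,
                    n_units = 0L, fraction_place = 0)
    ses <- generate_session(p, lfp = FALSE)
    ds2 <- events_of_kind(ses$truth$injected_events, "DS2")
    bc <- behavior_change_test(ses$behavior, ds2, "pupil_diameter",
                               n_draws = 10, seed = seed)
    changes <- c(changes, bc$change[!is.na(bc$change)])
  }
  expect_gt(length(changes), 150)
  expect_equal(mean(changes), sim_params()$pupil_dilation,
               tolerance = 0.12)
})

test_that("zero dilation amplitude gives the nominal false-alarm rate", {
  changes_sig <- logical(0)
  for (seed in 3:4) {
    p <- sim_params(duration = 600, rng_seed = seed, n_units = 0L,
                    fraction_place = 0, pupil_dilation = 0,
                    facial_amplitude = 0)
    ses <- generate_session(p, lfp = FALSE)
    ds2 <- events_of_kind(ses$truth$injected_events, "DS2")
    bc <- behavior_change_test(ses$behavior, ds2, "pupil_diameter",
                               n_draws = 100, seed = seed)
    changes_sig <- c(changes_sig, bc$significant[!is.na(bc$change)])
  }
  # two-sided 97.5th percentile null: ~2.5% flagged
  expect_lt(mean(changes_sig), 0.08)
})
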