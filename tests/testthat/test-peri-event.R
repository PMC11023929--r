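test_that("null units have flat z-scored peri-event traces", {
  # The z-scores use the session SD of the smoothed 100 ms rate, so a
  # 10 ms bin of a Poisson unit has a per-bin z SD of ~13 regardless of
  # rate; flatness is judged against the empirical standard error.
  set.seed(21)
  dur <- 400
  ev <- random_events(200, dur)
  sp <- poisson_units(40, 4, dur)
  pe <- perievent_zscores(sp, ev, dur)
  expect_length(pe, 40)
  expect_equal(ncol(pe[[1]]$rate_z), 40)
  traces <- vapply(pe, `[[`, numeric(40), "trace_z")
  mean_bins <- rowMeans(traces)
  se_bins <- apply(traces, 1, sd) / sqrt(ncol(traces))
  expect_lt(max(abs(mean_bins / se_bins)), 4.5)
  # no bin is systematically preferred for the peak
  peaks <- vapply(pe, `[[`, numeric(1), "peak_bin_time_ms")
  expect_gt(length(unique(peaks)), 10)
})

test_that("a gain-modulated unit peaks inside the kernel window", {
  set.seed(22)
  dur <- 400
  ev <- random_events(150, dur)
  sp <- gain_units(3, 2, 5, ev$peak_time, dur)
  pe <- perievent_zscores(sp, ev, dur)
  for (u in pe) {
    expect_gt(u$peak_z, 1)
    expect_lte(abs(u$peak_bin_time_ms), 50)
  }
})

test_that("units without rate variance are excluded with a message", {
  dur <- 100
  ev <- random_events(20, dur)
  # one spike in every 100 ms bin: constant binned rate, zero SD
  metronome <- seq(0.05, dur - 0.05, by = 0.1)
  sp <- spike_table(c(rep(1L, length(metronome)), rep(2L, 400)),
                    c(metronome, runif(400, 0, dur)), "X")
  expect_message(pe <- perievent_zscores(sp, ev, dur), "excluded")
  expect_length(pe, 1)  # only the variable unit survives
})

test_that("modulation test: degenerate units are never significant and
           gain units almost always are", {
  set.seed(23)
  dur <- 400
  ev <- random_events(200, dur)
  one <- spike_table(1L, ev$peak_time[3], "X")
  mt1 <- modulation_test(one, ev, n_shuffles = 100, seed = 1)
  expect_false(mt1$significant)

  spg <- gain_units(20, 2, 5, ev$peak_time, dur)
  mtg <- modulation_test(spg, ev, n_shuffles = 500, seed = 2)
  expect_gt(mean(mtg$significant), 0.9)
})

test_that("high-firing peaks flag the right bins", {
  set.seed(24)
  dur <- 300
  sp <- poisson_units(20, 5, dur)
  hf <- high_firing_peaks(sp, dur)
  expect_equal(attr(hf, "fraction_bins_above"), 0.001,
               tolerance = 0.35)
  # synchronous injected bursts dominate the percentile
  burst_t <- seq(10, 290, by = 10)
  extra <- spike_table(rep(1:20, each = length(burst_t) * 5),
                       rep(rep(burst_t, each = 5), 20) +
                         runif(20 * 5 * length(burst_t), 0, 0.01),
                       "X")
  spb <- spike_table(c(sp$unit_id, extra$unit_id),
                     c(sp$spike_time, extra$spike_time), "X")
  hfb <- high_firing_peaks(spb, dur)
  hits <- vapply(burst_t, function(b)
    any(abs(hfb$peak_time - b - 0.005) < 0.02), logical(1))
  expect_true(all(hits))
  expect_error(high_firing_peaks(spike_table(), dur), "empty")
})

test_that("behaviour change test flags injected steps and nothing on a
           constant trace", {
  n <- 500000
  tt <- seq(0, by = 0.02, length.out = n)
  # sparse events: the +/-2 s shifted null rarely straddles another step
  ev <- random_events(30, max(tt), margin = 5)
  # permanent +1 steps at each event
  x <- rnorm(n, 0, 0.05)
  for (tp in ev$peak_time) x[tt >= tp - 0.04] <- x[tt >= tp - 0.04] + 1
  tr <- behavior_trace(tt, rep(0, n), rep(0, n), pupil_diameter = x)
  bc <- behavior_change_test(tr, ev, "pupil_diameter", n_draws = 100,
                             seed = 3)
  expect_equal(mean(bc$change, na.rm = TRUE), 1, tolerance = 0.02)
  expect_gt(bc$fraction_significant, 0.95)

  const <- behavior_trace(tt, rep(0, n), rep(0, n),
                          pupil_diameter = rep(2, n))
  bc0 <- behavior_change_test(const, ev, "pupil_diameter",
                              n_draws = 50, seed = 4)
  expect_true(all(bc0$change[!is.na(bc0$change)] == 0))
  expect_equal(bc0$fraction_significant, 0)
})

test_that("events at the trace edge are skipped with a log entry", {
  n <- 500
  tt <- seq(0, by = 0.02, length.out = n)
  tr <- behavior_trace(tt, rep(0, n), rep(0, n),
                       pupil_diameter = rnorm(n))
  ev <- event_table(kind = c("DS2", "DS2"), peak_time = c(0.1, 5),
                    amplitude = 2)
  expect_message(bc <- behavior_change_test(tr, ev, n_draws = 10,
                                            seed = 5),
                 "skipped")
  expect_true(is.na(bc$change[1]))
  expect_false(is.na(bc$change[2]))
})

test_that("motion-state segmentation tiles the session", {
  tt <- seq(0, by = 1, length.out = 10)
  sp <- rep(c(0, 5), 5)
  tr <- behavior_trace(tt, rep(0, 10), sp)
  st <- segment_motion_state(tr, 1)
  expect_equal(nrow(st$immobility), 5)
  expect_equal(st$immobility$end - st$immobility$start, rep(1, 5))
  total <- dentate:::intervals_duration(st$immobility) +
    dentate:::intervals_duration(st$locomotion)
  expect_equal(total, 10)

  all0 <- behavior_trace(tt, rep(0, 10), rep(0, 10))
  st0 <- segment_motion_state(all0, 1)
  expect_equal(nrow(st0$immobility), 1)
  expect_equal(nrow(st0$locomotion), 0)

  # immobile time is monotonically non-decreasing in the threshold
  ses <- small_session()
  tm <- vapply(c(0.5, 1, 2, 5), function(thr)
    dentate:::intervals_duration(
      segment_motion_state(ses$behavior, thr)$immobility), numeric(1))
  expect_true(all(diff(tm) >= 0))
})

test_that("dF/F with a cubic baseline behaves as defined", {
  t <- seq(0, 10, by = 0.01)
  f <- 100 + 5 * t - 0.2 * t^2 + 0.01 * t^3
  expect_lt(max(abs(dff(f, t))), 1e-10)
  expect_lt(max(abs(dff(rep(3, 50)))), 1e-10)
  pulse <- 1 + 0.2 * (t > 5 & t < 5.2)
  d <- dff(f * pulse, t)
  expect_equal(max(d), 0.2, tolerance = 0.06)
  expect_error(dff(c(1, 2, 3)), "4 samples")
  expect_error(dff(c(5, 1, -6, -20, -40, -60)), "baseline")
  # event-aligned z uses the preceding second for standardization
  x <- c(rnorm(1000), rnorm(200) + 10)
  z <- event_aligned_z(x, fs = 100, event_times = 10,
                       window_s = c(0, 1))
  expect_gt(mean(z, na.rm = TRUE), 3)
})

test_that("z-scoring is invariant to unit relabelling", {
  set.seed(26)
  dur <- 200
  ev <- random_events(50, dur)
  sp <- poisson_units(5, 3, dur)
  relab <- spike_table(sp$unit_id + 100L, sp$spike_time, "X")
  p1 <- perievent_zscores(sp, ev, dur)
  p2 <- perievent_zscores(relab, ev, dur)
  expect_equal(lapply(p1, `[[`, "trace_z"),
               lapply(p2, `[[`, "trace_z"))
})
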