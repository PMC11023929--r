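flat_behavior <- function(dur = 100, L = 120) {
  tt <- seq(0, dur - 0.02, by = 0.02)
  behavior_trace(tt, wrap_pos <- (15 * tt) %% L, rep(15, length(tt)),
                 track_length = L)
}

test_that("tuning curves localize and normalize correctly", {
  bh <- flat_behavior(240)
  loco <- data.frame(start = 0, end = 240)
  # unit firing only when the animal crosses bin 7 ([30, 35) cm)
  cross <- bh$t[bh$position >= 31 & bh$position < 34]
  sp <- spike_table(rep(1L, length(cross)), cross, "CA1")
  tc <- tuning_curves(sp, bh, loco)
  expect_equal(which.max(tc$rate[1, ]), 7)
  far <- setdiff(seq_len(24), 4:10)
  expect_lt(max(tc$rate[1, far]), 0.05 * max(tc$rate[1, ]))

  # homogeneous unit: flat curve at its mean rate
  set.seed(41)
  hom <- spike_table(rep(1L, 1200), sort(runif(1200, 0, 240)), "CA1")
  tch <- tuning_curves(hom, bh, loco)
  expect_equal(unname(tch$rate[1, ]), rep(5, 24), tolerance = 0.35)

  # missing occupancy names the offending bin
  part <- behavior_trace(seq(0, 9.98, by = 0.02),
                         seq(0, 9.98, by = 0.02) * 5,
                         rep(5, 500))
  expect_error(tuning_curves(hom, part, data.frame(start = 0, end = 10)),
               "bin")
})

test_that("decode matches brute-force Poisson enumeration", {
  # hand case: 2 units x 3 bins, counts (1, 0)
  curves <- list(rate = matrix(c(10, 1, 1, 1, 1, 10), 2, byrow = TRUE),
                 bin_centers_cm = c(2.5, 7.5, 12.5),
                 unit_id = 1:2)
  d <- decode(c(1, 0), curves, tau_s = 0.02)
  oracle <- brute_decode(c(1, 0), curves$rate, 0.02)
  expect_equal(d$posterior, oracle, tolerance = 1e-12)
  expect_equal(d$map_bin, 1L)

  # random instances up to 3 units / 5 bins, machine precision
  set.seed(42)
  for (rep in 1:20) {
    nu <- sample(1:3, 1); nb <- sample(2:5, 1)
    r <- matrix(runif(nu * nb, 0, 20), nu, nb)
    cv <- list(rate = r, bin_centers_cm = seq_len(nb), unit_id = seq_len(nu))
    cnt <- rpois(nu, 2)
    expect_equal(decode(cnt, cv, 0.02)$posterior,
                 brute_decode(cnt, r, 0.02), tolerance = 1e-10)
  }
})

test_that("decode degenerate and symmetric cases", {
  # single unit tuned to bin 3 only
  r <- matrix(0.01, 1, 24); r[1, 3] <- 20
  cv <- list(rate = r, bin_centers_cm = (1:24 - 0.5) * 5, unit_id = 1L)
  d <- decode(2, cv, 0.02)
  expect_gt(d$posterior[3], 0.99)
  # all units flat and equal: uniform posterior
  rf <- matrix(5, 3, 24)
  cvf <- list(rate = rf, bin_centers_cm = (1:24 - 0.5) * 5, unit_id = 1:3)
  expect_equal(decode(c(1, 0, 2), cvf, 0.02)$posterior, rep(1 / 24, 24))
  expect_error(decode(1, list(rate = matrix(0, 1, 24),
                              bin_centers_cm = 1:24, unit_id = 1L)),
               "all-zero")
  # posterior invariant to a common scaling of all tuning curves
  d1 <- decode(c(1, 0, 2), cvf, 0.02)$posterior
  cvf2 <- cvf; cvf2$rate <- cvf$rate * 7
  d2 <- decode(c(1, 0, 2), cvf2, 0.02, rate_floor_hz = 0.07)$posterior
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("place-field recovery on a ground-truth session", {
  p <- sim_params(duration = 600, rng_seed = 19,
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  # preferred positions at bin centres make the true bin unambiguous
  n_pc <- sum(tr$unit_tuning$is_place)
  tr$unit_tuning$preferred_cm[tr$unit_tuning$is_place] <-
    (sample.int(24, n_pc, replace = TRUE) - 0.5) * 5
  sp <- generate_spikes(p, tr, bh)
  states <- segment_motion_state(bh, 1)
  tc <- tuning_curves(sp, bh, states$locomotion)
  tun <- tr$unit_tuning[tr$unit_tuning$is_place, ]
  est <- apply(tc$rate[match(tun$unit_id, tc$unit_id), ], 1, which.max)
  truth_bin <- floor(tun$preferred_cm / 5) + 1
  expect_gte(mean(est == truth_bin), 0.95)
})

test_that("candidate events honour boundaries and duration rules", {
  cfg <- pipeline_config()
  iv <- data.frame(start = 0, end = 60)
  # a single spike in silence is shorter than 50 ms after shrinking
  one <- spike_table(1L, 30, "X")
  expect_equal(nrow(candidate_events(one, iv, cfg)), 0)
  # a 100 ms 20-unit burst in a sparse background
  set.seed(43)
  bg <- poisson_units(20, 0.5, 60)
  burst <- spike_table(rep(1:20, each = 10),
                       rep(30, 200) + runif(200, 0, 0.1), "X")
  sp <- spike_table(c(bg$unit_id, burst$unit_id),
                    c(bg$spike_time, burst$spike_time), "X")
  cand <- candidate_events(sp, iv, cfg)
  hit <- cand[cand$start < 30.1 & cand$end > 30, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 30, tolerance = 0.02)
  expect_equal(hit$end, 30.1, tolerance = 0.02)
  # constant-rate spiking: mean-threshold runs are nearly all too short
  flat <- poisson_units(10, 5, 60)
  cflat <- candidate_events(flat, iv, cfg)
  expect_lt(nrow(cflat), 20)
  # MUA pools units: permuting ids changes nothing
  perm <- spike_table(sample(sp$unit_id), sp$spike_time, "X")
  expect_equal(candidate_events(perm, iv, cfg), cand)
})

test_that("trajectory fits are exact on delta ridges", {
  nb <- 24; Tn <- 12
  p <- matrix(1e-9, Tn, nb)
  for (t in 1:Tn) p[t, ((t - 1) %% nb) + 1] <- 1
  p <- p / rowSums(p)
  f <- fit_trajectory(p)
  expect_equal(f$slope_bins_per_step, 1, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)
  # stationary delta: slope 0, perfect fit
  ps <- matrix(1e-9, Tn, nb); ps[, 5] <- 1; ps <- ps / rowSums(ps)
  fs <- fit_trajectory(ps)
  expect_equal(fs$slope_bins_per_step, 0, tolerance = 1e-6)
  expect_equal(fs$r_squared, 1, tolerance = 1e-6)
  expect_error(fit_trajectory(p[1:2, ]), "3 time steps")
})

test_that("noisy injected slopes are recovered within 10% and match a
           brute-force grid search", {
  set.seed(44)
  nb <- 24; Tn <- 12; s_true <- 0.8
  mk_post <- function() {
    p <- matrix(runif(Tn * nb, 0, 0.08), Tn, nb)
    for (t in 1:Tn) {
      mu <- (s_true * (t - 1) + 3) %% nb
      d <- pmin(abs(seq_len(nb) - 1 - mu), nb - abs(seq_len(nb) - 1 - mu))
      p[t, ] <- p[t, ] + exp(-d^2 / 2)
    }
    p / rowSums(p)
  }
  brute_fit <- function(p) {
    a <- 2 * pi / nb
    best <- c(NA, -1)
    for (s in seq(-3, 3, by = 0.01)) {
      for (ph in seq(0, nb, by = 0.25)) {
        w <- 0
        for (t in 1:Tn)
          w <- w + sum(p[t, ] * cos(a * (seq_len(nb) - 1 - s * (t - 1) - ph)))
        if (w > best[2]) best <- c(s, w)
      }
    }
    best[1]
  }
  for (rep in 1:3) {
    p <- mk_post()
    f <- fit_trajectory(p)
    expect_lt(abs(f$slope_bins_per_step - s_true) / s_true, 0.1)
    expect_equal(f$slope_bins_per_step, brute_fit(p), tolerance = 0.02)
    expect_gt(f$r_squared, 0.3)
  }
})

test_that("posterior rows sum to one across a sliding decode", {
  ses <- spike_session()
  cfg <- pipeline_config()
  states <- segment_motion_state(ses$behavior, 1)
  ca1 <- ses$spikes[ses$spikes$region == "CA1", ]
  tc <- tuning_curves(ca1, ses$behavior, states$locomotion, cfg)
  ps <- decode_sliding(ca1, tc, 10, 10.5)
  expect_equal(rowSums(ps$p), rep(1, nrow(ps$p)), tolerance = 1e-9)
  expect_true(all(ps$p >= 0))
})

test_that("the current-location test flags a perfect decoder and not a
           random one", {
  set.seed(45)
  bh <- flat_behavior(400)
  ev <- random_events(100, 380)
  # strongly tuned units: decoded position tracks the actual position
  n_u <- 24
  id <- integer(0); st <- numeric(0)
  for (u in 1:n_u) {
    pref <- (u - 0.5) * 5
    d <- abs(((bh$position - pref + 60) %% 120) - 60)
    lam <- 0.02 * (0.1 + 30 * exp(-d^2 / 18))
    k <- rpois(length(lam), lam)
    st <- c(st, rep(bh$t, k) + runif(sum(k), 0, 0.02))
    id <- c(id, rep(u, sum(k)))
  }
  sp <- spike_table(id, st, "CA1")
  tc <- tuning_curves(sp, bh, data.frame(start = 0, end = 400))
  det <- decoding_error_test(ev, sp, tc, bh, seed = 7)
  expect_true(det$over_represented[det$bin_centers_cm == 0])
  expect_equal(det$proportion[det$bin_centers_cm == 0],
               max(det$proportion))
})

test_that("spatial-information screening separates place cells from
           homogeneous units", {
  # needs behaviour with immobility bouts: on uninterrupted constant-
  # speed laps a circular time shift is a position shift and the null
  # would be as informative as the data
  p <- sim_params(duration = 300, rng_seed = 47, n_units = 8L,
                  fraction_place = 0.5, peak_rate_hz = c(15, 20),
                  baseline_rate_hz = c(2, 3),
                  event_rates = c(SPWR = 0, DS1 = 0, DS2 = 0))
  bh <- generate_behavior(p)
  tr <- simulate_ground_truth(p, bh)
  sp <- generate_spikes(p, tr, bh)
  states <- segment_motion_state(bh, 1)
  sel <- select_place_cells(sp, bh, states$locomotion,
                            n_shuffles = 30, seed = 9)
  expect_setequal(sel, tr$unit_tuning$unit_id[tr$unit_tuning$is_place])
})
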