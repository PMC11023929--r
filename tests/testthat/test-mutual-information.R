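mk_states <- function(m, time_ms = NULL) {
  if (is.null(time_ms))
    time_ms <- seq(-200 + 2.5, 200 - 2.5, by = 5)[seq_len(ncol(m))]
  attr(m, "time_ms") <- time_ms
  m
}

test_that("plug-in MI equals brute-force evaluation of the formula", {
  # explicit joint table: P = [[.4,.1],[.1,.4]]
  P <- matrix(c(.4, .1, .1, .4), 2, 2)
  expect_equal(brute_mi(P), 0.2780719, tolerance = 1e-6)
  a <- rep(c(0L, 0L, 1L, 1L), c(40, 10, 10, 40))
  b <- rep(c(0L, 1L, 0L, 1L), c(40, 10, 10, 40))
  expect_equal(dentate:::plugin_mi(a, b, 2), brute_mi(P))
  # random joint tables, machine precision
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    av <- sample(0:3, n, TRUE)
    bv <- sample(0:3, n, TRUE)
    Pj <- matrix(tabulate(av + 4 * bv + 1, 16) / n, 4, 4)
    expect_equal(dentate:::plugin_mi(av, bv, 4), brute_mi(Pj),
                 tolerance = 1e-12)
  }
})

test_that("quartile discretization follows the tie-to-lower rule", {
  dur <- 100
  ev <- random_events(40, dur)
  set.seed(32)
  sp <- poisson_units(4, 10, dur, region = "A")
  states <- discretize_counts(sp, ev, "A")
  expect_equal(dim(states), c(40, 80))
  expect_true(all(states %in% 0:3))
  # counts uniform over {0,1,2,3}: states are the identity mapping
  counts <- matrix(rep(0:3, 250), 10, 100)
  qs <- quantile(counts, c(.25, .5, .75), type = 1)
  st <- matrix(0L, 10, 100)
  for (q in qs) st <- st + (counts > q)
  expect_identical(st, matrix(rep(0:3, 250), 10, 100) + 0L)
  # Poisson(2) occupancies match the analytic masses (ties to lower)
  set.seed(33)
  x <- matrix(rpois(40000, 2), 200)
  qs <- quantile(x, c(.25, .5, .75), type = 1)
  stx <- matrix(0L, nrow(x), ncol(x))
  for (q in qs) stx <- stx + (x > q)
  occ <- tabulate(stx + 1, 4) / length(x)
  expected <- c(ppois(qs[1], 2),
                ppois(qs[2], 2) - ppois(qs[1], 2),
                ppois(qs[3], 2) - ppois(qs[2], 2),
                1 - ppois(qs[3], 2))
  expect_equal(occ, unname(expected), tolerance = 0.02)
  expect_error(discretize_counts(sp, ev, "NOPE"), "region")
})

test_that("yoked uniform streams give 2 bits and the baseline identity", {
  set.seed(34)
  a <- mk_states(matrix(sample(0:3, 300 * 80, TRUE), 300, 80))
  res <- mutual_info_timecourse(a, a)
  expect_equal(mean(res$mi), 2, tolerance = 0.02)  # log2(4)
  base_idx <- which(res$time_ms >= -200 & res$time_ms < -100)
  expect_equal(mean(res$delta_mi[base_idx]), 0, tolerance = 1e-12)
  # independence: delta-MI stays near zero
  b <- mk_states(matrix(sample(0:3, 300 * 80, TRUE), 300, 80))
  expect_lt(mutual_info_timecourse(a, b)$delta_mi_max, 0.1)
  # MI is symmetric and non-negative
  r1 <- mutual_info_timecourse(a, b)
  r2 <- mutual_info_timecourse(b, a)
  expect_equal(r1$mi, r2$mi)
  expect_true(all(r1$mi >= 0))
  expect_error(mutual_info_timecourse(a[1, , drop = FALSE],
                                      b[1, , drop = FALSE]), "2 trials")
})

test_that("event-locked coupling is maximally significant; errors guard
           the inputs", {
  set.seed(35)
  nt <- 120; nb <- 80
  a <- matrix(sample(0:3, nt * nb, TRUE), nt, nb)
  b <- matrix(sample(0:3, nt * nb, TRUE), nt, nb)
  post <- 41:60  # yoked only around the event
  b[, post] <- a[, post]
  a <- mk_states(a); b <- mk_states(b)
  res <- mi_significance(a, b, n_shuffles = 400, seed = 6)
  expect_equal(res$p_value, 1 / 401)
  expect_true(res$significant)
  expect_gt(res$delta_mi_max, 1.5)
  expect_error(mi_significance(a, b, n_shuffles = 0), "n_shuffles")
})

test_that("the coupling graph keeps significant, well-sampled pairs", {
  res <- data.frame(
    region_a = c("A", "A", "A", "B", "A"),
    region_b = c("B", "B", "C", "C", "D"),
    session = c(1, 2, 1, 1, 1),
    delta_mi_max = c(.5, .7, .1, .2, .05),
    significant = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  g1 <- coupling_graph(res, min_sessions = 1)
  expect_equal(g1$percent_significant, 50)  # 2 of 4 eligible pairs
  expect_equal(g1$sum_delta_mi, 0.7 + 0.05)
  expect_equal(igraph::ecount(g1$graph), 2)
  # session minimum prunes all pairs
  g5 <- coupling_graph(res, min_sessions = 5)
  expect_equal(g5$percent_significant, 0)
  expect_equal(igraph::ecount(g5$graph), 0)
})

test_that("a single coupled pair in a 4-region system is recovered", {
  set.seed(36)
  dur <- 300
  ev <- random_events(80, dur)
  # regions A and B share per-event burst fluctuations; C and D draw
  # independent ones, so only A-B covary across trials
  shared <- rbinom(80, 1, 0.5)
  mk_region <- function(coupled, region) {
    id <- integer(0); st <- numeric(0)
    for (u in 1:6) {
      t_u <- runif(rpois(1, 3 * dur), 0, dur)
      for (i in seq_len(80)) {
        g <- if (coupled) shared[i] else rbinom(1, 1, 0.5)
        k <- rpois(1, g * 2)
        t_u <- c(t_u, ev$peak_time[i] + runif(k, -0.02, 0.02))
      }
      id <- c(id, rep(u, length(t_u))); st <- c(st, t_u)
    }
    spike_table(id, pmax(0, st), region)
  }
  sp <- do.call(rbind, list(mk_region(TRUE, "A"), mk_region(TRUE, "B"),
                            mk_region(FALSE, "C"), mk_region(FALSE, "D")))
  sp <- spike_table(sp$unit_id, sp$spike_time, sp$region)
  combs <- combn(c("A", "B", "C", "D"), 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    sa <- discretize_counts(sp, ev, combs[1, k])
    sb <- discretize_counts(sp, ev, combs[2, k])
    r <- mi_significance(sa, sb, n_shuffles = 300, seed = k)
    data.frame(region_a = combs[1, k], region_b = combs[2, k],
               session = 1, delta_mi_max = r$delta_mi_max,
               significant = r$significant)
  })
  mi <- do.call(rbind, rows)
  g <- coupling_graph(mi, min_sessions = 1)
  edges <- igraph::as_edgelist(g$graph)
  expect_equal(nrow(edges), 1)
  expect_setequal(as.character(edges[1, ]), c("A", "B"))
})
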