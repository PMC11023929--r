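# Population-vector similarity of brain-wide ensembles during DS2, with
# hierarchical ordering, shuffle significance, and permutation-tested
# linear classification of stimulus identity.

#' Event-locked population vectors
#'
#' Spike count of each unit in the 200 ms window centred on each DS2
#' peak (`[peak - 100 ms, peak + 100 ms)`), normalized per unit by its
#' maximum count. Units with session mean rate above `max_rate_hz`
#' (default 5) or with no spikes in any window are excluded.
#'
#' @param spikes a [spike_table()].
#' @param events an [event_table()] (typically DS2).
#' @param duration session duration, seconds (for the mean-rate
#'   exclusion).
#' @param window_ms full window width (default 200).
#' @param max_rate_hz exclusion threshold (default 5).
#' @return list: `matrix` (units x events, entries in [0, 1]),
#'   `unit_id` (included units), `excluded` data.frame.
#' @export
population_vectors <- function(spikes, events, duration,
                               window_ms = 200, max_rate_hz = 5) {
  if (nrow(events) == 0) stop("need at least 1 event")
  units <- sort(unique(spikes$unit_id))
  by_unit <- split_units(spikes, units)
  half <- window_ms / 2000
  counts <- t(vapply(units, function(u) {
    st <- by_unit[[as.character(u)]]
    vapply(events$peak_time, function(tp)
      findInterval(tp + half, st) - findInterval(tp - half, st),
      numeric(1))
  }, numeric(nrow(events))))
  mean_rate <- vapply(by_unit, length, numeric(1)) / duration
  silent <- rowSums(counts) == 0
  drop <- mean_rate > max_rate_hz | silent
  if (all(drop)) stop("all units excluded")
  m <- counts[!drop, , drop = FALSE]
  m <- m / apply(m, 1, max)
  list(matrix = m, unit_id = units[!drop],
       excluded = data.frame(unit_id = units[drop],
                             mean_rate_hz = mean_rate[drop],
                             silent = silent[drop]))
}

#' Pairwise similarity of population vectors with a shuffle null
#'
#' Pearson correlation and cosine similarity over all event pairs;
#' the null independently permutes each unit's event axis (shuffling
#' event indices within units), recomputes both similarity matrices,
#' and flags observed pairs above the pooled null percentile.
#'
#' @param pv from [population_vectors()].
#' @param n_shuffles null draws (default 1000).
#' @param percentile flagging percentile (default 97.5).
#' @param seed RNG seed.
#' @return list: `pearson`, `cosine` (event x event matrices; Pearson
#'   `NA` where a vector has zero variance), `pearson_significant`,
#'   `cosine_significant`, `pearson_cutoff`, `cosine_cutoff`.
#' @export
vector_similarity <- function(pv, n_shuffles = 1000, percentile = 97.5,
                              seed = 1L) {
  m <- pv$matrix
  if (ncol(m) < 2) stop("need at least 2 events")
  cos_mat <- function(x) {
    nrm <- sqrt(colSums(x^2))
    cn <- crossprod(x) / outer(nrm, nrm)
    cn[, nrm == 0] <- NA; cn[nrm == 0, ] <- NA
    cn
  }
  pear_mat <- function(x) {
    v <- apply(x, 2, var)
    suppressWarnings(cr <- cor(x))
    cr[, v == 0] <- NA; cr[v == 0, ] <- NA
    cr
  }
  obs_p <- pear_mat(m); obs_c <- cos_mat(m)
  ut <- upper.tri(obs_p)
  null_p <- numeric(0); null_c <- numeric(0)
  with_substream(seed, "similarity_null", {
    for (s in seq_len(n_shuffles)) {
      sh <- t(apply(m, 1, sample))
      null_p <- c(null_p, pear_mat(sh)[ut])
      null_c <- c(null_c, cos_mat(sh)[ut])
    }
  })
  pc <- quantile(null_p, percentile / 100, na.rm = TRUE, names = FALSE)
  cc <- quantile(null_c, percentile / 100, na.rm = TRUE, names = FALSE)
  list(pearson = obs_p, cosine = obs_c,
       pearson_significant = !is.na(obs_p) & obs_p > pc & ut,
       cosine_significant = !is.na(obs_c) & obs_c > cc & ut,
       pearson_cutoff = pc, cosine_cutoff = cc)
}

#' Hierarchical ordering of units and events
#'
#' Agglomerative clustering with Euclidean distance and Ward variance
#' minimization linkage (ward.D2 on Euclidean distances), applied to
#' the rows (units) and columns (events) of the population-vector
#' matrix. Returns display leaf orders and cluster labels at a cut.
#'
#' @param pv from [population_vectors()] (or a plain matrix).
#' @param k_units,k_events number of clusters at the cut (default 2).
#' @return list: `unit_order`, `event_order`, `unit_cluster`,
#'   `event_cluster`, `unit_hclust`, `event_hclust`.
#' @export
cluster_order <- function(pv, k_units = 2, k_events = 2) {
  m <- if (is.list(pv)) pv$matrix else pv
  one <- function(x, k) {
    if (nrow(x) < 2)
      return(list(order = seq_len(nrow(x)),
                  cluster = rep(1L, nrow(x)), hc = NULL))
    hc <- hclust(dist(x), method = "ward.D2")
    list(order = order.dendrogram(as.dendrogram(hc)),
         cluster = stats::cutree(hc, k = min(k, nrow(x))), hc = hc)
  }
  ru <- one(m, k_units)
  re <- one(t(m), k_events)
  list(unit_order = ru$order, event_order = re$order,
       unit_cluster = ru$cluster, event_cluster = re$cluster,
       unit_hclust = ru$hc, event_hclust = re$hc)
}

# simple online perceptron; deterministic (zero init, fixed order)
perceptron_fit <- function(x, y, epochs = 100, lr = 1) {
  w <- numeric(ncol(x)); b <- 0
  for (ep in seq_len(epochs)) {
    changed <- FALSE
    for (i in seq_len(nrow(x))) {
      pred <- as.numeric(sum(w * x[i, ]) + b > 0)
      if (pred != y[i]) {
        delta <- lr * (y[i] - pred)
        w <- w + delta * x[i, ]; b <- b + delta
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(w = w, b = b)
}

perceptron_predict <- function(fit, x)
  as.numeric(x %*% fit$w + fit$b > 0)

# stratified fold assignment (returns fold index per row)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Permutation-tested stimulus-identity classification
#'
#' Linear threshold (perceptron) classifier scored by stratified
#' k-fold cross-validation; significance by permuting the labels
#' `n_permutations` times and recomputing the CV accuracy. The
#' empirical p includes the observed arrangement, so it is never 0.
#'
#' @param x events x features matrix (e.g. place-cell firing vectors).
#' @param labels two-class factor/character (e.g. tone vs puff).
#' @param n_folds folds (default 10).
#' @param n_permutations label permutations (default 1000).
#' @param epochs perceptron epochs (default 100).
#' @param seed RNG seed.
#' @return list: `accuracy` (mean over folds), `p_value`,
#'   `null_accuracy` (permutation distribution).
#' @export
stimulus_identity_test <- function(x, labels, n_folds = 10,
                                   n_permutations = 1000,
                                   epochs = 100, seed = 1L) {
  x <- as.matrix(x)
  cls <- unique(labels)
  if (length(cls) != 2) stop("need exactly 2 classes")
  y <- as.numeric(labels == cls[2])
  if (min(table(y)) < n_folds)
    stop("stratification error: a class has fewer events than folds")
  cv_acc <- function(yy, fold) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (length(unique(yy[tr])) < 2) return(NA_real_)
      fit <- perceptron_fit(x[tr, , drop = FALSE], yy[tr], epochs)
      mean(perceptron_predict(fit, x[te, , drop = FALSE]) == yy[te])
    }, numeric(1)), na.rm = TRUE)
  }
  with_substream(seed, "stimulus_null", {
    fold <- stratified_folds(y, n_folds)
    obs <- cv_acc(y, fold)
    null <- vapply(seq_len(n_permutations), function(s)
      cv_acc(sample(y), fold), numeric(1))
    p <- (1 + sum(null >= obs)) / (1 + n_permutations)
    list(accuracy = obs, p_value = p, null_accuracy = null)
  })
}
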