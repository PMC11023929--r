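# CSD computation around DS events and DS1/DS2 separation by PCA +
# density-based clustering of normalized CSD profiles.
#
# The voltage is bandpass-filtered to the DS detection band before the
# spatial difference: the second difference amplifies channel noise,
# and the out-of-band (mostly very slow, 1/f) components would
# otherwise dominate the event profiles.

#' Current source density around events
#'
#' Second spatial difference of voltage across equally spaced channels
#' within a symmetric window around each event peak, on the channels
#' from the deepest dentate channel up to the fissure. Sign convention:
#' sinks negative (`csd_k = 2 v_k - v_{k-1} - v_{k+1}`). Edge channels
#' use Vaknin padding (boundary channels duplicated), so the output has
#' one row per channel in the range.
#'
#' @param lfp an [lfp_recording()].
#' @param events an [event_table()].
#' @param channel_range integer length-2: (shallowest, deepest) channel
#'   of the dentate span, e.g. fissure to deepest dentate channel.
#' @param window_ms full window width around each peak (default 50).
#' @param band pre-filter applied per channel before the spatial
#'   difference (Hz); `NULL` for raw voltage.
#' @return list of per-event lists with `event_id`, `csd` (channels x
#'   samples), `channels`, `time_ms`.
#' @export
compute_csd <- function(lfp, events, channel_range,
                        window_ms = 50, band = c(5, 100)) {
  chs <- seq(min(channel_range), max(channel_range))
  if (length(chs) < 3) stop("need at least 3 channels for CSD")
  half <- round(window_ms / 2000 * lfp$fs)
  ns <- ncol(lfp$voltage)
  tms <- lfp_times(lfp)
  volt <- lfp$voltage[chs, , drop = FALSE]
  if (!is.null(band) && ns > 6 * ceiling(lfp$fs / band[1]))
    volt <- t(apply(volt, 1, bandpass, band = band, fs = lfp$fs))
  lapply(seq_len(nrow(events)), function(i) {
    c0 <- round((events$peak_time[i] - lfp$t0) * lfp$fs) + 1
    if (c0 - half < 1 || c0 + half > ns)
      stop("event ", i, " window falls outside the recording")
    v <- volt[, (c0 - half):(c0 + half), drop = FALSE]
    vp <- rbind(v[1, ], v, v[nrow(v), ])  # Vaknin padding
    k <- 2:(nrow(vp) - 1)
    csd <- 2 * vp[k, , drop = FALSE] - vp[k - 1, , drop = FALSE] -
      vp[k + 1, , drop = FALSE]
    list(event_id = i, csd = csd, channels = chs,
         time_ms = ((-half):half) / lfp$fs * 1000)
  })
}

# DBSCAN on a points x dims matrix. Classic algorithm; euclidean
# distances, labels 0 = noise. Small-n quadratic implementation.
dbscan_cluster <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  labels <- rep(NA_integer_, n)
  cl <- 0L
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_pts
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j]) || labels[j] == 0L) {
        newly <- is.na(labels[j])
        labels[j] <- cl
        if (newly && core[j])
          queue <- c(queue, setdiff(neighbours[[j]],
                                    which(!is.na(labels) & labels > 0L)))
      }
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

# default radius from the k-distance curve: the 95th percentile of the
# k-nearest-neighbour distances. Within a cluster almost every point
# reaches its k-th neighbour well inside this radius, while separated
# clusters sit many radii apart, so the choice is stable over the
# sweep of usable eps values.
knee_eps <- function(x, k = 5) {
  d <- as.matrix(dist(x))
  kd <- apply(d, 1, function(r) sort(r)[k + 1])
  quantile(kd, 0.95, names = FALSE)
}

#' Classify dentate spikes into DS1 and DS2
#'
#' Each event's CSD profile is flattened, normalized to unit Euclidean
#' norm (removing amplitude, preserving shape), and projected onto the
#' first two principal components of the event x feature matrix.
#' Density-based clustering (DBSCAN) on the two-dimensional scores
#' finds the event types; the two largest clusters are labelled by sink
#' depth: the cluster whose mean CSD sink sits shallower (outer
#' molecular layer) is DS1, the deeper one (middle molecular layer)
#' DS2. Points outside both clusters are `unclustered`.
#'
#' @param profiles list from [compute_csd()].
#' @param eps DBSCAN radius; `NULL` (default) picks the knee of the
#'   5-nearest-neighbour distance curve.
#' @param min_samples DBSCAN minimum neighbourhood size (default 5).
#' @return data.frame with `event_id`, `label` (`DS1`/`DS2`/
#'   `unclustered`), `pc1`, `pc2`; attribute `"sink_channel"` holds the
#'   per-cluster mean sink channels.
#' @export
classify_ds <- function(profiles, eps = NULL, min_samples = 5) {
  n <- length(profiles)
  if (n < 3) stop("need at least 3 events to classify")
  feat <- t(vapply(profiles, function(p) {
    v <- as.numeric(p$csd)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }, numeric(length(as.numeric(profiles[[1]]$csd)))))
  pc <- prcomp(feat, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  if (is.null(eps)) eps <- knee_eps(scores, k = min(5, n - 1))
  labels <- dbscan_cluster(scores, eps, min_samples)
  out <- data.frame(event_id = vapply(profiles, `[[`, integer(1), "event_id"),
                    label = "unclustered",
                    pc1 = scores[, 1], pc2 = scores[, 2],
                    stringsAsFactors = FALSE)
  sizes <- table(labels[labels > 0])
  if (length(sizes) < 2) {
    warning("fewer than two CSD clusters found; all events unclustered")
    return(out)
  }
  top2 <- as.integer(names(sort(sizes, decreasing = TRUE))[1:2])
  # sink depth of each cluster: channel (row) of the most negative
  # entry of the cluster-mean CSD at its overall minimum
  sink_row <- vapply(top2, function(cl) {
    m <- Reduce(`+`, lapply(which(labels == cl),
                            function(i) profiles[[i]]$csd)) / sum(labels == cl)
    idx <- which(m == min(m), arr.ind = TRUE)
    # weighted mean row at the sink time column for stability
    col <- idx[1, 2]
    w <- pmax(0, -m[, col])
    sum(seq_len(nrow(m)) * w) / sum(w)
  }, numeric(1))
  # shallower sink (smaller channel index, channels ordered superficial
  # to deep) = DS1; tie broken by lower mean index
  ord <- order(sink_row, top2)
  cl_ds1 <- top2[ord[1]]; cl_ds2 <- top2[ord[2]]
  out$label[labels == cl_ds1] <- "DS1"
  out$label[labels == cl_ds2] <- "DS2"
  attr(out, "sink_channel") <-
    stats::setNames(sink_row[ord], c("DS1", "DS2"))
  attr(out, "eps") <- eps
  out
}

#' Apply DS classification labels to an event table
#'
#' @param events table of `DS_unclassified` events (order matching the
#'   profiles passed to [classify_ds()]).
#' @param assignment result of [classify_ds()].
#' @return event table with kinds replaced by `DS1`/`DS2` (unclustered
#'   events keep `DS_unclassified`).
#' @export
apply_ds_labels <- function(events, assignment) {
  stopifnot(nrow(events) == nrow(assignment))
  kind <- events$kind
  kind[assignment$label == "DS1"] <- "DS1"
  kind[assignment$label == "DS2"] <- "DS2"
  events$kind <- kind
  events
}

#' Rank channels for the fissure by low-theta band power
#'
#' Helper only: the fissure channel (maximal theta amplitude) and hilus
#' channel are ultimately user-confirmable.
#'
#' @param lfp an [lfp_recording()].
#' @param band Hz, default 5-10.
#' @return numeric vector of band power per channel.
#' @export
theta_power_by_channel <- function(lfp, band = c(5, 10)) {
  vapply(seq_len(nrow(lfp$voltage)), function(ch) {
    f <- bandpass(lfp$voltage[ch, ], band, lfp$fs)
    mean(f^2)
  }, numeric(1))
}
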