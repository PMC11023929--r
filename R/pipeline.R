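# End-to-end pipeline: detection -> classification -> peri-event
# statistics -> mutual information -> decoding -> similarity, writing
# each stage's outputs plus a machine-readable summary.

#' Exclude events with mixed kinds within a window
#'
#' Drops events that have an event of a different kind within
#' `window_ms` (the peri-event analyses require single-kind
#' neighbourhoods).
#'
#' @param events an [event_table()].
#' @param window_ms exclusion window (default 200).
#' @return filtered event table.
#' @export
exclude_mixed_events <- function(events, window_ms = 200) {
  if (nrow(events) < 2) return(events)
  w <- window_ms / 1000
  keep <- vapply(seq_len(nrow(events)), function(i) {
    d <- abs(events$peak_time - events$peak_time[i])
    !any(d <= w & events$kind != events$kind[i])
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a session directory
#'
#' Stages, in order: DS + SPW-R detection, CSD classification,
#' peri-event modulation statistics, region-pair mutual information,
#' Bayesian decoding with the current-location test, and
#' population-vector similarity. Each stage's tables are written under
#' `out_dir`, plus `summary.json`. A failure in any stage aborts with
#' the stage name in the error. Identical config + session + seed give
#' byte-identical summaries.
#'
#' @param config a [pipeline_config()] (the session seed lives in
#'   `config$rng_seed`).
#' @param session_dir directory readable by [read_session()].
#' @param out_dir report directory (created).
#' @param channels named list with `hilus`, `pyramidal`, `fissure`,
#'   `deep_dentate` indices; default = the synthetic probe layout.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, session_dir, out_dir,
                         channels = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ses <- stage("load", read_session(session_dir))
  if (is.null(channels)) {
    pr <- default_probe(if (is.null(ses$lfp)) 16L else nrow(ses$lfp$voltage))
    channels <- pr[c("hilus", "pyramidal", "fissure", "deep_dentate")]
  }
  seed <- config$rng_seed
  duration <- max(ses$behavior$t) + (ses$behavior$t[2] - ses$behavior$t[1])
  summary <- list(seed = seed)

  # 1. detection
  events <- stage("detect", {
    if (is.null(ses$lfp)) stop("session has no LFP")
    ds <- detect_ds(ses$lfp, channels$hilus, config)
    swr <- detect_swr(ses$lfp, channels$pyramidal, config)
    rbind(ds, swr)
  })
  events <- events[order(events$peak_time), ]
  write_events(events, file.path(out_dir, "events.tsv"))
  summary$n_ds_detected <- sum(events$kind == "DS_unclassified")
  summary$n_swr_detected <- sum(events$kind == "SPWR")

  # 2. classification
  events <- stage("classify", {
    ds <- events_of_kind(events, "DS_unclassified")
    if (nrow(ds) >= 10) {
      prof <- compute_csd(ses$lfp, ds,
                          c(channels$fissure, channels$deep_dentate),
                          config$csd_window_ms)
      asn <- classify_ds(prof, config$dbscan_eps,
                         config$dbscan_min_samples)
      ds <- apply_ds_labels(ds, asn)
    }
    rbind(ds, events_of_kind(events, "SPWR"))
  })
  events <- events[order(events$peak_time), ]
  write_events(events, file.path(out_dir, "events_typed.tsv"))
  summary$n_ds1 <- sum(events$kind == "DS1")
  summary$n_ds2 <- sum(events$kind == "DS2")

  clean <- exclude_mixed_events(events, 200)

  # 3. peri-event statistics
  stage("perievent", {
    states <- segment_motion_state(ses$behavior, config$immobility_cm_s)
    peri <- list()
    for (kind in c("DS2", "SPWR")) {
      ev <- events_of_kind(clean, kind)
      if (nrow(ev) < 5 || nrow(ses$spikes) == 0) next
      mt <- modulation_test(ses$spikes, ev, config$n_shuffles,
                            config$modulation_percentile, config,
                            seed = seed)
      write_tsv(mt, file.path(out_dir,
                              paste0("modulation_", kind, ".tsv")))
      peri[[kind]] <- mean(mt$significant)
      rate <- event_rate(ev, states$immobility)
      summary[[paste0("rate_", kind, "_immobile_hz")]] <- rate
    }
    summary$fraction_modulated <- peri
    ds2 <- events_of_kind(clean, "DS2")
    if (nrow(ds2) >= 5) {
      bc <- behavior_change_test(ses$behavior, ds2,
                                 signal = "pupil_diameter",
                                 n_draws = min(config$behavior_null_draws, 200),
                                 shift_s = config$behavior_shift_s,
                                 seed = seed)
      summary$fraction_pupil_significant <- bc$fraction_significant
    }
  })

  # 4. mutual information
  stage("mutualinfo", {
    regions <- sort(unique(ses$spikes$region))
    ds2 <- events_of_kind(clean, "DS2")
    if (length(regions) >= 2 && nrow(ds2) >= 10) {
      combs <- utils::combn(regions, 2)
      rows <- lapply(seq_len(ncol(combs)), function(k) {
        sa <- discretize_counts(ses$spikes, ds2, combs[1, k],
                                config$mi_bin_ms, config$mi_n_states)
        sb <- discretize_counts(ses$spikes, ds2, combs[2, k],
                                config$mi_bin_ms, config$mi_n_states)
        res <- mi_significance(sa, sb,
                               n_shuffles = min(config$mi_n_shuffles, 1000),
                               alpha = config$mi_alpha,
                               n_states = config$mi_n_states, seed = seed)
        data.frame(region_a = combs[1, k], region_b = combs[2, k],
                   delta_mi_max = res$delta_mi_max,
                   p_value = res$p_value, significant = res$significant)
      })
      mi <- do.call(rbind, rows)
      write_tsv(mi, file.path(out_dir, "mutual_information.tsv"))
      summary$n_significant_pairs <- sum(mi$significant)
    }
  })

  # 5. decoding
  stage("decode", {
    if (!any(ses$spikes$region == "CA1")) {
      message("decoding skipped: no CA1 units")
      summary$decoding <- "skipped: no CA1 units"
    } else {
      states <- segment_motion_state(ses$behavior, config$immobility_cm_s)
      ca1 <- ses$spikes[ses$spikes$region == "CA1", , drop = FALSE]
      tc <- tuning_curves(ca1, ses$behavior, states$locomotion, config)
      ds2 <- events_of_kind(clean, "DS2")
      if (nrow(ds2) >= 10) {
        det <- decoding_error_test(ds2, ca1, tc, ses$behavior, config,
                                   seed = seed)
        write_tsv(data.frame(bin_cm = det$bin_centers_cm,
                             proportion = det$proportion,
                             over_represented = det$over_represented),
                  file.path(out_dir, "decoding_error_DS2.tsv"))
        summary$ds2_zero_error_over_represented <-
          det$over_represented[det$bin_centers_cm == 0]
      }
      cand <- candidate_events(ses$spikes, states$immobility, config)
      fits <- fit_candidate_slopes(cand, ca1, tc, config)
      write_tsv(fits, file.path(out_dir, "replay_slopes.tsv"))
      summary$n_candidates <- nrow(cand)
      summary$n_replay_fits <- sum(fits$included)
    }
  })

  # 6. similarity
  stage("similarity", {
    ds2 <- events_of_kind(clean, "DS2")
    if (nrow(ds2) >= 10 && nrow(ses$spikes) > 0) {
      pv <- population_vectors(ses$spikes, ds2, duration,
                               config$pv_window_ms, config$pv_max_rate_hz)
      sim <- vector_similarity(pv,
                               n_shuffles = min(config$similarity_n_shuffles, 200),
                               seed = seed)
      write_matrix_bin(sim$cosine, file.path(out_dir, "cosine.bin"))
      ord <- cluster_order(pv)
      write_tsv(data.frame(unit_id = pv$unit_id[ord$unit_order]),
                file.path(out_dir, "unit_order.tsv"))
      summary$mean_cosine <-
        mean(sim$cosine[upper.tri(sim$cosine)], na.rm = TRUE)
    }
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
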