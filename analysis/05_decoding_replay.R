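#!/usr/bin/env Rscript
# Bayesian position decoding: tuning curves from locomotion, decoder
# accuracy, the current-location over-representation test at DS2 vs
# SPW-R, and replay-slope fits on MUA candidate events, compared with
# the injected replay trajectories.
suppressPackageStartupMessages(library(dentate))

ses <- read_session("results/session")
truth_replay <- dentate:::read_tsv("results/session/ground_truth/replay.tsv")
events <- exclude_mixed_events(read_events("results/events_typed.tsv"))
cfg <- pipeline_config()
states <- segment_motion_state(ses$behavior, cfg$immobility_cm_s)
ca1 <- ses$spikes[ses$spikes$region == "CA1", ]
tc <- tuning_curves(ca1, ses$behavior, states$locomotion, cfg)

ds2 <- events_of_kind(events, "DS2")
swr <- events_of_kind(events, "SPWR")
det2 <- decoding_error_test(ds2, ca1, tc, ses$behavior, cfg, seed = 5)
detr <- decoding_error_test(swr, ca1, tc, ses$behavior, cfg, seed = 6)
cat(sprintf("DS2: %.0f%% of events decode to the current position bin (cutoff %.0f%%) -> %s\n",
            100 * det2$proportion[det2$bin_centers_cm == 0],
            100 * det2$cutoff,
            if (det2$over_represented[det2$bin_centers_cm == 0])
              "over-represented" else "not over-represented"))
cat(sprintf("SPWR: %.0f%% at zero error (cutoff %.0f%%) -> %s\n",
            100 * detr$proportion[detr$bin_centers_cm == 0],
            100 * detr$cutoff,
            if (detr$over_represented[detr$bin_centers_cm == 0])
              "over-represented" else "not over-represented"))

cand <- candidate_events(ses$spikes, states$immobility, cfg)
fits <- fit_candidate_slopes(cand, ca1, tc, cfg)
dentate:::write_tsv(fits, "results/replay_slopes.tsv")
cat(sprintf("%d candidate events, %d slope fits pass R^2 >= %.1f\n",
            nrow(cand), sum(fits$included), cfg$r2_min))

near_swr <- vapply(fits$start, function(s)
  any(abs(swr$peak_time - (s + 0.075)) < 0.15), logical(1))
s_swr <- abs(fits$slope_cm_s[fits$included & near_swr])
s_ds2 <- abs(fits$slope_cm_s[fits$included & !near_swr])
if (length(s_swr) > 5 && length(s_ds2) > 5)
  cat(sprintf("|slope| SPWR %.0f vs other %.0f cm/s (rank-sum p = %.2g)\n",
              median(s_swr), median(s_ds2),
              wilcox.test(s_swr, s_ds2, alternative = "greater")$p.value))
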