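#!/usr/bin/env Rscript
# Peri-event firing statistics: z-scored rates, shuffle modulation
# tests per event kind, event rates during immobility, high brain-wide
# firing peaks, and the pupil-dilation test with its +/-2 s null.
suppressPackageStartupMessages(library(dentate))

ses <- read_session("results/session")
events <- read_events("results/events_typed.tsv")
events <- exclude_mixed_events(events, 200)
cfg <- pipeline_config()
duration <- max(ses$behavior$t) + 0.02
states <- segment_motion_state(ses$behavior, cfg$immobility_cm_s)

for (kind in c("DS2", "SPWR", "DS1")) {
  ev <- events_of_kind(events, kind)
  if (nrow(ev) < 5) next
  mt <- modulation_test(ses$spikes, ev, n_shuffles = 500,
                        config = cfg, seed = 1)
  write_tsv <- dentate:::write_tsv
  write_tsv(mt, sprintf("results/modulation_%s.tsv", kind))
  cat(sprintf("%s: %.2f Hz during immobility; %.0f%% of units modulated\n",
              kind, event_rate(ev, states$immobility),
              100 * mean(mt$significant)))
}

hf <- high_firing_peaks(ses$spikes, duration, cfg)
co <- coincidence(hf, events_of_kind(events, "DS2"),
                  cfg$high_firing_window_ms)
cat(sprintf("high-firing peaks: %d; fraction within 60 ms of DS2: %.2f\n",
            nrow(hf), co$fraction))

ds2 <- events_of_kind(events, "DS2")
bc <- behavior_change_test(ses$behavior, ds2, "pupil_diameter",
                           n_draws = 200, seed = 2)
cat(sprintf("mean pupil change after DS2: %.2f a.u. (null cutoff %.2f)\n",
            mean(bc$change, na.rm = TRUE), bc$cutoff))
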