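#!/usr/bin/env Rscript
# Generate the study's default synthetic session -- 600 s of 16-channel
# laminar LFP with injected DS1/DS2/SPW-R events, ~50 place cells with
# replay and current-location reactivation, and arousal-coupled
# behaviour -- and write it (with ground truth) under results/session.
suppressPackageStartupMessages(library(dentate))

params <- sim_params(duration = 600, rng_seed = 1)
ses <- generate_session(params, dir = "results/session")

ev <- ses$truth$injected_events
cat("session written to results/session\n")
cat(sprintf("  %d injected events:\n", nrow(ev)))
print(table(ev$kind))
cat(sprintf("  %d units (%d spikes), %.0f%% immobile time\n",
            length(unique(ses$spikes$unit_id)), nrow(ses$spikes),
            100 * mean(ses$behavior$speed < 1)))
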