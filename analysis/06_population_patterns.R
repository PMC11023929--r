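#!/usr/bin/env Rscript
# Population-vector similarity of ensembles in the 200 ms window around
# each DS2 (max-normalized per unit, >5 Hz and silent units excluded),
# with Ward/Euclidean ordering and a within-unit shuffle null.
suppressPackageStartupMessages(library(dentate))

ses <- read_session("results/session")
events <- exclude_mixed_events(read_events("results/events_typed.tsv"))
ds2 <- events_of_kind(events, "DS2")
duration <- max(ses$behavior$t) + 0.02

pv <- population_vectors(ses$spikes, ds2, duration)
cat(sprintf("%d units included, %d excluded (>5 Hz or silent)\n",
            length(pv$unit_id), nrow(pv$excluded)))
sim <- vector_similarity(pv, n_shuffles = 500, seed = 3)
ut <- upper.tri(sim$cosine)
cat(sprintf("mean cosine similarity %.3f; %.1f%% of pairs above the null cutoff\n",
            mean(sim$cosine[ut], na.rm = TRUE),
            100 * mean(sim$cosine_significant[ut])))
ord <- cluster_order(pv)
dentate:::write_tsv(data.frame(unit_id = pv$unit_id[ord$unit_order]),
                    "results/unit_order.tsv")
dentate:::write_matrix_bin(sim$cosine, "results/cosine.bin")
cat("wrote results/unit_order.tsv and results/cosine.bin\n")
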