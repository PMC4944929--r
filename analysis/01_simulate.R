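#!/usr/bin/env Rscript
# Stage 1: draw a retina-like synthetic sample at the study defaults
# (950 typed neurons + 173 glia in a 132 x 114 x 80 um box, 10 planted
# plane modules, lognormal contact areas, 14% reversed duplicate listings)
# and write it out as the plain-text raw-data files the rest of the
# pipeline ingests.

library(retinaflow)

seed <- 42
out_dir <- "results/sample"

params <- generator_params()
sample <- generate_sample(params, seed = seed)
write_sample(sample, out_dir)

message(sprintf("sample written to %s", out_dir))
message(sprintf("  neurons: %d  glia: %d", nrow(sample$catalog),
                nrow(sample$glia)))
message(sprintf("  contact listings: %d (of which %s reversed duplicates)",
                nrow(sample$contacts),
                attr(sample$contacts, "provenance")[["duplicated_listings"]]))
message(sprintf("  contacts lost to box excision: %d", nrow(sample$truncated)))
message(sprintf("  planted modules: %d", params$n_modules))
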