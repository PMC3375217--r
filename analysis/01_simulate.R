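#!/usr/bin/env Rscript
# Generate the synthetic population recording used by the downstream
# analysis steps and write it (three CSVs + config sidecar) under
# results/recording/.  Sizes are a scaled-down version of the emulated
# array recordings so the full workflow runs in minutes on one CPU.

library(latwta)

cfg <- generator_config(n_units = 48, repetitions = 120, seed = 20260925)
rec <- generate_population(cfg)
print(rec)

dir.create("results", showWarnings = FALSE)
write_recording(rec, "results/recording")

u <- rec$units
cat(sprintf("units: %d (%d designated onset-like), orientations: %d, %d trials\n",
            nrow(u), sum(u$is_onset), length(cfg$orientations),
            nrow(rec$trials)))
cat(sprintf("spikes: %d (mean %.1f per trial)\n", nrow(rec$spikes),
            nrow(rec$spikes) / nrow(rec$trials)))
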