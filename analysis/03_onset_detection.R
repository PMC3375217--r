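#!/usr/bin/env Rscript
# Stimulus-onset detection from the pooled activity of the onset-detector
# units: threshold calibration, per-trial onsets at the standard operating
# point (T = 20 ms, 4 SD), and the ROC over criteria.  Writes
# results/onsets.csv and results/onset_roc.csv.

library(latwta)

rec <- load_recording("results/recording")
cl <- read.csv("results/units_classified.csv")
ids <- cl$unit_id[cl$label == "onset_detector"]
cat("onset-detector units:", length(ids), "\n")

oc <- calibrate_onset_threshold(rec, ids, window_ms = 20, n_sd = 4)
cat(sprintf("spontaneous pooled counts in 20 ms: mean %.3f, sd %.3f -> m = %d\n",
            oc$mu0, oc$sigma0, oc$m))

ons <- detect_trial_onsets(rec, ids, oc)
write.csv(data.frame(trial_id = names(ons), onset_ms = as.numeric(ons)),
          "results/onsets.csv", row.names = FALSE)
cat(sprintf("detected onsets: %.1f%% of trials, mean %.1f ms, sd %.1f ms\n",
            100 * mean(!is.na(ons)), mean(ons, na.rm = TRUE),
            sd(ons, na.rm = TRUE)))

roc <- onset_roc(rec, ids, n_sd_grid = c(0, 1, 2, 3, 4, 5, 6, 8))
write.csv(roc, "results/onset_roc.csv", row.names = FALSE)
print(roc)
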