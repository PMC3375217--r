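#!/usr/bin/env Rscript
# Single-cell 2AFC neurometrics: probability of correct discrimination
# versus orientation difference for the first/second/third-spike race
# readouts and the spike-count comparator, with mean decision times.
# Writes results/neurometric_single.csv.

library(latwta)

rec <- load_recording("results/recording")
cl <- read.csv("results/units_classified.csv")
tuned <- cl[cl$label == "tuned", ]
# the three most strongly tuned units
pick <- tuned$unit_id[order(-tuned$B)][1:min(3, nrow(tuned))]

out <- list()
for (u in pick) {
  nc <- neurometric_curve(rec, u, n_values = 1:3, split_seed = 7)
  nc$unit_id <- u
  out[[length(out) + 1]] <- nc
  coarse <- nc[nc$delta_theta == 90, ]
  cat(sprintf("unit %d (pref %.1f deg): Pc at 90 deg -- %s\n",
              u, attr(nc, "pref"),
              paste(sprintf("%s %.2f (dt %.0f ms)", coarse$readout,
                            coarse$pc, coarse$decision_time),
                    collapse = ", ")))
}
res <- do.call(rbind, out)
write.csv(res, "results/neurometric_single.csv", row.names = FALSE)
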