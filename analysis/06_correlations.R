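#!/usr/bin/env Rscript
# Trial-to-trial first-spike latency correlations between tuned units and
# their dependence on the difference in preferred orientations.  Writes
# results/latency_correlations.csv and results/correlation_vs_dpo.csv.

library(latwta)

rec <- load_recording("results/recording")
cl <- read.csv("results/units_classified.csv")
tuned <- cl[cl$label == "tuned", ]

tbl <- latency_correlations(rec, tuned$unit_id,
                            phi = setNames(tuned$phi, tuned$unit_id))
write.csv(tbl, "results/latency_correlations.csv", row.names = FALSE)
cat(sprintf("%d (pair, orientation) coefficients; mean %.3f, sd %.3f\n",
            nrow(tbl), mean(tbl$r), sd(tbl$r)))

vd <- correlation_vs_dpo(tbl)
write.csv(vd$bins, "results/correlation_vs_dpo.csv", row.names = FALSE)
print(vd$bins)
cat(sprintf("regression of r on dPO: slope %.2g +/- %.2g (p = %.2g)\n",
            vd$slope, vd$slope_se, vd$slope_p))
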