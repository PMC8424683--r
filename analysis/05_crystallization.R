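#!/usr/bin/env Rscript
# Isothermal crystallization kinetics at isochronal conditions: generate
# the preset permittivity decays (half-lives matching the reported
# devitrification of neat EZB/FEN/SVT and the therapeutic ternary blend),
# normalize them and extract onset, half-life and endset times.

suppressPackageStartupMessages(library(amorphstab))
dir.create("results", showWarnings = FALSE)

pres <- crystallization_presets()
tab <- do.call(rbind, lapply(seq_len(nrow(pres)), function(i) {
  cs <- make_crystallization(pres$t_half_s[i],
                             temperature = pres$temperature_K[i],
                             cfg = generator_config(700 + i,
                                                    "multiplicative", 0.005),
                             sample_label = pres$scenario[i])
  kt <- kinetic_times(normalize_series(cs))
  data.frame(scenario = pres$scenario[i],
             onset_min = kt$onset_s / 60,
             t_half_min = kt$t_half_s / 60,
             endset_min = kt$endset_s / 60,
             t_half_true_min = pres$t_half_s[i] / 60)
}))
write.csv(tab, "results/crystallization_kinetics.csv", row.names = FALSE)

cat("Crystallization kinetics (minutes; thresholds 0.05 / 0.5 / 0.95):\n")
print(tab, row.names = FALSE, digits = 4)
cat(sprintf("\nAll half-lives within one 600 s sampling interval: %s\n",
            all(abs(tab$t_half_min - tab$t_half_true_min) < 10)))
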