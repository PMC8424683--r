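#!/usr/bin/env Rscript
# Havriliak-Negami fitting of synthetic broadband dielectric spectra for
# the eutectic 10/20/70 EZB/SVT/FEN composition: generate a temperature
# series whose loss peaks follow the sample's VFT law, fit each spectrum
# (HN + dc conductivity), convert to structural relaxation times and save
# the relaxation map for the next stage.

suppressPackageStartupMessages(library(amorphstab))
dir.create("results", showWarnings = FALSE)

pres <- vft_presets()
r <- pres[pres$sample == "10/20/70", ]
law <- vft_parameters(r$log10_tau_inf, r$B_K, r$T0_K)

series <- make_bds_series(law, bds_temperature_grid(law, n = 13),
                          cfg = generator_config(11, "multiplicative",
                                                 0.005))
fits <- lapply(series, fit_hn)
map <- data.frame(
  temperature_K = vapply(series, `[[`, 0, "temperature"),
  tau_alpha_s = vapply(fits, `[[`, 0, "tau_alpha"),
  a = vapply(fits, function(f) f$parameters$a, 0),
  b = vapply(fits, function(f) f$parameters$b, 0),
  delta_eps = vapply(fits, function(f) f$parameters$delta_eps, 0),
  residual = vapply(fits, `[[`, 0, "residual_norm"))
write.csv(map, "results/relaxation_map_102070.csv", row.names = FALSE)

gt <- attr(series, "ground_truth")$map
cat("HN fits across temperature (10/20/70, 0.5% multiplicative noise):\n")
print(cbind(round(map, 4),
            dlog10_tau = round(log10(map$tau_alpha_s) -
                                 log10(gt$tau_alpha_s), 4)),
      row.names = FALSE)
cat(sprintf("\nmax |dlog10 tau| vs construction: %.4f decades\n",
            max(abs(log10(map$tau_alpha_s) - log10(gt$tau_alpha_s)))))
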