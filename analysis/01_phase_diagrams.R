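#!/usr/bin/env Rscript
# Ideal (Schroeder-Van Laar) phase diagrams of the EZB/SVT/FEN system:
# binary liquidus branches and eutectic points for all three drug pairs,
# and the ternary liquidus surface with its eutectic.
#
# The registry's melting points and fusion enthalpies are literature
# placeholder constants (the analysis chain is exercised end to end on
# synthetic ground truth); swap in calorimetric values via
# component_registry(file = ...) for a real prediction.

suppressPackageStartupMessages(library(amorphstab))
dir.create("results", showWarnings = FALSE)

reg <- component_registry()
comps <- reg[c("EZB", "SVT", "FEN")]

pairs <- combn(names(comps), 2, simplify = FALSE)
binaries <- do.call(rbind, lapply(pairs, function(pr) {
  e <- binary_eutectic(comps[[pr[1]]], comps[[pr[2]]])
  data.frame(system = paste(pr, collapse = "/"),
             x_e_first_component = e$x_e, T_e_K = e$T_e)
}))
write.csv(binaries, "results/binary_eutectics.csv", row.names = FALSE)

tern <- ternary_eutectic(comps$EZB, comps$SVT, comps$FEN,
                         grid_resolution = 0.01)
write.csv(tern$grid, "results/ternary_liquidus_surface.csv",
          row.names = FALSE)
w_e <- mole_to_weight(tern$x_e, vapply(comps, `[[`, 0, "molar_mass"))

cat("Binary eutectics (mole fraction of first-named component):\n")
print(binaries, row.names = FALSE, digits = 4)
cat(sprintf("\nTernary eutectic: x = (%.3f, %.3f, %.3f) EZB/SVT/FEN,",
            tern$x_e[1], tern$x_e[2], tern$x_e[3]))
cat(sprintf(" w = (%.2f, %.2f, %.2f), T_e = %.1f K\n",
            w_e[1], w_e[2], w_e[3], tern$T_e))
cat(sprintf("Every binary T_e exceeds the ternary T_e: %s\n",
            all(binaries$T_e_K >= tern$T_e)))
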