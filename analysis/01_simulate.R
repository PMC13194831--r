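#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study systems with known ground truth.
#
# Produces (under results/):
#   dispersed.xyz / condensed.xyz  - single-frame coordinate sets
#   collapse.xyz                   - 5-frame collapse trajectory
#   truth.json                     - the generators' ground truth
#
# The condensed system emulates a peptide condensate: 40 pseudo-peptide
# chains of 40 residues packed in a 25 A sphere inside a 70 A periodic box,
# with 400 water oxygens. The collapse trajectory confines 8 chains from a
# 60 A down to a 25 A radius, mimicking condensation from the dispersed
# initial state.

library(condenskit)

seed <- 20260929L
dir.create("results", showWarnings = FALSE)

dispersed <- generate_configuration("dispersed", n_chains = 20,
                                    chain_length = 10, box = 127,
                                    n_waters = 500, seed = seed)
write_frame(dispersed$frame, "results/dispersed.xyz")

condensed <- generate_configuration("condensed", n_chains = 40,
                                    chain_length = 40, box = 70,
                                    sphere_radius = 25, n_waters = 400,
                                    water_margin = 2, seed = seed + 1)
write_frame(condensed$frame, "results/condensed.xyz")

collapse <- generate_collapse_series(n_frames = 5, start_radius = 60,
                                     end_radius = 25, n_chains = 8,
                                     chain_length = 10, box = 150,
                                     seed = seed + 2)
write_trajectory(collapse$trajectory, "results/collapse.xyz")

truth <- list(dispersed = dispersed$truth, condensed = condensed$truth,
              collapse = collapse$truth["radii"])
jsonlite::write_json(truth, "results/truth.json", auto_unbox = TRUE,
                     digits = NA, null = "null")

conc <- box_concentration(20, 12.7)
cat(sprintf("dispersed system: 20 chains in a 12.7 nm box = %.1f mM (~16 mM)\n",
            conc))
cat(sprintf("condensed system: %d/%d waters inside the 25 A sphere\n",
            condensed$truth$n_waters_inside, condensed$truth$n_waters_total))
cat(sprintf("collapse trajectory radii: %s A\n",
            paste(round(collapse$truth$radii, 1), collapse = ", ")))
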