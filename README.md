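# condenskit

Analytics for catalytic peptide condensates formed by liquid–liquid phase
separation (LLPS). Histidine-rich, oppositely charged peptides demix into
dense droplets that concentrate reactants and catalyse ester hydrolysis;
characterising them means answering four quantitative questions from four
very different data sources:

- **How compact is the condensate?** From coordinates/trajectories:
  Shrake–Rupley solvent-accessible surface area (SASA) under periodic
  boundaries, and the *collapse degree*
  SASA(reference)/SASA(t) — 1 at the dispersed start, > 1 under compaction.
- **How much water does it hold, and which His pairs could form catalytic
  sites?** A voxel flood-fill construction of the solvent-accessible
  boundary of the largest peptide cluster gives the enclosed volume and the
  waters inside it; His Cα pair-distance distributions (minimum image,
  cell-list accelerated) and a geometric screen for low-barrier hydrogen
  bonds (N–N ≤ 2.7 Å, Cα–Cα in 5–11 Å, near-coplanar rings) locate
  candidate sites.
- **How mobile is the interior?** FRAP traces are corrected by the
  standard double normalization
  I_corr = (R1 − R3)·(R2_pre − R3_pre)/(R2 − R3), min–max scaled, and
  fitted to y = a − b·cˣ; the half time is t½ = log_c(0.5·a/b) and the
  plateau a is the recovery (mobile fraction) in percent.
- **How active and how acidic/basic is it?** Plate-reader kinetics: initial
  rates V₀ from the first 2.5 min divided by a calibration slope,
  Michaelis–Menten parameters via Lineweaver–Burk (V_max, K_m,
  k_cat = V_max/[catalyst] at 3 mM), percent conversion, encapsulation
  efficiency (C_T − C_sup)/C_T, turbidity phase diagrams, and the 25 %/30 %
  single-pass replicate outlier rules. Ratiometric (SNARF-type) pH comes
  from a four-parameter logistic calibration of the 580/640 nm emission
  ratio with closed-form inversion to pH.

Every stage has a synthetic-data generator with known ground truth
(pseudo-atom peptide configurations, three-channel FRAP traces built by
algebraic inversion of the correction pipeline, Michaelis–Menten plate
reads, two-channel logistic ratio data), so all pipelines are testable
end-to-end without external data. See the methods vignette
(`vignettes/condensate-analytics.Rmd`) for the models, parameter defaults
and design rationale.

## Worked example

```r
library(condenskit)

# a synthetic condensate: 40 pseudo-peptide chains in a 25 A sphere,
# 400 waters, 70 A periodic box
g <- generate_configuration("condensed", n_chains = 40, chain_length = 40,
                            box = 70, sphere_radius = 25, n_waters = 400,
                            water_margin = 2, seed = 7)
wc <- condensate_water_content(g$frame, grid_spacing = 1, probe = 1.4)
wc
#> <boundary_result> enclosed 52610 A^3 (void 155), 60/400 waters inside, density 0.0011 A^-3
g$truth$n_waters_inside
#> [1] 60

# FRAP: simulate channels from a known recovery curve, run the full
# correction + fit pipeline
times <- seq(0, 120, by = 2)
tr <- frap_truth(a = 70, c = 0.95, bleach_index = 8)
ch <- simulate_frap_channels(tr, times, photofade = 0.998)
cn <- correct_and_normalize(frap_trace(ch$time, ch$R1, ch$R2, ch$R3,
                                       bleach_index = 8))
fit_recovery(cn)
#> <recovery_fit> a=70.00% b=70.00 c=0.95000 t1/2=13.51 s (n=54)
```

The water count equals the generator's sphere truth (60/60); the FRAP fit
returns the generating parameters exactly on noiseless channels, with
t½ = ln(0.5)/ln(0.95) = 13.51 s and a 70 % mobile fraction.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `05_ph.R`); each is a thin script over the package
functions that prints what it found and writes tables under `results/`.

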