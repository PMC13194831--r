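---
title: "Methods: condensate trajectory and assay analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condensate trajectory and assay analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condenskit)
```

`condenskit` re-implements, as tested reusable code, the analysis
computations used to characterise histidine-rich peptide condensates formed
by liquid–liquid phase separation (LLPS): trajectory-derived condensate
metrics, FRAP recovery analysis, plate-reader kinetics, and ratiometric pH
determination. Because the raw inputs of such a study (MD trajectories,
microscope intensity tables, plate reads) are large and instrument-specific,
every pipeline stage is paired with a synthetic-data generator that produces
inputs with *known ground truth*; the test suite and the acceptance script
exercise the full pipelines against that truth.

## Coordinate model

All geometry operates on a `molecular_frame`: an atom table (element, atom
name, residue name/index, chain id, van der Waals radius) with Cartesian
coordinates in Å inside an orthorhombic periodic box. Distances use the
minimum-image convention throughout, and neighbour searches go through a
cell list (with an automatic brute-force fallback when the box is smaller
than three cells per dimension; the two paths are tested for exact
agreement). Radii default to C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
Zn 1.39 Å and are user-overridable; unknown elements are an error unless a
default is configured, so silent mis-assignment cannot happen.

File support is deliberately narrow: a fixed-width PDB subset (ATOM/HETATM,
no altloc or insertion codes — anything else is rejected loudly), XYZ and
multi-frame XYZ (comment line carries `t=<ns>` and `box=x,y,z`), and CSV
time-series tables. PDB chain columns hold a single character, so round
trips of synthetic many-chain systems use XYZ. Binary trajectory formats are
out of scope; a practitioner converts upstream.

## Solvent-accessible surface area and collapse degree

SASA uses the Shrake–Rupley construction: for each selected atom,
`n_sphere_points` test points are placed on the probe-expanded sphere
(radius $r_i + r_\mathrm{probe}$) by a Fibonacci (golden-angle) lattice,
and the accessible fraction — points outside every other selected atom's
expanded sphere, under minimum image — is multiplied by
$4\pi (r_i + r_\mathrm{probe})^2$. Defaults: probe 1.4 Å (the standard
water probe) and 960 points, at which doubling the point count changes
totals by well under 0.5 % (a tested property). An isolated atom reproduces
its analytic area; overlapping clusters are validated against an
independent Monte-Carlo surface-rejection oracle.

The *collapse degree* of a trajectory frame is
$\mathrm{SASA}_\mathrm{ref} / \mathrm{SASA}_t$, with the dispersed initial
frame as the reference, so the reference frame scores exactly 1 and
compaction scores above 1. The selection defaults to all peptide atoms; an
equilibration window (`eq_time`, default 0) can discard early frames from
the reported series, mirroring the common MD practice of dropping the first
stretch of a production run (a 200 ns discard in the motivating setting) —
synthetic trajectories have no such timescale, hence the off-by-default
choice.

## Condensate boundary and water content

The "water content of the condensate" requires a boundary. The package
defines it operationally: (1) find the largest peptide cluster — connected
component of the chain-contact graph, where any heavy-atom pair within
4.5 Å links two chains (union-find; ties broken by atom count then lowest
chain id); (2) unwrap the cluster across periodic images (chains unwrapped
internally along their atom order, then placed by BFS over the contact
graph) and re-centre it in the box; a contact that cannot be reproduced by
a single image placement means the cluster wraps around the box, and such
percolating clusters are rejected with an explicit error rather than
guessed at; (3) voxelize the box (default 1 Å spacing) and mark voxels
within $r_i + r_\mathrm{probe}$ of any cluster atom as solid; (4) flood-fill
the exterior from the box faces (6-connectivity, no periodic wrap — this is
why re-centring matters); (5) everything not reached is the enclosed
region.

Two volumes are reported: `enclosed_volume` (the full non-exterior region,
i.e. the condensate including its peptide material — this is the volume
used for water densities) and `void_volume` (interior cavities only). A
spherical-shell phantom of atoms at centre radius $R_c$ must enclose a
cavity of $\tfrac43 \pi (R_c - r_\mathrm{atom} - r_\mathrm{probe})^3$
within 5 % at 1 Å spacing, which the suite checks analytically.

Waters (single oxygen points) are counted inside when their wrapped
position falls in an enclosed voxel. Near the boundary the classification
is genuinely scale-dependent: a water sitting in a solvent channel a voxel
wide is "outside" by the SAS definition even if a coarse geometric truth
calls it inside. `classify_waters()` therefore reports, per water, whether
all voxels within a clearance distance (default two grid spacings) share
its classification; for waters robust at that clearance the count matches
the generator's sphere truth exactly, and that exactness is an acceptance
check. The headline count may differ from the coarse truth by at most the
handful of non-robust boundary waters.

## His Cα pair distribution and LBHB screening

The pair distribution tallies minimum-image Cα–Cα distances between His
residues frame by frame, by default across distinct chains only (the
intermolecular contacts that matter for inter-peptide catalytic sites).
Because the natural y-axis normalisation of such plots varies, both raw
counts and counts/(frames × pairs × bin width) are returned; the bin total
is conserved under bin-width changes (tested). The cell-list tally equals a
brute-force $O(n^2)$ oracle exactly.

Low-barrier hydrogen bonds (LBHBs) between His imidazoles are screened
geometrically: a pair is a candidate when the *shortest* N–N distance over
all Nδ/Nε combinations is ≤ 2.7 Å (a screening tolerance slightly above the
~2.58 Å exemplar donor–acceptor distance), the Cα–Cα distance falls in the
5–11 Å supportive window, and — when full imidazole rings are present — the
ring planes are within 30° of coplanar. The coplanarity threshold
quantifies "near coplanar", which is not otherwise pinned down; it is a
declared, configurable choice. Pseudo-atom models without rings skip the
plane test. An empty candidate list is a valid result, and the output is
invariant to atom ordering.

## FRAP double normalization and recovery fitting

Three ROI channels enter: bleached ROI $R_1(t)$, reference ROI $R_2(t)$
(tracks acquisition photofading), and background $R_3(t)$. The corrected
trace is

$$I_\mathrm{corr}(t) = \bigl(R_1(t) - R_3(t)\bigr)\,
  \frac{R_2^\mathrm{pre} - R_3^\mathrm{pre}}{R_2(t) - R_3(t)},$$

the standard background-subtracted double normalization, followed by
min–max scaling to percent with $I_\mathrm{min}$ the *post-bleach* minimum
(pre-bleach noise should not set the floor) and $I_\mathrm{pre}$ the
pre-bleach mean. The correction is invariant to rescaling all three
channels by a common positive constant (tested), and $R_2 - R_3$ crossing
zero is an error naming the sample.

The normalized trace is fitted by bounded Levenberg–Marquardt least squares
to $y = a - b\,c^x$ with $x$ in seconds from the first post-bleach sample,
$a \in (0, 200]$, $b > 0$, $c \in (0, 1)$; initial values come from the
tail mean, the first post-bleach sample and a log-linear regression of
$(a_0 - y)$. The half time is the closed form
$t_{1/2} = \log_c(0.5\,a/b)$, reported as undefined (never fabricated) when
$0.5\,a/b \notin (0,1)$, and the recovery percentage is the fitted plateau
$a$ — the mobile fraction — not the last observed sample. Evaluation
horizons (e.g. 180 s or 50 s) truncate the fitted window.

The channel generator inverts this pipeline algebraically so the noiseless
round trip is exact to machine precision. One consequence is structural:
because the min–max step pins the post-bleach minimum sample to 0 %, an
exact round trip requires the model curve to start at zero, i.e. $b = a$
(full bleach). The generator therefore fixes $b = a$; `fit_recovery()`
itself fits $b$ freely, which matters for real, partially-bleached traces.

## Plate-reader analytics

*Outlier rule.* Replicates are filtered in a single pass: the mean of all
values is computed once and a value is excluded when its relative deviation
exceeds 25 % (kinetics) or 30 % (calibration); the mean is never
recomputed. The rule is order-invariant.

*Calibration.* Blank-subtracted replicate means per concentration level
(after the 30 % rule) are fitted by ordinary least squares *with* an
intercept, but only the slope (AU/mM) is used downstream — signals are
divided by it. Regression statistics are computed in closed form so exact
synthetic data do not trip spurious perfect-fit warnings.

*Initial rates.* The substrate-free control trace is subtracted pointwise,
a line is fitted to the samples up to 2.5 min, and the slope is divided by
the calibration slope: $V_0$ in mM/min (the unit is explicit and
configurable because printed rate tables often omit it). The standard error
propagates from the linear fit. $V_0$ is invariant to constant offsets
applied to both signal and control.

*Michaelis–Menten.* Parameters come from the Lineweaver–Burk plot — OLS of
$1/V_0$ on $1/S$, $V_\mathrm{max} = 1/\mathrm{intercept}$,
$K_m = \mathrm{slope} \cdot V_\mathrm{max}$,
$k_\mathrm{cat} = V_\mathrm{max}/[\mathrm{catalyst}]$ with a 3 mM default
catalyst concentration — matching the source protocol despite the known
statistical weakness of double-reciprocal fits; a direct nonlinear fit
(`fit_michaelis_menten_direct()`) is provided as a labelled cross-check and
the two agree exactly on noiseless data while diverging predictably under
noise. A non-positive intercept (unphysical $V_\mathrm{max}$) is an error.
SEs propagate by the delta method.

*Conversion, EE, turbidity, line scans.* Conversion is
$100 \cdot [\mathrm{product}]/[\mathrm{substrate}]$ with a 0.7 mM default
denominator; negative blank-subtracted products are clamped to zero and
flagged. Encapsulation efficiency is $(C_T - C_\mathrm{sup})/C_T$;
supernatant above total yields a flagged negative value, not a silent
clip. Turbidity matrices average replicate wells per condition, subtract
the buffer blank and set negatives to zero, leaving missing cells missing.
Line-scan profiles are min–max normalized onto $[0,1]$ with exact
endpoints; constant profiles are an error.

## Ratiometric pH

The calibration model is a four-parameter logistic in base 10,

$$R(\mathrm{pH}) = R_\mathrm{acid} +
  \frac{R_\mathrm{base} - R_\mathrm{acid}}
       {1 + 10^{\,k\,(\mathrm{pH}_{50} - \mathrm{pH})}},$$

fitted by bounded nonlinear least squares from standards spanning the
transition (the motivating protocol uses pH 6.5–9.0 in 0.5 steps). The
source protocol says only "logistic function"; this parameterisation is the
declared choice because it admits the closed-form inversion

$$\mathrm{pH} = \mathrm{pH}_{50} - \frac{1}{k}\,
  \log_{10}\!\Bigl(\frac{R_\mathrm{base} - R_\mathrm{acid}}
                        {R - R_\mathrm{acid}} - 1\Bigr),$$

so measured ratios are solved exactly rather than numerically. Ratios at or
beyond the asymptotes are an out-of-range error — the calibration is never
extrapolated silently. Non-monotone calibration data are rejected.

Dilute-phase (background) ROIs within one image are averaged to a single
ratio *before* inversion — one pH per image — while dense-phase ROIs are
inverted individually; because the inversion is nonlinear the two orders
differ, and a regression test pins the implemented order. Calibrations are
fitted per condition (e.g. per Zn²⁺ level) and never pooled.

## What the generators emulate — and what they do not

The configuration generator builds pseudo-atom peptides: one Cα per residue
on a 3.8 Å self-avoiding random walk (2.0 Å minimum separation), two
imidazole nitrogens on each His, water as single oxygen points. Condensed
mode packs every peptide atom inside a stated sphere — with enough inward
margin that the solvent-accessible boundary stays inside the truth sphere —
and records exact inside/outside water counts; dispersed mode scatters
chains through the box. The collapse generator grows chains once and
contracts chain centroids radially (rigid conformations) so the confinement
radius interpolates linearly; collapse degrees on its output must be
non-decreasing within SASA sampling tolerance. Defaults mirror the
motivating simulation scale where one exists: 20 chains in a 12.7 nm cubic
box is the ~16 mM bookkeeping check, the kinetics substrate window is
0.3–1.1 mM, the calibration pH grid is 6.5–9.0 in 0.5 steps, and the
dense/dilute pH scenario uses 10.8 vs 7.7.

These generators validate *algorithms*, not physics: there is no force
field, no solvent structure, no Zn²⁺ coordination chemistry, no real
photophysics. Passing tests demonstrate that the computations are correct
on inputs whose answer is known — not that a particular wet-lab or MD
result is reproduced. Quantities that derive from quantum chemistry or
400 ns all-atom trajectories (free-energy barriers, absolute rate
constants, measured half-times) are out of scope by design.

## Numerical choices and problem sizes

Degenerate inputs fail loudly everywhere: zero SASA selections, percolating
clusters, constant line scans, zero calibration slopes, asymptote ratios,
non-monotone calibration data, undefined half times. Ties in the
largest-cluster choice resolve deterministically (chain count, atom count,
lowest chain id). Seeds make every generator byte-reproducible.

The shipped analyses and checks run at deliberately desk-scale sizes — a
40-chain × 40-residue condensate with 400 waters in a 70 Å box on a 1 Å
grid, 5-frame collapse series of 8 × 10-residue chains, 100-seed FRAP and
200-seed pH noise studies — chosen so the whole suite completes in well
under a minute of compute while still exercising every code path at
realistic densities (the condensate packs ~0.037 atoms/Å³, enough that the
solvent-accessible boundary is watertight).

## Known limitations

- Orthorhombic boxes only; no triclinic cells.
- The boundary operation assumes a single dominant cluster; percolating
  (box-spanning) condensates are rejected, not analysed.
- SASA point sampling makes collapse degrees stochastic at the ~0.1 %
  level; tests and documentation carry explicit tolerances.
- The PDB writer truncates chain ids to one character (format limit).
- FRAP channel simulation covers full-bleach experiments ($b = a$); the
  fitting side handles partial bleaches, but no generator produces them.
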