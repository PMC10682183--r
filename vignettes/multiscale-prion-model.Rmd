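---
title: "A multiscale model of amyloid prion propagation in growing yeast colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of amyloid prion propagation in growing yeast colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioncolony)
```

Yeast prions such as [PSI+], [URE3] and [PIN+] are epigenetic elements
carried by amyloid forms of cytosolic proteins.  They propagate not through
the genome but through the cytoplasm: fibrils grow by monomer addition, are
fragmented into new propagons by the chaperone machinery, and are shared —
often unequally — between mother and bud at cell division.  Whether a
lineage keeps or loses ("cures") the prion therefore depends jointly on
single-cell chemical kinetics and on the population structure of the growing
colony.  `prioncolony` couples the two scales explicitly: a stochastic
lattice model of colony growth carries, inside every cell, a deterministic
chemical model of amyloid kinetics, and the two communicate at cell
division.

## The particle layer: colony growth on a lattice

Cells live on a square lattice whose segment side is the daughter diameter
`2 R_D = 2.5` micrometres.  A daughter is a sphere occupying one segment; a
mature mother is a rectangular solid of aspect ratio 2 (5.0 x 2.5 x 2.5
micrometres) occupying a 1 x 2 domino.  Two transitions drive the life
cycle: a mother budding a daughter, and a daughter expanding into a mother.
Each is governed by a time constant `tau` and a minimum delay `delta`,
through the survival law `S(t) = exp(-ln 2 (t - delta)/tau)` in the stage
age `t`.

The scheduler tests each eligible cell once per coarse interval `dt'`
(default 20 min).  We use the *conditional* per-interval probability
`1 - S(t + dt')/S(t)`, which is the hazard-consistent discretisation of the
survival law: once the delay has passed the per-interval hazard is the
constant `1 - exp(-ln 2 dt'/tau)`, so waiting times are geometric and
independent of how the interval grid is laid down.  The primitive absolute
rule (a uniform draw against `S(t)` itself) is exposed as
`temporal_test()`; the scheduler's form is `interval_hazard()`.  A cell
whose temporal test fails simply re-tests next interval with its
accumulated stage age — nothing is reset by failure.

Where a transition succeeds temporally, space must be found.  A mother
offers a bud at one of six plane-adjacent sites (two off each long side,
one off each end); a daughter expands into one of four axis neighbours.
Sites are tried in random order without replacement.  Occupied sites can be
freed by pushing the obstructing chain of cells one segment outward along
the axis from the growing cell through the site; the push is priced by the
Metropolis-like factor `exp(-dE*)` with `dE* = 2 epsilon R_D N`, where `N`
counts the obstructing segments on the cheaper of the two opposing
directions and `epsilon` is the confluence energy per unit length.  We
price the *minimum* of the two directional counts (the physically sensible
Metropolis move — push the cheaper side); a `max` variant is kept as an
`obstruction_rule` switch for sensitivity work.  Displacement moves whole
cells, so mother dominoes stay intact; a push that cannot complete inside
the plate makes that direction infinitely expensive.  With
`epsilon = 1e12 m^-1` any push is effectively forbidden and the colony
grows only at its free edge (confluent growth); with `epsilon = 1e5 m^-1` a
single-segment push costs `dE* = 0.25` and interior growth is common.

Heritable variability enters through the time constants.  Each new
generation draws a perturbation `g ~ Normal(A_av, sigma_A^2)` and uses
`tau(G) = (1 + g) tau(0)`; across generations `A_av` performs a random walk
with step s.d. `sigma_B` and `sigma_A` evolves multiplicatively by
`|1 + b|`.  The absolute value is our choice: the printed recursion can
produce a negative standard deviation when the draw falls below -1, and a
standard deviation must be non-negative.  A clamp at `1e-3 tau(0)` keeps
inherited time constants positive.  The random-walk consequence
`Var[A_av(G)] = (G - 1) sigma_B^2` is verified by simulation in the test
suite.  One perturbation is drawn per transition constant (the two
constants of a daughter are perturbed independently); the model text does
not fix this, and the shared-draw variant would only correlate the two
constants within a cell.

Cell death is optional: a cell dies at the first epoch at which its
replicative age has reached `max_replicative_age`, or when its
chronological age exceeds `max_chronological_age`.  Both default to
unbounded.

## The chemical layer: amyloid kinetics inside each cell

Five concentrations are tracked per cell: free monomer `C_M`, single-fibril
number `C_A1` and mass `C_MA1` (monomer units), and clumped-fiber number
`C_A2` and mass `C_MA2`.  Mean sizes are `<i_A1> = C_MA1/C_A1` and
`<i_A2> = C_MA2/C_A2`; below a positivity floor of `1e-30 M` in the number
concentration the mean is treated as zero, which avoids 0/0 without
perturbing any realistic trajectory.  Monomer is produced from an
amino-acid pool that shrinks with amyloid load,
`C_AA = C_AA_basal (1 - psi S/(Omega + S))`, `S = C_MA1 + C_MA2` — a
saturating self-limitation standing in for the metabolic burden of the
aggregate.

Two mechanism variants are implemented.  *Standard breakage* treats
nucleation (nucleus size fixed at 2), elongation, endwise monomer loss,
end-to-end joining, internal breakage (at the endwise rate) and lateral
clumping; clumped fibers never fragment or shed monomer but elongate at
both exposed ends.  *Munching* allows the internal breakage rate `b_A1` to
differ from the endwise rate `b_G` (preferential endwise depolymerisation
when `b_G > b_A1`, enhanced internal scission when `b_A1 > b_G`); it is
limited to single filaments.  Its nucleus-concentration estimate assumes an
exponential fibril length distribution with decay constant
`k = 1/(<i_A1> - 2)`; we take the normalising geometric sum in closed form
over all lengths from the dimer up, giving `C_2 = C_A1 (1 - e^{-k})`, and
set `C_2 = C_A1` when the mean size is at the dimer floor.  The nucleus
dissociation rate `b_N` is carried in the configuration but aliased to
`b_G` inside both derivative functions, per the model's stated assumption.

The two variants use slightly different bookkeeping for fiber joining (a
factor of two in the `C_A1` sink).  We implement each equation set exactly
as written; consequently the munching equations reduce to the standard ones
only for single filaments *without* joining (`f_A1 = 0`) when
`b_A1 = b_G`, and that is the regime in which the equivalence is asserted
in the tests.  A related caveat: the breakage bookkeeping term
`b_G (C_MA1 - 3 C_A1)` can transiently drive `C_A1` negative when
`<i_A1> < 3`; the integrator clamps negative excursions to zero, and the
clamp is exercised only in that start-up regime.

Integration uses a fixed-step modified-midpoint (midpoint Runge–Kutta)
scheme: two derivative evaluations per fine step, no adaptive control.
Correctness is anchored externally — against an independent plain-R Euler
integrator transcribed directly from the printed equations (agreement to
`1e-6` relative at a 100-fold step refinement over a 5 s window, where the
first-order oracle's own bias stays below the tolerance) and by Richardson
step-halving (observed order at least 2).  Mass balance
`d(C_M + C_MA1 + C_MA2)/dt = f_M C_AA - b_M C_M` is an algebraic identity
of the rate vector, so any Runge–Kutta step satisfies it to round-off; the
tests assert residuals below `1e-12 M/s` along whole trajectories.

## Coupling: volume change and partition

Each coarse interval runs the particle step first, then advances every
cell's chemistry through `n_steps` fine steps (default 1200, i.e. a 1 s
fine step for the 20 min coarse interval — comfortably inside the
stability region of the fastest default rates, `0.05 s^-1` for elongation
at steady-state monomer and `1 s^-1` for partition).  Cells of fixed
geometry integrate in place.  Growing cells (a bud inflating over its
budding interval; a daughter maturing into a mother) follow a linear volume
trajectory; each fine step first rescales concentrations by
`V(t)/V(t + dt)` — which conserves amounts exactly — and then applies the
reaction step at the new concentration scale.

While the septum is open (exactly the one coarse interval of bud growth),
mother (alpha) and bud (beta) exchange material by first-order partition
with per-class constants `k_ab`, `k_ba` for monomer, single fibrils
(number and mass move together) and clumps.  The mother-side source term
carries the volume factor `V_beta/V_alpha`, which is precisely what makes
`C_alpha V_alpha + C_beta V_beta` invariant under the exchange; the tests
verify this identity to round-off.  The fine-step operator order is
dilution, reaction, partition — all first-order splits whose composite
error is second-order in the fine step and covered by the oracle
tolerance.  The bud starts at 5% of the daughter volume (not zero, so the
volume ratio and the dilution factor are finite at the first fine step)
with all concentrations zero, and is filled by partition alone; its own
monomer production switches on only after septum closure.  This is the
conservative reading of a point the model leaves open — whether a nascent
bud synthesises protein — and it slightly delays, never inflates, the
bud's chemical inheritance.  At septum closure the bud becomes an
independent daughter, the mother's replicative age increments and both
stage clocks reset.

These choices reproduce the characteristic single-cell signatures: a
concentration spike in the nascent bud at budding (material partitioned
into a still-small volume), dilution during the daughter-to-mother volume
growth, and recovery toward the fixed-volume pseudo-equilibrium
afterwards.

## Phenotype and analysis

The red/white colony screen is modelled as a gamma transform of free
monomer between `C_M_min` (white, RGB 255/255/255) and `C_M_max` (red,
RGB 255/0/0): `G = B = round(255 (1 - x^gamma))` with the clipped fraction
`x`, rounding half away from zero (the rounding rule is ours; the model
does not state one).  The default `C_M_max` is the aggregation-free steady
state `f_M C_AA_basal / b_M`, so an amyloid-free cell is fully red.  The
binary prion classifier accepts five markers; for the amyloid markers
(`C_MA1`, `N_A1`, `C_MA2`, `N_A2`) a cell is prion-positive at or above
the threshold, while for `C_M` the inequality is reversed — low free
monomer indicates sequestration into prion, which is how the colour assay
itself reads.

Analyses are pure functions of the exported tables: dplyr-style census
queries (`query_cells()`), one- and two-dimensional histograms, backward
lineage maps, forward fate maps (with newick export for tree viewers) and
curing curves by generation.  Displacement histograms measure each cell
from the unweighted centre of all occupied segments, normalised by `R_D`;
curing curves are computed on the final census by default, and living
cells only are counted (the model is silent on dead cells; including them
would mix death with curing).

## Scenario presets and what the defaults emulate

The preset system encodes the documented parameter sets: three fixed-volume
kinetic regimes (`fig4A` standard breakage, `fig4B` munching, `fig4C`
clumping; common constants `f_M = b_M = 0.01 s^-1`, `f_N = 1e-3`,
`C_AA_basal = Omega = 1e-7 M`, `psi = 0.95`, initial `C_M = 1e-7 M`),
confluent vs non-confluent 700-min colony growth (`fig7_*`, growth
constants `tau = 20 min` for both transitions, `delta` of 50 and 0 min),
the lineage-mapping run (`fig8`), three 900-min curing experiments
(`fig9A` blocked amyloid partition, `fig9B` limited partition
`k_A1,ab = 0.0065 s^-1`, `fig9C` clumping with `f_A2 = 5e4`,
`b_A2 = 0.001`) and the fragmentation-off curing-curve run
(`fig10_guhcl`: all breakage and nucleation off, a preformed seed of
`C_A1 = 1e-7 M` at mean size 5 diluting through the pedigree).  Where the
figure captions print a value, the preset uses it; beaker-mode horizons
(not printed) default to 500 min, and the plate is a 201 x 201-segment
square, large enough that no documented run touches its boundary.

The generator emulates monolayer growth under a coverslip: a single
founder, discrete segment geometry, division completed within one coarse
interval.  It does not emulate continuous cell sizes, slow mother
enlargement, nutrient fields, quorum sensing or three-dimensional
colonies, so passing tests say nothing about those aspects of real
colonies; they do validate the transition statistics, the conservation
structure of the chemistry and partition, and the qualitative curing
phenomenology.

## Numerical and design notes

* Units: minutes at the particle layer, seconds at the chemical layer
  (converted at the coupling boundary), molar concentrations, micrometre
  geometry.  Absolute particle numbers use Avogadro's number with
  `1 um^3 = 1e-15 L`.
* Mother volume `5 x 2.5 x 2.5 = 31.25 um^3`; daughter
  `(4/3) pi 1.25^3 = 8.18 um^3`.  The model prints shapes, not volumes.
* Determinism: a configuration plus seed reproduces byte-identical CSV
  exports; all randomness flows through R's RNG (the C++ kernel is
  deterministic).
* Test problem sizes: stochastic laws at `1e4`–`1e5` draws, the
  branching-process cross-check at 120 colony replicates against 2000
  oracle replicates, conservation runs over full 700-min colonies.  These
  sizes put Monte-Carlo error well below the asserted tolerances while the
  full suite stays fast.
* Known limitations: the lattice admits several layouts of the six bud
  sites (only the count is constrained; ours is documented in
  `candidate_bud_sites()`); partition constants are per species class, so
  fibril number and mass migrate together, i.e. partition does not sort
  fibrils by size; and clump composition is tracked only in moment form.
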