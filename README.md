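# prioncolony

Multiscale simulation of amyloid prion propagation in growing
budding-yeast colonies.

Yeast prions ([PSI+], [URE3], [PIN+], ...) are epigenetic elements carried
by self-templating amyloid fibrils in the cytosol.  Their fate in a colony
is decided by processes on two very different scales: inside each cell,
fibrils nucleate, elongate, fragment and clump on a chemical clock of
seconds; between cells, prions are handed from mother to bud at each
division and diluted through the pedigree on a clock of hours.
`prioncolony` is a tool for yeast and amyloid biologists who want to
simulate that coupling explicitly — for example to ask how a curing curve
(the fraction of prion-negative cells per generation) responds to blocked
partition, reduced fragmentation (the GuHCl/Hsp104 experiment) or fibril
clumping.

## The model in brief

**Particle layer.**  Cells occupy a square lattice (segment side
2·R_D = 2.5 μm): daughters are spheres on one segment, mothers are 1×2
dominoes.  The two life-cycle transitions M → M + D and D → M are
stochastic first-order processes with delay, survival
S(t) = exp(−ln2·(t−δ)/τ).  Spatial feasibility is decided by a
Metropolis-like confluence test, P = exp(−ΔE*) with ΔE* = 2·ε·R_D·min(N⊥, N⊤),
where N counts the obstructing segments that must be displaced; ε switches
the colony between edge-only (confluent) and interior growth.  Division
time constants are heritable with generation-wise evolving variability
(A_av random walk, multiplicative σ_A, step σ_B).

**Chemical layer.**  Per cell, five concentrations
(C_M, C_A1, C_MA1, C_A2, C_MA2) evolve under nucleated-polymerisation
kinetics (nucleus size 2) with monomer production from a self-limiting
amino-acid pool C_AA = C_AA_basal·(1 − ψ·S/(Ω+S)).  Two mechanisms are
available: standard breakage (with optional end-to-end joining and lateral
clumping) and position-dependent "munching" (b_A1 ≠ b_G).  Integration is
fixed-step modified midpoint on a fine clock (default 1 s).

**Coupling.**  While the septum is open, mother (α) and bud (β) exchange
every species class by first-order partition,
α-side flux (V_β/V_α)·(−k_ab·C_α + k_ba·C_β), which conserves moles
exactly; growing cells are diluted along a linear volume trajectory.  A
gamma-transform colour map turns free monomer into the red/white colony
screen, and a binary classifier (markers C_M, C_MA1, N_A1, C_MA2, N_A2)
produces curing curves.

## Worked example: a fragmentation-off curing experiment

The `fig10_guhcl` preset starts one mother carrying a preformed amyloid
seed (C_A1 = 1×10⁻⁷ M, mean size 5) with nucleation and all breakage
switched off — the situation created by guanidine-HCl inhibition of
Hsp104.  Fibrils can only elongate and be diluted through the pedigree:

```r
library(prioncolony)
sim <- run_simulation("fig10_guhcl", seed = 1)
glance(sim)
#> # A tibble: 1 x 7
#>   clock_min n_cells n_total_ever max_generation total_N_A1 total_N_A2
#>       <dbl>   <int>        <int>          <int>      <dbl>      <dbl>
#> 1       900      92           92              8      1882.          0

curing_curve(sim, colour_params(marker = "N_A1", classifier_threshold = 1))
#>   generation n_cells n_cured fraction_cured
#> 1          1       1       0              0
#> 2          2       5       0              0
#> 3          3       9       0              0
#> 4          4      14       0              0
#> 5          5      20       0              0
#> 6          6      21      21              1
#> 7          7      18      18              1
#> 8          8       4       4              1
```

After 900 minutes the colony holds 92 cells in 8 generations.  The total
fibril count (1882 — exactly the founder's seed, N = C_A1·V·N_Avogadro) is
conserved because nothing fragments, but per-cell numbers halve-ish at
each division: generations 6–8 have fallen below one particle per cell and
are classified cured, the canonical GuHCl curing curve.  `plot_colony(sim)`
draws the red/white plate image, `lineage_of(sim, k)` /
`fate_of(sim, k)` give backward and forward maps with the per-cell
chemical series, and `autoplot()` works on all of them.

Other presets: `fig4A/B/C` (single-cell kinetics under breakage, munching
and clumping; see `beaker_run()`), `fig7_confluent` /
`fig7_nonconfluent` (growth-pattern comparison), `fig8` (lineage mapping
with free partition), `fig9A/B/C` (curing by blocked partition, limited
partition, clumping).  `make_scenario()` documents all of them;
configurations round-trip through JSON/YAML via `write_scenario()` /
`read_scenario()`.

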