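# silicabrush

Coarse-grained Brownian-dynamics modelling of how grafted DNA brushes steer
silica-precursor condensation on six-helix-bundle (6HB) DNA origami, plus
the worm-like-chain analysis used to quantify bundle stiffening.

## The problem

Sol-gel silicification coats DNA origami with silica: a cationic silane
(TMAPS) adsorbs to the polyanionic DNA and co-condenses with TEOS.  Grafting
DNA brushes onto the origami changes where the shell grows — double-stranded
(DS) brushes promote much stronger condensation on the brush-carrying
regions than flexible, weakly charged single-stranded (SS) polythymine
brushes.  `silicabrush` asks whether generic polyelectrolyte physics alone —
chain stiffness and linear charge density — reproduces that contrast, using
a model with no reaction chemistry: a rigid 6HB template, bead-spring
brushes, +1 precursor beads, and three interactions (in units of the
thermal energy k_BT, lengths in nm):

* WCA excluded volume between all beads;
* screened electrostatics `U = ℓ_B q_i q_j exp(−r/λ_D)/r`, with Bjerrum
  length ℓ_B = 0.71 nm and Debye length λ_D set by the salt
  (λ_D = 0.304/√I nm; 2.48 nm in the 5 mM MgCl₂ working buffer);
* one short-range attractive well (depth ε_att, the single calibrated
  constant) between precursors and every DNA species alike.

SS and DS brushes differ only in bead mapping: SS — 3 nt/bead, −0.75 e,
freely jointed; DS — 3 bp/bead, −1.5 e, bending constant chosen for a
~50 nm persistence length.  Charges are Manning-renormalised effective
values.  The analyses mirror the source study: regional condensation
densities and brush-over-bare enhancement, brush residence times, radial
brush charge profiles, probe electrostatic-energy scans, Mg²⁺ screening
sweeps, and a tangent-correlation worm-like-chain estimator
(⟨cos θ(s)⟩ = e^(−s/2L_p) in 2D) with bootstrap errors.

## Worked example

Parse a brush layout, build the coarse-grained system, run a trajectory and
analyse condensation:

```r
library(silicabrush)

spec <- parse_layout("6HB-5*/17/5*-DS")
spec
#> <brush_layout> 6HB-5*/17/5*-DS  (27 domains, kind DS, density factor 1)
nrow(enumerate_graft_sites(parse_layout("6HB-27*-SS"), 400))
#> [1] 162

cfg <- default_config()        # scaled-down 9-domain study system
sys <- build_study_system("DS", seed = 1, config = cfg)
sys$topo
#> <cg_topology> 1136 beads | 288 bonds | 240 angles
#>    CORE:798  DS_BEAD:288  PRECURSOR:50
#>    box 54.0 x 54.0 x 90.0 nm (REFLECTING/REFLECTING/PERIODIC)

r <- run_condensation_experiment("DS", seed = 1, config = cfg)
r$condensation
#> <regional_condensation> rho_brush 0.1470 /nm, rho_bare 0.1534 /nm, enhancement -4.2%
```

`rho_brush` and `rho_bare` are condensed precursors per nm of bundle in the
brush-grafted and bare regions, averaged over the last half of the
trajectory; the enhancement is their percent excess.  A single seed is
very noisy (this one happens to land slightly negative; per-seed values
scatter over tens of percentage points) — `condensation_study()` runs
several seeds and reports the pooled-density enhancement with a jackknife
standard error, which is the statistic the package quotes.

The worm-like-chain toolkit validates itself by parameter recovery:

```r
chains <- lapply(1:30, function(i) generate_wlc(555, 1000, 10, seed = i))
estimate_lp(chains)
#> <wlc_fit> L_p = 635.2 +/- 69.8 nm (2D convention, 30 contours)
```

A thin command-line interface (`inst/cli/silicabrush`) exposes `build`,
`simulate`, `analyze`, `sweep` and `wlc` subcommands over the same
functions; every run writes a provenance JSON (config hash, seed, package
version).

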