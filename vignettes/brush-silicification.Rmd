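---
title: "Coarse-grained modelling of DNA-brush-directed silica condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of DNA-brush-directed silica condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model addresses

Silica can be grown on DNA origami through sol-gel (Stöber) chemistry: a
cationic silane (TMAPS) adsorbs to the polyanionic DNA backbone and
co-condenses with a silica source (TEOS).  Grafting long DNA brushes onto a
six-helix-bundle (6HB) origami changes where and how fast this shell grows.
Experimentally, double-stranded (DS) brushes promote markedly stronger
silicification of the brush-carrying regions than single-stranded (SS)
polythymine brushes.  `silicabrush` implements a coarse-grained
Brownian-dynamics model of this system to ask whether generic
polyelectrolyte physics — chain stiffness and linear charge density, with
no chemical specificity — is sufficient to reproduce that contrast.

The model deliberately contains no reaction chemistry.  "Condensation" is
defined geometrically (a precursor sitting within a cutoff of the bundle
surface), and the TMAPS/TEOS pair is represented by a single +1 spherical
precursor particle.  Everything the model can show is therefore about
capture, retention and spatial bias of precursors, not about siloxane
network formation.

## Model components

**Rigid 6HB core.**  Six straight strings of fixed beads whose centres lie
on a 2-nm ring, one bead per 0.68 nm (2 bp), each carrying −1 e.  With a
1-nm helix radius the envelope diameter is the theoretical 6 nm.  The core
is never integrated: snapshots of silicified bundles show an undeformed
rod, so treating the origami as a rigid template removes its (irrelevant
and expensive) internal dynamics.  The −1 e per 2 bp is a
Manning-renormalised effective charge: bare B-DNA carries one phosphate
per 0.17 nm per strand, far above the condensation threshold, and the
renormalised line density is approximately one elementary charge per
Bjerrum length (0.71 nm), i.e. ~1 e per 0.68-nm bead.

**Brush chains.**  Bead-spring chains grafted to the core bead nearest to
their layout site, pointing radially outward at build time:

| parameter | SS brush | DS brush |
|---|---|---|
| mapping | 3 nt / bead | 3 bp / bead |
| bond length | 1.5 nm | 1.0 nm |
| bead radius | 0.4 nm | 0.5 nm |
| bead charge | −0.75 e | −1.5 e |
| bending constant | 0 (freely jointed) | 50 kBT/rad² |
| implied persistence length | ~bond length | ~50 nm |

The DS bending constant follows the discrete worm-like-chain relation
L_p ≈ κ·b; the test suite verifies that equilibrated DS chains measured
with the package's own tangent-correlation estimator reach ~50 nm.  The DS
bead radius is 0.5 nm — a thin-rod representation rather than the full
1-nm duplex radius — because overlapping large spheres on 1-nm bonds
create pathologically stiff 1-4 excluded-volume contacts; the charge line
density (1.5 e/nm vs 0.5 e/nm for SS), which carries the mechanism, is
unaffected.  Bonded neighbours (1-2) and next neighbours (1-3) are
excluded from non-bonded interactions, as in standard bead-spring force
fields.

**Precursors and salt.**  Precursors are 0.5-nm-radius, +1 e beads placed
uniformly in the box.  Salt is implicit by default: it only sets the Debye
length.  The reference condition is the silicification working buffer —
5 mM Mg²⁺ as chloride, ionic strength 15 mM — giving
λ_D = 0.304/√0.015 = 2.48 nm.  An explicit-ion mode
(divalent beads plus neutralising monovalent ions) exists for the Mg²⁺
competition mechanism but is not the default: at desk scale the implicit
treatment is orders of magnitude cheaper and captures the screening trend.

**Interactions.**  All energies are in kBT:

* WCA excluded volume between every pair, σ = sum of radii, ε = 1.
* Debye–Hückel screened Coulomb `ℓ_B q_i q_j exp(−r/λ_D)/r` between
  charged pairs, energy-shifted to zero at the 6-nm cutoff.
* A short-range attractive well between precursors and DNA beads only:
  the attractive branch of a Lennard-Jones potential, flat at depth
  ε_att inside its minimum and energy-shifted to zero at 3.5 nm.  This is
  the effective stand-in for TMAPS adsorption chemistry.  One scalar
  applies to core, SS and DS beads alike, so any difference between brush
  kinds must emerge from charge and geometry.

Energy-shifting makes the energy exactly continuous at the cutoffs; the
residual force discontinuity there is O(10⁻³) kBT/nm, far below the
thermal force scale, and is accepted in exchange for keeping the pair
energy the exact closed form plus a constant.

**ε_att calibration.**  ε_att is the model's one fitted constant.  It was
tuned once against the ~54% DS regional condensation enhancement and then
held fixed for every other analysis (SS system, retention ratio, energy
scans, Mg²⁺ sweeps).  The frozen value is 0.45 kBT.  The response of the
DS enhancement to ε_att is strongly nonlinear: below ~0.4 kBT the brush
canopy captures precursors without delivering them to the surface and the
enhancement turns negative (sequestration), while from 0.45 to 1 kBT it
sits on a high plateau whose multi-seed pooled values range from ~55% to
~110% — the ε_att dependence there is smaller than the seed-to-seed
spread, so the calibration can place the model at the foot of the plateau
but cannot pin the 54% value more tightly.  Across that whole range the
SS enhancement stays near ~0–14% (length-dependent; see the protocol
note), so the SS ≪ DS contrast is a genuine prediction, not a second
fit.  Per-seed enhancement values are heavy-tailed (seed standard
deviation ~40–60 percentage points, driven by slow precursor exchange
between regions), so multi-seed pooled densities with a jackknife error
are the quoted statistic, and five-seed means still carry a
±20–25-point sampling error.

## Dynamics

Overdamped position-Langevin (Brownian) dynamics at kBT = 1:

x ← x + (dt/γ) F + √(2 dt/γ) ξ,

with Stokes-like per-species friction γ proportional to bead radius
(γ = 1 for the 0.5-nm precursor defines the time unit τ).  Only
configurational statistics are analysed, so no velocities are carried.

Numerical choices, all config-exposed:

* **dt = 0.002 τ.**  The stiffest routine interactions (harmonic bonds at
  100 kBT/nm², WCA contacts under thermal compression) are stable at this
  step; dt = 0.005 was not.
* **Displacement clamp 0.5 nm.**  A bead's per-step displacement is capped
  at 0.5 nm (~3σ of the thermal noise for the fastest species).  Steep WCA
  contacts occasionally produce forces whose Euler step would overshoot;
  capping them prevents the overshoot-oscillation failure mode of
  overdamped Euler with hard potentials.  In production runs the clamp
  fires on ~2×10⁻⁵ of bead-steps, so equilibrium sampling is unaffected
  (the Boltzmann-distribution test in the suite runs with the clamp
  active).  Setting `clamp_disp = 0` recovers pure Euler–Maruyama with a
  hard instability error at 1 nm.
* **Verlet list, skin 1.5 nm**, rebuilt when any bead drifts more than
  half the skin; the cell-list pair set is validated against a brute-force
  oracle in the tests.
* **Boundaries.**  Reflecting walls in x/y, periodic in z: the bundle
  approximates an infinite rod segment and the precursor count is
  conserved.
* Randomness: build-time randomness flows through R's RNG, thermal noise
  through a Mersenne–Twister seeded per run; identical (system, seed)
  pairs give bit-identical trajectories on one thread.

## The desk-scale study system

The reference experiment is a scaled-down analogue of the end-modified
5*/17/5* bundle:

* 9 domains of 10 nm (layout `6HB-2*/5/2*`): 2 brush domains at each end,
  5 bare in the middle.  Brush fraction 4/9 vs 10/27 at full scale.
* Brushes of 12-nm contour (SS: 8 beads; DS: 12 beads) at every modified
  domain on all six helices — 24 chains.
* 50 precursors (~0.2 mM) in a 54 × 54 × 90 nm box (radial clearance =
  2 × brush contour).
* 150 000 steps (300 τ), frames every 750 steps; analyses use the last
  half, which is reported, not assumed converged — condensation still
  accumulates slowly there, as in the source data.  The length is the
  protocol's compromise between statistical maturity and keeping a
  ten-trajectory multi-seed study within minutes on one CPU; longer runs
  (500 τ) shift the SS enhancement up by roughly ten percentage points
  as the slower single-stranded funnel develops.

Full-scale geometry (27 domains, 400-nm bundle, 162 grafts, hundreds-of-
nucleotide brushes) is available through the same builders; the desk scale
keeps a multi-seed study within minutes per seed on one CPU.

## Analyses

* **Regional condensation** — a precursor is condensed when its *surface
  separation* from the nearest core bead is ≤ r_condense (1.5 nm ≈ one
  precursor diameter + the attraction well width).  Surface separation
  (centre distance minus both radii) rather than centre distance is used
  so one threshold is meaningful for all bead sizes; a centre-distance
  reading of the same number would sit inside the excluded volume and
  never fire.  Counts are assigned to BRUSH/BARE regions by the axial
  position of the nearest core bead (half-open intervals), converted to
  per-length densities so the unequal region lengths cancel, and
  summarised as the percent excess of the brush-region density.
* **Residence events** — contiguous frames with a precursor within
  r_near = 1.2 nm (surface separation) of a brush bead; excursions of up
  to 2 frames are bridged (the grace rule), since a precursor rattling at
  the canopy edge is chemically still "in" the brush.  The brush-kind
  comparison restricts events to canopy beads (≥ 6.5 nm from the bundle
  axis = envelope + attraction range): unrestricted events are dominated
  by precursors adsorbed at the core surface next to graft anchors, whose
  binding — core electrostatics plus the shared adhesion well — is
  identical for SS and DS and therefore measures the surface, not the
  brushes.
* **Radial charge profile** — brush charge binned by distance from the
  bundle axis, time-averaged; its unnormalised sum equals the total brush
  charge by construction.
* **Electrostatic scan** — a +1 probe at 0.5 nm from the core envelope,
  scanned axially and averaged over azimuths and ≥10 decorrelated frames;
  energy is the exact (uncut) screened-Coulomb sum over core and brush
  charges.  Mobile precursors and ions are excluded so the scan measures
  the DNA-generated field, not the instantaneous adsorbate layer.
* **Mg²⁺ sweep** — the implicit mode recomputes λ_D per level (5 mM →
  2.15 nm, 16 mM → 1.32 nm); stronger screening weakens the
  electrostatic funnel and lowers the condensed count.

## Worm-like-chain estimator

`generate_wlc()` draws tangent angles as a Gaussian walk with per-step
variance step/L_p (2D convention, ⟨cos θ(s)⟩ = exp(−s/2L_p)); the 3D
convention drops the factor 2.  `estimate_lp()` pools tangent correlations
over contours, fits log⟨cos θ⟩ against s through the origin up to half the
contour length, and bootstraps over contours for the standard error.  The
2D convention is the default because experimental contours come from
chains equilibrated on a surface (AFM).  Parameter-recovery tests cover
L_p ∈ {50, 500, 1000} nm and the 555 → 834 → 1054 nm stiffening ordering
observed for progressively thicker silica shells.  Equal-arc resampling
precedes fitting because traced contours have uneven spacing; chord-based
resampling leaves percent-level spacing variation on curved traces, which
is negligible against the fit's statistical error.

## What the synthetic systems do and do not emulate

The generator reproduces: the 6HB geometry and its brush layouts, the
SS/DS contrast as a pure stiffness + charge-density contrast at equal
contour length, precursor concentration and screening conditions, and
seeded stochasticity.  It does not emulate: silica network growth (no
precursor–precursor attraction by default; a config flag exists),
hybridisation kinetics, sequence effects, hydrodynamic interactions, or
the AFM imaging process.  Passing acceptance therefore supports the
electrostatic-mechanism story — capture, retention and a 2–3 kBT surface
energy bias — but says nothing about shell morphology or growth kinetics
in real chemistry.

## Where the parameterisation reaches its limits

Two observables are systematically smaller in this parameterisation than
the regime the experiments point to, and both trace to the same constant:
the Manning-renormalised brush charges.  With DS beads at −1.5 e/nm of
contour against SS at −0.5 e/nm, the extra well depth a precursor feels in
the DS canopy over the SS canopy is ~0.9–1.0 kBT, which caps the mean
canopy residence ratio near e^1 ≈ 2.5 (measured 1.5–2.0 across grace and
canopy-threshold settings, and ~1.2 without the canopy restriction).
Likewise the screened-Coulomb energy a surface probe gains from nearby DS
brush charge is ~1.2 kBT over the bare surface rather than 2–3 kBT.  Both
would grow roughly linearly with the brush line charge; bare
(unrenormalised) charges would overshoot in the other direction.  We
report the model's own values rather than re-tuning charges per
observable: the single calibrated constant remains the precursor–DNA
adhesion ε_att, and the regional-enhancement contrast (the primary
observable) is reproduced with it.

## Known limitations

* Condensation counts are small at desk scale (tens of precursors), so
  per-seed enhancement values are noisy; multi-seed means with seed
  standard errors are the quoted quantity, as in the acceptance checks.
* The last-half analysis window is not a converged steady state; the
  window is part of the reported protocol.
* Residence durations are right-censored by the finite trajectory; both
  brush kinds are censored alike, so the DS/SS ratio is bias-cancelling to
  first order.
* The displacement clamp is a pragmatic stabiliser; it is inactive in all
  property tests that probe equilibrium statistics, except through its
  ~10⁻⁵ activation rate.
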