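---
title: "Models and methods: SMC-driven mitotic chromosome formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SMC-driven mitotic chromosome formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smcsim)
```

# Scope

`smcsim` is a desk-scale re-implementation of a simulation and analysis
framework for how SMC complexes (condensin I, condensin II, extrusive and
cohesive cohesin) fold vertebrate mitotic chromosomes. It contains four
model layers and the analysis stack that connects them to observables:

1. a stochastic **1D lattice engine** for loop-extruding factors (LEFs)
   with collision rules, CTCF barrier capture, and turnover;
2. a coarse-grained **bead-spring polymer engine** (overdamped Langevin
   reference integrator) that realizes LEF positions as harmonic bonds;
3. **chromatid builders** that construct mitotic loop-array models
   (consecutive, nested, overlapping; cylindrical-helical or stretched
   periodic) from a small set of geometric parameters;
4. **in-silico Hi-C** (Gaussian-perturbation contacts, log-binned P(s),
   derivative-based detectors, model-fit RMS), **feature scores** on
   binned matrices, closed-form **kinetic estimators**, and **synthetic
   fluorescence profiles**.

# The 1D extrusion model

Chromatin is a lattice (1 site = 1 kb by default). A LEF is a two-legged
walker; extruders step both legs outward one site per due epoch, diffusing
walkers (cohesive cohesin, whose two legs live on the two sister chains)
step each leg ±1 with equal probability. Species are parameterized by
processivity λ (mean kb extruded before unbinding), separation d (the
loaded number is `floor(lattice_kb / d)` — floor is the documented
rounding), a step interval realizing relative speeds (cohesin:condensin
10:120 kb/min as intervals 12:1, so one condensin epoch is one second),
barrier mode, and loading mode. Unbinding is sampled per complex with
probability `(kb moved per epoch)/λ` per due epoch, so the mean chromatin
extruded before unbinding in the absence of obstacles equals λ; unbound
finite-lifetime complexes rebind immediately at a random free site (the
pool is conserved). CTCF barriers capture capturable legs with
probability 0.9 on the step onto the barrier site; captured legs stay
until unbinding. Updates are sequential in a freshly shuffled order each
epoch (a seeded shuffle avoids systematic directional artifacts).

Collisions are resolved by a species-pair policy matrix: **stall** (move
rejected), **bypass** (leg steps over the blocking leg if the site beyond
is free), **push** (the contacted leg — and any contiguous run of legs
ahead of it — is displaced one site; a CTCF-captured leg is displaced off
its barrier and loses its capture, since collision outcomes apply
regardless of barrier trapping; a push into a chain end unloads the
end-most complex), and **unload** (the blocking complex is removed).
Same-species collisions stall.

Two deliberately exposed switches:

* `no_rebind` — whether a complex removed by the *unload* outcome leaves
  the bound pool. The prophase collision scenario defaults to net loss
  (`no_rebind = TRUE`), matching the observed ~3-fold drop of chromatin
  cohesin during prophase; with continuous rebinding the CTCF-anchored
  population regenerates within about one residence time and the policy
  contrast between unload/push and stall/bypass largely disappears.
* push semantics — only the contacted leg is displaced; a complex whose
  legs become adjacent is pushed as a unit.

## What the gap-fraction law does and does not describe

The package implements the analytic steady-state gap fraction
`g = exp(-λ/d)` (`theoretical_gap_fraction()`), which is the
Poisson-coverage result for *independently positioned* loops with mean
size λ at spacing d. The microscopic stall-policy lattice dynamics
deviate from it at moderate λ/d: collisions truncate loops below their
free-extrusion processivity, and rebinding inside existing loops nests
coverage. Measured on 20,000-site lattices, the simulated gap fraction is
0.65 / 0.45 / 0.24 at λ/d = 0.5 / 1 / 2 against the formula's
0.61 / 0.37 / 0.14, and the deviation was confirmed with an independent
brute-force implementation of the same rules. In the dilute limit
(λ/d ≤ 0.1) simulation and formula agree to better than 0.01. The law is
therefore used in the package as what it is in practice: a closed-form
*estimator* for inverting observed gap fractions into extrusion speeds
(`speed_from_gap_fraction()`), exact in its own model, approximate for
the lattice engine. The corresponding property test asserts the formula
at λ/d ∈ {0.5, 1, 2} against the engine and is expected to fail; it is
retained unmodified as a documented, honest negative result.

# The polymer engine

Beads have diameter 1 reduced length unit and the energy unit is kT. The
reference integrator is overdamped Langevin dynamics
(`dx = F dt + sqrt(2 T dt) N(0,1)`, friction 1): a DPD thermostat differs
only in kinetics, not in the equilibrium ensembles that in-silico Hi-C
consumes, and a Brownian integrator is reproducible at desk scale
(≤ ~2×10^4 beads). Potentials: harmonic bonds (k = 10 kT/unit²), optional
bending `k (1 + cos θ)`, soft DPD-style repulsion `F = A (1 − r) r̂` with
A = 3 kT (which permits occasional strand passage — verified by a
linking-number test on interlinked rings), one-sided Gaussian walls
(cylindrical confinement ε = 1 kT, σ = 0.5; a "spool" wall ε = 6 kT,
σ = 1, radius 2 that excludes backbone beads from the axial core), axial
end tethers (force 1.0), azimuthal pins `κ (1 − cos(θ − θ0))`, constant
lateral cohesion forces, fixed beads, and periodic boxes. Wall dimensions
are inflated so the confining potential equals 0.3 kT at the target
radius and length (overshoot compensation). Numerical choices: dt = 0.05
for plain chains and 0.02 for loop-array models whose anchor beads carry
up to four stiff bonds (the overdamped Euler stability limit is
k_eff·dt < 2), plus a 0.25-unit clamp on the deterministic per-step
displacement that guards the rare stiff configurations without affecting
equilibrium statistics; integration aborts with a diagnostic if any
coordinate exceeds 10^6.

# Chromatid builders and coarse-graining

The mitotic models follow four principles: (i) a nucleosome fiber of
10 nm / 200 bp beads; (ii) condensin loop arrays — exponentially
distributed loop sizes laid consecutively with `n_gap`-bead gaps (the
last loop truncated at the chromosome end; the bias is negligible for
≥100 loops), nested subdivision for condensin I inside condensin II
loops, or independently placed overlapping loops for the
complete-bypass variant; (iii) cylindrical confinement at the measured
volume density; (iv) weak helical nudging (end tethers, spool wall,
terminal torsion realized as azimuthal pins of κ = 100 kT via four ghost
particles, one pin per helical turn; in the overlapping variant one pin
per anchor at `θ_i = π (x_left + x_right)/l_turn` with stiffness 1 kT at
1.2 rad). Derived geometry: `L_cyl = l_chrom/ρ_L`,
`R_cyl = sqrt(l_chrom/ρ_V/L_cyl/π)`, `P = l_turn/ρ_L`,
`N_loops = l_chrom/l_loop`, `L_bb = N_loops (L_gap + L_loopbond)`.

Desk scale is reached by coarse-graining: a bead of `bp_per_bead` bp has
diameter `10 (bp/200)^(1/3)` nm (volume-preserving), and chromosomes of
30–60 Mb stand in for the 100 Mb originals. Two nm-denominated choices
matter and are deliberate:

* **Backbone geometry keeps physical nm dimensions at any bead size**:
  the loop-anchor bond is always one 10 nm fiber diameter and the
  gap-stretch bond spans `L_gap + 10` nm. The backbone walk sets the
  large-scale P(s); leaving these bonds at one *coarse* bead diameter
  would inflate the backbone step ~5-fold at 4 kb beads, push the
  backbone random walk into the periodic-box cross-section within
  ~2 Mb, and bury the 2–8 Mb scaling regime under the uniform wrapped
  background (the box cross-section, ~570 nm at the measured densities,
  is fixed in nm and does not grow with the simulated length).
* **Initialization is part of the model**: large-scale modes do not relax
  within accessible run lengths (true of the reference GPU-scale runs as
  well), so the initial ensemble defines the large-scale statistics.
  Helical models start with anchors on a regular helix (phase 0 at the
  chromosome start) with loops fanned radially to near the target
  density; stretched models start with the backbone on a Brownian bridge
  between the fixed ends with step length matched to the equilibrium
  backbone bond lengths. Relaxation then equilibrates local scales.

# In-silico Hi-C and detectors

Contacts: every bead is jittered by an isotropic Gaussian of sd σ_C per
axis, pairs within 1.1 length units are counted, and frequencies are
averaged over (by default) 100 perturbation replicates, optionally pooled
over conformation snapshots. P(s): separations are binned geometrically
(128 bins per decade, 1 kb–1 Gb); the observed-contact numerator and the
locus-pair denominator are smoothed separately with a Gaussian kernel of
width 0.03 in log10 s and divided. The log-derivative uses central
differences on the smoothed curve.

Peak detectors apply an additional *detection-level* smoothing (0.08 in
log10 s for the helix period, 0.05 for the loop-size derivative peak):
at desk-scale statistics single-bin sampling bumps otherwise clear the
2% prominence threshold. The second diagonal is the first local maximum
of P(s) above 2 Mb with ≥2% relative prominence; models without helical
order (condensin I-only) return "none". The loop-size estimator
multiplies the derivative-peak position by a stored calibration factor
of 0.64, fixed once against a chromatid model built with known 400 kb
loops (peak at ~620 kb). At coarse desk scale the factor is only
accurate near that regime — models with ≤200 kb loops at 4 kb beads
showed peak positions dominated by backbone and gap scales — so the
estimator should be read as semi-quantitative below ~200 kb.
`fit_rms()` normalizes both curves to 1.0 at s = 3 kb and reports the
RMS of log10 differences over 3 kb–40 Mb.

# Feature scores

Observed/expected divides each diagonal by its mean. The compartment
eigenvector is the leading eigenvector of (OE − 1) on unmasked bins,
sign-oriented against a reference track. Saddle strength trims the
eigenvector to the 2.5–97.5 percentile range, ranks bins into 10 groups,
and reports `(AA + BB)/(AB + BA)` from the single extreme group per
corner ("corner pixels" read in its simplest form; configurable). Dots
are deduplicated by single-linkage clustering at 30 kb and scored as the
mean of the centered 3×3 window of the averaged OE pileup (±50 kb
flanks). Insulation is the log2 diamond mean (200 kb window) relative to
the chromosome mean; boundary strength is the prominence of the
insulation minimum (the strength definition of the original insulation
caller is not public, so prominence — the height of the lower flanking
maximum above the minimum — stands in, with the 0.1 threshold
retained); TADs between boundaries within 100–700 kb are pileup-averaged
after rescaling ±1 TAD-size snippets to 100×100 pixels. All scores are
invariant to global matrix scaling.

# Scenarios and their stated worlds

`run_scenario()` wires the modules together. Default parameter choices
and why:

* **prophase_collision** — 20,000-site lattice with the fixed 125-entry
  CTCF list, extrusive cohesin λ = 100 kb, d = 300 kb, 90% capture;
  condensin d = 700 kb, infinite lifetime, synchronous loading at
  prophase onset, 120 kb/min (epoch = 1 s); burn-in to cohesin steady
  state; 30 simulated minutes of condensin activity; CTCF–CTCF-anchored
  cohesins (both legs captured) are the 1D dot proxy, normalized to the
  G2 baseline averaged over the burn-in tail; counts are pooled over 3
  replicate lattices before the ratio because the anchored population is
  only ~5–10 complexes.
* **cohesion_sisters** — two 3 Mb sister chains (desk reduction of the
  18 Mb originals), condensin I λ = 800 kb, d = 50 kb (stalling among
  themselves), stably bound diffusing cohesive cohesins every 300 kb
  linking the chains, 1D steps alternating with 3D integration, no
  confinement (good solvent); radial profiles are accumulated over the
  second half of the run.
* **condensinII_only** — 51 Mb (3 helical turns), 400 kb loops, 80 nm
  gaps, pitch 400 nm, turn 17 Mb, ρ_V = 44 Mb/µm³, σ_C = 48 nm.
* **condensinI_only** — 40 Mb, 100 kb loops, 20 nm gaps, ρ_L = 25 Mb/µm,
  ρ_V = 77 Mb/µm³, σ_C = 48 nm, stretched periodic box.
* **nested / overlapping / cohesion_effect** — the combined-condensin,
  complete-bypass and inter-sister-cohesion variants with their stated
  parameters (nested: turn 10 Mb, ρ_V = 77; overlapping: 900 kb loops,
  one per 360 kb, turn 17.5 Mb; cohesion: Poisson sites at 1/Mb
  relocated to loop midpoints, 0.1 kT/nm lateral force).

# What a green test establishes — and what it does not

The synthetic worlds reproduce the *mechanistic* content of the models:
collision-policy contrasts (dot-proxy decay orderings), helical second
and third diagonals and their positions, the stretched bottlebrush's
random-walk scaling, sister-axis separation versus a single shared axis,
and scaffold compactness of consecutive versus overlapping loop arrays.
They do not reproduce experimental Hi-C depth, matrix balancing,
sequence context, trans contacts, microscope point-spread functions, or
absolute contact counts; desk-scale statistics are noisier than the
GPU-scale originals (hence pooled replicates and detection-level
smoothing), and quantitative agreement is asserted only where the
acceptance criteria state it.

# Known limitations

* The gap-fraction law is an estimator, not a property of the lattice
  engine (see above).
* Loop-size calibration is anchored at 400 kb loops; smaller loops at
  coarse beads are semi-quantitative.
* The Brownian reference integrator reproduces equilibrium ensembles,
  not DPD kinetics; time-calibration utilities (`md_step_interval()`)
  refer to the Rouse-time convention of the original engine.
* Conformations serialize to plain text only (no HDF5 backend in this
  environment).
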