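# smcsim

Simulation and analysis of SMC-driven mitotic chromosome formation, at
desk scale, in R.

During mitosis, chromatin is refolded by loop-extruding SMC complexes:
condensin II forms large stable loops in prophase, condensin I subdivides
them after nuclear envelope breakdown, extrusive cohesin maintains
interphase loops that condensins must dismantle, and cohesive cohesin
holds the sister chromatids together. `smcsim` implements the models
used to study this process and the analyses that connect them to data:

* **1D loop extrusion** (`lattice()`, `lef_species()`,
  `collision_policy()`, `initialize_state()`, `step_epoch()`): two-legged
  loop-extruding factors (LEFs) on a kb lattice with processivity λ
  (mean extruded length, unbinding probability per epoch = kb moved / λ),
  separation d (complex count = floor(lattice kb / d)), CTCF barriers
  with 90% leg capture, and the four condensin-vs-cohesin collision
  outcomes — stall, bypass, push, unload. The steady-state gap fraction
  estimator `g = exp(-λ/d)` and its inversion into extrusion speeds are
  in the kinetics module.
* **Polymer engine** (`init_conformation()`, `integrate_brownian()`,
  `update_lef_bonds()`): overdamped Langevin dynamics of a bead-spring
  fiber (bond k = 10 kT/unit², soft repulsion F = A(1−r) with A = 3 kT,
  confinement walls, helical restraints, periodic boxes); LEF legs map to
  harmonic bonds that track the 1D simulation.
* **Chromatid builders** (`sample_consecutive_loops()`,
  `subdivide_nested()`, `sample_overlapping_loops()`,
  `derive_geometry()`, `build_force_spec()`, `plant_cohesion()`): mitotic
  bottlebrush models with derived geometry L_cyl = l_chrom/ρ_L,
  R_cyl = √(l_chrom/ρ_V/L_cyl/π), P = l_turn/ρ_L, N_loops = l_chrom/l_loop.
* **In-silico Hi-C** (`simulate_contacts()`, `ps_from_contacts()`,
  `log_derivative()`, `second_diagonal_position()`, `loop_size_estimate()`,
  `fit_rms()`): Gaussian-perturbation contacts (jitter sd σ_C per axis,
  1.1-unit cutoff, 100 replicates), P(s) on 128 log-bins per decade with
  0.03-decade smoothing, helix-period and loop-size detectors, and the
  log-log RMS model-fit metric normalized at s = 3 kb.
* **Matrix feature scores** (`oe_matrix()`, `compartment_ev()`,
  `saddle_strength()`, `dedup_dots()`, `dot_strength()`,
  `insulation_track()`, `call_boundaries()`, `tad_pileup()`,
  `timecourse_norm()`).
* **Kinetic estimators** (`speed_from_first_loops()`,
  `speed_from_gap_fraction()`, `period_growth_rate()`,
  `effective_velocity()`, `md_step_interval()`, `nucleosome_cube_side()`,
  `complexes_per_mb()`).
* **Synthetic fluorescence profiles** (`extract_spine()`,
  `pair_spines()`, `radial_profile()`, `width_half_max()`,
  `scaffold_dispersion()`).
* **Scenario pipelines** (`scenario_config()`, `run_scenario()`):
  prophase condensin-cohesin collisions, two-chain sister cohesion,
  condensin II-only / condensin I-only / nested / overlapping / cohesion
  chromatid models, end to end from loop sampling to P(s) and profiles.

## Worked example

Build the condensin II-only chromatid (400 kb loops, 80 nm gaps, 400 nm
pitch, 17 Mb per helical turn, 44 Mb/µm³) at a 51 Mb desk scale and read
the helical period off the simulated P(s):

```r
library(smcsim)
cfg <- scenario_config("condensinII_only", seed = 1, relax_steps = 20000,
                       n_snapshots = 2, snapshot_every = 3000, n_reps = 60)
res <- run_scenario(cfg)
res$second_diag_Mb
#> [1] 15.8204
ps_peaks(res$ps, detect_sigma = 0.03)
#> [1] 15.8204 31.9085
```

The first P(s) peak beyond 2 Mb — the second Hi-C diagonal — sits at
15.8 Mb, close to one helical turn (contacts between adjacent gyres),
and the next peak at 31.9 Mb ≈ 2× reflects contacts two gyres apart.
The same arithmetic that converts observed dynamics into speeds:

```r
format_speed(period_growth_rate(6.6, 16.4, 15))  # helical period growth
#> [1] "10.9 kb/s"
format_speed(speed_from_gap_multiplier(400, 4, 600))
#> [1] "2.7 kb/s"
nucleosome_cube_side(44)
#> [1] 16.56504
```

And the collision-rule contrast that distinguishes how condensin removes
extrusive cohesin (CTCF–CTCF-anchored cohesins as the dot proxy,
normalized to G2):

```r
res <- run_scenario(scenario_config("prophase_collision", seed = 2,
                                    policy = "unload", n_replicates = 6))
min(res$dot_series$dots_norm[res$dot_series$epoch <= 720])
#> [1] 0.1151079   # dots collapse; under "stall" they stay above 0.5
```

## Acceptance script

`scripts/acceptance.R` rebuilds the condensin I-only chromatid model
from scratch (exponential 100 kb loops, 20 nm gaps, backbone stretched
to 25 Mb/µm in a periodic box at 77 Mb/µm³, contact radius 48 nm;
48 Mb desk scale, three independent loop arrays), runs relaxation and
in-silico Hi-C, and reports the mean logarithmic P(s) slope over
2–8 Mb:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON maps each target id to the recomputed value and the problem
size used. See `vignettes/chromatid-models.Rmd` for the models, their
assumptions, parameter meanings, and known desk-scale limitations.
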