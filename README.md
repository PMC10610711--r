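# sorbtrack

Analysis of penetrant sorption and transport in molecular dynamics
trajectories of polymer systems — water in a crosslinked resin being the
motivating case. Given per-frame coordinates in an orthorhombic periodic
box plus a per-atom topology (element, mass, molecule, species, bonds,
hydrogen-bond roles), the package computes:

* **Self-diffusion coefficients** via the Einstein relation,
  `D = (1/6) d⟨|r(t₀+τ) − r(t₀)|²⟩/dτ`, from the multi-origin
  centre-of-mass mean-squared displacement, with automatic detection of the
  Fickian window (the lag range where the log–log slope of MSD vs τ is ≈ 1)
  and a molecule-block standard error. Units: Å²/ps internally, reported in
  m²/s (1 Å²/ps = 10⁻⁸ m²/s).
* **A geometric hydrogen-bond census** (H···A < 2.8 Å strictly, donor angle
  ≥ 120°, acceptor angle ≥ 90° against every heavy neighbour of the
  acceptor), decomposed into water–water, polymer–polymer and polymer–water
  classes with the exact identity `N_pw = N_T − N_pp − N_ww`.
* **Water cluster statistics** by single-linkage components of the
  minimum-image O–O contact graph (default cutoff 3.5 Å), including
  mass-weighted radii of gyration measured with boundary-spanning clusters
  made whole.
* **Density projections** (1D/2D, number or mass) with an exact
  normalisation identity and a coefficient-of-variation uniformity metric.

Because deposited trajectories are rarely available, the package ships
seeded synthetic generators — Brownian/ballistic/confined walker ensembles,
planted cluster scenes, and exact planted hydrogen-bond geometries — that
give every analysis stage an input with known ground truth. A config-driven
pipeline (`run_pipeline()`, plus a thin `inst/scripts/sorbtrack` CLI) chains
the stages and writes checksummed, byte-reproducible artifacts.

Intended users: simulation scientists who have MD trajectories of
penetrant/polymer systems (dental resins, membranes, coatings) and want the
standard transport and structure analyses as tested, scriptable R functions.

## Worked example

Generate a Brownian water ensemble at a prescribed diffusion coefficient,
recover it, and analyse a planted cluster scene:

```r
library(sorbtrack)

# 500 water-like walkers, 1000 frames at 5 ps, D = 2.5016e-12 m^2/s
sp <- synth_spec("brownian", n_molecules = 500, n_frames = 1000, dt = 5,
                 d_true = 2.5016e-12, box = c(50, 50, 50), seed = 42)
gw <- gen_walkers(sp)
est <- estimate_diffusion(unwrap(gw$wrapped), gw$topology)
est
#> <diffusion_estimate> D = 2.5085e-12 m^2/s +/- 1.82e-14
#>   window 5..495 ps, slope 1.5051e-03 A^2/ps, R^2 1.00000, N = 500
```

The fit recovers the prescribed coefficient within 0.3%; the window
`5..495 ps` is the auto-detected Fickian regime (capped at 10% of the run),
the slope is in Å²/ps, and the `±` is a 5-block molecule-resampling
standard error.

```r
# a planted scene whose largest water cluster has 11 molecules
scene <- gen_cluster_scene(cluster_scene(c(11, 5, 2, 1), cutoff = 3.5,
                                         min_gap = 7.5, box = c(44, 44, 44),
                                         seed = 8))
cluster_frame(frame_coords(scene$traj, 1), scene$topology,
              scene$traj$box[1, ], cutoff = 3.5)
#> <cluster_set> 4 clusters, sizes: 11 5 2 1

# polymer-water hydrogen bonds by difference from class counts
pw_by_difference(666, 251, 78)
#> [1] 337
```

File-based workflows use `read_trajectory()` (multi-frame XYZ with a
`Lattice` comment line, multi-model PDB with CRYST1, GRO) with a JSON/CSV
topology sidecar (`read_topology()`), or derive water topologies from
`HOH`/`SOL` residue names with `topology_from_residues()`.

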