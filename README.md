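# membind

Post-processing for molecular dynamics trajectories of **peripheral membrane
proteins binding lipid bilayers**, built around the analyses used to
characterise recruitment of the lipid kinase PIP5K1A to
PI4P-containing membranes: how fast the protein finds the membrane, in which
orientation it binds, through which residues it touches the
phosphoinositide headgroups, and how a side-by-side dimer sits on the
bilayer surface.

For researchers running coarse-grained (CG) or atomistic (AT) simulations of
protein-membrane recruitment who want the standard figure panels — binding
curves, contact profiles, orientation landscapes, hinge angles, H-bond
counts, RMSF — as reproducible data files rather than one-off scripts.

## What it computes

* **Binding kinetics.** Per-frame protein–bilayer centre-of-mass distance
  (full 3D or z-component, minimum image), replicate-ensemble means, and
  exponential fits

  d(t) = d<sub>∞</sub> + (d<sub>0</sub> − d<sub>∞</sub>) e<sup>−t/τ</sup>

  by bounded Levenberg–Marquardt.
* **Residue–lipid contacts.** Per-residue contact counts against PIP
  headgroups under either the CG convention (minimum particle–particle
  distance < 0.7 nm) or the AT convention (residue COM to lipid headgroup
  COM < 0.35 nm), normalised to the most-contacted residue; residue × time
  occupancy matrices; lipid counts within a radius of an active site.
* **Orientation landscapes.** R<sub>zz</sub> — the (3,3) element of the
  Kabsch rotation onto a productively bound reference after in-plane (xy)
  fitting — paired with membrane distance, pooled over replicates into a 2D
  probability map; binding modes detected as smoothed density peaks.
* **Dimer geometry.** Three-anchor hinge angle (catalytic lysine of each
  subunit about a vertex residue), per-subunit membrane distances,
  geometric hydrogen-bond counting (0.35 nm / 30° default) with moving
  averages, and per-residue RMSF after superposition on the average
  structure.
* **Synthetic ground truth.** A rigid-body encounter generator (bilayer
  lattice of 75/20/5 PC/PS/PI4P, spherical bead protein with planted
  hotspot residues, exponential approach with one or two planted
  orientational binding modes) whose every planted parameter is recovered
  by the analysis stages in the test suite.

Structures are read from GRO and PDB, trajectories from DCD, multi-model
PDB and multi-frame GRO; simulation↔PDB residue renumbering ships with the
kinase model's scheme (sim 1–253 ↔ PDB 57–309, sim 254–324 ↔ PDB 356–426).

## Worked example

```r
library(membind)

bilayer <- build_bilayer(bilayer_spec(grid_nx = 8, grid_ny = 8), seed = 1)
protein <- build_protein_model(seed = 1)
runs <- simulate_ensemble(protein, bilayer,
                          encounter_params(n_frames = 1500, tau = 100, seed = 1),
                          n_replicates = 5)

series <- lapply(runs, function(r) com_distance_series(r$trajectory))
fit_binding_curve(ensemble_mean(series))
#> <binding_fit> d0 = 8.003 nm, d_inf = 4.866 nm, tau = 98.47 ns, rms = 0.1345 nm

prof <- residue_contact_profile(runs[[1]]$trajectory,
                                lipid_target_sel = "headgroup", cutoff = 0.7)
head(prof[order(-prof$normalized), ], 5)
#>     residue  raw normalized
#> 180     180 1008  1.0000000
#> 181     181 1003  0.9950397
#> 182     182  999  0.9910714
#> 184     184  986  0.9781746
#> 183     183  982  0.9742063

trajs <- lapply(runs, `[[`, "trajectory")
ref <- pick_reference(trajs, lipid_target_sel = "headgroup")
ors <- lapply(trajs, orientation_series, reference = ref)
map <- distance_orientation_map(series, ors)
find_modes(map, k = 2)
#> mode1: distance 4.79 nm, Rzz 0.98, mass 0.66
#> mode2: distance 5.58 nm, Rzz 0.42, mass 0.34
```

The fitted τ of 98.5 ns recovers the planted 100 ns approach time constant
from five noisy replicates; the top contact residues are the planted
PIP-binding motif (180–184); and the two landscape peaks are the productive
pose (bound close, R<sub>zz</sub> ≈ 1, i.e. catalytic site facing the
bilayer) and the loop-first pose (further out, tilted), with their relative
weights.

A config-driven pipeline runs the same stages over a replicate manifest or
a synthetic spec and writes CSV/JSON (see
`inst/extdata/demo_config.yaml`):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "membind"))
```

or from a shell via the thin wrapper `inst/scripts/membind`
(`membind synth`, `membind run --config demo.yaml`, ...).

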