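# Demo: synthetic replicate ensemble of membrane-encounter trajectories,
# analysed for binding kinetics, PI4P contacts and the distance/Rzz landscape.
seed: 1
output: membind_demo_out
stages: [distances, contacts, landscape]
synthetic:
  n_replicates: 3
  bilayer: {grid_nx: 8, grid_ny: 8}
  protein: {n_residues: 324, radius: 2.5}
  params:
    n_frames: 600
    dt: 0.5
    tau: 60
    noise_sigma: 0.3
    bound_distance: [5.5, 4.7]
    bound_rzz: [0.4, 1.0]
    mode_weights: [0.5, 0.5]
distances:
  metric: z_component
contacts:
  cutoff: 0.7
  mode: min_particle
  target: headgroup
landscape:
  n_bins_d: 40
  n_bins_r: 40
  site_residues: [180, 181, 182, 183, 184]
  target: headgroup
  k: 2
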