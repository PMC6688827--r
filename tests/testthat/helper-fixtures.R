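# Small systems built in code for unit tests.

# topology with nres 1-bead protein residues followed by nlip 3-bead lipids
make_mixed_topology <- function(nres = 5, nlip = 3, lipid_species = "PI4P") {
  prot <- data.frame(name = "BB", resid = seq_len(nres), resname = "GLY",
                     subunit = "A", mass = 72, species = "protein",
                     headgroup = FALSE, stringsAsFactors = FALSE)
  lip <- data.frame(name = rep(c("HD", "T1", "T2"), nlip),
                    resid = rep(seq_len(nlip), each = 3),
                    resname = rep(rep_len(lipid_species, nlip), each = 3),
                    subunit = "M", mass = 72,
                    species = rep(rep_len(lipid_species, nlip), each = 3),
                    headgroup = rep(c(TRUE, FALSE, FALSE), nlip),
                    stringsAsFactors = FALSE)
  topology(rbind(prot, lip))
}

# trajectory from a list of N x 3 coordinate matrices
make_traj <- function(top, coord_list, box = c(10, 10, 10), dt = 1) {
  coords <- array(0, dim = c(n_particles(top), 3, length(coord_list)))
  for (i in seq_along(coord_list)) coords[, , i] <- coord_list[[i]]
  trajectory(top, (seq_along(coord_list) - 1) * dt, coords, box)
}

# random frame: protein beads and lipids scattered in the box
random_contact_frame <- function(nres, nlip, box = c(6, 6, 6)) {
  top <- make_mixed_topology(nres, nlip)
  n <- n_particles(top)
  xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  list(top = top, xyz = xyz, box = box)
}

random_rotation_matrix <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    3, 3, byrow = TRUE)
}

# small standard synthetic encounter setup shared by several tests
small_encounter <- function(n_frames = 600, noise_sigma = 0, tau = 50,
                            bound_rzz = 1, bound_distance = 4.7,
                            mode_weights = 1, seed = 7,
                            hotspots = c(180:184, 187:197), ...) {
  bil <- build_bilayer(bilayer_spec(grid_nx = 6, grid_ny = 6), seed = 1)
  prot <- build_protein_model(hotspot_residues = hotspots, seed = 1)
  params <- encounter_params(n_frames = n_frames, dt = 0.5,
                             noise_sigma = noise_sigma, tau = tau,
                             bound_rzz = bound_rzz,
                             bound_distance = bound_distance,
                             mode_weights = mode_weights, seed = seed,
                             hotspot_residues = hotspots, ...)
  run <- simulate_encounter(prot, bil, params)
  list(bilayer = bil, protein = prot, params = params, run = run)
}
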