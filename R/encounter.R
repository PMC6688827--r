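#' Encounter/binding generator parameters
#'
#' Defaults reproduce the statistical structure of the coarse-grained
#' encounter simulations: 2 us of frames written every 0.5 ns, the protein
#' COM starting 8 nm from the bilayer COM, exponential approach with a
#' ~100 ns time constant, ~0.3 nm distance noise, and two bound orientational
#' modes — a loop-first pose further from the membrane and a productive pose
#' (hotspots down, Rzz = 1 against the built reference) closer in.
#'
#' @param n_frames number of frames
#' @param dt frame spacing, ns
#' @param start_distance initial COM-COM z distance, nm
#' @param bound_distance bound-state COM-COM distance per mode, nm (recycled
#'   across modes)
#' @param tau approach time constant, ns
#' @param bound_rzz bound orientation per mode, in `[-1, 1]`
#' @param mode_weights mode probabilities, summing to 1
#' @param noise_sigma Gaussian distance noise s.d., nm (orientation jitter in
#'   the bound state scales with it)
#' @param hotspot_residues planted hotspot residues (recorded in the truth)
#' @param seed integer seed
#' @param tumble_sd per-frame free-tumbling rotation s.d., rad
#' @param orient_tau bound-orientation relaxation time, ns
#' @param bind_eps extra binding-threshold margin as a fraction of the
#'   approach amplitude (keeps the binding time finite when `noise_sigma = 0`)
#' @return object of class `encounter_params`
#' @export
encounter_params <- function(n_frames = 4000, dt = 0.5, start_distance = 8,
                             bound_distance = c(5.5, 4.7), tau = 100,
                             bound_rzz = c(0.4, 1.0),
                             mode_weights = c(0.5, 0.5), noise_sigma = 0.3,
                             hotspot_residues = c(180:184, 187:197, 276:313),
                             seed = 1L, tumble_sd = 0.12, orient_tau = tau / 5,
                             bind_eps = 0.02) {
  if (tau <= 0) stop("encounter_params: tau must be > 0")
  k <- length(bound_rzz)
  bound_distance <- rep_len(bound_distance, k)
  if (length(mode_weights) != k)
    stop("encounter_params: mode_weights and bound_rzz lengths differ")
  if (abs(sum(mode_weights) - 1) > 1e-9)
    stop("encounter_params: mode_weights must sum to 1")
  if (any(bound_distance <= 0) || any(bound_distance >= start_distance))
    stop("encounter_params: need 0 < bound_distance < start_distance")
  if (any(abs(bound_rzz) > 1))
    stop("encounter_params: bound_rzz must lie in [-1, 1]")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 start_distance = start_distance,
                 bound_distance = bound_distance, tau = tau,
                 bound_rzz = bound_rzz, mode_weights = mode_weights,
                 noise_sigma = noise_sigma,
                 hotspot_residues = as.integer(hotspot_residues),
                 seed = as.integer(seed), tumble_sd = tumble_sd,
                 orient_tau = orient_tau, bind_eps = bind_eps),
            class = "encounter_params")
}

#' Simulate a rigid-body membrane-encounter trajectory
#'
#' The protein moves as a rigid body above a static bilayer.  Its COM-COM z
#' distance follows `d(t) = d_b + (d0 - d_b) exp(-t / tau)` plus Gaussian
#' noise; the orientation tumbles freely while unbound (deterministic
#' distance above `d_b + 2 sigma` plus a small margin) and, once bound,
#' relaxes exponentially to the drawn mode's bound orientation (a tilt of
#' `acos(bound_rzz)` away from the built productive pose).  Everything is
#' reproducible from `params$seed`.
#'
#' @param protein list with `topology`/`frame` from [build_protein_model()]
#' @param bilayer list with `topology`/`frame` from [build_bilayer()]
#' @param params an [encounter_params()]
#' @return list with `trajectory` and `truth`; `truth` records the realized
#'   mode, the binding frame, a per-frame mode label (0 while unbound) and
#'   the parameters used
#' @export
simulate_encounter <- function(protein, bilayer, params = encounter_params()) {
  stopifnot(inherits(params, "encounter_params"))
  ptop <- protein$topology
  ref <- protein$frame$coords
  ref <- sweep(ref, 2, center_of_mass(ptop, ref))
  btop <- bilayer$topology
  bxyz <- bilayer$frame$coords
  box <- bilayer$frame$box
  mem_com <- center_of_mass(btop, bxyz)
  np <- n_particles(ptop)
  nb <- n_particles(btop)
  times <- (seq_len(params$n_frames) - 1) * params$dt

  with_seed(params$seed, {
    mode <- sample.int(length(params$mode_weights), 1,
                       prob = params$mode_weights)
    d_b <- params$bound_distance[mode]
    d_det <- d_b + (params$start_distance - d_b) * exp(-times / params$tau)
    noise <- if (params$noise_sigma > 0)
      stats::rnorm(params$n_frames, 0, params$noise_sigma) else
      numeric(params$n_frames)
    threshold <- d_b + 2 * params$noise_sigma +
      params$bind_eps * (params$start_distance - d_b)
    bound <- d_det <= threshold
    binding_frame <- if (any(bound)) which(bound)[1] else NA_integer_
    target <- rotation_axis_angle(c(1, 0, 0), acos(params$bound_rzz[mode]))
    jitter_sd <- 0.1 * params$noise_sigma
    relax <- 1 - exp(-params$dt / params$orient_tau)

    R <- random_small_rotation(pi)  # random initial orientation
    coords <- array(0, dim = c(np + nb, 3, params$n_frames))
    for (i in seq_len(params$n_frames)) {
      if (i > 1) {
        if (!bound[i]) {
          R <- random_small_rotation(params$tumble_sd) %*% R
        } else {
          rel <- rotation_to_axis_angle(target %*% t(R))
          R <- rotation_axis_angle(rel$axis, relax * rel$angle) %*% R
          if (jitter_sd > 0) R <- random_small_rotation(jitter_sd) %*% R
        }
      }
      com <- c(mem_com[1], mem_com[2], mem_com[3] + d_det[i] + noise[i])
      coords[seq_len(np), , i] <- sweep(ref %*% t(R), 2, com, "+")
      coords[np + seq_len(nb), , i] <- bxyz
    }
    part <- rbind(ptop$particles, btop$particles)
    part$particle_id <- NULL
    top <- topology(part)
    traj <- trajectory(top, times, coords, box)
    truth <- structure(list(params = params, mode = mode,
                            binding_frame = binding_frame,
                            mode_per_frame = ifelse(bound, mode, 0L),
                            bound_distance = d_b,
                            reference = ref,
                            seed = params$seed),
                       class = "synthetic_truth")
    list(trajectory = traj, truth = truth)
  })
}

#' Simulate a replicate ensemble of encounters
#'
#' Replicate `r` uses seed `base seed + r - 1`; each replicate draws its own
#' bound mode, emulating independent repeats started with different
#' velocities.
#'
#' @inheritParams simulate_encounter
#' @param n_replicates number of replicates
#' @return list of `simulate_encounter()` results
#' @export
simulate_ensemble <- function(protein, bilayer, params = encounter_params(),
                              n_replicates = 5) {
  lapply(seq_len(n_replicates), function(r) {
    p <- params
    p$seed <- params$seed + r - 1L
    simulate_encounter(protein, bilayer, p)
  })
}

#' Write a synthetic truth record as JSON
#' @param truth a `synthetic_truth` from [simulate_encounter()]
#' @param path output path
#' @export
write_truth <- function(truth, path) {
  rec <- list(params = unclass(truth$params), mode = truth$mode,
              binding_frame = truth$binding_frame,
              mode_per_frame = truth$mode_per_frame, seed = truth$seed)
  rec$params$hotspot_residues <- as.integer(rec$params$hotspot_residues)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
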