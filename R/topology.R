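#' Particle topology
#'
#' A topology decouples particle metadata from coordinates.  It is a thin S3
#' wrapper around a data frame with one row per particle (atom or
#' coarse-grained bead) carrying residue indexing, subunit labels, a species
#' class and a headgroup flag used by the lipid-contact machinery.
#'
#' @param particles data frame with columns `name`, `resid` (1-based
#'   simulation residue index), `resname`, `subunit`, `mass` (amu),
#'   `species` (one of `r paste(membind_species_levels(), collapse = ", ")`)
#'   and `headgroup` (logical).  A `particle_id` column (1-based, contiguous)
#'   is added if absent.
#' @return object of class `topology`
#' @export
topology <- function(particles) {
  stopifnot(is.data.frame(particles))
  required <- c("name", "resid", "resname", "subunit", "mass", "species", "headgroup")
  missing_cols <- setdiff(required, names(particles))
  if (length(missing_cols))
    stop("topology: missing columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(particles)
  if (is.null(particles$particle_id)) particles$particle_id <- seq_len(n)
  particles$species <- as.character(particles$species)
  particles$headgroup <- as.logical(particles$headgroup)
  top <- structure(list(particles = particles, n = n), class = "topology")
  validate_topology(top)
  top
}

membind_species_levels <- function() {
  c("protein", "PC", "PS", "PI4P", "PIP2", "ion", "solvent")
}

validate_topology <- function(top) {
  p <- top$particles
  if (!identical(as.integer(p$particle_id), seq_len(nrow(p))))
    stop("topology: particle_ids must be contiguous 1..N")
  bad <- !(p$species %in% membind_species_levels())
  if (any(bad))
    stop("topology: unknown species class: ",
         paste(unique(p$species[bad]), collapse = ", "))
  if (any(p$headgroup & p$species %in% c("protein", "ion", "solvent")))
    stop("topology: headgroup flag only valid on lipid particles")
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n, " particles, ",
      length(unique(x$particles$resid)), " residues\n", sep = "")
  tab <- table(x$particles$species)
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of particles
#' @param top a [topology()]
#' @export
n_particles <- function(top) top$n

#' Single time-stamped coordinate set
#'
#' @param time time in ns
#' @param coords N x 3 matrix of coordinates in nm
#' @param box orthorhombic box edge lengths, length-3 numeric, nm
#' @return object of class `frame`
#' @export
frame <- function(time, coords, box) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(box) == 3)
  if (any(box <= 0)) stop("frame: box edges must be > 0")
  structure(list(time = as.numeric(time), coords = unname(coords),
                 box = as.numeric(box)), class = "frame")
}

#' Trajectory: a topology plus time-ordered frames
#'
#' Coordinates are stored as an `n_particles x 3 x n_frames` array in nm.
#'
#' @param topology a [topology()]
#' @param times numeric vector, ns, strictly increasing
#' @param coords `N x 3 x n_frames` array (nm)
#' @param box length-3 box (nm), or `n_frames x 3` matrix for a fluctuating box
#' @return object of class `trajectory`
#' @export
trajectory <- function(topology, times, coords, box) {
  stopifnot(inherits(topology, "topology"))
  coords <- as_coord_array(coords)
  nf <- dim(coords)[3]
  if (length(times) != nf) stop("trajectory: length(times) != n_frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop("trajectory: frame times must be strictly increasing")
  if (dim(coords)[1] != n_particles(topology))
    stop("trajectory: coordinate count (", dim(coords)[1],
         ") does not match topology (", n_particles(topology), ")")
  if (is.matrix(box)) {
    stopifnot(nrow(box) == nf, ncol(box) == 3)
  } else {
    stopifnot(length(box) == 3)
    box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  }
  if (any(box <= 0)) stop("trajectory: box edges must be > 0")
  structure(list(topology = topology, times = as.numeric(times),
                 coords = coords, box = unname(as.matrix(box))),
            class = "trajectory")
}

as_coord_array <- function(coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  unname(coords)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames, ",
      n_particles(x$topology), " particles, t = ",
      x$times[1], " .. ", x$times[n_frames(x)], " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj a [trajectory()]
#' @param i frame index (1-based)
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  frame(traj$times[i], traj$coords[, , i, drop = TRUE], traj$box[i, ])
}

#' Standard bead/atom masses
#'
#' Coarse-grained beads get the standard 72 amu 4:1-mapping bead mass;
#' atomistic masses come from the leading element letter of the atom name.
#'
#' @param names character vector of particle names
#' @param model `"cg"` or `"at"`
#' @return numeric vector of masses in amu
#' @export
guess_masses <- function(names, model = c("cg", "at")) {
  model <- match.arg(model)
  if (model == "cg") return(rep(72, length(names)))
  elements <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                P = 30.974, S = 32.06)
  lead <- toupper(substr(gsub("^[0-9]+", "", names), 1, 1))
  m <- elements[lead]
  m[is.na(m)] <- 12.011
  unname(m)
}
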