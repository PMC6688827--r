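#' Bilayer build specification
#'
#' Defaults reproduce the study membrane: a two-leaflet lattice of
#' 75% PC / 20% PS / 5% PI4P, 20 x 20 lipids per leaflet (800 lipids) on a
#' 0.375 nm grid (a 7.5 x 7.5 nm^2 patch), 4 nm headgroup-to-headgroup
#' thickness.
#'
#' @param grid_nx,grid_ny lipids per leaflet edge
#' @param spacing lattice spacing, nm
#' @param thickness leaflet-to-leaflet headgroup distance, nm
#' @param composition named fractions over species classes, summing to 1
#' @return object of class `bilayer_spec`
#' @export
bilayer_spec <- function(grid_nx = 20, grid_ny = 20, spacing = 0.375,
                         thickness = 4,
                         composition = c(PC = 0.75, PS = 0.20, PI4P = 0.05)) {
  if (grid_nx < 1 || grid_ny < 1) stop("bilayer_spec: grid sizes must be >= 1")
  if (any(composition < 0)) stop("bilayer_spec: negative composition fraction")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("bilayer_spec: composition fractions must sum to 1 (got ",
         format(sum(composition)), ")")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 spacing = spacing, thickness = thickness,
                 composition = composition), class = "bilayer_spec")
}

#' Largest-remainder apportionment of species counts
#'
#' Each species count differs from `fraction * n` by less than one lipid;
#' ties in the fractional remainders are broken by species order.
#'
#' @param fractions named non-negative fractions summing to 1
#' @param n total count
#' @return named integer vector summing to `n`
#' @export
composition_counts <- function(fractions, n) {
  ideal <- fractions * n
  counts <- floor(ideal)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(-(ideal - counts), seq_along(ideal))
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Build a planar two-leaflet bilayer
#'
#' Lipids sit on two square lattices at `z = +/- thickness/2` centred in a
#' box of height 20 nm; each lipid is one headgroup bead (`HD`) and two tail
#' beads (`T1`, `T2`) pointing toward the midplane, so the bilayer centre of
#' mass lies exactly at the box-centre plane.  Species are apportioned by
#' largest remainder and placed in seed-shuffled lattice order.
#'
#' @param spec a [bilayer_spec()]
#' @param seed integer seed for the placement shuffle
#' @param box_z box height, nm
#' @return list with `topology` and `frame`; the bilayer COM has z = box_z/2
#' @export
build_bilayer <- function(spec, seed = 1L, box_z = 20) {
  stopifnot(inherits(spec, "bilayer_spec"))
  n_leaf <- spec$grid_nx * spec$grid_ny
  n_lip <- 2L * n_leaf
  counts <- composition_counts(spec$composition, n_lip)
  species_seq <- rep(names(counts), counts)
  if (length(unique(species_seq)) > 1)
    species_seq <- with_seed(seed, sample(species_seq))
  gx <- (seq_len(spec$grid_nx) - 0.5) * spec$spacing
  gy <- (seq_len(spec$grid_ny) - 0.5) * spec$spacing
  lat <- expand.grid(x = gx, y = gy)
  z0 <- box_z / 2
  half <- spec$thickness / 2
  # per-lipid: head z, two tails stepped 0.5/1.0 nm toward the midplane
  lip_x <- rep(c(lat$x, lat$x), each = 3)
  lip_y <- rep(c(lat$y, lat$y), each = 3)
  head_z <- c(rep(z0 + half, n_leaf), rep(z0 - half, n_leaf))
  sgn <- c(rep(-1, n_leaf), rep(1, n_leaf))
  z <- as.numeric(vapply(seq_len(n_lip),
                         function(i) head_z[i] + sgn[i] * c(0, 0.5, 1.0),
                         numeric(3)))
  coords <- cbind(lip_x, lip_y, z)
  part <- data.frame(
    name = rep(c("HD", "T1", "T2"), n_lip),
    resid = rep(seq_len(n_lip), each = 3),
    resname = rep(species_seq, each = 3),
    subunit = "M",
    mass = 72,
    species = rep(species_seq, each = 3),
    headgroup = rep(c(TRUE, FALSE, FALSE), n_lip),
    stringsAsFactors = FALSE)
  box <- c(spec$grid_nx * spec$spacing, spec$grid_ny * spec$spacing, box_z)
  list(topology = topology(part), frame = frame(0, coords, box),
       counts = counts)
}

#' Build a spherical bead-model protein
#'
#' One bead per residue on a quasi-uniform (Fibonacci) sphere of the given
#' radius.  The designated hotspot residues are assigned the lattice points
#' nearest the `-z` pole, so that the built pose is the "productive" one with
#' the hotspots facing a membrane lying below the protein; a seeded random
#' rotation about z decorrelates the in-plane arrangement between seeds.
#' The hotspot cap is compressed toward the pole by `pole_compression`,
#' leaving an angular margin between the planted hotspots and the rest of
#' the surface (this is what makes the planted set identifiable from contact
#' counts; at 1 the lattice is exactly quasi-uniform and boundary beads tie).
#'
#' @param n_residues number of residues/beads (>= 3)
#' @param radius sphere radius, nm
#' @param hotspot_residues residue indices placed on the binding pole
#' @param seed integer seed
#' @param subunit subunit label
#' @param pole_compression factor in (0, 1] scaling hotspot polar angles
#' @return list with `topology` and `frame` (COM at the origin)
#' @export
build_protein_model <- function(n_residues = 324, radius = 2.5,
                                hotspot_residues = c(180:184, 187:197, 276:313),
                                seed = 1L, subunit = "A",
                                pole_compression = 0.75) {
  if (n_residues < 3) stop("build_protein_model: need >= 3 residues")
  hotspot_residues <- as.integer(hotspot_residues)
  if (length(hotspot_residues) &&
      (min(hotspot_residues) < 1 || max(hotspot_residues) > n_residues))
    stop("build_protein_model: hotspot index out of range 1..", n_residues)
  pts <- fibonacci_sphere(n_residues) * radius
  # order lattice points by angle from the -z binding pole
  pole_order <- order(pts[, 3])
  assign <- integer(n_residues)
  assign[hotspot_residues] <- pole_order[seq_along(hotspot_residues)]
  rest <- setdiff(seq_len(n_residues), hotspot_residues)
  assign[rest] <- pole_order[seq_along(rest) + length(hotspot_residues)]
  coords <- pts[assign, , drop = FALSE]
  if (length(hotspot_residues) && pole_compression < 1) {
    hp <- coords[hotspot_residues, , drop = FALSE]
    theta <- acos(pmax(-1, pmin(1, -hp[, 3] / radius)))  # angle from -z pole
    rxy <- sqrt(hp[, 1]^2 + hp[, 2]^2)
    phi <- ifelse(rxy < 1e-12, 0, atan2(hp[, 2], hp[, 1]))
    theta <- theta * pole_compression
    coords[hotspot_residues, ] <- radius *
      cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), -cos(theta))
  }
  phi <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  coords <- coords %*% t(rotation_axis_angle(c(0, 0, 1), phi))
  # centre the COM while keeping every bead on the sphere: alternate
  # recentring with radial projection (converges in a few rounds)
  for (it in 1:25) {
    coords <- sweep(coords, 2, colMeans(coords))
    coords <- coords * (radius / sqrt(rowSums(coords^2)))
  }
  part <- data.frame(
    name = "BB", resid = seq_len(n_residues), resname = "GLY",
    subunit = subunit, mass = 72, species = "protein", headgroup = FALSE,
    stringsAsFactors = FALSE)
  list(topology = topology(part), frame = frame(0, coords, c(20, 20, 20)))
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Synthetic crystallographic-pose dimer (stand-in)
#'
#' Builds a side-by-side two-subunit bead model whose three hinge-anchor
#' residues (arm A, vertex, arm B) are collinear by construction, mimicking
#' the flat crystallographic dimer whose hinge angle is 180 degrees at the
#' start of a simulation.  This is a synthetic stand-in for a deposited
#' structure, intended for validating the hinge-angle metric, not a model of
#' the real interface.
#'
#' Subunit B is the C2 image of subunit A about a vertical axis on the dimer
#' (x) axis; residues carry per-subunit indices 1..n with subunit labels
#' `"A"`/`"B"` (see [dimer_resid()] for the global figure numbering).
#'
#' @inheritParams build_protein_model
#' @param arm_resid,vertex_resid anchor residues (defaults: catalytic lysine
#'   182 and vertex residue 29)
#' @param separation COM-COM subunit separation, nm
#' @return list with `topology` and `frame`
#' @export
build_dimer_model <- function(n_residues = 324, radius = 2.5,
                              hotspot_residues = c(180:184, 187:197, 276:313),
                              arm_resid = 182L, vertex_resid = 29L,
                              separation = 5.2, seed = 1L) {
  mono <- build_protein_model(n_residues, radius, hotspot_residues, seed, "A")
  xyz <- mono$frame$coords
  # orient subunit A so the vertex->arm direction is exactly -x and level
  v <- xyz[arm_resid, ] - xyz[vertex_resid, ]
  xyz <- xyz %*% t(rotation_between(v, c(-1, 0, 0)))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # C2 axis: vertical line through (separation/2, vertex_y)
  cx <- separation / 2
  cy <- xyz[vertex_resid, 2]
  xyz_b <- cbind(2 * cx - xyz[, 1], 2 * cy - xyz[, 2], xyz[, 3])
  coords <- rbind(xyz, xyz_b)
  pa <- mono$topology$particles
  pb <- pa
  pb$subunit <- "B"
  part <- rbind(pa, pb)
  part$particle_id <- NULL
  center <- c(10, 10, 10)
  coords <- sweep(coords, 2, center - colMeans(coords), "+")
  list(topology = topology(part), frame = frame(0, coords, c(20, 20, 20)))
}

# rotation taking vector a onto the direction of b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  axis <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * a) * a
    return(rotation_axis_angle(axis, pi))
  }
  rotation_axis_angle(axis, atan2(s, cth))
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
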