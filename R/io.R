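#' Load a structure file
#'
#' Reads a PDB (via bio3d) or GRO file into a ([topology()], [frame()]) pair.
#' Coordinates are converted to nm.  Species classes are inferred from residue
#' names through the species lookup table; subunits come from the chain
#' identifier (PDB) or are split at residue-number restarts (GRO), falling
#' back to a single subunit `"A"`.
#'
#' @param path file path
#' @param format `"PDB"` or `"GRO"`; inferred from the file extension when
#'   missing
#' @param species_table see [default_species_table()]
#' @param mass_model `"cg"` or `"at"`, passed to [guess_masses()]
#' @return list with elements `topology` and `frame`
#' @export
load_structure <- function(path, format = NULL,
                           species_table = default_species_table(),
                           mass_model = c("cg", "at")) {
  mass_model <- match.arg(mass_model)
  format <- toupper(format %||% tools::file_ext(path))
  if (!nzchar(format))
    stop("load_structure: cannot infer format from extension; pass `format`")
  if (!file.exists(path)) stop("load_structure: no such file: ", path)
  switch(format,
         GRO = load_gro(path, species_table, mass_model),
         PDB = load_pdb(path, species_table, mass_model),
         stop("load_structure: unsupported format: ", format))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GRO -------------------------------------------------------------------

parse_gro_block <- function(lines, offset) {
  title <- lines[offset]
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 1])))
  if (is.na(natoms))
    stop("GRO format error at line ", offset + 1, ": expected atom count")
  atom_lines <- lines[offset + 1 + seq_len(natoms)]
  if (length(atom_lines) < natoms || anyNA(atom_lines))
    stop("GRO format error: truncated atom block starting line ", offset + 2)
  resid   <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  name    <- trimws(substr(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO format error at line ", offset + 1 + bad[1], ": ",
         atom_lines[bad[1]])
  box_line <- lines[offset + 2 + natoms]
  if (is.na(box_line))
    stop("GRO format error: missing box line after line ", offset + 1 + natoms)
  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]))
    stop("GRO format error at line ", offset + 2 + natoms, ": bad box line")
  time <- NA_real_
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  list(natoms = natoms, resid = resid, resname = resname, name = name,
       coords = cbind(x, y, z), box = box[1:3], time = time,
       next_offset = offset + 3 + natoms)
}

read_gro_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("GRO format error: empty file: ", path)
  blocks <- list()
  offset <- 1L
  while (offset <= length(lines) && nzchar(trimws(lines[offset]))) {
    b <- parse_gro_block(lines, offset)
    blocks[[length(blocks) + 1L]] <- b
    offset <- b$next_offset
  }
  blocks
}

load_gro <- function(path, species_table, mass_model) {
  b <- read_gro_frames(path)[[1]]
  species <- classify_species(b$resname, species_table)
  # GRO has no chain ids; split protein subunits at residue-number restarts
  restarts <- c(TRUE, diff(b$resid) < 0)
  chain <- cumsum(restarts & species == "protein")
  subunit <- ifelse(species == "protein", LETTERS[pmax(chain, 1)], "M")
  top <- topology(data.frame(
    name = b$name, resid = b$resid, resname = b$resname, subunit = subunit,
    mass = guess_masses(b$name, mass_model), species = species,
    headgroup = headgroup_flags(b$resname, b$name, species, species_table),
    stringsAsFactors = FALSE))
  list(topology = top,
       frame = frame(ifelse(is.na(b$time), 0, b$time), b$coords, b$box))
}

#' Write a structure as GRO
#'
#' @param top a [topology()]
#' @param fr a [frame()]
#' @param path output path
#' @param title title line (a `t= <ns>` tag is appended automatically)
#' @export
write_gro <- function(top, fr, path, title = "membind system") {
  p <- top$particles
  lines <- c(
    sprintf("%s, t= %.5f", title, fr$time),
    sprintf("%5d", n_particles(top)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            p$resid %% 100000L, substr(p$resname, 1, 5), substr(p$name, 1, 5),
            p$particle_id %% 100000L,
            fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
  writeLines(lines, path)
  invisible(path)
}

# ---- PDB (via bio3d) -------------------------------------------------------

load_pdb <- function(path, species_table, mass_model) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  species <- classify_species(a$resid, species_table)
  subunit <- ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain)
  top <- topology(data.frame(
    name = a$elety, resid = a$resno, resname = a$resid, subunit = subunit,
    mass = guess_masses(a$elety, mass_model), species = species,
    headgroup = headgroup_flags(a$resid, a$elety, species, species_table),
    stringsAsFactors = FALSE))
  box <- pdb_box(pdb)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  list(topology = top, frame = frame(0, coords, box), pdb = pdb)
}

pdb_box <- function(pdb) {
  cr <- pdb$cryst1
  if (!is.null(cr) && !is.null(cr$abc) && all(is.finite(cr$abc)) &&
      all(cr$abc > 0)) cr$abc / 10 else c(100, 100, 100)  # generous open box
}

#' Write a structure (or trajectory) as PDB
#'
#' Multi-frame trajectories are written as multi-model PDB readable by
#' [load_trajectory()].
#'
#' @param top a [topology()]
#' @param x a [frame()] or [trajectory()]
#' @param path output path
#' @export
write_pdb <- function(top, x, path) {
  p <- top$particles
  if (inherits(x, "frame")) {
    xyz <- matrix(as.numeric(t(x$coords)) * 10, nrow = 1)
    box <- x$box
  } else {
    nf <- n_frames(x)
    xyz <- t(vapply(seq_len(nf),
                    function(i) as.numeric(t(x$coords[, , i])) * 10,
                    numeric(3 * n_particles(top))))
    box <- x$box[1, ]
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = p$resid,
                   resid = substr(p$resname, 1, 4), elety = p$name,
                   chain = substr(p$subunit, 1, 1))
  invisible(path)
}

# ---- Trajectories ----------------------------------------------------------

#' Load a trajectory against a known topology
#'
#' Supported containers: multi-model PDB and DCD (both via bio3d) and
#' multi-frame GRO.  If the file stores no frame times, a uniform grid
#' `t = (0, dt, 2 dt, ...)` is applied.
#'
#' @param path trajectory file
#' @param topology a [topology()] whose particle count must match the file
#' @param dt frame spacing in ns used when the file carries no times
#' @param box fallback box (nm) for formats without box information
#' @return a [trajectory()]
#' @export
load_trajectory <- function(path, topology, dt = 0.5, box = NULL) {
  if (!file.exists(path)) stop("load_trajectory: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr"))
    stop("load_trajectory: XTC/TRR reading is not supported; convert to ",
         "DCD or multi-model PDB (e.g. with `mdconvert` or `gmx trjconv`)")
  n <- n_particles(topology)
  if (ext == "gro") {
    blocks <- read_gro_frames(path)
    counts <- vapply(blocks, `[[`, integer(1), "natoms")
    if (any(counts != n))
      stop("load_trajectory: atom count ", counts[which(counts != n)[1]],
           " does not match topology (", n, ")")
    coords <- array(0, dim = c(n, 3, length(blocks)))
    boxes <- matrix(0, length(blocks), 3)
    times <- vapply(blocks, `[[`, numeric(1), "time")
    for (i in seq_along(blocks)) {
      coords[, , i] <- blocks[[i]]$coords
      boxes[i, ] <- blocks[[i]]$box
    }
    if (anyNA(times)) times <- (seq_along(blocks) - 1) * dt
    return(trajectory(topology, times, coords, boxes))
  }
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz)
    if (ncol(xyz) != 3 * n)
      stop("load_trajectory: atom count ", ncol(xyz) / 3,
           " does not match topology (", n, ")")
    coords <- array(0, dim = c(n, 3, nf))
    for (i in seq_len(nf))
      coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    return(trajectory(topology, (seq_len(nf) - 1) * dt, coords,
                      box %||% apply(coords, 2, function(m) max(m) - min(m)) + 1))
  }
  # multi-model PDB
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (ncol(pdb$xyz) != 3 * n)
    stop("load_trajectory: atom count ", ncol(pdb$xyz) / 3,
         " does not match topology (", n, ")")
  nf <- nrow(pdb$xyz)
  coords <- array(0, dim = c(n, 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
  trajectory(topology, (seq_len(nf) - 1) * dt, coords, box %||% pdb_box(pdb))
}

#' Write a trajectory as multi-frame GRO
#'
#' @param traj a [trajectory()]
#' @param path output path
#' @export
write_gro_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- traj$topology$particles
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , i]
    writeLines(c(
      sprintf("membind trajectory, t= %.5f", traj$times[i]),
      sprintf("%5d", nrow(p)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              p$resid %% 100000L, substr(p$resname, 1, 5), substr(p$name, 1, 5),
              p$particle_id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
      sprintf("%10.5f%10.5f%10.5f", traj$box[i, 1], traj$box[i, 2],
              traj$box[i, 3])), con)
  }
  invisible(path)
}
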