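#' Simulation-to-PDB residue renumbering
#'
#' MD models of proteins with unresolved regions are renumbered relative to
#' the deposited structure.  A `residue_map` is a piecewise-constant offset
#' map between 1-based simulation residue indices and 1-based PDB residue
#' numbers, stored as non-overlapping segments.
#'
#' @param segments data frame with columns `sim_start`, `sim_end`,
#'   `pdb_offset` (pdb = sim + offset)
#' @return object of class `residue_map`
#' @export
residue_map <- function(segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("sim_start", "sim_end", "pdb_offset") %in% names(segments)))
  segments <- segments[order(segments$sim_start), , drop = FALSE]
  if (any(segments$sim_end < segments$sim_start))
    stop("residue_map: segment with sim_end < sim_start")
  if (nrow(segments) > 1 &&
      any(segments$sim_start[-1] <= segments$sim_end[-nrow(segments)]))
    stop("residue_map: segments overlap in simulation space")
  # injectivity: PDB ranges must not overlap either
  pdb_lo <- segments$sim_start + segments$pdb_offset
  pdb_hi <- segments$sim_end + segments$pdb_offset
  o <- order(pdb_lo)
  if (nrow(segments) > 1 && any(pdb_lo[o][-1] <= pdb_hi[o][-nrow(segments)]))
    stop("residue_map: mapping is not injective (PDB ranges overlap)")
  structure(list(segments = segments), class = "residue_map")
}

#' The kinase model's default renumbering
#'
#' Two segments: simulation residues 1-253 are PDB 57-309 and simulation
#' residues 254-324 are PDB 356-426 (the gap is the unmodelled insert).
#'
#' @return a [residue_map()]
#' @export
default_residue_map <- function() {
  residue_map(data.frame(sim_start = c(1L, 254L), sim_end = c(253L, 324L),
                         pdb_offset = c(56L, 102L)))
}

#' Map simulation residue indices to PDB numbering (and back)
#'
#' @param map a [residue_map()]
#' @param sim_index integer vector of simulation residue indices
#' @return integer vector of PDB residue numbers
#' @export
map_residue <- function(map, sim_index) {
  stopifnot(inherits(map, "residue_map"))
  sim_index <- as.integer(sim_index)
  s <- map$segments
  out <- integer(length(sim_index))
  for (i in seq_along(sim_index)) {
    j <- which(sim_index[i] >= s$sim_start & sim_index[i] <= s$sim_end)
    if (!length(j))
      stop("map_residue: simulation residue ", sim_index[i],
           " falls in no segment")
    out[i] <- sim_index[i] + s$pdb_offset[j]
  }
  out
}

#' @rdname map_residue
#' @param pdb_index integer vector of PDB residue numbers
#' @export
unmap_residue <- function(map, pdb_index) {
  stopifnot(inherits(map, "residue_map"))
  pdb_index <- as.integer(pdb_index)
  s <- map$segments
  out <- integer(length(pdb_index))
  for (i in seq_along(pdb_index)) {
    j <- which(pdb_index[i] >= s$sim_start + s$pdb_offset &
               pdb_index[i] <= s$sim_end + s$pdb_offset)
    if (!length(j))
      stop("unmap_residue: PDB residue ", pdb_index[i], " falls in no segment")
    out[i] <- pdb_index[i] - s$pdb_offset[j]
  }
  out
}

#' Global dimer residue numbering
#'
#' Figures of side-by-side kinase dimers label subunit-B residues by a global
#' index equal to the subunit-A simulation index plus a fixed offset (the
#' catalytic lysine, per-subunit residue 182, is labelled 505 in subunit B,
#' hence the default offset of 323).
#'
#' @param resid per-subunit simulation residue index
#' @param subunit `"A"` or `"B"`
#' @param offset subunit-B offset (default 323)
#' @return global dimer residue index
#' @export
dimer_resid <- function(resid, subunit = "A", offset = 323L) {
  ifelse(subunit == "B", resid + offset, resid)
}
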