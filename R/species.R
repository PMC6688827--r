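#' Default residue-name to species-class lookup
#'
#' Maps residue names found in structure files to the species classes used by
#' the contact machinery, and lists the particle names regarded as lipid
#' headgroup sites for each lipid class.  The defaults cover common MARTINI
#' coarse-grained names (`POPC`, `POPS`, `POP4`/`PIP4`, `POP2`/`PIP2`, beads
#' `NC3`/`CNO`/`PO4` and the inositol/phosphate beads `C1..C3`, `P1`..`P5`),
#' atomistic phosphoinositide headgroup atoms, and the bead names emitted by
#' the synthetic system builders (`HD`, `T1`, `T2`).  Everything is a plain
#' list so a user can edit it, or load a modified copy from YAML with
#' [read_species_table()].
#'
#' @return list with elements `residues` (named character vector:
#'   residue name -> species class) and `headgroups` (named list:
#'   species class -> particle names counted as headgroup)
#' @export
default_species_table <- function() {
  amino <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HSD", "HSE", "HSP")
  residues <- c(
    stats::setNames(rep("protein", length(amino)), amino),
    POPC = "PC", DOPC = "PC", DPPC = "PC", PC = "PC",
    POPS = "PS", DOPS = "PS", PS = "PS",
    POP4 = "PI4P", PIP4 = "PI4P", PI4P = "PI4P", POPI = "PI4P",
    POP2 = "PIP2", PIP2 = "PIP2",
    ION = "ion", "NA" = "ion", CL = "ion", "NA+" = "ion", "CL-" = "ion",
    SOD = "ion", CLA = "ion", K = "ion",
    W = "solvent", SOL = "solvent", HOH = "solvent", TIP3 = "solvent",
    WAT = "solvent"
  )
  headgroups <- list(
    PC   = c("NC3", "PO4", "HD", "P"),
    PS   = c("CNO", "PO4", "HD", "P"),
    PI4P = c("PO4", "C1", "C2", "C3", "P1", "P2", "P3", "P4", "P5", "HD",
             "P", "O2", "O3", "O4", "O5", "O6", "P4A", "OP42", "OP43", "OP44"),
    PIP2 = c("PO4", "C1", "C2", "C3", "P1", "P2", "P3", "P4", "P5", "HD", "P")
  )
  list(residues = residues, headgroups = headgroups)
}

#' Read a species lookup table from YAML
#'
#' @param path YAML file with top-level keys `residues` (map residue name ->
#'   class) and `headgroups` (map class -> list of particle names)
#' @return list in the format of [default_species_table()]
#' @export
read_species_table <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(is.list(y$residues), is.list(y$headgroups))
  list(residues = unlist(y$residues), headgroups = lapply(y$headgroups, unlist))
}

#' Classify residue names into species classes
#'
#' Unknown residue names are classified as `solvent` with a warning, so that
#' stray co-solutes never silently enter a lipid selection.
#'
#' @param resnames character vector
#' @param table species table, see [default_species_table()]
#' @return character vector of species classes
#' @export
classify_species <- function(resnames, table = default_species_table()) {
  cls <- unname(table$residues[resnames])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown residue name(s) classified as solvent: ",
            paste(unique(resnames[unknown]), collapse = ", "))
    cls[unknown] <- "solvent"
  }
  cls
}

headgroup_flags <- function(resnames, atom_names, species,
                            table = default_species_table()) {
  flag <- logical(length(resnames))
  for (cl in names(table$headgroups)) {
    sel <- species == cl & atom_names %in% table$headgroups[[cl]]
    flag[sel] <- TRUE
  }
  flag
}
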