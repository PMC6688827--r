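#' Select particles by expression
#'
#' A small selection language over topology metadata.  Primaries:
#' \itemize{
#'   \item `species <class>` — one of the species classes
#'   \item `resid <n> <a>-<b> ...` — residue indices and inclusive ranges
#'   \item `resname <name> ...`, `name <name> ...`, `subunit <label> ...`
#'   \item `headgroup` — lipid headgroup particles
#'   \item `protein`, `lipid`, `all`
#' }
#' combined with `and`, `or`, `not` and parentheses; `and` binds tighter than
#' `or`.  Example: `"species PI4P and headgroup"`.
#'
#' @param top a [topology()]
#' @param expression selection text
#' @return sorted integer vector of particle indices (1-based rows of the
#'   topology / coordinate matrix); empty selections are legal
#' @export
select_particles <- function(top, expression) {
  stopifnot(inherits(top, "topology"))
  tokens <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  mask <- parse_or(st, top)
  if (st$pos <= nrow(st$tokens))
    sel_error(st, "unexpected token")
  sort(which(mask))
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1)
    stop("selection error: expression must be a single string")
  # split parentheses off as their own tokens, track character positions
  expr <- gsub("\\(", " ( ", gsub("\\)", " ) ", expression))
  m <- gregexpr("[^ \t]+", expr)[[1]]
  if (m[1] == -1) stop("selection error: empty expression")
  data.frame(text = regmatches(expr, gregexpr("[^ \t]+", expr))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

sel_peek <- function(st) {
  if (st$pos > nrow(st$tokens)) NA_character_ else st$tokens$text[st$pos]
}
sel_next <- function(st) {
  tok <- sel_peek(st)
  st$pos <- st$pos + 1L
  tok
}
sel_error <- function(st, msg) {
  at <- if (st$pos > nrow(st$tokens)) "end of expression"
        else sprintf("'%s' (position %d)", st$tokens$text[st$pos],
                     st$tokens$pos[st$pos])
  stop("selection error: ", msg, " at ", at)
}

sel_keywords <- c("and", "or", "not", "(", ")", "species", "resid", "resname",
                  "name", "subunit", "headgroup", "protein", "lipid", "all")

parse_or <- function(st, top) {
  mask <- parse_and(st, top)
  while (identical(sel_peek(st), "or")) {
    sel_next(st)
    mask <- mask | parse_and(st, top)
  }
  mask
}

parse_and <- function(st, top) {
  mask <- parse_factor(st, top)
  while (identical(sel_peek(st), "and")) {
    sel_next(st)
    mask <- mask & parse_factor(st, top)
  }
  mask
}

parse_factor <- function(st, top) {
  tok <- sel_peek(st)
  if (is.na(tok)) sel_error(st, "expected a selection term")
  if (tok == "not") {
    sel_next(st)
    return(!parse_factor(st, top))
  }
  if (tok == "(") {
    sel_next(st)
    mask <- parse_or(st, top)
    if (!identical(sel_peek(st), ")")) sel_error(st, "expected ')'")
    sel_next(st)
    return(mask)
  }
  parse_primary(st, top)
}

# consume value tokens until the next keyword / paren / end
sel_values <- function(st, what) {
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% sel_keywords))
    vals <- c(vals, sel_next(st))
  if (!length(vals)) sel_error(st, paste0("expected value(s) after '", what, "'"))
  vals
}

parse_primary <- function(st, top) {
  p <- top$particles
  tok <- sel_next(st)
  switch(tok,
    species = {
      vals <- sel_values(st, "species")
      bad <- setdiff(vals, membind_species_levels())
      if (length(bad)) { st$pos <- st$pos - 1L
                         sel_error(st, paste0("unknown species '", bad[1], "'")) }
      p$species %in% vals
    },
    resid = {
      vals <- sel_values(st, "resid")
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^[0-9]+-[0-9]+$", v)) {
          ab <- as.integer(strsplit(v, "-")[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else if (grepl("^[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else { st$pos <- st$pos - 1L
                 sel_error(st, "expected residue index or range") }
      }
      p$resid %in% ids
    },
    resname = p$resname %in% sel_values(st, "resname"),
    name = p$name %in% sel_values(st, "name"),
    subunit = p$subunit %in% sel_values(st, "subunit"),
    headgroup = p$headgroup,
    protein = p$species == "protein",
    lipid = p$species %in% c("PC", "PS", "PI4P", "PIP2"),
    all = rep(TRUE, nrow(p)),
    { st$pos <- st$pos - 1L; sel_error(st, "unknown term") }
  )
}
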