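#' Atom selection mini-grammar
#'
#' Masks are strings of clauses joined by \code{and}; an atom is selected when
#' every clause holds. Clauses:
#' \itemize{
#'   \item \code{all} — every atom;
#'   \item \code{heavy} — element is not H;
#'   \item \code{resid 1-12,15} — residue ids, comma-separated values or
#'     \code{a-b} ranges (inclusive);
#'   \item \code{name N1,O6,C1'} — atom names, comma-separated;
#'   \item \code{resname G,C} — residue names;
#'   \item \code{element K} — element symbols;
#'   \item \code{not <clause>} — negation of any single clause.
#' }
#' Example: \code{"resid 5-13 and name P,O5',C5',C4',C3',O3'"} selects the
#' duplex backbone. There is no external selection language; this grammar is
#' the whole surface.
#'
#' @param x a \linkS4class{StructureModel}, \linkS4class{TrajectorySet} or
#'   \linkS4class{EnsembleBundle} (selection applies to the shared topology).
#' @param selection selection string, or an integer vector passed through
#'   unchanged (after bounds checking).
#' @return integer atom indices (1-based, in topology order).
#' @export
selectAtoms <- function(x, selection) {
  tab <- atoms(x)
  n <- nrow(tab)
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n)) stop("atom index out of range")
    return(idx)
  }
  selection <- trimws(selection)
  if (!nzchar(selection)) stop("empty selection")
  clauses <- strsplit(selection, "\\s+and\\s+")[[1L]]
  keep <- rep(TRUE, n)
  for (cl in clauses) {
    cl <- trimws(cl)
    neg <- grepl("^not\\s+", cl)
    if (neg) cl <- sub("^not\\s+", "", cl)
    m <- .clause_mask(cl, tab)
    if (neg) m <- !m
    keep <- keep & m
  }
  which(keep)
}

.clause_mask <- function(cl, tab) {
  if (cl == "all") return(rep(TRUE, nrow(tab)))
  if (cl == "heavy") return(toupper(tab$element) != "H")
  parts <- strsplit(cl, "\\s+")[[1L]]
  if (length(parts) < 2L)
    stop(sprintf("cannot parse selection clause '%s'", cl))
  key <- parts[1L]
  val <- paste(parts[-1L], collapse = "")
  items <- strsplit(val, ",", fixed = TRUE)[[1L]]
  switch(key,
    resid = {
      ids <- unlist(lapply(items, function(it) {
        if (grepl("^-?[0-9]+--?[0-9]+$", it) || grepl("^[0-9]+-[0-9]+$", it)) {
          ab <- as.integer(strsplit(it, "-", fixed = TRUE)[[1L]])
          seq.int(ab[1L], ab[2L])
        } else as.integer(it)
      }))
      if (anyNA(ids)) stop(sprintf("bad resid clause '%s'", cl))
      tab$resid %in% ids
    },
    name = tab$name %in% items,
    resname = tab$resname %in% items,
    element = toupper(tab$element) %in% toupper(items),
    stop(sprintf("unknown selection keyword '%s'", key))
  )
}

## Resolve (resid, name) pairs to atom indices; errors list unresolvable atoms.
.atom_index <- function(tab, resid, name) {
  key <- paste(tab$resid, tab$name)
  idx <- match(paste(resid, name), key)
  if (anyNA(idx)) {
    missing <- paste0(resid[is.na(idx)], ":", name[is.na(idx)])
    stop(sprintf("atoms not found in topology: %s",
                 paste(unique(missing), collapse = ", ")))
  }
  idx
}
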