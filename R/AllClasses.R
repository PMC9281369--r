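#' @import methods
NULL

## ---------------------------------------------------------------------------
## StructureModel: one conformation. Atom bookkeeping lives in a data.frame
## (name, resid, resname, element), coordinates in an n x 3 matrix (Angstrom).
## ---------------------------------------------------------------------------

#' StructureModel: a single structure with named atoms
#'
#' Holds one conformation of a nucleic-acid system: an atom table with atom
#' name, 1-based residue id, residue name and element, plus an n x 3 coordinate
#' matrix in Angstrom.
#'
#' @slot atoms data.frame with columns \code{name}, \code{resid},
#'   \code{resname}, \code{element}.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", coords = "matrix"),
  validity = function(object) {
    a <- object@atoms
    need <- c("name", "resid", "resname", "element")
    if (!all(need %in% names(a)))
      return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
    if (nrow(a) != nrow(object@coords))
      return("atom table and coordinate matrix differ in length")
    if (ncol(object@coords) != 3L)
      return("coords must have 3 columns")
    if (nrow(object@coords) && !all(is.finite(object@coords)))
      return("coordinates must be finite")
    key <- paste(a$resid, a$name)
    if (anyDuplicated(key))
      return(sprintf("duplicate (resid, atom name) pair: %s",
                     key[duplicated(key)][1L]))
    TRUE
  }
)

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns \code{name}, \code{resid},
#'   \code{resname}, \code{element}.
#' @param coords numeric n x 3 matrix in Angstrom.
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, coords) {
  atoms <- as.data.frame(atoms)
  atoms$resid <- as.integer(atoms$resid)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, coords = coords)
}

## ---------------------------------------------------------------------------
## EnsembleBundle: ordered models sharing one topology (e.g. an NMR bundle).
## ---------------------------------------------------------------------------

#' EnsembleBundle: ordered structure models sharing one topology
#'
#' @slot models list of \linkS4class{StructureModel}, identical atom ordering.
#' @slot labels character labels, one per model (e.g. "NMR-1").
#' @export
setClass("EnsembleBundle",
  representation(models = "list", labels = "character"),
  validity = function(object) {
    if (!length(object@models)) return("bundle must contain at least one model")
    if (length(object@labels) != length(object@models))
      return("labels must match model count")
    ref <- object@models[[1L]]@atoms[, c("resid", "name")]
    for (i in seq_along(object@models)) {
      m <- object@models[[i]]
      if (!is(m, "StructureModel")) return("models must be StructureModel")
      if (nrow(m@atoms) != nrow(ref))
        return(sprintf("model %d has %d atoms; model 1 has %d",
                       i, nrow(m@atoms), nrow(ref)))
      if (!identical(m@atoms[, c("resid", "name")], ref))
        return(sprintf("model %d atom ordering differs from model 1", i))
    }
    TRUE
  }
)

#' Construct an EnsembleBundle
#' @param models list of \linkS4class{StructureModel} sharing atom ordering.
#' @param labels optional character labels (default "model-1", ...).
#' @return an \linkS4class{EnsembleBundle}.
#' @export
EnsembleBundle <- function(models, labels = NULL) {
  if (is(models, "StructureModel")) models <- list(models)
  if (is.null(labels)) labels <- paste0("model-", seq_along(models))
  new("EnsembleBundle", models = models, labels = labels)
}

## ---------------------------------------------------------------------------
## TrajectorySet: frames over one topology. Coordinates as natom x 3 x nframe.
## ---------------------------------------------------------------------------

#' TrajectorySet: an MD trajectory over a fixed topology
#'
#' @slot topology \linkS4class{StructureModel} giving atom identities.
#' @slot coords numeric array natom x 3 x nframes, Angstrom.
#' @slot times numeric, frame times in ps, strictly increasing.
#' @slot box numeric matrix nframes x 3 of orthorhombic box edges in Angstrom,
#'   or a 0-row matrix when no periodic box applies.
#' @export
setClass("TrajectorySet",
  representation(topology = "StructureModel", coords = "array",
                 times = "numeric", box = "matrix"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      return("coords must be a natom x 3 x nframes array")
    if (d[1] != nrow(object@topology@atoms))
      return("frame atom count differs from topology atom count")
    if (length(object@times) != d[3])
      return("times length must equal frame count")
    if (d[3] > 1L && any(diff(object@times) <= 0))
      return("frame times must be strictly increasing")
    if (nrow(object@box) && nrow(object@box) != d[3])
      return("box must have one row per frame (or none)")
    TRUE
  }
)

#' Construct a TrajectorySet
#' @param topology \linkS4class{StructureModel}.
#' @param coords natom x 3 x nframes array (Angstrom).
#' @param times frame times in ps; default 1 ps spacing starting at 0.
#' @param box optional nframes x 3 matrix of orthorhombic box edges, or a
#'   3-vector recycled to all frames.
#' @return a \linkS4class{TrajectorySet}.
#' @export
TrajectorySet <- function(topology, coords, times = NULL, box = NULL) {
  nf <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (is.null(box)) {
    box <- matrix(numeric(0), 0L, 3L)
  } else if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = nf), nf, 3L)
  }
  new("TrajectorySet", topology = topology, coords = coords,
      times = as.numeric(times), box = box)
}

## ---------------------------------------------------------------------------
## NOETable: interproton distance restraints as atom-group pairs.
## ---------------------------------------------------------------------------

#' NOETable: NOE distance restraints
#'
#' Each restraint relates two proton groups (one or more (resid, atom name)
#' protons each; ambiguous/equivalent protons stay grouped) with lower/upper
#' bounds and an optional target distance, all in Angstrom.
#'
#' @slot restraints data.frame with columns \code{id}, \code{groupA},
#'   \code{groupB} (list columns of data.frames with \code{resid},
#'   \code{name}), \code{lower}, \code{upper}, \code{target} (NA if absent).
#' @export
setClass("NOETable",
  representation(restraints = "data.frame"),
  validity = function(object) {
    r <- object@restraints
    need <- c("id", "groupA", "groupB", "lower", "upper", "target")
    if (!all(need %in% names(r)))
      return(sprintf("restraints must have columns %s", paste(need, collapse = ", ")))
    if (nrow(r)) {
      if (any(r$lower < 0)) return("lower bounds must be >= 0")
      bad <- which(r$lower > r$upper)
      if (length(bad))
        return(sprintf("restraint %s has lower > upper", r$id[bad[1L]]))
      t_ok <- is.na(r$target) | (r$lower <= r$target & r$target <= r$upper)
      if (!all(t_ok))
        return(sprintf("restraint %s has target outside [lower, upper]",
                       r$id[which(!t_ok)[1L]]))
    }
    TRUE
  }
)

#' Construct an NOETable
#' @param restraints data.frame as documented for \linkS4class{NOETable}.
#' @return an \linkS4class{NOETable}.
#' @export
NOETable <- function(restraints) {
  if (is.null(restraints$target)) restraints$target <- NA_real_
  rownames(restraints) <- NULL
  new("NOETable", restraints = restraints)
}

## ---------------------------------------------------------------------------
## StructuralAnnotation: tetrads, loops, duplex pairs, junction.
## ---------------------------------------------------------------------------

#' StructuralAnnotation: structural elements of a quadruplex-duplex system
#'
#' @slot tetrads list of integer(4) residue groups, ordered bottom-to-top
#'   along the channel axis.
#' @slot loops data.frame with columns \code{class} (propeller, lateral,
#'   diagonal or V-shaped), \code{from}, \code{to} (inclusive residue range).
#' @slot duplexPairs integer matrix (n x 2) of Watson-Crick paired residues.
#' @slot junction integer(2) residue pair (or length 0 when absent).
#' @export
setClass("StructuralAnnotation",
  representation(tetrads = "list", loops = "data.frame",
                 duplexPairs = "matrix", junction = "integer"),
  validity = function(object) {
    for (t in object@tetrads) {
      if (length(t) != 4L) return("each tetrad must list exactly 4 residues")
    }
    if (nrow(object@loops)) {
      ok <- object@loops$class %in% c("propeller", "lateral", "diagonal", "V-shaped")
      if (!all(ok)) return("unknown loop class")
      if (any(object@loops$from > object@loops$to))
        return("loop range reversed")
    }
    if (nrow(object@duplexPairs) && ncol(object@duplexPairs) != 2L)
      return("duplexPairs must have 2 columns")
    all_res <- c(unlist(object@tetrads),
                 unlist(Map(seq, object@loops$from, object@loops$to)),
                 as.vector(object@duplexPairs))
    ## duplex pairs live inside the diagonal loop, so only tetrads vs loops
    ## need disjointness; tetrad residues must not sit in any loop range
    tet <- unlist(object@tetrads)
    in_loop <- unlist(Map(seq, object@loops$from, object@loops$to))
    if (length(intersect(tet, in_loop)))
      return("a residue is assigned to both a tetrad and a loop")
    TRUE
  }
)

#' Construct a StructuralAnnotation
#' @param tetrads list of integer(4) residue groups (may be empty; they can be
#'   filled later from \code{\link{detectTetrads}}).
#' @param loops data.frame with \code{class}, \code{from}, \code{to}.
#' @param duplexPairs two-column matrix (or data.frame) of paired residues.
#' @param junction integer(2) or NULL.
#' @return a \linkS4class{StructuralAnnotation}.
#' @export
StructuralAnnotation <- function(tetrads = list(), loops = NULL,
                                 duplexPairs = NULL, junction = NULL) {
  if (is.null(loops))
    loops <- data.frame(class = character(0), from = integer(0), to = integer(0))
  loops$from <- as.integer(loops$from)
  loops$to <- as.integer(loops$to)
  if (is.null(duplexPairs)) duplexPairs <- matrix(integer(0), 0L, 2L)
  duplexPairs <- as.matrix(duplexPairs)
  storage.mode(duplexPairs) <- "integer"
  dimnames(duplexPairs) <- NULL
  if (is.null(junction)) junction <- integer(0)
  new("StructuralAnnotation", tetrads = lapply(tetrads, as.integer),
      loops = loops, duplexPairs = duplexPairs, junction = as.integer(junction))
}

## ---------------------------------------------------------------------------
## Result containers with invariants worth enforcing.
## ---------------------------------------------------------------------------

#' RDFProfile: radial distribution function from a solute centre of mass
#'
#' @slot r numeric bin centers (Angstrom).
#' @slot g numeric g(r) values (dimensionless, >= 0).
#' @slot cumulative numeric mean particle count within r (non-decreasing).
#' @slot binWidth numeric (Angstrom).
#' @slot bulkDensity numeric, particles per cubic Angstrom used to normalize.
#' @export
setClass("RDFProfile",
  representation(r = "numeric", g = "numeric", cumulative = "numeric",
                 binWidth = "numeric", bulkDensity = "numeric"),
  validity = function(object) {
    if (length(object@g) != length(object@r)) return("g and r differ in length")
    if (length(object@cumulative) != length(object@r))
      return("cumulative and r differ in length")
    if (any(object@g < -1e-12)) return("g(r) must be non-negative")
    if (any(diff(object@cumulative) < -1e-9))
      return("cumulative count must be non-decreasing")
    if (object@bulkDensity <= 0) return("bulk density must be positive")
    TRUE
  }
)

#' DensityGrid: voxelized time-averaged particle density (SDF)
#'
#' @slot origin numeric(3), corner of voxel (1,1,1) in Angstrom.
#' @slot edge numeric voxel edge length in Angstrom.
#' @slot values 3-d array of densities normalized by the reference density
#'   (1 means bulk-like).
#' @slot referenceDensity numeric, particles per cubic Angstrom.
#' @slot rawCountSum numeric, total (un-normalized) counts over all frames.
#' @export
setClass("DensityGrid",
  representation(origin = "numeric", edge = "numeric", values = "array",
                 referenceDensity = "numeric", rawCountSum = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3-d array")
    if (object@edge <= 0) return("voxel edge must be positive")
    if (object@referenceDensity <= 0) return("reference density must be positive")
    TRUE
  }
)

#' ChannelOccupancy: per-frame channel states of selected ions
#'
#' @slot states character matrix, frames x ions, values in
#'   bulk/approach/in-plane/cavity.
#' @slot ions integer resids of the classified ions.
#' @slot events data.frame with \code{ion}, \code{frame}, \code{from},
#'   \code{to} listing every state change.
#' @slot boundCount integer per-frame count of ions in the cavity.
#' @export
setClass("ChannelOccupancy",
  representation(states = "matrix", ions = "integer", events = "data.frame",
                 boundCount = "integer"),
  validity = function(object) {
    ok <- object@states %in% c("bulk", "approach", "in-plane", "cavity")
    if (!all(ok)) return("unknown channel state label")
    if (ncol(object@states) != length(object@ions))
      return("state columns must match ion count")
    if (length(object@boundCount) != nrow(object@states))
      return("boundCount must have one entry per frame")
    TRUE
  }
)

#' ClusterSolution: hierarchical clustering of trajectory frames
#'
#' @slot labels integer per-frame cluster label (1..k).
#' @slot populations numeric cluster population fractions, summing to 1.
#' @slot representatives integer medoid frame index per cluster.
#' @slot linkage character linkage method used.
#' @slot merge merge record from \code{\link[stats]{hclust}}.
#' @slot stride integer frame stride applied before the pairwise matrix.
#' @export
setClass("ClusterSolution",
  representation(labels = "integer", populations = "numeric",
                 representatives = "integer", linkage = "character",
                 merge = "matrix", stride = "integer"),
  validity = function(object) {
    k <- length(object@populations)
    if (length(object@representatives) != k)
      return("one representative per cluster required")
    if (abs(sum(object@populations) - 1) > 1e-9)
      return("populations must sum to 1")
    if (length(object@labels) && !all(object@labels %in% seq_len(k)))
      return("labels must cover 1..k")
    for (c in seq_len(k)) {
      if (object@labels[object@representatives[c]] != c)
        return("representative must belong to its cluster")
    }
    TRUE
  }
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d atoms, %d residues\n",
              nrow(object@atoms), length(unique(object@atoms$resid))))
})

setMethod("show", "EnsembleBundle", function(object) {
  cat(sprintf("EnsembleBundle: %d models x %d atoms (%s%s)\n",
              length(object@models), nrow(object@models[[1L]]@atoms),
              paste(utils::head(object@labels, 3L), collapse = ", "),
              if (length(object@labels) > 3L) ", ..." else ""))
})

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@coords)
  cat(sprintf("TrajectorySet: %d frames x %d atoms, t = %.6g..%.6g ps%s\n",
              d[3], d[1], object@times[1L], object@times[d[3]],
              if (nrow(object@box)) ", periodic" else ""))
})

setMethod("show", "NOETable", function(object) {
  cat(sprintf("NOETable: %d restraints\n", nrow(object@restraints)))
})

setMethod("show", "StructuralAnnotation", function(object) {
  cat(sprintf(
    "StructuralAnnotation: %d tetrads, %d loops, %d duplex pairs, junction %s\n",
    length(object@tetrads), nrow(object@loops), nrow(object@duplexPairs),
    if (length(object@junction)) paste(object@junction, collapse = "-") else "none"))
})

setMethod("show", "RDFProfile", function(object) {
  cat(sprintf("RDFProfile: %d bins of %.3g A, bulk density %.6g /A^3\n",
              length(object@r), object@binWidth, object@bulkDensity))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels, edge %.3g A\n",
              d[1], d[2], d[3], object@edge))
})

setMethod("show", "ChannelOccupancy", function(object) {
  cat(sprintf("ChannelOccupancy: %d frames x %d ions, %d events\n",
              nrow(object@states), length(object@ions), nrow(object@events)))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: %d frames in %d clusters (%s linkage)\n",
              length(object@labels), length(object@populations),
              object@linkage))
})
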