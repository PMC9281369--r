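## Accessor generics. Slot access stays internal to the package; user code
## goes through these.

#' @rdname accessors
#' @param x a quadval object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @rdname accessors
#' @export
setGeneric("modelLabels", function(x) standardGeneric("modelLabels"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("boxEdges", function(x) standardGeneric("boxEdges"))

#' @rdname accessors
#' @export
setGeneric("restraints", function(x) standardGeneric("restraints"))

#' @rdname accessors
#' @export
setGeneric("tetrads", function(x) standardGeneric("tetrads"))

#' @rdname accessors
#' @export
setGeneric("loops", function(x) standardGeneric("loops"))

#' @rdname accessors
#' @export
setGeneric("duplexPairs", function(x) standardGeneric("duplexPairs"))

#' @rdname accessors
#' @export
setGeneric("junction", function(x) standardGeneric("junction"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("channelStates", function(x) standardGeneric("channelStates"))

#' @rdname accessors
#' @export
setGeneric("channelEvents", function(x) standardGeneric("channelEvents"))

#' Accessors for quadval classes
#'
#' \code{atoms} returns the atom table; \code{coords} the coordinates (for a
#' \linkS4class{TrajectorySet}, of one frame); \code{nAtoms}/\code{nFrames}/
#' \code{nModels} the obvious sizes; \code{frameTimes} the frame times in ps;
#' \code{boxEdges} the per-frame orthorhombic box edges (or NULL);
#' \code{restraints} the restraint data.frame of an \linkS4class{NOETable};
#' \code{tetrads}, \code{loops}, \code{duplexPairs}, \code{junction} the
#' elements of a \linkS4class{StructuralAnnotation};
#' \code{clusterLabels}, \code{populations}, \code{representatives} the parts
#' of a \linkS4class{ClusterSolution}; \code{channelStates},
#' \code{channelEvents} the parts of a \linkS4class{ChannelOccupancy}.
#'
#' @param x a quadval object.
#' @param frame 1-based frame index (TrajectorySet coords only).
#' @param ... passed on between methods.
#' @name accessors
NULL

#' @rdname accessors
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("atoms", "TrajectorySet", function(x) x@topology@atoms)
#' @rdname accessors
setMethod("atoms", "EnsembleBundle", function(x) x@models[[1L]]@atoms)

#' @rdname accessors
setMethod("coords", "StructureModel", function(x, ...) x@coords)
#' @rdname accessors
setMethod("coords", "TrajectorySet", function(x, frame = 1L, ...) {
  x@coords[, , frame, drop = TRUE]
})

#' @rdname accessors
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "TrajectorySet", function(x) dim(x@coords)[1L])
#' @rdname accessors
setMethod("nAtoms", "EnsembleBundle", function(x) nrow(x@models[[1L]]@atoms))

#' @rdname accessors
setMethod("nFrames", "TrajectorySet", function(x) dim(x@coords)[3L])

#' @rdname accessors
setMethod("nModels", "EnsembleBundle", function(x) length(x@models))
#' @rdname accessors
setMethod("models", "EnsembleBundle", function(x) x@models)
#' @rdname accessors
setMethod("modelLabels", "EnsembleBundle", function(x) x@labels)

#' @rdname accessors
setMethod("frameTimes", "TrajectorySet", function(x) x@times)
#' @rdname accessors
setMethod("boxEdges", "TrajectorySet", function(x) {
  if (nrow(x@box)) x@box else NULL
})

#' @rdname accessors
setMethod("restraints", "NOETable", function(x) x@restraints)

#' @rdname accessors
setMethod("tetrads", "StructuralAnnotation", function(x) x@tetrads)
#' @rdname accessors
setMethod("loops", "StructuralAnnotation", function(x) x@loops)
#' @rdname accessors
setMethod("duplexPairs", "StructuralAnnotation", function(x) x@duplexPairs)
#' @rdname accessors
setMethod("junction", "StructuralAnnotation", function(x) x@junction)

#' @rdname accessors
setMethod("clusterLabels", "ClusterSolution", function(x) x@labels)
#' @rdname accessors
setMethod("populations", "ClusterSolution", function(x) x@populations)
#' @rdname accessors
setMethod("representatives", "ClusterSolution", function(x) x@representatives)

#' @rdname accessors
setMethod("channelStates", "ChannelOccupancy", function(x) x@states)
#' @rdname accessors
setMethod("channelEvents", "ChannelOccupancy", function(x) x@events)

#' Extract a subset of frames from a trajectory
#'
#' Half-open, 0-based frame ranges follow the package convention; use
#' \code{frames} as a plain 1-based integer vector instead when preferred.
#'
#' @param x a \linkS4class{TrajectorySet}.
#' @param from,to 0-based half-open range [from, to).
#' @param frames alternative: explicit 1-based frame indices.
#' @return a \linkS4class{TrajectorySet} with the selected frames.
#' @export
frameSubset <- function(x, from = NULL, to = NULL, frames = NULL) {
  stopifnot(is(x, "TrajectorySet"))
  if (is.null(frames)) {
    if (is.null(from) || is.null(to)) stop("give either frames or from/to")
    if (from < 0 || to > nFrames(x) || from >= to)
      stop("frame range out of bounds")
    frames <- seq.int(from + 1L, to)
  }
  TrajectorySet(x@topology, x@coords[, , frames, drop = FALSE],
                times = x@times[frames],
                box = if (nrow(x@box)) x@box[frames, , drop = FALSE] else NULL)
}

#' Turn one trajectory frame into a StructureModel
#' @param x a \linkS4class{TrajectorySet}.
#' @param frame 1-based frame index.
#' @return a \linkS4class{StructureModel}.
#' @export
frameModel <- function(x, frame) {
  StructureModel(x@topology@atoms, x@coords[, , frame])
}
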