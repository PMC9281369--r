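## Duplex-flexibility clustering: frames aligned on the quadruplex, distances
## measured on the duplex, agglomerative merging, and representativeness
## reporting.

#' Pairwise RMSD matrix between trajectory frames
#'
#' Entry (i, j) is the RMSD over \code{measureMask} after superposing frame j
#' onto frame i using \code{alignMask} (the align-on-quadruplex,
#' measure-on-duplex scheme used to expose duplex conformational families).
#' The matrix is symmetrized by averaging the (i, j) and (j, i) fits.
#'
#' @param traj a \linkS4class{TrajectorySet} with >= 2 frames.
#' @param alignMask,measureMask selection strings.
#' @param stride keep every stride-th frame before the O(n^2) computation
#'   (default 1; consider 10 for > 10^4 frames). The stride is recorded in the
#'   \code{"stride"} attribute.
#' @return symmetric numeric matrix (Angstrom) with zero diagonal.
#' @export
pairwiseRmsdMatrix <- function(traj, alignMask, measureMask, stride = 1L) {
  nf0 <- nFrames(traj)
  if (nf0 < 2L) stop("need at least 2 frames")
  frames <- seq.int(1L, nf0, by = stride)
  tab <- atoms(traj)
  ai <- .select_on(tab, alignMask)
  mi <- .select_on(tab, measureMask)
  if (!length(ai) || !length(mi)) stop("empty mask")
  n <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi_a <- traj@coords[ai, , frames[i]]
    xi_m <- traj@coords[mi, , frames[i]]
    for (j in seq.int(i + 1L, n)) {
      fit_ji <- superpose(traj@coords[ai, , frames[j]], xi_a)
      d1 <- .rmsd_raw(fit_ji$transform(traj@coords[mi, , frames[j]]), xi_m)
      fit_ij <- superpose(xi_a, traj@coords[ai, , frames[j]])
      d2 <- .rmsd_raw(fit_ij$transform(xi_m), traj@coords[mi, , frames[j]])
      m[i, j] <- m[j, i] <- (d1 + d2) / 2
    }
  }
  attr(m, "stride") <- as.integer(stride)
  attr(m, "frames") <- frames
  m
}

#' Hierarchical agglomerative clustering of a distance matrix
#'
#' Standard agglomerative merging (via \code{\link[stats]{hclust}}) cut either
#' at a cluster count or at a merge-height cutoff. The representative of each
#' cluster is its medoid, the member minimizing the summed intra-cluster
#' distance, with ties broken by the lowest frame index.
#'
#' @param m symmetric distance matrix (e.g. from
#'   \code{\link{pairwiseRmsdMatrix}}).
#' @param linkage linkage method (default "average").
#' @param k target number of clusters (mutually exclusive with \code{h}).
#' @param h merge-height cutoff in Angstrom.
#' @return a \linkS4class{ClusterSolution}.
#' @export
hierarchicalCluster <- function(m, linkage = "average", k = NULL, h = NULL) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  if (!is.null(k) && k > n) stop("more clusters requested than frames")
  if (is.null(k) && is.null(h)) stop("give k or h")
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
            else stats::cutree(hc, h = h)
  ## relabel clusters by first appearance for determinism
  first_seen <- order(vapply(seq_len(max(labels)),
                             function(c) min(which(labels == c)), integer(1)))
  relabel <- integer(max(labels))
  relabel[first_seen] <- seq_along(first_seen)
  labels <- relabel[labels]
  kk <- max(labels)
  reps <- integer(kk)
  pops <- numeric(kk)
  for (c in seq_len(kk)) {
    memb <- which(labels == c)
    pops[c] <- length(memb) / n
    ssum <- rowSums(m[memb, memb, drop = FALSE])
    reps[c] <- memb[which.min(ssum)]  # which.min takes the lowest index on ties
  }
  new("ClusterSolution", labels = as.integer(labels), populations = pops,
      representatives = reps, linkage = linkage, merge = hc$merge,
      stride = if (is.null(attr(m, "stride"))) 1L else attr(m, "stride"))
}

#' Representative conformations to a cumulative coverage
#'
#' Sorts clusters by population (descending, ties broken by the earlier
#' representative frame) and returns the shortest prefix whose cumulative
#' population reaches \code{coverage} — the representativeness criterion used
#' to quantify duplex conformational diversity.
#'
#' @param solution a \linkS4class{ClusterSolution}.
#' @param coverage target cumulative population in (0, 1], default 0.80.
#' @return data.frame with columns \code{cluster}, \code{population},
#'   \code{cumulative}, \code{representative} (frame index).
#' @export
representativeSet <- function(solution, coverage = 0.80) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  pops <- populations(solution)
  reps <- representatives(solution)
  ord <- order(-pops, reps)
  cum <- cumsum(pops[ord])
  need <- which(cum >= coverage - 1e-12)[1L]
  sel <- ord[seq_len(need)]
  data.frame(cluster = sel, population = pops[sel],
             cumulative = cum[seq_len(need)], representative = reps[sel])
}
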