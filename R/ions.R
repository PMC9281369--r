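## Ion-atmosphere analyses: COM-referenced RDF with bulk-shell normalization,
## voxelized spatial densities (SDF), channel-occupancy classification, and
## occupancy-based binding free energies.

#' Radial distribution function from a solute centre of mass
#'
#' Counts selected particles in spherical shells around the per-frame centre
#' of mass of \code{soluteMask}, under the minimum-image convention when the
#' trajectory carries a box, and normalizes by the ideal-shell expectation
#' \eqn{\rho 4\pi r^2 dr}. The reference bulk density is measured in a shell
#' at \code{bulkShell} from the centre of mass, following the convention of
#' normalizing against the density far from an irregular solute; no
#' excluded-volume correction is applied (the shells near the solute surface
#' therefore underestimate contact densities, a known qualitative limitation
#' recorded in the profile's metadata).
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param soluteMask selection string for the reference centre of mass.
#' @param particleSelection selection string for the counted particles.
#' @param binWidth shell thickness in Angstrom.
#' @param rMax maximum radius in Angstrom.
#' @param bulkShell two radii (Angstrom) bounding the reference bulk shell.
#' @param bulkDensity override: use this bulk density (particles per cubic
#'   Angstrom) instead of measuring the shell.
#' @return an \linkS4class{RDFProfile}.
#' @export
rdfCom <- function(traj, soluteMask, particleSelection, binWidth = 0.1,
                   rMax = 35, bulkShell = c(30, 31), bulkDensity = NULL) {
  tab <- atoms(traj)
  sol <- .select_on(tab, soluteMask)
  par <- .select_on(tab, particleSelection)
  if (!length(par)) stop("empty particle selection")
  if (!length(sol)) stop("empty solute mask")
  nf <- nFrames(traj)
  box <- boxEdges(traj)
  nbin <- ceiling(rMax / binWidth)
  counts <- numeric(nbin)
  bulk_counts <- 0
  shell_vol <- 4 / 3 * pi * (bulkShell[2L]^3 - bulkShell[1L]^3)
  for (f in seq_len(nf)) {
    xyz <- traj@coords[, , f]
    com <- colMeans(xyz[sol, , drop = FALSE])
    b <- if (!is.null(box)) box[f, ] else NULL
    if (!is.null(b) && bulkShell[2L] > min(b) / 2)
      stop("bulk shell lies outside the periodic box")
    d <- sweep(xyz[par, , drop = FALSE], 2L, com)
    d <- .min_image(d, b)
    r <- sqrt(rowSums(d^2))
    idx <- floor(r / binWidth) + 1L
    idx <- idx[idx >= 1L & idx <= nbin]
    counts <- counts + tabulate(idx, nbins = nbin)
    bulk_counts <- bulk_counts + sum(r >= bulkShell[1L] & r < bulkShell[2L])
  }
  counts <- counts / nf
  rho <- if (!is.null(bulkDensity)) bulkDensity
         else (bulk_counts / nf) / shell_vol
  if (!is.finite(rho) || rho <= 0)
    stop("no particles in the bulk reference shell; supply bulkDensity")
  edges <- (seq_len(nbin) - 1L) * binWidth
  shell_vols <- 4 * pi * (edges + binWidth / 2)^2 * binWidth
  g <- counts / (rho * shell_vols)
  new("RDFProfile", r = edges + binWidth / 2, g = g,
      cumulative = cumsum(counts), binWidth = binWidth, bulkDensity = rho)
}

#' Spatial distribution function on a voxel grid
#'
#' Frames are first superposed onto the first frame over \code{alignMask} (so
#' the density is accumulated around a fixed solute orientation), then the
#' selected particles are binned into cubic voxels and the time-averaged
#' occupancy is normalized by \code{referenceDensity * voxelVolume}: a voxel
#' value of 1 is bulk-water-like density.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param particleSelection selection string for the gridded particles.
#' @param voxelVolume voxel volume in cubic Angstrom (default 0.125, i.e.
#'   0.5 Angstrom edges).
#' @param referenceDensity particles per cubic Angstrom; the default 0.033456
#'   is water at 1.0 g/mL.
#' @param alignMask selection used to superpose frames; NULL skips alignment
#'   (already-aligned input).
#' @param padding grid margin in Angstrom beyond the particle extent.
#' @return a \linkS4class{DensityGrid}.
#' @export
sdfGrid <- function(traj, particleSelection, voxelVolume = 0.125,
                    referenceDensity = 0.033456, alignMask = "heavy",
                    padding = 1) {
  if (voxelVolume <= 0) stop("voxel volume must be positive")
  if (referenceDensity <= 0) stop("reference density must be positive")
  tab <- atoms(traj)
  par <- .select_on(tab, particleSelection)
  if (!length(par)) stop("empty particle selection")
  edge <- voxelVolume^(1 / 3)
  nf <- nFrames(traj)
  ## collect aligned particle positions
  pts <- vector("list", nf)
  grab <- function(f) matrix(traj@coords[par, , f], ncol = 3L)
  if (!is.null(alignMask)) {
    am <- .select_on(tab, alignMask)
    ref <- matrix(traj@coords[am, , 1L], ncol = 3L)
    for (f in seq_len(nf)) {
      fit <- superpose(matrix(traj@coords[am, , f], ncol = 3L), ref)
      pts[[f]] <- fit$transform(grab(f))
    }
  } else {
    for (f in seq_len(nf)) pts[[f]] <- grab(f)
  }
  all_pts <- do.call(rbind, pts)
  lo <- apply(all_pts, 2L, min) - padding
  hi <- apply(all_pts, 2L, max) + padding
  nvox <- pmax(1L, as.integer(ceiling((hi - lo) / edge)))
  counts <- array(0, dim = nvox)
  for (f in seq_len(nf)) {
    p <- pts[[f]]
    if (is.null(dim(p))) p <- matrix(p, 1L, 3L)
    ijk <- floor(sweep(p, 2L, lo) / edge) + 1L
    keep <- ijk[, 1L] >= 1L & ijk[, 1L] <= nvox[1L] &
            ijk[, 2L] >= 1L & ijk[, 2L] <= nvox[2L] &
            ijk[, 3L] >= 1L & ijk[, 3L] <= nvox[3L]
    ijk <- ijk[keep, , drop = FALSE]
    for (row in seq_len(nrow(ijk)))
      counts[ijk[row, 1L], ijk[row, 2L], ijk[row, 3L]] <-
        counts[ijk[row, 1L], ijk[row, 2L], ijk[row, 3L]] + 1
  }
  values <- (counts / nf) / (referenceDensity * voxelVolume)
  new("DensityGrid", origin = lo, edge = edge, values = values,
      referenceDensity = referenceDensity, rawCountSum = sum(counts))
}

#' Write a density grid in OpenDX format
#' @param grid a \linkS4class{DensityGrid}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDensityGrid <- function(grid, path) {
  d <- dim(grid@values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.4f 0 0", grid@edge),
    sprintf("delta 0 %.4f 0", grid@edge),
    sprintf("delta 0 0 %.4f", grid@edge),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(d))), con)
  vals <- as.vector(aperm(grid@values, c(3, 2, 1)))  # x fastest -> z fastest
  full <- length(vals) %/% 3L
  if (full > 0) {
    m <- matrix(vals[seq_len(full * 3L)], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  rem <- vals[(full * 3L + 1L):length(vals)]
  if (length(vals) %% 3L)
    writeLines(paste(sprintf("%.6g", rem), collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Classify channel-cation states frame by frame
#'
#' Every selected ion is labelled per frame from the geometry of the tetrad
#' O6 planes: \code{cavity} when within \code{cavityCutoff} of any inter-plane
#' midpoint; otherwise \code{in-plane} when within \code{planeHalfwidth} of a
#' tetrad O6-centroid plane and inside that tetrad's O6 ring radius (plus 1
#' Angstrom of slack); otherwise \code{approach} when within
#' \code{approachCutoff} of an outer plane on the solvent side and near the
#' channel axis; otherwise \code{bulk}. Events are emitted on every state
#' change.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param tetradGroups list of integer(4) tetrad residue groups (>= 2, bottom
#'   to top).
#' @param ionSelection selection string for the ions (default all K).
#' @param cavityCutoff,planeHalfwidth,approachCutoff thresholds in Angstrom.
#' @return a \linkS4class{ChannelOccupancy}.
#' @export
classifyChannelStates <- function(traj, tetradGroups,
                                  ionSelection = "element K",
                                  cavityCutoff = 2.0, planeHalfwidth = 1.0,
                                  approachCutoff = 4.5) {
  if (length(tetradGroups) < 2L)
    stop("channel classification needs at least 2 tetrads")
  tab <- atoms(traj)
  ions <- .select_on(tab, ionSelection)
  if (!length(ions)) stop("empty ion selection")
  nf <- nFrames(traj)
  states <- matrix(NA_character_, nf, length(ions))
  for (f in seq_len(nf)) {
    xyz <- traj@coords[, , f]
    anch <- .channel_anchors(xyz, tab, tetradGroups)
    ntet <- nrow(anch$centroids)
    for (j in seq_along(ions)) {
      p <- xyz[ions[j], ]
      ## the in-plane slab test is tighter than the cavity-sphere test and
      ## takes precedence: with a canonical 3.4 A rise the two regions
      ## overlap, and an ion seated in an O6 plane is not cavity-bound
      lab <- "bulk"
      for (t in seq_len(ntet)) {
        rel <- p - anch$centroids[t, ]
        axial <- sum(rel * anch$axis)
        radial <- sqrt(max(0, sum(rel^2) - axial^2))
        rad_ok <- radial <= anch$planes[[t]]$radius + 1
        if (abs(axial) <= planeHalfwidth && rad_ok) {
          lab <- "in-plane"
          break
        }
        solvent_side <- (t == 1L && axial < 0) || (t == ntet && axial > 0)
        if (solvent_side && abs(axial) <= approachCutoff && rad_ok)
          lab <- "approach"
      }
      if (lab != "in-plane") {
        dmid <- sqrt(rowSums(sweep(anch$midpoints, 2L, p)^2))
        if (any(dmid <= cavityCutoff)) lab <- "cavity"
      }
      states[f, j] <- lab
    }
  }
  events <- list()
  for (j in seq_along(ions)) {
    ch <- which(states[-1L, j] != states[-nf, j])
    for (f in ch) {
      events[[length(events) + 1L]] <- data.frame(
        ion = tab$resid[ions[j]], frame = f,  # 0-based frame of the new state
        from = states[f, j], to = states[f + 1L, j])
    }
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(ion = integer(0), frame = integer(0),
                            from = character(0), to = character(0))
  new("ChannelOccupancy", states = states, ions = tab$resid[ions],
      events = events, boundCount = as.integer(rowSums(states == "cavity")))
}

#' Occupancy-based ion binding free energy
#'
#' Counts bound versus unbound ion-frames, forms the equilibrium constant
#' K = bound/unbound, and reports the Gibbs free-energy difference
#' \eqn{\Delta G = -RT \ln K} in kJ/mol.
#'
#' @param occupancy a \linkS4class{ChannelOccupancy}.
#' @param boundStates states counted as bound (default "cavity": an ion seated
#'   between two tetrad planes).
#' @param temperature Kelvin.
#' @return list with \code{boundFraction}, \code{unboundFraction}, \code{K},
#'   \code{deltaG} (kJ/mol; NA with \code{oneSided = TRUE} when a class is
#'   empty), \code{oneSided}, \code{temperature}.
#' @export
bindingFreeEnergy <- function(occupancy, boundStates = "cavity",
                              temperature = 300) {
  st <- channelStates(occupancy)
  n_bound <- sum(st %in% boundStates)
  n_unbound <- length(st) - n_bound
  R <- 8.314
  if (n_bound == 0L || n_unbound == 0L) {
    return(list(boundFraction = n_bound / length(st),
                unboundFraction = n_unbound / length(st),
                K = if (n_unbound == 0L) Inf else 0,
                deltaG = NA_real_, oneSided = TRUE,
                temperature = temperature))
  }
  K <- n_bound / n_unbound
  list(boundFraction = n_bound / length(st),
       unboundFraction = n_unbound / length(st), K = K,
       deltaG = -R * temperature * log(K) / 1000, oneSided = FALSE,
       temperature = temperature)
}
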