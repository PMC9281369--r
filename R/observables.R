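## Structural observables compared against the NMR bundle: RMSD splits, RMSF,
## NOE back-calculation with r^-6 ensemble averaging, H-bond distance/angle
## series, and backbone torsion occupancy matrices.

## resolve a selection on the trajectory topology and align it with a
## reference model by (resid, atom name); errors if an atom is absent
.match_masks <- function(traj_tab, ref_tab, selection) {
  idx_t <- which(seq_len(nrow(traj_tab)) %in%
                   .select_on(traj_tab, selection))
  if (!length(idx_t)) stop("empty mask: ", selection)
  idx_r <- .atom_index(ref_tab, traj_tab$resid[idx_t], traj_tab$name[idx_t])
  list(traj = idx_t, ref = idx_r)
}

.select_on <- function(tab, selection) {
  fake <- StructureModel(tab, matrix(0, nrow(tab), 3L))
  selectAtoms(fake, selection)
}

#' Per-frame RMSD of a trajectory against reference models
#'
#' Every frame is superposed onto each reference model using \code{alignMask}
#' (Kabsch-optimal) and the RMSD is then measured over \code{measureMask},
#' which may differ (e.g. align on everything, measure on the tetrad-core
#' nucleobases). An optional centred running average with an edge-shrunk
#' window is attached, the usual way long RMSD traces are smoothed for
#' plotting.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param references an \linkS4class{EnsembleBundle} or single
#'   \linkS4class{StructureModel}.
#' @param alignMask,measureMask selection strings (see
#'   \code{\link{selectAtoms}}); \code{measureMask} defaults to the align
#'   mask.
#' @param window running-average window length in frames (NULL for none).
#' @return data.frame with columns \code{reference}, \code{frame} (0-based),
#'   \code{time}, \code{rmsd} and, when \code{window} is given,
#'   \code{runavg}.
#' @export
rmsdSeries <- function(traj, references, alignMask = "heavy",
                       measureMask = NULL, window = NULL) {
  if (is(references, "StructureModel"))
    references <- EnsembleBundle(list(references))
  if (is.null(measureMask)) measureMask <- alignMask
  ttab <- atoms(traj)
  rtab <- atoms(references)
  am <- .match_masks(ttab, rtab, alignMask)
  mm <- .match_masks(ttab, rtab, measureMask)
  nf <- nFrames(traj)
  out <- vector("list", nModels(references))
  for (k in seq_len(nModels(references))) {
    ref_xyz <- coords(models(references)[[k]])
    rmsd <- numeric(nf)
    for (f in seq_len(nf)) {
      fr <- traj@coords[, , f]
      fit <- superpose(fr[am$traj, , drop = FALSE],
                       ref_xyz[am$ref, , drop = FALSE])
      moved <- fit$transform(fr[mm$traj, , drop = FALSE])
      rmsd[f] <- .rmsd_raw(moved, ref_xyz[mm$ref, , drop = FALSE])
    }
    df <- data.frame(reference = modelLabels(references)[k],
                     frame = seq_len(nf) - 1L, time = frameTimes(traj),
                     rmsd = rmsd)
    if (!is.null(window)) df$runavg <- runningAverage(rmsd, window)
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Root-mean-square fluctuation about the average structure
#'
#' Frames are superposed onto their mean structure (the mean is recomputed
#' once after an initial alignment) before fluctuations are taken; the
#' per-residue profile averages the per-atom RMSF over each residue's masked
#' atoms.
#'
#' @param traj a \linkS4class{TrajectorySet} with >= 2 frames.
#' @param mask selection string.
#' @return list with \code{perAtom} (data.frame: resid, name, rmsf) and
#'   \code{perResidue} (data.frame: resid, rmsf).
#' @export
rmsfProfile <- function(traj, mask = "heavy") {
  nf <- nFrames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  tab <- atoms(traj)
  idx <- .select_on(tab, mask)
  if (!length(idx)) stop("empty mask: ", mask)
  sub <- traj@coords[idx, , , drop = FALSE]
  ## iterate the average once: align to the raw mean, re-average, re-align
  avg <- apply(sub, c(1, 2), mean)
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      fit <- superpose(sub[, , f], avg)
      sub[, , f] <- fit$transform(sub[, , f])
    }
    if (pass == 1L) avg <- apply(sub, c(1, 2), mean)
  }
  disp2 <- vapply(seq_len(nf), function(f) rowSums((sub[, , f] - avg)^2),
                  numeric(length(idx)))
  rmsf <- sqrt(rowMeans(matrix(disp2, nrow = length(idx))))
  per_atom <- data.frame(resid = tab$resid[idx], name = tab$name[idx],
                         rmsf = rmsf)
  per_res <- stats::aggregate(rmsf ~ resid, per_atom, mean)
  list(perAtom = per_atom, perResidue = per_res)
}

.equilibrated_frames <- function(traj, equilibration) {
  nf <- nFrames(traj)
  if (is.function(equilibration)) {
    keep <- which(equilibration(frameTimes(traj)))
  } else if (is.character(equilibration) && equilibration == "plateau") {
    ## first frame after which the all-atom RMSD running average stays within
    ## 0.5 A of its final value
    rs <- rmsdSeries(frameSubset(traj, frames = seq_len(nf)),
                     frameModel(traj, 1L), alignMask = "all",
                     window = max(3L, nf %/% 10L))
    ra <- rs$runavg
    final <- ra[nf]
    ok <- abs(ra - final) <= 0.5
    start <- nf
    for (f in rev(seq_len(nf))) {
      if (!ok[f]) break
      start <- f
    }
    keep <- seq.int(start, nf)
  } else if (is.numeric(equilibration) && length(equilibration) == 1L &&
             equilibration < 1) {
    keep <- seq.int(floor(equilibration * nf) + 1L, nf)
  } else {
    keep <- as.integer(equilibration)
  }
  if (!length(keep)) stop("zero equilibrated frames")
  keep
}

#' Back-calculate NOE distances from a trajectory
#'
#' For each restraint the effective distance is the r^-6 ensemble average
#' \eqn{d = \langle r^{-6} \rangle^{-1/6}}, where the mean pools all
#' equilibrated frames and all inter-group proton pairs (equivalent protons
#' are averaged, not summed, so a constant distance back-calculates to
#' itself). The excess column is \code{max(0, lower - d, d - upper)}.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param table an \linkS4class{NOETable}.
#' @param equilibration fraction of initial frames to discard (default 0.1),
#'   "plateau" for the running-average plateau criterion, explicit 1-based
#'   frame indices, or a predicate over frame times.
#' @return data.frame with columns \code{id}, \code{residA}, \code{residB},
#'   \code{d}, \code{lower}, \code{upper}, \code{target}, \code{excess}.
#' @export
noeBackcalculate <- function(traj, table, equilibration = 0.1) {
  r <- restraints(table)
  tab <- atoms(traj)
  frames <- .equilibrated_frames(traj, equilibration)
  n <- nrow(r)
  d <- numeric(n)
  for (i in seq_len(n)) {
    ia <- .atom_index(tab, r$groupA[[i]]$resid, r$groupA[[i]]$name)
    ib <- .atom_index(tab, r$groupB[[i]]$resid, r$groupB[[i]]$name)
    acc <- 0
    for (f in frames) {
      xyz <- traj@coords[, , f]
      dx <- xyz[rep(ia, each = length(ib)), , drop = FALSE] -
            xyz[rep(ib, times = length(ia)), , drop = FALSE]
      r2 <- rowSums(dx^2)
      acc <- acc + mean(r2^-3)
    }
    d[i] <- (acc / length(frames))^(-1 / 6)
  }
  excess <- pmax(0, r$lower - d, d - r$upper)
  ## guard against float noise so exact-bound restraints (padding 0 against
  ## their own reference) report excess identically 0
  excess[excess < 1e-9] <- 0
  data.frame(
    id = r$id,
    residA = vapply(r$groupA, function(g) g$resid[1L], integer(1)),
    residB = vapply(r$groupB, function(g) g$resid[1L], integer(1)),
    d = d, lower = r$lower, upper = r$upper, target = r$target,
    excess = excess)
}

#' NOE violation accounting
#'
#' A restraint is violated when its back-calculated distance exceeds a bound
#' by more than \code{tolerance} (1 Angstrom by default, the customary slack
#' for uncertainties in NOE-derived bounds). Violations are attributed to both
#' participating residues in the per-residue table.
#'
#' @param comparison data.frame from \code{\link{noeBackcalculate}}.
#' @param tolerance non-negative slack in Angstrom.
#' @return list with \code{perRestraint} (comparison + \code{violated}),
#'   \code{perResidue} (resid, count; violated restraints only),
#'   \code{nViolations}.
#' @export
noeViolations <- function(comparison, tolerance = 1.0) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  v <- comparison$excess > tolerance
  per_restraint <- cbind(comparison, violated = v)
  if (any(v)) {
    res_pairs <- comparison[v, c("residA", "residB")]
    resids <- unlist(lapply(seq_len(nrow(res_pairs)), function(i)
      unique(c(res_pairs$residA[i], res_pairs$residB[i]))))
    per_res <- as.data.frame(table(resid = resids), stringsAsFactors = FALSE)
    names(per_res) <- c("resid", "count")
    per_res$resid <- as.integer(per_res$resid)
    per_res$count <- as.integer(per_res$count)
  } else {
    per_res <- data.frame(resid = integer(0), count = integer(0))
  }
  list(perRestraint = per_restraint, perResidue = per_res,
       nViolations = sum(v))
}

#' Hydrogen-bond distance/angle series and persistence
#'
#' For every definition the donor-acceptor distance and donor-H-acceptor
#' angle are monitored per frame; the bond is formed when distance <=
#' \code{distanceCutoff} and angle >= \code{angleCutoff}, and persistence is
#' the formed fraction of frames.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param definitions data.frame from \code{\link{hbondDefinitions}}.
#' @param distanceCutoff Angstrom (default 3.0).
#' @param angleCutoff degrees (default 135).
#' @param bundle optional \linkS4class{EnsembleBundle}; adds per-definition
#'   mean distance/angle over the bundle models as overlay columns
#'   \code{bundleDist}, \code{bundleAngle}.
#' @return list with \code{summary} (definitions + persistence, meanDist,
#'   meanAngle and overlays), \code{distance} and \code{angle} (frames x
#'   definitions matrices).
#' @export
hbondSeries <- function(traj, definitions, distanceCutoff = 3.0,
                        angleCutoff = 135, bundle = NULL) {
  tab <- atoms(traj)
  nd <- nrow(definitions)
  nf <- nFrames(traj)
  di <- .atom_index(tab, definitions$donorRes, definitions$donorAtom)
  hi <- .atom_index(tab, definitions$donorRes, definitions$hydrogen)
  ai <- .atom_index(tab, definitions$acceptorRes, definitions$acceptorAtom)
  dist <- matrix(NA_real_, nf, nd)
  ang <- matrix(NA_real_, nf, nd)
  for (f in seq_len(nf)) {
    xyz <- traj@coords[, , f]
    dist[f, ] <- sqrt(rowSums((xyz[di, , drop = FALSE] -
                               xyz[ai, , drop = FALSE])^2))
    ang[f, ] <- .angle(xyz[di, , drop = FALSE], xyz[hi, , drop = FALSE],
                       xyz[ai, , drop = FALSE])
  }
  formed <- dist <= distanceCutoff & ang >= angleCutoff
  summary <- cbind(definitions,
                   persistence = colMeans(formed),
                   meanDist = colMeans(dist),
                   meanAngle = colMeans(ang))
  if (!is.null(bundle)) {
    bd <- matrix(NA_real_, nModels(bundle), nd)
    ba <- matrix(NA_real_, nModels(bundle), nd)
    btab <- atoms(bundle)
    bdi <- .atom_index(btab, definitions$donorRes, definitions$donorAtom)
    bhi <- .atom_index(btab, definitions$donorRes, definitions$hydrogen)
    bai <- .atom_index(btab, definitions$acceptorRes, definitions$acceptorAtom)
    for (k in seq_len(nModels(bundle))) {
      xyz <- coords(models(bundle)[[k]])
      bd[k, ] <- sqrt(rowSums((xyz[bdi, , drop = FALSE] -
                               xyz[bai, , drop = FALSE])^2))
      ba[k, ] <- .angle(xyz[bdi, , drop = FALSE], xyz[bhi, , drop = FALSE],
                        xyz[bai, , drop = FALSE])
    }
    summary$bundleDist <- colMeans(bd)
    summary$bundleAngle <- colMeans(ba)
  }
  rownames(summary) <- NULL
  list(summary = summary, distance = dist, angle = ang)
}

#' Backbone torsion occupancy matrix with NMR-bundle overlay
#'
#' Torsions are histogrammed per (residue, angle name) into left-closed
#' 15-degree bins over [-180, 180) and normalized to unit mass. Bundle models
#' contribute one overlay point each, the way experimental bundle values are
#' dotted onto simulation occupancy matrices. Definitions whose atoms are
#' missing in the topology are marked undefined, never zero-filled.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param definitions data.frame from \code{\link{backboneDihedrals}}.
#' @param bundle optional \linkS4class{EnsembleBundle} for overlay values.
#' @param binWidth bin width in degrees (default 15; must divide 360).
#' @return list with \code{occupancy} (array residue x dihedral x bin),
#'   \code{binCenters}, \code{defined} (logical matrix), \code{overlay}
#'   (data.frame resid, name, model, value).
#' @export
dihedralMatrix <- function(traj, definitions, bundle = NULL, binWidth = 15) {
  if (360 %% binWidth != 0) stop("binWidth must divide 360")
  nbin <- as.integer(360 / binWidth)
  breaks <- seq(-180, 180, by = binWidth)
  tab <- atoms(traj)
  resids <- sort(unique(definitions$resid))
  dihs <- unique(definitions$name)
  occ <- array(NA_real_, dim = c(length(resids), length(dihs), nbin),
               dimnames = list(resids, dihs, NULL))
  defined <- matrix(FALSE, length(resids), length(dihs),
                    dimnames = list(resids, dihs))
  overlay <- list()
  key <- paste(tab$resid, tab$name)
  for (row in seq_len(nrow(definitions))) {
    def <- definitions[row, ]
    if (!def$defined) next
    want <- paste(c(def$res1, def$res2, def$res3, def$res4),
                  c(def$atom1, def$atom2, def$atom3, def$atom4))
    idx <- match(want, key)
    ri <- match(def$resid, resids); ci <- match(def$name, dihs)
    if (anyNA(idx)) next  # atoms absent in this topology: leave undefined
    vals <- .torsion(t(traj@coords[idx[1L], , ]), t(traj@coords[idx[2L], , ]),
                     t(traj@coords[idx[3L], , ]), t(traj@coords[idx[4L], , ]))
    bins <- findInterval(vals, breaks, rightmost.closed = FALSE,
                         left.open = FALSE)
    bins[bins > nbin] <- 1L  # +180 wraps onto -180 (principal value)
    h <- tabulate(bins, nbins = nbin)
    occ[ri, ci, ] <- h / sum(h)
    defined[ri, ci] <- TRUE
    if (!is.null(bundle)) {
      btab <- atoms(bundle)
      bidx <- match(want, paste(btab$resid, btab$name))
      if (!anyNA(bidx)) {
        for (k in seq_len(nModels(bundle))) {
          xyz <- coords(models(bundle)[[k]])
          overlay[[length(overlay) + 1L]] <- data.frame(
            resid = def$resid, name = def$name,
            model = modelLabels(bundle)[k],
            value = .torsion(xyz[bidx[1L], ], xyz[bidx[2L], ],
                             xyz[bidx[3L], ], xyz[bidx[4L], ]))
        }
      }
    }
  }
  overlay <- if (length(overlay)) do.call(rbind, overlay)
             else data.frame(resid = integer(0), name = character(0),
                             model = character(0), value = numeric(0))
  list(occupancy = occ,
       binCenters = breaks[-length(breaks)] + binWidth / 2,
       defined = defined, overlay = overlay)
}
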