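## Synthetic structures and trajectories with known ground truth. Bases carry
## the minimal atom set the analyses touch: the Hoogsteen/Watson-Crick donors
## and acceptors (N1, N2, N7, O6 / N3, N4, O2), the glycosidic C1', a
## deoxyribose-phosphate backbone chain (P, O5', C5', C4', C3', O3') and named
## protons. Ring geometry follows the standard planar base reference frames.

## planar guanine heavy-atom frame (x, y; z = 0), Angstrom
.G_BASE <- rbind(
  N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
  C5 = c(0.071, 2.833),  C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
  N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
  N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177), `C1'` = c(-2.477, 5.399))

## planar cytosine heavy-atom frame
.C_BASE <- rbind(
  N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158), O2 = c(-2.628, 2.709),
  N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868),  N4 = c(1.875, 2.027),
  C5 = c(1.056, 4.275),  C6 = c(-0.023, 5.068), `C1'` = c(-2.477, 5.399))

## backbone + sugar-proton offsets from C1', chosen non-collinear so every
## backbone torsion is well defined; not meant to be chemically exact
.BB_OFFSETS <- rbind(
  `C4'` = c(-1.0, 1.2, 0.8), `C3'` = c(-1.6, 0.2, 1.0),
  `O3'` = c(-2.4, 0.4, 1.8), `C5'` = c(-0.6, 2.5, 1.2),
  `O5'` = c(0.5, 3.0, 1.6),  P     = c(1.2, 4.0, 2.0),
  `H1'` = c(0.4, 0.6, 0.7))

.element_of <- function(name) {
  if (grepl("^H", name)) "H"
  else if (grepl("^P", name)) "P"
  else substr(name, 1L, 1L)
}

## assemble one residue: base heavy atoms (2-d frame -> 3-d), backbone, and
## base protons placed relative to ring atoms. H-bonding protons (H1, H21,
## H41) get chemically sensible in-plane starting positions and are re-aimed
## along their donor -> acceptor lines once the assembly is known.
.residue_atoms <- function(base2d, resname) {
  xyz <- cbind(base2d, 0)
  rownames(xyz) <- rownames(base2d)
  ctr <- colMeans(xyz[setdiff(rownames(xyz), "C1'"), , drop = FALSE])
  hpos <- list()
  place_h <- function(on, nm, len = 1.08) {
    d <- xyz[on, ] - ctr
    d <- d / sqrt(sum(d^2))
    hpos[[nm]] <<- xyz[on, ] + len * d
  }
  ## amino protons: +/- 30 deg about the C-N bond extension, in plane
  place_amino <- function(n_atom, c_atom, nm1, nm2, len = 1.01) {
    v <- xyz[n_atom, ] - xyz[c_atom, ]
    v <- v / sqrt(sum(v^2))
    w <- c(-v[2L], v[1L], 0)
    hpos[[nm1]] <<- xyz[n_atom, ] + len * (cos(pi / 6) * v + sin(pi / 6) * w)
    hpos[[nm2]] <<- xyz[n_atom, ] + len * (cos(pi / 6) * v - sin(pi / 6) * w)
  }
  if (resname == "G") {
    place_h("C8", "H8")
    place_h("N1", "H1", 1.01)
    place_amino("N2", "C2", "H21", "H22")
  }
  if (resname == "C") {
    place_h("C5", "H5")
    place_h("C6", "H6")
    place_amino("N4", "C4", "H41", "H42")
  }
  bb <- sweep(.BB_OFFSETS, 2L, xyz["C1'", ], "+")
  rbind(xyz, do.call(rbind, hpos), bb)
}

## H-bonding protons are re-aimed exactly along donor -> acceptor after
## assembly (idealized geometry: the donor-H-acceptor angle is then 180 deg)
.aim_proton <- function(coords, tab, dres, datom, hname, ares, aatom,
                        len = 1.01) {
  di <- which(tab$resid == dres & tab$name == datom)
  ai <- which(tab$resid == ares & tab$name == aatom)
  v <- coords[ai, ] - coords[di, ]
  coords[which(tab$resid == dres & tab$name == hname), ] <-
    coords[di, ] + len * v / sqrt(sum(v^2))
  coords
}

.model_from_residues <- function(res_list) {
  tabs <- list(); xyzs <- list()
  for (r in res_list) {
    nm <- rownames(r$xyz)
    tabs[[length(tabs) + 1L]] <- data.frame(
      name = nm, resid = r$resid, resname = r$resname,
      element = vapply(nm, .element_of, character(1)))
    xyzs[[length(xyzs) + 1L]] <- r$xyz
  }
  StructureModel(do.call(rbind, tabs), do.call(rbind, xyzs))
}

## solve the tetrad placement (radial shift R, in-plane spin phi) so that the
## cyclic Hoogsteen donor-acceptor distances are exactly `target` Angstrom
.solve_tetrad_placement <- function(target = 2.87) {
  place <- function(R, phi, k) {
    g <- cbind(.G_BASE, 0) %*% t(.rotz(phi))
    g[, 1] <- g[, 1] + R
    g %*% t(.rotz(90 * k))
  }
  objective <- function(p) {
    g0 <- place(p[1L], p[2L], 0L)
    g1 <- place(p[1L], p[2L], 1L)
    rn <- rownames(.G_BASE)
    d1 <- sqrt(sum((g0[rn == "N1", ] - g1[rn == "O6", ])^2))
    d2 <- sqrt(sum((g0[rn == "N2", ] - g1[rn == "N7", ])^2))
    (d1 - target)^2 + (d2 - target)^2
  }
  best <- NULL
  for (R0 in c(3, 4, 5, 6)) for (phi0 in seq(0, 315, by = 45)) {
    fit <- stats::optim(c(R0, phi0), objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value > 1e-8)
    stop("tetrad placement optimization failed to converge")
  list(R = best$par[1L], phi = best$par[2L], place = place)
}

.tetrad_placement_cache <- new.env(parent = emptyenv())

#' Build an idealized stacked G-tetrad core
#'
#' Places \code{nTetrads} planar guanine quartets with perfect cyclic
#' Hoogsteen geometry (every N1-O6 and N2-N7 donor-acceptor distance equal to
#' 2.87 Angstrom), stacked with the given helical rise and twist, plus
#' optional channel cations at the midpoints between adjacent tetrad O6
#' planes. Residues are numbered tetrad by tetrad in Hoogsteen cyclic order;
#' ions follow the guanines with residue name/atom name K.
#'
#' @param nTetrads number of stacked quartets (>= 1).
#' @param rise helical rise between quartets in Angstrom.
#' @param twist helical twist between quartets in degrees.
#' @param channelIons number of channel cations, at most \code{nTetrads - 1}.
#' @return a \linkS4class{StructureModel}.
#' @export
buildIdealG4 <- function(nTetrads = 3L, rise = 3.4, twist = 30,
                         channelIons = 0L) {
  nTetrads <- as.integer(nTetrads)
  channelIons <- as.integer(channelIons)
  if (nTetrads < 1L) stop("nTetrads must be >= 1")
  if (channelIons > nTetrads - 1L)
    stop(sprintf("%d channel ions exceed the %d inter-plane slots",
                 channelIons, nTetrads - 1L))
  if (is.null(.tetrad_placement_cache$sol))
    .tetrad_placement_cache$sol <- .solve_tetrad_placement()
  sol <- .tetrad_placement_cache$sol

  res <- list()
  resid <- 0L
  for (t in seq_len(nTetrads) - 1L) {
    rot_t <- .rotz(twist * t)
    for (k in 0:3) {
      resid <- resid + 1L
      ra <- .residue_atoms(.G_BASE, "G")
      ## whole residue follows the solved base placement: spin phi, radial
      ## shift R, quarter-turn k, helical twist and rise of tetrad t
      x <- ra %*% t(.rotz(sol$phi))
      x[, 1] <- x[, 1] + sol$R
      x <- x %*% t(.rotz(90 * k)) %*% t(rot_t)
      x[, 3] <- x[, 3] + t * rise
      rownames(x) <- rownames(ra)
      res[[length(res) + 1L]] <- list(resid = resid, resname = "G", xyz = x)
    }
  }
  model <- .model_from_residues(res)
  tab <- atoms(model)
  xyz <- coords(model)
  ## aim the Hoogsteen protons along their donor -> acceptor lines
  for (t in seq_len(nTetrads) - 1L) {
    ids <- t * 4L + 1:4
    nxt <- c(ids[-1L], ids[1L])
    for (k in 1:4) {
      xyz <- .aim_proton(xyz, tab, ids[k], "N1", "H1", nxt[k], "O6")
      xyz <- .aim_proton(xyz, tab, ids[k], "N2", "H21", nxt[k], "N7")
    }
  }
  model <- StructureModel(tab, xyz)
  if (channelIons > 0L) {
    tab <- atoms(model); xyz <- coords(model)
    nres <- max(tab$resid)
    ion_rows <- list(); ion_xyz <- list()
    for (i in seq_len(channelIons)) {
      ## midpoint between O6-centroid planes of tetrads i and i+1
      z <- (i - 0.5) * rise
      ion_rows[[i]] <- data.frame(name = "K", resid = nres + i,
                                  resname = "K", element = "K")
      ion_xyz[[i]] <- c(0, 0, z)
    }
    model <- StructureModel(rbind(tab, do.call(rbind, ion_rows)),
                            rbind(xyz, do.call(rbind, ion_xyz)))
  }
  model
}

## solve the Watson-Crick placement of a flipped cytosine against a guanine:
## in-plane shift (dx, dy) and spin (deg) bringing the three H-bond
## distances to their targets
.solve_wc_placement <- function(targets = c(2.90, 2.90, 2.86)) {
  gx <- cbind(.G_BASE, 0)
  place_c <- function(p) {
    cx <- cbind(.C_BASE[, 1], -.C_BASE[, 2], 0)  # 180 deg flip about x
    rownames(cx) <- rownames(.C_BASE)
    cx <- cx %*% t(.rotz(p[3L]))
    cx[, 1] <- cx[, 1] + p[1L]
    cx[, 2] <- cx[, 2] + p[2L]
    cx
  }
  objective <- function(p) {
    cx <- place_c(p)
    d1 <- sqrt(sum((gx["O6", ] - cx["N4", ])^2))
    d2 <- sqrt(sum((gx["N1", ] - cx["N3", ])^2))
    d3 <- sqrt(sum((gx["N2", ] - cx["O2", ])^2))
    sum((c(d1, d2, d3) - targets)^2)
  }
  best <- NULL
  for (dx in c(-1, 0, 1)) for (s in c(-20, 0, 20)) {
    fit <- stats::optim(c(dx, 0, s), objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value > 1e-6)
    stop("Watson-Crick placement optimization failed to converge")
  list(par = best$par, place_c = place_c)
}

.wc_placement_cache <- new.env(parent = emptyenv())

#' Build an idealized GC duplex stem
#'
#' Stacks \code{nPairs} Watson-Crick G-C pairs with the three canonical
#' H-bonds (O6-N4, N1-N3, N2-O2) at 2.8-3.0 Angstrom and idealized
#' donor-H-acceptor angles of 180 degrees. Guanines are residues
#' 1..\code{nPairs} (5' to 3'); cytosines are numbered so that pair i is
#' (i, 2 nPairs + 1 - i), the antiparallel convention.
#'
#' @param nPairs number of G-C pairs (>= 1).
#' @param rise,twist stacking rise (Angstrom) and twist (degrees).
#' @return a \linkS4class{StructureModel} with a \code{"duplexPairs"}
#'   attribute holding the ground-truth pair matrix.
#' @export
buildDuplexStem <- function(nPairs = 3L, rise = 3.4, twist = 30) {
  nPairs <- as.integer(nPairs)
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (is.null(.wc_placement_cache$sol))
    .wc_placement_cache$sol <- .solve_wc_placement()
  sol <- .wc_placement_cache$sol
  res <- list()
  for (i in seq_len(nPairs)) {
    t <- i - 1L
    rot <- .rotz(twist * t)
    ra_g <- .residue_atoms(.G_BASE, "G")
    g3 <- ra_g %*% t(rot); g3[, 3] <- g3[, 3] + t * rise
    rownames(g3) <- rownames(ra_g)
    res[[length(res) + 1L]] <- list(resid = i, resname = "G", xyz = g3)

    ra_c <- .residue_atoms(.C_BASE, "C")
    ## flip about x, then the solved in-plane shift/spin
    c3 <- ra_c
    c3[, 2] <- -c3[, 2]; c3[, 3] <- -c3[, 3]
    c3 <- c3 %*% t(.rotz(sol$par[3L]))
    c3[, 1] <- c3[, 1] + sol$par[1L]
    c3[, 2] <- c3[, 2] + sol$par[2L]
    c3 <- c3 %*% t(rot); c3[, 3] <- c3[, 3] + t * rise
    rownames(c3) <- rownames(ra_c)
    res[[length(res) + 1L]] <- list(resid = 2L * nPairs + 1L - i,
                                    resname = "C", xyz = c3)
  }
  ord <- order(vapply(res, function(r) r$resid, integer(1)))
  model <- .model_from_residues(res[ord])
  tab <- atoms(model); xyz <- coords(model)
  for (i in seq_len(nPairs)) {
    ci <- 2L * nPairs + 1L - i
    xyz <- .aim_proton(xyz, tab, ci, "N4", "H41", i, "O6")
    xyz <- .aim_proton(xyz, tab, i, "N1", "H1", ci, "N3")
    xyz <- .aim_proton(xyz, tab, i, "N2", "H21", ci, "O2")
  }
  model <- StructureModel(tab, xyz)
  attr(model, "duplexPairs") <-
    cbind(seq_len(nPairs), 2L * nPairs + 1L - seq_len(nPairs))
  model
}

#' Build a combined quadruplex-duplex test system
#'
#' Merges an ideal tetrad stack and a duplex stem (displaced to the side, the
#' way a stem hangs off a long loop) into one model, renumbering duplex
#' residues after the guanine core and ions last, and returns the ground-truth
#' annotation alongside.
#'
#' @param nTetrads,nPairs,channelIons,rise,twist as in the element builders.
#' @param duplexOffset 3-vector displacement applied to the duplex stem.
#' @return list with \code{model} (\linkS4class{StructureModel}),
#'   \code{annotation} (\linkS4class{StructuralAnnotation} with tetrads and
#'   duplex pairs filled), and \code{ionResids}.
#' @export
buildSyntheticSystem <- function(nTetrads = 3L, nPairs = 3L, channelIons = 2L,
                                 rise = 3.4, twist = 30,
                                 duplexOffset = c(22, 0, 3)) {
  g4 <- buildIdealG4(nTetrads, rise, twist, channelIons = 0L)
  dx <- buildDuplexStem(nPairs, rise, twist)
  gtab <- atoms(g4); gxyz <- coords(g4)
  dtab <- atoms(dx); dxyz <- coords(dx)
  n_g <- nTetrads * 4L
  dtab$resid <- dtab$resid + n_g
  dxyz <- sweep(dxyz, 2L, duplexOffset, "+")
  tab <- rbind(gtab, dtab)
  xyz <- rbind(gxyz, dxyz)
  ion_resids <- integer(0)
  if (channelIons > 0L) {
    if (channelIons > nTetrads - 1L) stop("too many channel ions")
    nres <- max(tab$resid)
    for (i in seq_len(channelIons)) {
      tab <- rbind(tab, data.frame(name = "K", resid = nres + i,
                                   resname = "K", element = "K"))
      xyz <- rbind(xyz, c(0, 0, (i - 0.5) * rise))
      ion_resids <- c(ion_resids, nres + i)
    }
  }
  model <- StructureModel(tab, xyz)
  ann <- StructuralAnnotation(
    tetrads = lapply(seq_len(nTetrads) - 1L, function(t) t * 4L + 1:4),
    duplexPairs = attr(dx, "duplexPairs") + n_g)
  list(model = model, annotation = ann, ionResids = ion_resids)
}

#' Generate a Gaussian-fluctuating trajectory
#'
#' Every frame is the reference plus isotropic Gaussian noise with a
#' per-coordinate standard deviation taken from the atom's group. Atom groups
#' are given as selections; every atom must belong to exactly one group. The
#' output is a pure function of (inputs, seed).
#'
#' @param reference a \linkS4class{StructureModel}.
#' @param sigmaMap either a single sigma (Angstrom, applied to all atoms) or a
#'   data.frame with columns \code{selection} and \code{sigma}.
#' @param nFrames number of frames (>= 1).
#' @param dt frame spacing in ps.
#' @param seed RNG seed.
#' @param box optional orthorhombic box edges (3-vector).
#' @return a \linkS4class{TrajectorySet}.
#' @export
generateFluctuatingTrajectory <- function(reference, sigmaMap, nFrames,
                                          dt = 1, seed = 1L, box = NULL) {
  stopifnot(nFrames >= 1L)
  n <- nAtoms(reference)
  sig <- rep(NA_real_, n)
  if (is.numeric(sigmaMap) && length(sigmaMap) == 1L) {
    sig[] <- sigmaMap
  } else {
    sigmaMap <- as.data.frame(sigmaMap)
    assigned <- integer(0)
    for (i in seq_len(nrow(sigmaMap))) {
      idx <- selectAtoms(reference, sigmaMap$selection[i])
      dup <- intersect(idx, assigned)
      if (length(dup))
        stop(sprintf("atom %d assigned to more than one sigma group", dup[1L]))
      sig[idx] <- sigmaMap$sigma[i]
      assigned <- c(assigned, idx)
    }
    if (anyNA(sig)) {
      un <- which(is.na(sig))[1L]
      stop(sprintf("atom %d (%s %d:%s) not assigned to any sigma group",
                   un, atoms(reference)$resname[un],
                   atoms(reference)$resid[un], atoms(reference)$name[un]))
    }
  }
  if (any(sig < 0)) stop("sigma must be >= 0")
  ref <- coords(reference)
  arr <- array(0, dim = c(n, 3L, nFrames))
  set.seed(seed)
  for (f in seq_len(nFrames)) {
    noise <- matrix(stats::rnorm(n * 3L), n, 3L) * sig
    arr[, , f] <- ref + noise
  }
  TrajectorySet(reference, arr, times = (seq_len(nFrames) - 1L) * dt, box = box)
}

## per-frame channel anchors from the O6 positions of annotated tetrads
.channel_anchors <- function(xyz, tab, tetrad_groups) {
  planes <- lapply(tetrad_groups, function(g) {
    idx <- which(tab$resid %in% g & tab$name == "O6")
    pts <- xyz[idx, , drop = FALSE]
    list(centroid = colMeans(pts),
         radius = max(sqrt(rowSums(sweep(pts, 2L, colMeans(pts))^2))))
  })
  cents <- t(vapply(planes, `[[`, numeric(3), "centroid"))
  axis <- if (nrow(cents) > 1L) {
    v <- cents[nrow(cents), ] - cents[1L, ]
    v / sqrt(sum(v^2))
  } else c(0, 0, 1)
  mids <- if (nrow(cents) > 1L) {
    (cents[-1L, , drop = FALSE] + cents[-nrow(cents), , drop = FALSE]) / 2
  } else matrix(numeric(0), 0L, 3L)
  list(planes = planes, centroids = cents, axis = axis, midpoints = mids)
}

#' Script an ion-entry event into a trajectory
#'
#' Rewrites the coordinates of one ion so that it follows a schedule of
#' channel states, using per-frame geometric anchors computed from the tetrad
#' O6 planes: \code{bulk} places it 20 Angstrom off the channel axis,
#' \code{approach} on the axis 3 Angstrom above the outer O6 plane,
#' \code{in-plane} at the outer O6 plane centroid, and \code{cavity} at the
#' outermost inter-plane midpoint.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param ionResid residue id of the ion to script.
#' @param schedule data.frame with columns \code{frame} (0-based first frame
#'   of the segment) and \code{state}; each state holds until the next entry.
#'   An empty schedule leaves the trajectory unchanged.
#' @param tetradGroups list of integer(4) tetrad residue groups (bottom to
#'   top), e.g. from the generator's annotation or \code{\link{detectTetrads}}.
#' @return a \linkS4class{TrajectorySet} with the ion rewritten.
#' @export
injectIonEntry <- function(traj, ionResid, schedule, tetradGroups) {
  schedule <- as.data.frame(schedule)
  if (!nrow(schedule)) return(traj)
  nf <- nFrames(traj)
  if (any(schedule$frame < 0L | schedule$frame >= nf))
    stop("schedule references frames outside the trajectory")
  bad <- setdiff(schedule$state, c("bulk", "approach", "in-plane", "cavity"))
  if (length(bad)) stop(sprintf("unknown schedule state '%s'", bad[1L]))
  tab <- atoms(traj)
  ion_idx <- which(tab$resid == ionResid & toupper(tab$element) %in% c("K", "NA", "CS"))
  if (!length(ion_idx)) ion_idx <- which(tab$resid == ionResid)
  if (length(ion_idx) != 1L) stop("ionResid must select exactly one atom")
  schedule <- schedule[order(schedule$frame), , drop = FALSE]
  state_of <- rep(NA_character_, nf)
  for (i in seq_len(nrow(schedule))) {
    upto <- if (i < nrow(schedule)) schedule$frame[i + 1L] else nf
    state_of[(schedule$frame[i] + 1L):upto] <- schedule$state[i]
  }
  arr <- traj@coords
  for (f in seq_len(nf)) {
    s <- state_of[f]
    if (is.na(s)) next
    anch <- .channel_anchors(arr[, , f], tab, tetradGroups)
    top <- nrow(anch$centroids)
    pos <- switch(s,
      bulk = {
        perp <- c(anch$axis[2L], -anch$axis[1L], 0)
        if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
        perp <- perp / sqrt(sum(perp^2))
        anch$centroids[top, ] + 20 * perp
      },
      approach = anch$centroids[top, ] + 3 * anch$axis,
      `in-plane` = anch$centroids[top, ],
      cavity = {
        if (!nrow(anch$midpoints)) stop("cavity state needs >= 2 tetrads")
        anch$midpoints[nrow(anch$midpoints), ]
      })
    arr[ion_idx, , f] <- pos
  }
  TrajectorySet(traj@topology, arr, times = frameTimes(traj),
                box = boxEdges(traj))
}

#' Add uniformly distributed bulk ions to a trajectory
#'
#' Appends \code{n} cations whose positions are redrawn uniformly inside the
#' box every frame — the flat ion atmosphere needed to give radial/spatial
#' density analyses a meaningful bulk reference. (A physical trajectory would
#' have correlated ion motion; a uniform cloud is exactly the ideal-gas null
#' these estimators are tested against.)
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param n number of ions to add.
#' @param box orthorhombic box edges (3-vector); defaults to the trajectory
#'   box. Ions are drawn in [-box/2, box/2] around the origin.
#' @param seed RNG seed.
#' @return a \linkS4class{TrajectorySet} with \code{n} extra K atoms.
#' @export
addBulkIons <- function(traj, n, box = NULL, seed = 1L) {
  if (n < 1L) return(traj)
  if (is.null(box)) {
    b <- boxEdges(traj)
    if (is.null(b)) stop("no box on the trajectory; supply one")
    box <- b[1L, ]
  }
  tab <- atoms(traj)
  nres <- max(tab$resid)
  add <- data.frame(name = "K", resid = nres + seq_len(n), resname = "K",
                    element = "K")
  nf <- nFrames(traj)
  arr <- array(NA_real_, dim = c(nAtoms(traj) + n, 3L, nf))
  arr[seq_len(nAtoms(traj)), , ] <- traj@coords
  set.seed(seed)
  for (f in seq_len(nf)) {
    arr[nAtoms(traj) + seq_len(n), , f] <-
      cbind(stats::runif(n, -box[1L] / 2, box[1L] / 2),
            stats::runif(n, -box[2L] / 2, box[2L] / 2),
            stats::runif(n, -box[3L] / 2, box[3L] / 2))
  }
  TrajectorySet(StructureModel(rbind(tab, add),
                               rbind(coords(traj@topology),
                                     matrix(0, n, 3L))),
                arr, times = frameTimes(traj), box = boxEdges(traj))
}

#' Derive a self-consistent NOE restraint table from a reference
#'
#' Enumerates every unordered proton pair within \code{cutoff} in the
#' reference (for a bundle: within \code{cutoff} in at least one model) and
#' emits one restraint per pair with target equal to the reference distance
#' (bundle: the r^-6 average over models) and bounds target +/- padding
#' (lower floored at 0).
#'
#' @param reference a \linkS4class{StructureModel} or
#'   \linkS4class{EnsembleBundle} containing protons.
#' @param cutoff proton-pair distance cutoff in Angstrom.
#' @param padding half-width of the bound interval in Angstrom (>= 0).
#' @return an \linkS4class{NOETable}.
#' @export
deriveNOETable <- function(reference, cutoff = 5.0, padding = 0.5) {
  if (padding < 0) stop("padding must be >= 0")
  mods <- if (is(reference, "EnsembleBundle")) models(reference)
          else list(reference)
  tab <- atoms(mods[[1L]])
  h <- which(toupper(tab$element) == "H")
  if (!length(h)) stop("reference contains no protons")
  np <- length(h)
  ## pairwise distances per model
  dists <- lapply(mods, function(m) as.matrix(stats::dist(coords(m)[h, , drop = FALSE])))
  within <- Reduce(`|`, lapply(dists, function(d) d <= cutoff))
  r6 <- Reduce(`+`, lapply(dists, function(d) d^-6)) / length(dists)
  rows <- list()
  k <- 0L
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      if (!within[i, j]) next
      k <- k + 1L
      target <- r6[i, j]^(-1 / 6)
      rows[[k]] <- data.frame(
        id = sprintf("noe-%04d", k),
        lower = max(0, target - padding), upper = target + padding,
        target = target)
      rows[[k]]$groupA <- list(data.frame(resid = tab$resid[h[i]],
                                          name = tab$name[h[i]]))
      rows[[k]]$groupB <- list(data.frame(resid = tab$resid[h[j]],
                                          name = tab$name[h[j]]))
    }
  }
  if (!k) {
    empty <- data.frame(id = character(0), lower = numeric(0),
                        upper = numeric(0), target = numeric(0))
    empty$groupA <- list(); empty$groupB <- list()
    return(NOETable(empty))
  }
  NOETable(do.call(rbind, rows))
}
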