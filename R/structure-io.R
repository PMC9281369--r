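## Multi-model PDB, trajectory and report I/O. Coordinates are Angstrom and
## times ps everywhere; frame indexing is 0-based with half-open ranges at the
## user surface (see frameSubset).

.parse_pdb_atom <- function(line, lineno) {
  out <- tryCatch({
    name <- trimws(substr(line, 13, 16))
    resname <- trimws(substr(line, 18, 20))
    resid <- as.integer(substr(line, 23, 26))
    x <- as.numeric(substr(line, 31, 38))
    y <- as.numeric(substr(line, 39, 46))
    z <- as.numeric(substr(line, 47, 54))
    element <- trimws(substr(line, 77, 78))
    if (!nzchar(element)) element <- .element_of(name)
    if (is.na(resid) || is.na(x) || is.na(y) || is.na(z)) stop("bad fields")
    list(name = name, resname = resname, resid = resid,
         x = x, y = y, z = z, element = element)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out))
    stop(sprintf("unparsable ATOM record at line %d: %s", lineno, line))
  out
}

#' Read a (multi-model) PDB structure bundle
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL blocks become bundle members,
#' single-model files a bundle of size 1. All models must share atom count and
#' (residue, atom-name) ordering.
#'
#' @param path PDB file path.
#' @return an \linkS4class{EnsembleBundle} labelled \code{model-1..n} (or by
#'   the MODEL serial numbers).
#' @export
readStructureBundle <- function(path) {
  .check_file(path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  labels <- character(0)
  cur_tab <- list(); cur_xyz <- list()
  cur_label <- NA_character_
  in_any <- FALSE
  flush <- function() {
    if (!length(cur_tab)) return()
    tab <- do.call(rbind, cur_tab)
    xyz <- do.call(rbind, cur_xyz)
    models[[length(models) + 1L]] <<- StructureModel(tab, xyz)
    labels[length(labels) + 1L] <<-
      if (is.na(cur_label)) sprintf("model-%d", length(models)) else cur_label
    cur_tab <<- list(); cur_xyz <<- list(); cur_label <<- NA_character_
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      flush()
      cur_label <- paste0("model-", trimws(substr(lines[i], 7, 80)))
    } else if (startsWith(r, "ENDMDL")) {
      flush()
    } else if (r == "ATOM  " || r == "HETATM") {
      a <- .parse_pdb_atom(lines[i], i)
      cur_tab[[length(cur_tab) + 1L]] <- data.frame(
        name = a$name, resid = a$resid, resname = a$resname,
        element = a$element)
      cur_xyz[[length(cur_xyz) + 1L]] <- c(a$x, a$y, a$z)
      in_any <- TRUE
    }
  }
  flush()
  if (!length(models)) stop("no ATOM records found in ", path)
  n0 <- nAtoms(models[[1L]])
  for (k in seq_along(models)) {
    if (nAtoms(models[[k]]) != n0)
      stop(sprintf("model %s has %d atoms; %s has %d",
                   labels[k], nAtoms(models[[k]]), labels[1L], n0))
  }
  EnsembleBundle(models, labels)
}

#' Write a structure bundle (or single model) as multi-model PDB
#'
#' @param x an \linkS4class{EnsembleBundle} or \linkS4class{StructureModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructureBundle <- function(x, path) {
  if (is(x, "StructureModel")) x <- EnsembleBundle(list(x))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nModels(x) > 1L
  for (k in seq_len(nModels(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- models(x)[[k]]
    tab <- atoms(m); xyz <- coords(m)
    name_fmt <- ifelse(nchar(tab$name) < 4L,
                       sprintf(" %-3s", tab$name), tab$name)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(tab)), name_fmt, substr(tab$resname, 1, 3), tab$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], tab$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Trajectories: binary CHARMM-style DCD (written here, read back via
## bio3d::read.dcd) and a plain-text TSV dialect for text-only fixtures.
## ---------------------------------------------------------------------------

.write_fort_record <- function(con, writer) {
  ## Fortran unformatted record: payload length, payload, payload length
  raw_con <- rawConnection(raw(0), "w")
  writer(raw_con)
  payload <- rawConnectionValue(raw_con)
  close(raw_con)
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4L, endian = "little")
}

#' Write a trajectory
#'
#' \code{format = "dcd"} emits a CHARMM-format binary DCD (with unit-cell
#' records when the trajectory carries a box); \code{format = "tsv"} emits the
#' package's documented plain-text dialect: a header line
#' \code{# quadval-traj natoms <n>}, then per frame one line
#' \code{frame <time_ps> <bx> <by> <bz>} followed by \code{n} lines of
#' tab-separated x y z.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @param path output path.
#' @param format "dcd" or "tsv".
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path, format = c("dcd", "tsv")) {
  format <- match.arg(format)
  nf <- nFrames(traj); na <- nAtoms(traj)
  box <- boxEdges(traj)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# quadval-traj natoms %d", na), con)
    for (f in seq_len(nf)) {
      b <- if (!is.null(box)) box[f, ] else c(0, 0, 0)
      writeLines(sprintf("frame\t%.6f\t%.6f\t%.6f\t%.6f",
                         frameTimes(traj)[f], b[1], b[2], b[3]), con)
      xyz <- traj@coords[, , f]
      writeLines(sprintf("%.6f\t%.6f\t%.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  has_cell <- !is.null(box)
  dt_ps <- if (nf > 1L) diff(frameTimes(traj))[1L] else 1
  ## AKMA time unit used by CHARMM DCD headers
  delta <- dt_ps / 0.0488882129
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  .write_fort_record(con, function(rc) {
    writeBin(charToRaw("CORD"), rc)
    writeBin(icntrl[1:9], rc, size = 4L, endian = "little")
    writeBin(as.numeric(delta), rc, size = 4L, endian = "little")
    writeBin(icntrl[11:20], rc, size = 4L, endian = "little")
  })
  .write_fort_record(con, function(rc) {
    writeBin(1L, rc, size = 4L, endian = "little")
    title <- sprintf("%-80s", "quadval trajectory")
    writeBin(charToRaw(substr(title, 1, 80)), rc)
  })
  .write_fort_record(con, function(rc) {
    writeBin(as.integer(na), rc, size = 4L, endian = "little")
  })
  for (f in seq_len(nf)) {
    if (has_cell) {
      b <- box[f, ]
      .write_fort_record(con, function(rc) {
        writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), rc,
                 size = 8L, endian = "little")
      })
    }
    xyz <- traj@coords[, , f]
    for (k in 1:3) {
      .write_fort_record(con, function(rc) {
        writeBin(as.numeric(xyz[, k]), rc, size = 4L, endian = "little")
      })
    }
  }
  invisible(path)
}

.read_traj_tsv <- function(topology, path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# quadval-traj natoms ", lines[1L]))
    stop("not a quadval-traj TSV file: ", path)
  na <- as.integer(sub("^# quadval-traj natoms ", "", lines[1L]))
  if (na != nAtoms(topology))
    stop(sprintf("trajectory has %d atoms, topology %d", na, nAtoms(topology)))
  body <- lines[-1L]
  frame_starts <- which(startsWith(body, "frame"))
  if (!length(frame_starts)) stop("no frames in ", path)
  nf <- length(frame_starts)
  arr <- array(NA_real_, dim = c(na, 3L, nf))
  times <- numeric(nf)
  boxes <- matrix(0, nf, 3L)
  for (f in seq_len(nf)) {
    hdr <- strsplit(body[frame_starts[f]], "\t", fixed = TRUE)[[1L]]
    times[f] <- as.numeric(hdr[2L])
    boxes[f, ] <- as.numeric(hdr[3:5])
    rows <- frame_starts[f] + seq_len(na)
    if (max(rows) > length(body) ||
        (f < nf && frame_starts[f + 1L] - frame_starts[f] - 1L < na))
      stop(sprintf("truncated trajectory: last complete frame is %d", f - 1L))
    xyz <- matrix(as.numeric(unlist(strsplit(body[rows], "\t", fixed = TRUE))),
                  ncol = 3L, byrow = TRUE)
    if (anyNA(xyz))
      stop(sprintf("truncated trajectory: last complete frame is %d", f - 1L))
    arr[, , f] <- xyz
  }
  has_box <- any(boxes != 0)
  TrajectorySet(topology, arr, times = times,
                box = if (has_box) boxes else NULL)
}

.read_traj_dcd <- function(topology, path) {
  trj <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to read DCD (truncated or corrupt): ",
                             conditionMessage(e)))
  cell <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)),
    error = function(e) NULL)
  na <- ncol(trj) / 3L
  if (na != nAtoms(topology))
    stop(sprintf("trajectory has %d atoms, topology %d", na, nAtoms(topology)))
  nf <- nrow(trj)
  arr <- array(NA_real_, dim = c(na, 3L, nf))
  ## bio3d xyz rows are x1,y1,z1,x2,...: reshape accordingly
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(trj[f, ], ncol = 3L, byrow = TRUE)
  }
  box <- NULL
  if (!is.null(cell) && is.matrix(cell) && ncol(cell) >= 6L) {
    box <- cell[, c(1L, 2L, 3L), drop = FALSE]
    dimnames(box) <- NULL
    if (all(box == 0)) box <- NULL
  }
  TrajectorySet(topology, arr, times = as.numeric(seq_len(nf) - 1L), box = box)
}

#' Read a trajectory
#'
#' The declared format is required (no sniffing): "dcd" for binary
#' CHARMM-style DCD, "tsv" for the package's plain-text dialect. DCD carries
#' no time axis, so frames are assigned 0, 1, 2, ... ps; the TSV dialect
#' round-trips times exactly.
#'
#' @param topology \linkS4class{StructureModel} whose atom count must match.
#' @param path trajectory file.
#' @param format "dcd" or "tsv".
#' @return a \linkS4class{TrajectorySet}.
#' @export
readTrajectory <- function(topology, path, format = c("dcd", "tsv")) {
  .check_file(path)
  format <- match.arg(format)
  switch(format,
         tsv = .read_traj_tsv(topology, path),
         dcd = .read_traj_dcd(topology, path))
}

## ---------------------------------------------------------------------------
## Reports
## ---------------------------------------------------------------------------

#' Write an analysis report
#'
#' TSV reports have a deterministic column order (the data.frame's own) and
#' floats fixed at 6 decimals; JSON reports keep full precision via jsonlite.
#' Re-reading reproduces values to the written precision.
#'
#' @param results data.frame (TSV/JSON) or named list (JSON).
#' @param path output path.
#' @param format "tsv" or "json".
#' @return invisibly, the path.
#' @export
writeReport <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (!is.data.frame(results)) stop("TSV reports require a data.frame")
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.6f", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
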