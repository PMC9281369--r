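#' Parse a DNA sequence string
#'
#' Accepts a raw base string, the compact \code{d[...]} deoxy notation, or the
#' text of a single-record FASTA. Whitespace is ignored; bases are
#' case-insensitive.
#'
#' @param text sequence string.
#' @return data.frame with columns \code{index} (1-based) and \code{base}
#'   (uppercase A/C/G/T), one row per residue.
#' @export
#' @examples
#' seq <- parseSequence("d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]")
#' nrow(seq)  # 28
parseSequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (startsWith(trimws(text), ">")) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    text <- paste(lines[-1L], collapse = "")
  }
  text <- gsub("\\s", "", text)
  text <- sub("^d\\[(.*)\\]$", "\\1", text)
  if (!nzchar(text)) stop("empty sequence")
  bases <- toupper(strsplit(text, "")[[1L]])
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("invalid base '%s' at position %d", bases[bad[1L]], bad[1L]))
  data.frame(index = seq_along(bases), base = bases)
}

#' Read a sequence from a raw-string or single-record FASTA file
#' @param path file path.
#' @return as \code{\link{parseSequence}}.
#' @export
readSequence <- function(path) {
  parseSequence(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Detect G-tetrads geometrically
#'
#' A tetrad is a closed cycle of four guanines in which each one donates a
#' Hoogsteen pair of hydrogen bonds (N1 to the neighbour's O6 and N2 to its N7)
#' around the ring, with all four bases lying in a common plane. Candidate
#' donor-acceptor contacts within \code{distanceCutoff} define a directed
#' graph; 4-cycles whose base atoms deviate from their least-squares plane by
#' at most \code{planarityTolerance} are reported, ordered bottom-to-top along
#' the mean channel axis. Each returned quartet is in Hoogsteen cyclic donor
#' order (residue k donates to residue k+1).
#'
#' @param model a \linkS4class{StructureModel} containing guanine N1, N2, N7,
#'   O6 atoms. Guanines missing any of these atoms are skipped with a warning.
#' @param distanceCutoff donor-acceptor distance cutoff in Angstrom.
#' @param planarityTolerance maximum base-atom deviation from the tetrad plane,
#'   Angstrom.
#' @return list of integer(4) residue-id groups (possibly empty).
#' @export
detectTetrads <- function(model, distanceCutoff = 3.5, planarityTolerance = 1.0) {
  tab <- atoms(model)
  xyz <- coords(model)
  gres <- sort(unique(tab$resid[tab$resname %in% c("G", "DG", "GUA")]))
  need <- c("N1", "N2", "N7", "O6")
  pos <- list()
  keep <- logical(length(gres))
  for (i in seq_along(gres)) {
    r <- gres[i]
    idx <- vapply(need, function(nm) {
      j <- which(tab$resid == r & tab$name == nm)
      if (length(j)) j[1L] else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
      warning(sprintf("guanine %d missing atoms %s; skipped",
                      r, paste(need[is.na(idx)], collapse = ",")))
      next
    }
    keep[i] <- TRUE
    p <- xyz[idx, , drop = FALSE]
    rownames(p) <- need
    pos[[as.character(r)]] <- p
  }
  gres <- gres[keep]
  ng <- length(gres)
  if (ng < 4L) return(list())

  ## directed Hoogsteen edge i -> j: N1(i)-O6(j) and N2(i)-N7(j) within cutoff
  succ <- vector("list", ng)
  for (i in seq_len(ng)) {
    p_i <- pos[[as.character(gres[i])]]
    for (j in seq_len(ng)) {
      if (i == j) next
      pj <- pos[[as.character(gres[j])]]
      d1 <- sqrt(sum((p_i["N1", ] - pj["O6", ])^2))
      d2 <- sqrt(sum((p_i["N2", ] - pj["N7", ])^2))
      if (d1 <= distanceCutoff && d2 <= distanceCutoff)
        succ[[i]] <- c(succ[[i]], j)
    }
  }

  quartets <- list()
  seen <- character(0)
  for (a in seq_len(ng)) {
    for (b in succ[[a]]) for (c in succ[[b]]) for (d in succ[[c]]) {
      if (a %in% succ[[d]] && length(unique(c(a, b, c, d))) == 4L) {
        ids <- gres[c(a, b, c, d)]
        key <- paste(sort(ids), collapse = "-")
        if (key %in% seen) next
        base_xyz <- do.call(rbind, pos[as.character(ids)])
        pl <- .fit_plane(base_xyz)
        if (max(pl$deviations) <= planarityTolerance) {
          seen <- c(seen, key)
          ## canonical start: lowest residue id first, keeping cycle order
          k <- which.min(ids)
          quartets[[length(quartets) + 1L]] <-
            as.integer(ids[((seq_len(4L) + k - 2L) %% 4L) + 1L])
        }
      }
    }
  }
  if (length(quartets) < 2L) return(quartets)

  ## order quartets along the mean channel axis (PCA of O6 centroids)
  cents <- t(vapply(quartets, function(q) {
    colMeans(do.call(rbind, lapply(q, function(r)
      pos[[as.character(r)]]["O6", ])))
  }, numeric(3)))
  cc <- sweep(cents, 2L, colMeans(cents))
  axis <- svd(cc)$v[, 1L]
  proj <- as.vector(cc %*% axis)
  ## axis direction is tied to the residue numbering (smallest id among the
  ## two extreme quartets sits at the bottom) so the order is invariant under
  ## rigid moves of the model
  lo <- quartets[[which.min(proj)]]
  hi <- quartets[[which.max(proj)]]
  if (min(hi) < min(lo)) proj <- -proj
  quartets[order(proj)]
}

#' Enumerate hydrogen-bond definitions from a structural annotation
#'
#' Per tetrad (taken in Hoogsteen cyclic donor order): four N1-O6 and four
#' N2-N7 definitions, donor residue k to acceptor residue k+1 around the ring;
#' with \code{includeBifurcated}, four additional N1-N7 definitions along the
#' same cycle. Per Watson-Crick GC pair: O6-N4 (cytosine N4 donates to guanine
#' O6), N1-N3 and N2-O2 (guanine donates). Donor hydrogens are named by the
#' convention that the bonding imino proton is H1 (N1), the bonding amino
#' protons H21 (guanine N2) and H41 (cytosine N4).
#'
#' @param annotation a \linkS4class{StructuralAnnotation}.
#' @param sequence optional sequence data.frame (from
#'   \code{\link{parseSequence}}); when given, duplex pairs are checked and
#'   oriented so the guanine comes first. Pairs whose bases are not one G and
#'   one C raise an error naming the pair.
#' @param includeBifurcated also emit the bifurcated N1-N7 definitions
#'   monitored as a force-field artifact indicator.
#' @return data.frame with columns \code{class}, \code{donorRes},
#'   \code{donorAtom}, \code{hydrogen}, \code{acceptorRes},
#'   \code{acceptorAtom}, \code{element} ("tetrad" or "duplex").
#' @export
hbondDefinitions <- function(annotation, sequence = NULL,
                             includeBifurcated = FALSE) {
  rows <- list()
  add <- function(class, dres, datom, h, ares, aatom, element) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, donorRes = dres, donorAtom = datom, hydrogen = h,
      acceptorRes = ares, acceptorAtom = aatom, element = element)
  }
  for (tet in tetrads(annotation)) {
    nxt <- c(tet[-1L], tet[1L])
    for (k in seq_len(4L)) {
      add("N1-O6", tet[k], "N1", "H1", nxt[k], "O6", "tetrad")
      add("N2-N7", tet[k], "N2", "H21", nxt[k], "N7", "tetrad")
      if (includeBifurcated)
        add("N1-N7", tet[k], "N1", "H1", nxt[k], "N7", "tetrad")
    }
  }
  dp <- duplexPairs(annotation)
  if (nrow(dp)) {
    for (i in seq_len(nrow(dp))) {
      g <- dp[i, 1L]; c_ <- dp[i, 2L]
      if (!is.null(sequence)) {
        b <- sequence$base[match(c(g, c_), sequence$index)]
        if (setequal(b, c("G", "C"))) {
          if (b[1L] == "C") { tmp <- g; g <- c_; c_ <- tmp }
        } else {
          stop(sprintf("duplex pair %d-%d is %s-%s, not G-C",
                       dp[i, 1L], dp[i, 2L], b[1L], b[2L]))
        }
      }
      add("O6-N4", c_, "N4", "H41", g, "O6", "duplex")
      add("N1-N3", g, "N1", "H1", c_, "N3", "duplex")
      add("N2-O2", g, "N2", "H21", c_, "O2", "duplex")
    }
  }
  if (!length(rows)) {
    return(data.frame(class = character(0), donorRes = integer(0),
                      donorAtom = character(0), hydrogen = character(0),
                      acceptorRes = integer(0), acceptorAtom = character(0),
                      element = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate backbone torsion definitions
#'
#' Emits the six standard deoxyribose-phosphate backbone torsions per residue:
#' alpha O3'(i-1)-P-O5'-C5', beta P-O5'-C5'-C4', gamma O5'-C5'-C4'-C3',
#' delta C5'-C4'-C3'-O3', epsilon C4'-C3'-O3'-P(i+1), and zeta
#' C3'-O3'-P(i+1)-O5'(i+1). Under the default terminal convention the 5'
#' residue has no phosphate, so its alpha and beta are marked undefined, and
#' the 3' residue lacks epsilon and zeta.
#'
#' @param sequence sequence data.frame from \code{\link{parseSequence}}.
#' @return data.frame with columns \code{resid}, \code{name}, \code{defined},
#'   and \code{res1..res4}, \code{atom1..atom4} (NA where undefined).
#' @export
backboneDihedrals <- function(sequence) {
  n <- nrow(sequence)
  if (!n) stop("empty sequence")
  defs <- list(
    alpha   = function(i) list(c(i - 1L, "O3'"), c(i, "P"), c(i, "O5'"), c(i, "C5'")),
    beta    = function(i) list(c(i, "P"), c(i, "O5'"), c(i, "C5'"), c(i, "C4'")),
    gamma   = function(i) list(c(i, "O5'"), c(i, "C5'"), c(i, "C4'"), c(i, "C3'")),
    delta   = function(i) list(c(i, "C5'"), c(i, "C4'"), c(i, "C3'"), c(i, "O3'")),
    epsilon = function(i) list(c(i, "C4'"), c(i, "C3'"), c(i, "O3'"), c(i + 1L, "P")),
    zeta    = function(i) list(c(i, "C3'"), c(i, "O3'"), c(i + 1L, "P"), c(i + 1L, "O5'"))
  )
  out <- vector("list", n * 6L)
  k <- 0L
  for (i in sequence$index) {
    for (nm in names(defs)) {
      k <- k + 1L
      ## terminal rule: no 5' phosphate on residue 1 (alpha and beta need P(i),
      ## and beta/gamma of residue 1 need O5' which is present); no residue
      ## i+1 for the 3' terminus
      defined <- !((i == 1L && nm %in% c("alpha", "beta")) ||
                   (i == n && nm %in% c("epsilon", "zeta")))
      if (defined) {
        q <- defs[[nm]](i)
        out[[k]] <- data.frame(
          resid = i, name = nm, defined = TRUE,
          res1 = as.integer(q[[1L]][1L]), atom1 = q[[1L]][2L],
          res2 = as.integer(q[[2L]][1L]), atom2 = q[[2L]][2L],
          res3 = as.integer(q[[3L]][1L]), atom3 = q[[3L]][2L],
          res4 = as.integer(q[[4L]][1L]), atom4 = q[[4L]][2L])
      } else {
        out[[k]] <- data.frame(
          resid = i, name = nm, defined = FALSE,
          res1 = NA_integer_, atom1 = NA_character_,
          res2 = NA_integer_, atom2 = NA_character_,
          res3 = NA_integer_, atom3 = NA_character_,
          res4 = NA_integer_, atom4 = NA_character_)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a structural annotation config
#'
#' Annotations travel as plain YAML with keys \code{tetrads} (list of
#' 4-residue lists), \code{loops} (list of \code{class}/\code{from}/\code{to}),
#' \code{duplex_pairs} (list of 2-residue lists) and \code{junction}.
#'
#' @param path file path.
#' @return \code{readAnnotation}: a \linkS4class{StructuralAnnotation};
#'   \code{writeAnnotation}: invisibly, the path.
#' @export
readAnnotation <- function(path) {
  .check_file(path)
  y <- yaml::read_yaml(path)
  loops <- if (length(y$loops)) {
    do.call(rbind, lapply(y$loops, function(l)
      data.frame(class = l$class, from = l$from, to = l$to)))
  } else NULL
  dp <- if (length(y$duplex_pairs))
    do.call(rbind, lapply(y$duplex_pairs, as.integer)) else NULL
  ann <- StructuralAnnotation(
    tetrads = if (length(y$tetrads)) lapply(y$tetrads, as.integer) else list(),
    loops = loops, duplexPairs = dp,
    junction = if (length(y$junction)) as.integer(y$junction) else NULL)
  if (!is.null(y$sequence)) attr(ann, "sequence") <- y$sequence
  ann
}

#' @rdname readAnnotation
#' @param annotation a \linkS4class{StructuralAnnotation}.
#' @export
writeAnnotation <- function(annotation, path) {
  lp <- loops(annotation)
  y <- list(
    tetrads = lapply(tetrads(annotation), as.integer),
    loops = lapply(seq_len(nrow(lp)), function(i)
      list(class = lp$class[i], from = lp$from[i], to = lp$to[i])),
    duplex_pairs = lapply(seq_len(nrow(duplexPairs(annotation))), function(i)
      as.integer(duplexPairs(annotation)[i, ])),
    junction = as.integer(junction(annotation)))
  sq <- attr(annotation, "sequence")
  if (!is.null(sq)) y$sequence <- sq
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The packaged HIV LTR-III annotation
#'
#' Loads the shipped annotation of the 28-nt LTR-III quadruplex-duplex system:
#' the 1-nt propeller loop (C18), the V-shaped loop (G25-G26), the 3-nt
#' lateral loop (A22-T24), the 12-nt diagonal loop (G3-T14) carrying the
#' duplex stem (pairs G5-C13, G6-C12, G11-C7), and the A4/T14 junction. Tetrad
#' membership is deliberately left empty: fill it with
#' \code{\link{detectTetrads}} on a structure, since only one tetrad
#' composition is fixed by construction of the motif.
#'
#' @return a \linkS4class{StructuralAnnotation} with a \code{"sequence"}
#'   attribute carrying the LTR-III sequence string.
#' @export
ltr3Annotation <- function() {
  readAnnotation(system.file("extdata", "ltr3_annotation.yaml",
                             package = "quadval", mustWork = TRUE))
}
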