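## NOE restraint table I/O in three dialects. Bounds are Angstrom everywhere.
## Ambiguous/equivalent proton groups are preserved as groups; pseudoatom and
## wildcard names are expanded to explicit proton groups at parse time via the
## packaged nomenclature map, because back-calculation needs coordinates.

.pseudoatom_map <- function() {
  path <- system.file("extdata", "pseudoatom_map.tsv", package = "quadval",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## expand one atom-name token to explicit proton names
.expand_proton <- function(name, map) {
  hit <- match(name, map$pseudo)
  if (!is.na(hit))
    return(strsplit(map$expansion[hit], ",", fixed = TRUE)[[1L]])
  if (grepl("[*#%]$", name)) {
    stem <- sub("[*#%]$", "", name)
    hit <- match(paste0(stem, "*"), map$pseudo)
    if (!is.na(hit))
      return(strsplit(map$expansion[hit], ",", fixed = TRUE)[[1L]])
    stop(sprintf("unmapped wildcard atom name '%s'", name))
  }
  name
}

.group_df <- function(resids, names) data.frame(resid = as.integer(resids),
                                                name = names)

.check_restraint_rows <- function(df) {
  bad <- which(df$lower > df$upper)
  if (length(bad))
    stop(sprintf("restraint %s has lower (%.3f) > upper (%.3f)",
                 df$id[bad[1L]], df$lower[bad[1L]], df$upper[bad[1L]]))
}

## ---------------------------------------------------------------------------
## 8-column TSV dialect: id, residA, atomsA, residB, atomsB, lower, target,
## upper. atomsA/atomsB are comma-separated proton names (groups), wildcards
## allowed; target may be empty or NA.
## ---------------------------------------------------------------------------

.read_noe_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "residA", "atomsA", "residB", "atomsB",
            "lower", "target", "upper")
  if (!all(need %in% names(df)))
    stop(sprintf("TSV restraint file must have columns %s",
                 paste(need, collapse = ", ")))
  if (!nrow(df)) {
    empty <- data.frame(id = character(0), lower = numeric(0),
                        upper = numeric(0), target = numeric(0))
    empty$groupA <- list(); empty$groupB <- list()
    return(NOETable(empty))
  }
  map <- .pseudoatom_map()
  out <- data.frame(id = as.character(df$id), lower = as.numeric(df$lower),
                    upper = as.numeric(df$upper),
                    target = suppressWarnings(as.numeric(df$target)))
  .check_restraint_rows(out)
  out$groupA <- lapply(seq_len(nrow(df)), function(i) {
    nm <- unlist(lapply(strsplit(df$atomsA[i], ",", fixed = TRUE)[[1L]],
                        .expand_proton, map = map))
    .group_df(rep(df$residA[i], length(nm)), nm)
  })
  out$groupB <- lapply(seq_len(nrow(df)), function(i) {
    nm <- unlist(lapply(strsplit(df$atomsB[i], ",", fixed = TRUE)[[1L]],
                        .expand_proton, map = map))
    .group_df(rep(df$residB[i], length(nm)), nm)
  })
  NOETable(out)
}

## ---------------------------------------------------------------------------
## Amber DISANG-style &rst namelists. Atom indices (iat / igr1 / igr2) are
## 1-based positions in the supplied topology; r2/r3 are the flat-well bounds.
## ---------------------------------------------------------------------------

.read_noe_disang <- function(path, topology) {
  if (is.null(topology))
    stop("the DISANG dialect needs a topology to map atom indices to names")
  tab <- atoms(topology)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  blocks <- regmatches(txt, gregexpr("&rst.*?(/|&end)", txt))[[1L]]
  if (!length(blocks)) stop("no &rst records found in ", path)
  get_vec <- function(block, key) {
    m <- regmatches(block,
                    regexec(sprintf("\\b%s\\s*=\\s*([-0-9.,eE+ \n]+)", key),
                            block))[[1L]]
    if (length(m) < 2L) return(numeric(0))
    v <- as.numeric(strsplit(gsub("\\s", "", m[2L]), ",")[[1L]])
    v[!is.na(v)]
  }
  rows <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    iat <- get_vec(blocks[b], "iat")
    r2 <- get_vec(blocks[b], "r2")[1L]
    r3 <- get_vec(blocks[b], "r3")[1L]
    if (length(iat) < 2L || is.na(r2) || is.na(r3))
      stop(sprintf("restraint %d: missing iat/r2/r3", b))
    idxA <- if (iat[1L] > 0) iat[1L] else get_vec(blocks[b], "igr1")
    idxB <- if (iat[2L] > 0) iat[2L] else get_vec(blocks[b], "igr2")
    idxA <- idxA[idxA > 0]; idxB <- idxB[idxB > 0]
    if (any(c(idxA, idxB) > nrow(tab)))
      stop(sprintf("restraint %d references atom index beyond topology", b))
    row <- data.frame(id = sprintf("rst-%d", b), lower = r2, upper = r3,
                      target = NA_real_)
    row$groupA <- list(.group_df(tab$resid[idxA], tab$name[idxA]))
    row$groupB <- list(.group_df(tab$resid[idxB], tab$name[idxB]))
    rows[[b]] <- row
  }
  out <- do.call(rbind, rows)
  .check_restraint_rows(out)
  NOETable(out)
}

## ---------------------------------------------------------------------------
## NMR-STAR distance-constraint loops (minimal STAR reader). Recognizes a
## loop_ whose tags include _Gen_dist_constraint.* with member IDs, atom
## names, and lower/upper bound values; the two members of a constraint ID
## form groups A and B (multiple rows per member stay grouped).
## ---------------------------------------------------------------------------

.read_noe_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  loops <- which(lines == "loop_")
  for (start in loops) {
    i <- start + 1L
    tags <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Gen_dist_constraint\\.", tags))) next
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      rows[[length(rows) + 1L]] <- scan(text = lines[i], what = character(),
                                        quiet = TRUE)
      i <- i + 1L
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- sub("^_Gen_dist_constraint\\.", "", tags)
    need <- c("ID", "Member_ID", "Comp_index_ID", "Atom_ID",
              "Distance_lower_bound_val", "Distance_upper_bound_val")
    if (!all(need %in% names(df)))
      stop(sprintf("distance-constraint loop lacks tags: %s",
                   paste(setdiff(need, names(df)), collapse = ", ")))
    map <- .pseudoatom_map()
    ids <- unique(df$ID)
    out <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      d <- df[df$ID == ids[k], , drop = FALSE]
      mk_group <- function(dd) {
        nm <- unlist(lapply(dd$Atom_ID, .expand_proton, map = map))
        reps <- vapply(dd$Atom_ID,
                       function(a) length(.expand_proton(a, map)), integer(1))
        .group_df(rep(as.integer(dd$Comp_index_ID), reps), nm)
      }
      a <- d[d$Member_ID == d$Member_ID[1L], , drop = FALSE]
      b <- d[d$Member_ID != d$Member_ID[1L], , drop = FALSE]
      if (!nrow(b)) b <- a
      row <- data.frame(id = paste0("star-", ids[k]),
                        lower = as.numeric(d$Distance_lower_bound_val[1L]),
                        upper = as.numeric(d$Distance_upper_bound_val[1L]),
                        target = NA_real_)
      row$groupA <- list(mk_group(a))
      row$groupB <- list(mk_group(b))
      out[[k]] <- row
    }
    res <- do.call(rbind, out)
    .check_restraint_rows(res)
    return(NOETable(res))
  }
  stop("no _Gen_dist_constraint loop found in ", path)
}

#' Read an NOE restraint table
#'
#' The dialect must be declared explicitly; sniffing is refused because a
#' silently misparsed bound is the worst failure mode for a validation tool.
#' Pseudoatom and wildcard proton names are expanded to explicit proton groups
#' using the packaged nomenclature map; groups are preserved, never silently
#' collapsed to single atoms.
#'
#' @param path restraint file.
#' @param dialect "tsv" (documented 8-column dialect), "disang" (Amber-style
#'   \code{&rst} namelists; requires \code{topology}), or "nmrstar"
#'   (distance-constraint loop).
#' @param topology \linkS4class{StructureModel}, required for "disang" and
#'   used, when given, to verify that every named proton resolves.
#' @return an \linkS4class{NOETable}.
#' @export
readNOETable <- function(path, dialect = c("tsv", "disang", "nmrstar"),
                         topology = NULL) {
  .check_file(path)
  dialect <- match.arg(dialect)
  tbl <- switch(dialect,
                tsv = .read_noe_tsv(path),
                disang = .read_noe_disang(path, topology),
                nmrstar = .read_noe_star(path))
  if (!is.null(topology) && nrow(restraints(tbl))) {
    tab <- atoms(topology)
    key <- paste(tab$resid, tab$name)
    r <- restraints(tbl)
    missing <- character(0)
    for (g in c(r$groupA, r$groupB)) {
      bad <- !(paste(g$resid, g$name) %in% key)
      if (any(bad)) missing <- c(missing, paste0(g$resid[bad], ":", g$name[bad]))
    }
    if (length(missing))
      stop(sprintf("restraint atoms not in topology: %s",
                   paste(unique(missing), collapse = ", ")))
  }
  tbl
}

#' Write an NOE table in the package TSV dialect
#' @param table an \linkS4class{NOETable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNOETable <- function(table, path) {
  r <- restraints(table)
  df <- data.frame(
    id = r$id,
    residA = vapply(r$groupA, function(g) g$resid[1L], integer(1)),
    atomsA = vapply(r$groupA, function(g) paste(g$name, collapse = ","),
                    character(1)),
    residB = vapply(r$groupB, function(g) g$resid[1L], integer(1)),
    atomsB = vapply(r$groupB, function(g) paste(g$name, collapse = ","),
                    character(1)),
    lower = round(r$lower, 6), target = round(r$target, 6),
    upper = round(r$upper, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
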