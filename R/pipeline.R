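## Config-driven end-to-end runs. A single YAML config (or the equivalent
## nested list) names either file inputs or a synthetic spec, the masks, and
## every analysis threshold; the run functions write TSV/JSON reports into the
## configured output directory. CLI-style use goes through the thin wrapper in
## inst/scripts/quadval.R; the functions here are the real interface.

#' Default run configuration
#'
#' Returns the full default config: a synthetic quadruplex-duplex system (3
#' tetrads, 3 GC pairs, 2 channel ions), a Gaussian-fluctuating trajectory,
#' and the documented analysis thresholds (NOE tolerance 1.0 Angstrom, H-bond
#' 3.0 Angstrom / 135 degrees, 15-degree torsion bins, bulk shell at 30
#' Angstrom, 0.125 cubic-Angstrom voxels, coverage 0.80, running-average
#' window 1000, temperature 300 K).
#'
#' @param seed RNG seed used for every stochastic stage.
#' @return nested list; see the fields in the source and the vignette.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    outputDir = tempfile("quadval-run-"),
    synthetic = list(
      nTetrads = 3L, nPairs = 3L, channelIons = 2L,
      rise = 3.4, twist = 30,
      nFrames = 400L, dt = 1, bulkIons = 40L,
      sigma = list(g4 = 0.15, duplex = 0.45, ions = 0.1),
      noeCutoff = 5.0, noePadding = 1.0,
      box = c(80, 80, 80)),
    thresholds = list(
      noeTolerance = 1.0,
      hbondDistance = 3.0, hbondAngle = 135,
      dihedralBin = 15,
      rdfBinWidth = 0.1, rdfMax = 35, bulkShell = c(30, 31),
      voxelVolume = 0.125, referenceDensity = 0.033456,
      cavityCutoff = 2.0, planeHalfwidth = 1.0, approachCutoff = 4.5,
      coverage = 0.80, window = 1000L, nClusters = 6L,
      equilibration = 0.1, temperature = 300),
    manifest = list(systems = data.frame(
      name = c("K-TIP3P", "KCl-TIP3P", "K-TIP4P", "KCl-TIP4P"),
      replicates = 3L, length_us = 1.0)))
}

#' Read / write a run configuration
#' @param path YAML file.
#' @return \code{readRunConfig}: config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$manifest$systems))
    cfg$manifest$systems <- as.data.frame(
      do.call(rbind, lapply(cfg$manifest$systems, as.data.frame)))
  cfg
}

#' @rdname readRunConfig
#' @param config config list.
#' @export
writeRunConfig <- function(config, path) {
  if (is.data.frame(config$manifest$systems)) {
    s <- config$manifest$systems
    config$manifest$systems <- lapply(seq_len(nrow(s)), function(i)
      as.list(s[i, ]))
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

## Materialize inputs: either the synthetic system or files named in config.
## Returns list(model, annotation, traj, bundle, noe, sequence, masks).
.resolve_inputs <- function(config) {
  th <- config$thresholds
  if (!is.null(config$synthetic) && !is.null(config$inputs))
    stop("config must name exactly one of 'synthetic' or 'inputs'")
  if (!is.null(config$synthetic)) {
    sp <- config$synthetic
    sys <- buildSyntheticSystem(sp$nTetrads, sp$nPairs, sp$channelIons,
                                rise = sp$rise, twist = sp$twist)
    g4_res <- sort(unique(unlist(tetrads(sys$annotation))))
    dup_res <- sort(unique(as.vector(duplexPairs(sys$annotation))))
    sigma_map <- data.frame(
      selection = c(sprintf("resid %d-%d", min(g4_res), max(g4_res)),
                    sprintf("resid %d-%d", min(dup_res), max(dup_res)),
                    "element K"),
      sigma = c(sp$sigma$g4, sp$sigma$duplex, sp$sigma$ions))
    traj <- generateFluctuatingTrajectory(sys$model, sigma_map, sp$nFrames,
                                          dt = sp$dt, seed = config$seed,
                                          box = sp$box)
    if (!is.null(sp$ionSchedule)) {
      traj <- injectIonEntry(traj, sys$ionResids[1L],
                             as.data.frame(sp$ionSchedule),
                             tetrads(sys$annotation))
    }
    if (!is.null(sp$bulkIons) && sp$bulkIons > 0L)
      traj <- addBulkIons(traj, sp$bulkIons, box = sp$box,
                          seed = config$seed + 1L)
    bundle <- EnsembleBundle(list(sys$model), "reference")
    noe <- deriveNOETable(sys$model, cutoff = sp$noeCutoff,
                          padding = sp$noePadding)
    tab <- atoms(sys$model)
    res_tab <- unique(tab[tab$element != "K", c("resid", "resname")])
    sequence <- data.frame(index = res_tab$resid,
                           base = substr(res_tab$resname, 1, 1))
    annotation <- sys$annotation
  } else {
    inp <- config$inputs
    bundle <- readStructureBundle(inp$bundle)
    model <- models(bundle)[[1L]]
    traj <- readTrajectory(model, inp$trajectory,
                           format = inp$trajectoryFormat)
    noe <- readNOETable(inp$restraints, dialect = inp$restraintDialect,
                        topology = model)
    annotation <- readAnnotation(inp$annotation)
    if (!length(tetrads(annotation)))
      annotation@tetrads <- detectTetrads(model)
    sq <- attr(annotation, "sequence")
    sequence <- if (!is.null(sq)) parseSequence(sq) else NULL
    sys <- list(model = model, annotation = annotation)
  }
  g4_res <- sort(unique(unlist(tetrads(sys$annotation %||% annotation))))
  ann <- if (!is.null(config$synthetic)) sys$annotation else annotation
  dup_res <- sort(unique(as.vector(duplexPairs(ann))))
  masks <- list(
    g4 = sprintf("resid %s and heavy",
                 paste(range(g4_res), collapse = "-")),
    g4bases = sprintf("resid %s and name N1,N2,N3,N7,O6,C2,C4,C5,C6,C8",
                      paste(range(g4_res), collapse = "-")),
    duplexBB = sprintf("resid %s and name P,O5',C5',C4',C3',O3'",
                       paste(range(dup_res), collapse = "-")),
    backbone = "name P,O5',C5',C4',C3',O3'",
    duplex = sprintf("resid %s and heavy", paste(range(dup_res), collapse = "-")))
  if (!is.null(config$masks)) masks[names(config$masks)] <- config$masks
  list(model = if (!is.null(config$synthetic)) sys$model else model,
       annotation = ann, traj = traj, bundle = bundle, noe = noe,
       sequence = sequence, masks = masks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the NMR-observable validation stage
#'
#' NOE back-calculation + violation accounting, H-bond persistence (tetrad,
#' duplex and bifurcated classes), torsion occupancy matrices, RMSD splits
#' (all-heavy, backbone, duplex backbone, tetrad bases) and RMSF, written as
#' TSV reports plus one machine-readable JSON summary.
#'
#' @param config config list (see \code{\link{defaultRunConfig}}).
#' @return invisibly, the summary list.
#' @export
runValidation <- function(config = defaultRunConfig()) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  io <- .stage("inputs", .resolve_inputs(config))
  .log_stage("inputs", "%d frames, %d atoms, %d restraints",
             nFrames(io$traj), nAtoms(io$traj), nrow(restraints(io$noe)))

  cmp <- .stage("noe", noeBackcalculate(io$traj, io$noe,
                                        equilibration = th$equilibration))
  viol <- .stage("noe", noeViolations(cmp, tolerance = th$noeTolerance))
  writeReport(viol$perRestraint,
              file.path(config$outputDir, "noe_comparison.tsv"), "tsv")
  writeReport(viol$perResidue,
              file.path(config$outputDir, "noe_violations_by_residue.tsv"),
              "tsv")

  defs <- .stage("hbond", hbondDefinitions(io$annotation, io$sequence,
                                           includeBifurcated = TRUE))
  hb <- .stage("hbond", hbondSeries(io$traj, defs,
                                    distanceCutoff = th$hbondDistance,
                                    angleCutoff = th$hbondAngle,
                                    bundle = io$bundle))
  writeReport(hb$summary, file.path(config$outputDir, "hbonds.tsv"), "tsv")

  dih_defs <- if (!is.null(io$sequence))
    .stage("dihedral", backboneDihedrals(io$sequence)) else NULL
  dm <- if (!is.null(dih_defs))
    .stage("dihedral", dihedralMatrix(io$traj, dih_defs, bundle = io$bundle,
                                      binWidth = th$dihedralBin)) else NULL

  window <- min(th$window, max(3L, nFrames(io$traj) %/% 4L))
  rmsd_tabs <- list()
  for (mk in c("g4bases", "duplexBB", "backbone")) {
    rs <- .stage("rmsd", rmsdSeries(io$traj, io$bundle,
                                    alignMask = io$masks$g4,
                                    measureMask = io$masks[[mk]],
                                    window = window))
    rs$mask <- mk
    rmsd_tabs[[mk]] <- rs
  }
  rmsd_all <- do.call(rbind, rmsd_tabs)
  writeReport(rmsd_all, file.path(config$outputDir, "rmsd.tsv"), "tsv")
  rf <- .stage("rmsf", rmsfProfile(io$traj, "heavy"))
  writeReport(rf$perResidue, file.path(config$outputDir, "rmsf.tsv"), "tsv")

  bif <- defs$class == "N1-N7"
  summary <- list(
    configHash = .config_hash(config),
    manifest = runManifest(config, write = FALSE),
    nRestraints = nrow(restraints(io$noe)),
    nViolations = viol$nViolations,
    violationsByResidue = viol$perResidue,
    hbondPersistence = list(
      tetrad = mean(hb$summary$persistence[defs$element == "tetrad" & !bif]),
      duplex = mean(hb$summary$persistence[defs$element == "duplex"]),
      bifurcated = if (any(bif)) mean(hb$summary$persistence[bif]) else NA),
    rmsdMean = stats::aggregate(rmsd ~ mask, rmsd_all, mean),
    rmsfByResidue = rf$perResidue,
    dihedralsDefined = if (!is.null(dm)) sum(dm$defined) else NA)
  writeReport(summary, file.path(config$outputDir, "validation_summary.json"),
              "json")
  .log_stage("validation", "%d/%d restraints violated",
             summary$nViolations, summary$nRestraints)
  invisible(summary)
}

#' Run the ion-atmosphere stage
#'
#' COM-referenced RDF of the channel cations, SDF voxel grid, channel-state
#' classification and the occupancy-based binding free energy.
#'
#' @param config config list.
#' @return invisibly, list with the RDF profile, occupancy, free energy and
#'   density grid.
#' @export
runIonAnalysis <- function(config = defaultRunConfig()) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  io <- .stage("inputs", .resolve_inputs(config))
  g4_res <- sort(unique(unlist(tetrads(io$annotation))))
  solute <- sprintf("resid %d-%d and name O6", min(g4_res), max(g4_res))
  rdf <- .stage("rdf", rdfCom(io$traj, solute, "element K",
                              binWidth = th$rdfBinWidth, rMax = th$rdfMax,
                              bulkShell = th$bulkShell,
                              bulkDensity = th$rdfBulkDensityOverride))
  writeReport(data.frame(r = rdf@r, g = rdf@g, cumulative = rdf@cumulative),
              file.path(config$outputDir, "rdf.tsv"), "tsv")
  occ <- .stage("channel",
                classifyChannelStates(io$traj, tetrads(io$annotation),
                                      cavityCutoff = th$cavityCutoff,
                                      planeHalfwidth = th$planeHalfwidth,
                                      approachCutoff = th$approachCutoff))
  writeReport(channelEvents(occ),
              file.path(config$outputDir, "channel_events.tsv"), "tsv")
  dg <- .stage("deltaG", bindingFreeEnergy(occ, temperature = th$temperature))
  grid <- .stage("sdf", sdfGrid(io$traj, "element K",
                                voxelVolume = th$voxelVolume,
                                referenceDensity = th$referenceDensity,
                                alignMask = io$masks$g4))
  writeDensityGrid(grid, file.path(config$outputDir, "sdf_k.dx"))
  writeReport(list(configHash = .config_hash(config), freeEnergy = dg,
                   stateFractions = as.list(table(channelStates(occ)) /
                                              length(channelStates(occ))),
                   rdfBulkDensity = rdf@bulkDensity,
                   rdfNote = paste("spherical-shell normalization;",
                                   "no excluded-volume correction")),
              file.path(config$outputDir, "ion_summary.json"), "json")
  invisible(list(rdf = rdf, occupancy = occ, freeEnergy = dg, grid = grid))
}

#' Run the duplex-clustering stage
#'
#' Aligns frames on the quadruplex, clusters on duplex coordinates and writes
#' cluster labels plus the representative set reaching the configured
#' coverage.
#'
#' @param config config list.
#' @return invisibly, list with the \linkS4class{ClusterSolution} and the
#'   representative table.
#' @export
runClustering <- function(config = defaultRunConfig()) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  io <- .stage("inputs", .resolve_inputs(config))
  stride <- if (nFrames(io$traj) > 1e4) 10L else 1L
  m <- .stage("cluster", pairwiseRmsdMatrix(io$traj, io$masks$g4,
                                            io$masks$duplex, stride = stride))
  sol <- .stage("cluster",
                hierarchicalCluster(m, k = min(th$nClusters, nrow(m))))
  reps <- representativeSet(sol, coverage = th$coverage)
  writeReport(data.frame(frame = attr(m, "frames") - 1L,
                         label = clusterLabels(sol)),
              file.path(config$outputDir, "cluster_labels.tsv"), "tsv")
  writeReport(reps, file.path(config$outputDir, "representatives.tsv"), "tsv")
  rep_frames <- attr(m, "frames")[reps$representative]
  rep_bundle <- EnsembleBundle(lapply(rep_frames,
                                      function(f) frameModel(io$traj, f)),
                               sprintf("cluster-%d", reps$cluster))
  writeStructureBundle(rep_bundle,
                       file.path(config$outputDir, "representatives.pdb"))
  invisible(list(solution = sol, representatives = reps))
}

#' Study manifest: systems x replicates x lengths
#'
#' @param config config list with \code{manifest$systems} (data.frame:
#'   name, replicates, length_us).
#' @param write write \code{manifest.json} into the output directory.
#' @return list with the system table and \code{total_us}.
#' @export
runManifest <- function(config = defaultRunConfig(), write = FALSE) {
  s <- config$manifest$systems
  total <- if (is.null(s) || !nrow(s)) 0
           else sum(s$replicates * s$length_us)
  out <- list(systems = s, total_us = total)
  if (write) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeReport(out, file.path(config$outputDir, "manifest.json"), "json")
  }
  out
}

#' Run every stage
#' @param config config list.
#' @return invisibly, list of the stage results.
#' @export
runAll <- function(config = defaultRunConfig()) {
  list(manifest = runManifest(config, write = TRUE),
       validation = runValidation(config),
       ions = runIonAnalysis(config),
       clustering = runClustering(config))
}
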