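test_that("an ideal gas gives g(r) = 1 within sampling error", {
  tr <- ideal_gas_traj()
  rdf <- rdfCom(tr, "resid 1", "element K", binWidth = 1, rMax = 34,
                bulkShell = c(30, 31))
  ## mid-range bins, coarse 1 A width: Poisson counting error per bin
  n_ions <- 60; box <- 70; nf <- 40
  rho <- n_ions / box^3
  mid <- rdf@r >= 10 & rdf@r <= 25
  expected_counts <- rho * 4 * pi * rdf@r[mid]^2 * 1 * nf
  se_g <- sqrt(expected_counts) / expected_counts
  expect_true(all(abs(rdf@g[mid] - 1) <= 3 * se_g))
  ## the measured bulk density agrees with the true one
  expect_equal(rdf@bulkDensity, rho, tolerance = 0.25)
})

test_that("RDF counts obey the conservation sum rule", {
  tr <- ideal_gas_traj(n_ions = 30, n_frames = 10)
  rdf <- rdfCom(tr, "resid 1", "element K", binWidth = 0.5, rMax = 20,
                bulkShell = c(30, 31))
  ## cumulative count at rMax = mean number of ions within rMax of the COM
  com_counts <- vapply(1:10, function(f) {
    xyz <- tr@coords[, , f]
    com <- colMeans(xyz[1:3, ])
    d <- sweep(xyz[-(1:3), ], 2, com)
    sum(sqrt(rowSums(d^2)) < 20)
  }, numeric(1))
  expect_equal(max(rdf@cumulative), mean(com_counts), tolerance = 1e-9)
})

test_that("two fixed channel ions integrate to exactly 2", {
  sys <- fixture_system()
  tr <- generateFluctuatingTrajectory(sys$model, 0.05, 40, seed = 33,
                                      box = c(80, 80, 80))
  rdf <- rdfCom(tr, "resid 1", "element K", binWidth = 0.1, rMax = 12,
                bulkShell = c(30, 31), bulkDensity = 1e-4)
  ## first minimum after the channel peak: g drops to zero past the 2 seated
  ## ions, so the cumulative integral plateaus at 2
  plateau <- rdf@cumulative[rdf@r >= 6 & rdf@r <= 10]
  expect_equal(unique(round(plateau, 6)), 2)
})

test_that("particles beyond range give a flat zero profile without error", {
  far <- point_model(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(200, 200, 200)),
                     names = c("O6", "O6x", "O6y", "K"),
                     resids = c(1, 1, 1, 2), element = c("O", "O", "O", "K"))
  tr <- traj_from_frames(far, list(coords(far), coords(far)))
  rdf <- rdfCom(tr, "resid 1", "element K", binWidth = 0.5, rMax = 20,
                bulkShell = c(30, 31), bulkDensity = 0.01)
  expect_true(all(rdf@g == 0))
  expect_true(all(rdf@cumulative == 0))
})

test_that("RDF errors on empty selections and out-of-box bulk shells", {
  tr <- ideal_gas_traj(n_ions = 5, n_frames = 2)
  expect_error(rdfCom(tr, "name O6", "element MG"), "empty")
  expect_error(rdfCom(tr, "resid 1", "element K", bulkShell = c(40, 41)),
               "outside")
})

test_that("RDF is invariant under a global rotation of every frame", {
  tr <- ideal_gas_traj(n_ions = 25, n_frames = 6)
  rot <- random_rotation(3)
  moved <- tr@coords
  for (f in 1:6) moved[, , f] <- tr@coords[, , f] %*% rot
  tr2 <- TrajectorySet(tr@topology, moved, box = boxEdges(tr))
  a <- rdfCom(tr, "resid 1", "element K", binWidth = 1, rMax = 25,
              bulkShell = c(30, 31), bulkDensity = 1e-4)
  b <- rdfCom(tr2, "resid 1", "element K", binWidth = 1, rMax = 25,
              bulkShell = c(30, 31), bulkDensity = 1e-4)
  expect_equal(a@g, b@g, tolerance = 1e-9)
})

test_that("a fixed particle occupies one voxel at 1/(rho * V)", {
  m <- point_model(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1.2, 1.2, 1.2)),
                   names = c("C1", "C2", "C3", "K"), resids = c(1, 1, 1, 2),
                   element = c("C", "C", "C", "K"))
  tr <- traj_from_frames(m, list(coords(m), coords(m), coords(m)))
  g <- sdfGrid(tr, "element K", voxelVolume = 0.125, referenceDensity = 0.04,
               alignMask = "element C")
  vals <- g@values
  expect_equal(sum(vals > 0), 1)
  expect_equal(max(vals), 1 / (0.04 * 0.125), tolerance = 1e-9)
  expect_equal(g@rawCountSum, 3)  # one particle x three frames

  g2 <- sdfGrid(tr, "element K", voxelVolume = 0.125, referenceDensity = 0.08,
                alignMask = "element C")
  expect_equal(max(g2@values), max(vals) / 2, tolerance = 1e-9)
})

test_that("a uniform particle cloud grids to mean density ~ 1", {
  set.seed(77)
  n <- 4000; side <- 20
  rho <- n / side^3
  solute <- data.frame(name = c("C1", "C2", "C3"), resid = 1L, resname = "X",
                       element = "C")
  ions <- data.frame(name = "K", resid = 1L + seq_len(n), resname = "K",
                     element = "K")
  model <- StructureModel(rbind(solute, ions), matrix(0, n + 3, 3))
  frames <- lapply(1:3, function(f)
    rbind(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * side / 2,
          matrix(runif(n * 3, 0, side), n, 3)))
  tr <- traj_from_frames(model, frames)
  g <- sdfGrid(tr, "element K", voxelVolume = 8, referenceDensity = rho,
               alignMask = NULL, padding = 0)
  ## interior voxels (exclude boundary partial voxels)
  d <- dim(g@values)
  interior <- g@values[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  expect_equal(mean(interior), 1, tolerance = 0.1)
  expect_error(sdfGrid(tr, "element K", voxelVolume = -1), "positive")
})

test_that("channel states classify anchor positions directly", {
  sys <- fixture_system()
  m <- sys$model
  tets <- tetrads(sys$annotation)
  tr <- traj_from_frames(m, list(coords(m), coords(m)))
  occ <- classifyChannelStates(tr, tets)
  ## the generator seats both ions at inter-plane midpoints
  ion_cols <- match(sys$ionResids, occ@ions)
  expect_true(all(channelStates(occ)[, ion_cols] == "cavity"))
  expect_equal(occ@boundCount, c(2L, 2L))
  expect_equal(nrow(channelEvents(occ)), 0)

  ## park one ion 20 A off-axis: bulk everywhere, no events
  xyz <- coords(m)
  ion_idx <- which(atoms(m)$resid == sys$ionResids[1])
  xyz[ion_idx, ] <- c(20, 0, 3.4)
  tr2 <- traj_from_frames(StructureModel(atoms(m), xyz),
                          list(xyz, xyz, xyz))
  occ2 <- classifyChannelStates(tr2, tets)
  expect_true(all(channelStates(occ2)[, match(sys$ionResids[1],
                                              occ2@ions)] == "bulk"))
  expect_equal(nrow(channelEvents(occ2)), 0)

  expect_error(classifyChannelStates(tr, tets[1]), "2 tetrads")
})

test_that("scheduled state fractions are recovered exactly with events", {
  sys <- fixture_system()
  tr <- generateFluctuatingTrajectory(sys$model, 0.05, 50, seed = 44)
  sched <- data.frame(frame = c(0, 20, 30), state = c("bulk", "approach",
                                                      "cavity"))
  tr2 <- injectIonEntry(tr, sys$ionResids[1], sched, tetrads(sys$annotation))
  occ <- classifyChannelStates(tr2, tetrads(sys$annotation))
  col <- match(sys$ionResids[1], occ@ions)
  st <- channelStates(occ)[, col]
  expect_equal(unname(table(st)["bulk"] / 50), 20 / 50)
  expect_equal(unname(table(st)["approach"] / 50), 10 / 50)
  expect_equal(unname(table(st)["cavity"] / 50), 20 / 50)
  ev <- channelEvents(occ)
  ev <- ev[ev$ion == sys$ionResids[1], ]
  expect_equal(ev$frame, c(20, 30))
  expect_equal(ev$from, c("bulk", "approach"))
  expect_equal(ev$to, c("approach", "cavity"))
})

test_that("binding free energies follow -RT ln K", {
  mk_occ <- function(states) {
    new("ChannelOccupancy", states = matrix(states, ncol = 1),
        ions = 1L,
        events = data.frame(ion = integer(0), frame = integer(0),
                            from = character(0), to = character(0)),
        boundCount = as.integer(states == "cavity"))
  }
  half <- mk_occ(rep(c("cavity", "bulk"), 25))
  fe <- bindingFreeEnergy(half, temperature = 300)
  expect_equal(fe$K, 1)
  expect_equal(fe$deltaG, 0, tolerance = 1e-12)

  seventy <- mk_occ(c(rep("cavity", 70), rep("bulk", 30)))
  fe70 <- bindingFreeEnergy(seventy, temperature = 300)
  expect_equal(fe70$deltaG, -8.314 * 300 * log(7 / 3) / 1000,
               tolerance = 1e-12)
  expect_equal(fe70$deltaG, -2.11, tolerance = 0.005)

  allb <- mk_occ(rep("cavity", 10))
  fe_all <- bindingFreeEnergy(allb)
  expect_true(fe_all$oneSided)
  expect_true(is.na(fe_all$deltaG))

  ## antisymmetry under swapping the bound class
  fe_swap <- bindingFreeEnergy(seventy, boundStates = c("bulk", "approach",
                                                        "in-plane"))
  expect_equal(fe_swap$deltaG, -fe70$deltaG, tolerance = 1e-12)
})
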