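test_that("ideal tetrad stacks have exact Hoogsteen geometry and seated ions", {
  m <- buildIdealG4(3, channelIons = 2)
  tab <- atoms(m); xyz <- coords(m)
  expect_equal(sum(tab$resname == "G" & tab$name == "N9"), 12)  # 12 guanines
  expect_equal(sum(tab$element == "K"), 2)

  d <- function(r1, a1, r2, a2) {
    sqrt(sum((xyz[tab$resid == r1 & tab$name == a1, ] -
              xyz[tab$resid == r2 & tab$name == a2, ])^2))
  }
  for (t in 0:2) {
    ids <- t * 4 + 1:4
    nxt <- c(ids[-1], ids[1])
    for (k in 1:4) {
      expect_gte(d(ids[k], "N1", nxt[k], "O6"), 2.8)
      expect_lte(d(ids[k], "N1", nxt[k], "O6"), 3.0)
      expect_gte(d(ids[k], "N2", nxt[k], "N7"), 2.8)
      expect_lte(d(ids[k], "N2", nxt[k], "N7"), 3.0)
    }
  }
  ## each ion equidistant from the flanking O6-centroid planes
  for (i in 1:2) {
    ion <- xyz[tab$resid == 12 + i, ]
    plane_z <- vapply(list((i - 1) * 4 + 1:4, i * 4 + 1:4), function(g)
      mean(xyz[tab$resid %in% g & tab$name == "O6", 3]), numeric(1))
    expect_lt(abs(abs(ion[3] - plane_z[1]) - abs(ion[3] - plane_z[2])), 0.01)
  }
})

test_that("ion slots are limited to the inter-plane gaps", {
  expect_error(buildIdealG4(3, channelIons = 3), "slots")
  expect_error(buildIdealG4(1, channelIons = 1), "slots")
  expect_silent(buildIdealG4(1, channelIons = 0))
})

test_that("detectTetrads recovers the generator's quartets (cross-module)", {
  for (nt in c(1, 2, 4)) {
    m <- buildIdealG4(nt)
    tets <- detectTetrads(m)
    expect_length(tets, nt)
    expect_equal(lapply(tets, sort),
                 lapply(seq_len(nt) - 1L, function(t) t * 4L + 1:4))
  }
})

test_that("duplex stems satisfy all Watson-Crick H-bonds at 3.0 A / 135 deg", {
  dx <- buildDuplexStem(3)
  ann <- StructuralAnnotation(duplexPairs = attr(dx, "duplexPairs"))
  defs <- hbondDefinitions(ann)
  expect_equal(nrow(defs), 9)
  tr <- traj_from_frames(dx, list(coords(dx)))
  hb <- hbondSeries(tr, defs)
  expect_equal(hb$summary$persistence, rep(1, 9))
  expect_true(all(hb$summary$meanDist >= 2.8 & hb$summary$meanDist <= 3.0))
  expect_true(all(hb$summary$meanAngle >= 150))

  hb1 <- hbondSeries(traj_from_frames(buildDuplexStem(1),
                                      list(coords(buildDuplexStem(1)))),
                     hbondDefinitions(StructuralAnnotation(
                       duplexPairs = rbind(c(1L, 2L)))))
  expect_equal(hb1$summary$persistence, rep(1, 3))
})

test_that("zero-sigma trajectories are exact copies with zero RMSD", {
  m <- fixture_duplex()
  tr <- generateFluctuatingTrajectory(m, 0, 10, seed = 4)
  for (f in c(1, 10)) expect_equal(tr@coords[, , f], coords(m))
  rs <- rmsdSeries(tr, m, alignMask = "all")
  expect_equal(rs$rmsd, rep(0, 10), tolerance = 1e-9)
})

test_that("measured RMSF recovers sigma * sqrt(3) within 5% at 5000 frames", {
  m <- buildIdealG4(1)
  tr <- generateFluctuatingTrajectory(m, 0.5, 5000, seed = 12)
  rf <- rmsfProfile(tr, "all")
  expect_equal(mean(rf$perAtom$rmsf), 0.5 * sqrt(3), tolerance = 0.05)
})

test_that("generation is deterministic in the seed and errors on gaps", {
  m <- fixture_duplex()
  a <- generateFluctuatingTrajectory(m, 0.3, 20, seed = 99)
  b <- generateFluctuatingTrajectory(m, 0.3, 20, seed = 99)
  expect_identical(a@coords, b@coords)
  c <- generateFluctuatingTrajectory(m, 0.3, 20, seed = 100)
  expect_false(identical(a@coords, c@coords))

  expect_error(
    generateFluctuatingTrajectory(
      m, data.frame(selection = "name N1", sigma = 0.1), 5, seed = 1),
    "not assigned")
  expect_error(
    generateFluctuatingTrajectory(
      m, data.frame(selection = c("all", "name N1"), sigma = c(0.1, 0.2)),
      5, seed = 1),
    "more than one")
})

test_that("scripted ion entry round-trips through the state classifier", {
  sys <- fixture_system()
  tr <- generateFluctuatingTrajectory(sys$model, 0.05, 100, seed = 21)
  sched <- data.frame(frame = c(0, 10, 20),
                      state = c("bulk", "approach", "cavity"))
  tr2 <- injectIonEntry(tr, sys$ionResids[1], sched, tetrads(sys$annotation))
  occ <- classifyChannelStates(tr2, tetrads(sys$annotation))
  ion_col <- match(sys$ionResids[1], occ@ions)
  got <- channelStates(occ)[, ion_col]
  want <- c(rep("bulk", 10), rep("approach", 10), rep("cavity", 80))
  expect_equal(got, want)

  ## including an in-plane leg
  sched2 <- data.frame(frame = c(0, 10, 30),
                       state = c("approach", "in-plane", "cavity"))
  tr3 <- injectIonEntry(tr, sys$ionResids[1], sched2, tetrads(sys$annotation))
  occ2 <- classifyChannelStates(tr3, tetrads(sys$annotation))
  got2 <- channelStates(occ2)[, ion_col]
  expect_equal(got2, c(rep("approach", 10), rep("in-plane", 20),
                       rep("cavity", 70)))
})

test_that("empty schedules are no-ops and full-cavity gives occupancy 1", {
  sys <- fixture_system()
  tr <- generateFluctuatingTrajectory(sys$model, 0.05, 30, seed = 3)
  same <- injectIonEntry(tr, sys$ionResids[1],
                         data.frame(frame = integer(0), state = character(0)),
                         tetrads(sys$annotation))
  expect_identical(same@coords, tr@coords)

  allcav <- injectIonEntry(tr, sys$ionResids[1],
                           data.frame(frame = 0, state = "cavity"),
                           tetrads(sys$annotation))
  occ <- classifyChannelStates(allcav, tetrads(sys$annotation))
  ion_col <- match(sys$ionResids[1], occ@ions)
  expect_equal(mean(channelStates(occ)[, ion_col] == "cavity"), 1.0)

  bad <- data.frame(frame = 40, state = "bulk")
  expect_error(injectIonEntry(tr, sys$ionResids[1], bad,
                              tetrads(sys$annotation)), "outside")
})

test_that("derived NOE tables are self-consistent and respect padding", {
  m <- fixture_duplex()
  tbl <- deriveNOETable(m, cutoff = 5, padding = 0.5)
  expect_gt(nrow(restraints(tbl)), 0)
  tr <- traj_from_frames(m, list(coords(m)))
  cmp <- noeBackcalculate(tr, tbl, equilibration = 1L)
  expect_equal(cmp$d, cmp$target, tolerance = 1e-9)
  expect_equal(noeViolations(cmp, tolerance = 0)$nViolations, 0)

  expect_equal(nrow(restraints(deriveNOETable(m, cutoff = 0.5))), 0)

  two <- point_model(rbind(c(0, 0, 0), c(4, 0, 0)), names = c("H1", "H2"),
                     element = c("H", "H"))
  t2 <- restraints(deriveNOETable(two, cutoff = 5, padding = 0.5))
  expect_equal(t2$lower, 3.5)
  expect_equal(t2$upper, 4.5)
  expect_error(deriveNOETable(two, padding = -1), "padding")
})

test_that("bundle-derived tables use the r^-6 average over models", {
  base <- point_model(rbind(c(0, 0, 0), c(3, 0, 0)), names = c("H1", "H2"),
                      element = c("H", "H"))
  m2 <- point_model(rbind(c(0, 0, 0), c(5, 0, 0)), names = c("H1", "H2"),
                    element = c("H", "H"))
  b <- EnsembleBundle(list(base, m2))
  tbl <- restraints(deriveNOETable(b, cutoff = 10, padding = 0.5))
  expect_equal(tbl$target, ((3^-6 + 5^-6) / 2)^(-1 / 6), tolerance = 1e-9)
})
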