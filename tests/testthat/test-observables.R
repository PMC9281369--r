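test_that("superpose recovers exact rigid transforms", {
  set.seed(31)
  x <- matrix(rnorm(30), 10, 3)
  fit0 <- superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  rot <- random_rotation(7)
  trans <- c(2, -1, 4)
  y <- x %*% t(rot) + matrix(trans, 10, 3, byrow = TRUE)
  fit <- superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, rot, tolerance = 1e-8)
  expect_equal(fit$transform(x), y, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)  # proper rotation
})

test_that("superpose matches a brute-force rotation search and bio3d", {
  ## 4-point asymmetric set vs a perturbed copy: the Kabsch RMSD must lower-
  ## bound (and approach) the best RMSD over densely sampled rotations
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.5, 0.5, 2.5))
  set.seed(8)
  y <- x %*% t(random_rotation(3)) + matrix(rnorm(12, 0, 0.15), 4, 3)
  fit <- superpose(x, y)

  center <- function(m) sweep(m, 2, colMeans(m))
  xc <- center(x); yc <- center(y)
  euler_rmsd <- function(abc) {
    r <- quadval:::.rotz(abc[1]) %*%
      matrix(c(1, 0, 0, 0, cospi(abc[2] / 180), sinpi(abc[2] / 180),
               0, -sinpi(abc[2] / 180), cospi(abc[2] / 180)), 3, 3) %*%
      quadval:::.rotz(abc[3])
    sqrt(mean(rowSums((xc %*% t(r) - yc)^2)))
  }
  best <- Inf; best_abc <- c(0, 0, 0)
  for (a in seq(0, 340, by = 20)) for (b in seq(0, 340, by = 20))
    for (c in seq(0, 340, by = 20)) {
      v <- euler_rmsd(c(a, b, c))
      if (v < best) { best <- v; best_abc <- c(a, b, c) }
    }
  ## polish the coarse grid optimum by direct minimization over Euler angles
  best <- stats::optim(best_abc, euler_rmsd, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))$value
  expect_lte(fit$rmsd, best + 1e-8)
  expect_equal(fit$rmsd, best, tolerance = 1e-6)

  ## bio3d stores fitted coordinates at reduced precision; compare loosely
  expect_equal(fit$rmsd,
               bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE),
               tolerance = 5e-3)
})

test_that("superpose rejects degenerate masks", {
  line <- cbind(0:4, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate|collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("rmsdSeries is zero against the generating model and obeys masks", {
  m <- fixture_duplex()
  rot <- random_rotation(5)
  frames <- lapply(1:4, function(f)
    coords(m) %*% rot + matrix(f * c(1, 2, 3), nAtoms(m), 3, byrow = TRUE))
  tr <- traj_from_frames(m, frames)
  rs <- rmsdSeries(tr, m, alignMask = "heavy")
  expect_equal(rs$rmsd, rep(0, 4), tolerance = 1e-8)
})

test_that("mean RMSD of a Gaussian trajectory matches the closed form", {
  ## after superposition onto the noise-free reference, E[RMSD^2] is slightly
  ## below 3 sigma^2 (6 fitted dof over 3n coordinates)
  m <- buildIdealG4(2)
  sigma <- 0.3
  tr <- generateFluctuatingTrajectory(m, sigma, 400, seed = 17)
  rs <- rmsdSeries(tr, m, alignMask = "all")
  expect_equal(mean(rs$rmsd), sigma * sqrt(3), tolerance = 0.05)
})

test_that("running averages use edge-shrunk centred windows", {
  expect_equal(quadval:::runningAverage(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  expect_equal(quadval:::runningAverage(c(1, 1, 1, 1), 1000), rep(1, 4))
  x <- rnorm(50)
  expect_equal(length(quadval:::runningAverage(x, 7)), 50)
})

test_that("RMSD and RMSF are invariant under global rigid motion", {
  m <- fixture_g4()
  tr <- generateFluctuatingTrajectory(m, 0.2, 30, seed = 2)
  rot <- random_rotation(13)
  moved <- tr@coords
  for (f in 1:30) moved[, , f] <- tr@coords[, , f] %*% rot +
    matrix(c(10, 0, -5), nAtoms(m), 3, byrow = TRUE)
  tr2 <- TrajectorySet(tr@topology, moved)

  rs1 <- rmsdSeries(tr, m, "heavy")
  rs2 <- rmsdSeries(tr2, m, "heavy")
  expect_equal(rs1$rmsd, rs2$rmsd, tolerance = 1e-7)

  rf1 <- rmsfProfile(tr, "heavy")
  rf2 <- rmsfProfile(tr2, "heavy")
  expect_equal(rf1$perResidue$rmsf, rf2$perResidue$rmsf, tolerance = 1e-7)
})

test_that("RMSF separates fluctuation groups and is zero for static input", {
  m <- fixture_g4()
  static <- traj_from_frames(m, list(coords(m), coords(m)))
  rf0 <- rmsfProfile(static, "all")
  expect_equal(max(rf0$perAtom$rmsf), 0, tolerance = 1e-10)
  expect_error(rmsfProfile(traj_from_frames(m, list(coords(m))), "all"),
               "2 frames")

  sm <- data.frame(selection = c("resid 1-4", "not resid 1-4"),
                   sigma = c(0.2, 0.6))
  tr <- generateFluctuatingTrajectory(m, sm, 600, seed = 23)
  rf <- rmsfProfile(tr, "all")
  lo <- rf$perResidue$rmsf[rf$perResidue$resid %in% 1:4]
  hi <- rf$perResidue$rmsf[!rf$perResidue$resid %in% 1:4]
  expect_true(max(lo) < min(hi))
})

test_that("NOE back-calculation reproduces hand-computed r^-6 averages", {
  two <- point_model(rbind(c(0, 0, 0), c(4.2, 0, 0)), names = c("HA", "HB"),
                     element = c("H", "H"))
  tbl <- NOETable({
    df <- data.frame(id = "x", lower = 1, upper = 10, target = NA_real_)
    df$groupA <- list(data.frame(resid = 1L, name = "HA"))
    df$groupB <- list(data.frame(resid = 2L, name = "HB"))
    df
  })
  tr_const <- traj_from_frames(two, list(coords(two), coords(two),
                                         coords(two)))
  cmp <- noeBackcalculate(tr_const, tbl, equilibration = 0)
  expect_equal(cmp$d, 4.2, tolerance = 1e-10)

  f2 <- coords(two); f2[2, 1] <- 3
  f3 <- coords(two); f3[2, 1] <- 5
  tr2 <- traj_from_frames(two, list(f2, f3))
  cmp2 <- noeBackcalculate(tr2, tbl, equilibration = 1:2)
  expect_equal(cmp2$d, ((3^-6 + 5^-6) / 2)^(-1 / 6), tolerance = 1e-10)
  expect_equal(cmp2$d, 3.3417, tolerance = 1e-4)

  bad <- tbl
  bad@restraints$groupA[[1]]$name <- "H9"
  expect_error(noeBackcalculate(tr2, bad, equilibration = 1:2), "1:H9")
})

test_that("r^-6 averages sit between the minimum and arithmetic mean", {
  ## power-mean inequality, checked across random two-proton trajectories
  two <- point_model(rbind(c(0, 0, 0), c(3, 0, 0)), names = c("HA", "HB"),
                     element = c("H", "H"))
  tbl <- NOETable({
    df <- data.frame(id = "x", lower = 0, upper = 99, target = NA_real_)
    df$groupA <- list(data.frame(resid = 1L, name = "HA"))
    df$groupB <- list(data.frame(resid = 2L, name = "HB"))
    df
  })
  set.seed(41)
  for (rep in 1:5) {
    dists <- runif(20, 2, 8)
    frames <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
    tr <- traj_from_frames(two, frames)
    d6 <- noeBackcalculate(tr, tbl, equilibration = seq_along(dists))$d
    expect_gte(d6, min(dists) - 1e-9)
    expect_lte(d6, mean(dists) + 1e-9)
  }
})

test_that("violation logic respects the tolerance boundary and monotonicity", {
  cmp <- data.frame(id = c("a", "b", "c"), residA = c(1L, 2L, 3L),
                    residB = c(4L, 5L, 6L), d = c(3.4, 3.6, 2.0),
                    lower = c(1, 1, 1), upper = c(2.5, 2.5, 2.5),
                    target = NA_real_,
                    excess = pmax(0, c(3.4, 3.6, 2.0) - 2.5))
  v1 <- noeViolations(cmp, tolerance = 1.0)
  expect_equal(v1$perRestraint$violated, c(FALSE, TRUE, FALSE))
  expect_equal(v1$nViolations, 1)
  expect_equal(v1$perResidue$resid, c(2L, 5L))

  ## monotone in tolerance
  tols <- seq(0, 2, by = 0.25)
  counts <- vapply(tols, function(t) noeViolations(cmp, t)$nViolations,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(noeViolations(cmp, tolerance = -0.1), "tolerance")

  clean <- cmp
  clean$excess <- 0
  v0 <- noeViolations(clean, tolerance = 0)
  expect_equal(v0$nViolations, 0)
  expect_equal(nrow(v0$perResidue), 0)
})

test_that("hydrogen bonds gate on both distance and angle", {
  ## donor-H...acceptor at 3.2 A, perfectly linear: distance fails
  mk <- function(dist, angle_dev) {
    h <- c(1.0, 0, 0)
    acc <- c(dist * cospi(angle_dev / 180), dist * sinpi(angle_dev / 180), 0)
    point_model(rbind(c(0, 0, 0), h, acc), names = c("N1", "H1", "O6"),
                resids = c(1, 1, 2), element = c("N", "H", "O"))
  }
  defs <- data.frame(class = "N1-O6", donorRes = 1L, donorAtom = "N1",
                     hydrogen = "H1", acceptorRes = 2L, acceptorAtom = "O6",
                     element = "tetrad")
  far <- mk(3.2, 0)
  hb_far <- hbondSeries(traj_from_frames(far, list(coords(far))), defs)
  expect_equal(hb_far$summary$persistence, 0)

  ## 2.9 A but donor-H-acceptor angle 120 degrees: angle fails
  bent <- point_model(rbind(c(0, 0, 0), c(1, 0, 0),
                            c(1 + 2.2 * cospi(60 / 180),
                              2.2 * sinpi(60 / 180), 0)),
                      names = c("N1", "H1", "O6"), resids = c(1, 1, 2),
                      element = c("N", "H", "O"))
  tr_b <- traj_from_frames(bent, list(coords(bent)))
  hb_b <- hbondSeries(tr_b, defs)
  expect_lt(hb_b$summary$meanDist, 3.0)
  expect_lt(hb_b$summary$meanAngle, 135)
  expect_equal(hb_b$summary$persistence, 0)

  ok <- mk(2.9, 0)
  hb_ok <- hbondSeries(traj_from_frames(ok, list(coords(ok))), defs)
  expect_equal(hb_ok$summary$persistence, 1)
})

test_that("dihedral histograms bin at 15 degrees and normalize", {
  ## four atoms engineered so the torsion is exactly 60 degrees
  p <- rbind(c(0, 1, -1), c(0, 0, -1), c(0, 0, 0),
             c(sinpi(60 / 180), cospi(60 / 180), 0))
  expect_equal(as.numeric(quadval:::.torsion(p[1, ], p[2, ], p[3, ], p[4, ])),
               -60, tolerance = 1e-8)

  m <- point_model(p, names = c("C5'", "C4'", "C3'", "O3'"),
                   resids = rep(1, 4), element = c("C", "C", "C", "O"))
  defs <- data.frame(resid = 1L, name = "delta", defined = TRUE,
                     res1 = 1L, atom1 = "C5'", res2 = 1L, atom2 = "C4'",
                     res3 = 1L, atom3 = "C3'", res4 = 1L, atom4 = "O3'")
  tr <- traj_from_frames(m, list(p, p, p))
  dm <- dihedralMatrix(tr, defs)
  occ <- dm$occupancy[1, 1, ]
  expect_equal(sum(occ), 1, tolerance = 1e-9)
  bin_of_minus60 <- findInterval(-60, seq(-180, 180, 15))
  expect_equal(occ[bin_of_minus60], 1)
  expect_equal(dm$binCenters[bin_of_minus60], -52.5)
})

test_that("uniform random torsions fill bins uniformly (binomial oracle)", {
  n <- 1e5
  set.seed(55)
  angles <- runif(n, -180, 180)
  ## feed the angles through the same binning used by dihedralMatrix
  breaks <- seq(-180, 180, 15)
  bins <- findInterval(angles, breaks)
  h <- tabulate(bins, 24) / n
  se <- sqrt((1 / 24) * (23 / 24) / n)
  expect_true(all(abs(h - 1 / 24) <= 3 * se + 1e-12))
})

test_that("dihedralMatrix marks missing atoms undefined and overlays bundles", {
  sys <- fixture_system()
  tab <- atoms(sys$model)
  seq_df <- data.frame(index = sort(unique(tab$resid[tab$element != "K"])))
  seq_df$base <- "G"
  defs <- backboneDihedrals(seq_df)
  tr <- generateFluctuatingTrajectory(sys$model, 0.05, 8, seed = 6)
  bundle <- EnsembleBundle(list(sys$model, sys$model), c("m1", "m2"))
  dm <- dihedralMatrix(tr, defs, bundle = bundle)
  expect_true(any(dm$defined))
  ## undefined at the termini under the convention
  expect_false(dm$defined["1", "alpha"])
  sums <- apply(dm$occupancy, c(1, 2), sum)
  expect_true(all(abs(sums[dm$defined] - 1) < 1e-9))
  expect_true(all(is.na(dm$occupancy[!dm$defined])))
  ## bundle overlay: identical models give identical overlay values
  ov <- dm$overlay
  expect_equal(nrow(ov[ov$model == "m1", ]), nrow(ov[ov$model == "m2", ]))
  expect_equal(ov$value[ov$model == "m1"], ov$value[ov$model == "m2"])
})

test_that("equilibration predicates select the right frames", {
  m <- fixture_duplex()
  tr <- generateFluctuatingTrajectory(m, 0.1, 20, seed = 1)
  expect_equal(quadval:::.equilibrated_frames(tr, 0.1), 3:20)
  expect_equal(quadval:::.equilibrated_frames(tr, 5:8), 5:8)
  fn <- function(times) times >= 10
  expect_equal(quadval:::.equilibrated_frames(tr, fn), 11:20)
})
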