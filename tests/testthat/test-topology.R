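test_that("parseSequence handles d[...] notation, FASTA and raw strings", {
  s <- parseSequence("d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]")
  expect_equal(nrow(s), 28)
  expect_equal(s$base[1], "G")
  expect_equal(s$base[18], "C")
  expect_equal(s$index, 1:28)

  expect_equal(nrow(parseSequence("G")), 1)
  expect_equal(parseSequence(">hdr\nGGA\nTT")$base, c("G", "G", "A", "T", "T"))
  expect_equal(parseSequence("ggat")$base, c("G", "G", "A", "T"))
})

test_that("parseSequence rejects empty input and bad alphabets with position", {
  expect_error(parseSequence("d[]"), "empty")
  expect_error(parseSequence("GGXG"), "position 3")
  expect_error(parseSequence("U"), "position 1")
})

test_that("detectTetrads finds all quartets of an ideal stack in stack order", {
  tets <- detectTetrads(fixture_g4())
  expect_length(tets, 3)
  expect_equal(lapply(tets, sort), list(1:4, 5:8, 9:12))
  ## Hoogsteen cyclic order is preserved within each quartet
  expect_equal(tets[[1]][1], 1L)
})

test_that("detectTetrads returns nothing for a duplex and for broken geometry", {
  expect_length(detectTetrads(fixture_duplex()), 0)

  ## displace one O6 beyond the cutoff: the cycle through that guanine breaks
  m <- buildIdealG4(1)
  xyz <- coords(m)
  tab <- atoms(m)
  i <- which(tab$resid == 2 & tab$name == "O6")
  xyz[i, ] <- xyz[i, ] + c(0, 0, 6)
  broken <- StructureModel(tab, xyz)
  ## brute-force oracle: no 4-subset of guanines can close a Hoogsteen cycle
  expect_length(detectTetrads(broken), 0)
})

test_that("detectTetrads is invariant under rigid rotation and translation", {
  m <- fixture_g4()
  rot <- random_rotation(11)
  moved <- StructureModel(atoms(m), coords(m) %*% rot +
                            matrix(c(5, -3, 8), nAtoms(m), 3, byrow = TRUE))
  expect_identical(detectTetrads(moved), detectTetrads(m))
})

test_that("detectTetrads skips guanines missing required atoms with a warning", {
  m <- buildIdealG4(1)
  tab <- atoms(m); xyz <- coords(m)
  drop <- which(tab$resid == 1 & tab$name == "N7")
  m2 <- StructureModel(tab[-drop, ], xyz[-drop, ])
  expect_warning(res <- detectTetrads(m2), "missing atoms")
  expect_length(res, 0)
})

test_that("hbondDefinitions counts follow 8 per tetrad + 3 per GC pair", {
  sys <- fixture_system()
  defs <- hbondDefinitions(sys$annotation)
  expect_equal(sum(defs$element == "tetrad"), 24)
  expect_equal(sum(defs$element == "duplex"), 9)

  defs_b <- hbondDefinitions(sys$annotation, includeBifurcated = TRUE)
  expect_equal(sum(defs_b$class == "N1-N7"), 12)

  ## count formula as a property over assorted annotations
  for (nt in 0:3) for (np in 0:2) for (bif in c(FALSE, TRUE)) {
    ann <- StructuralAnnotation(
      tetrads = lapply(seq_len(nt) - 1L, function(t) t * 4L + 1:4),
      duplexPairs = if (np > 0) cbind(100 + seq_len(np), 200 + seq_len(np)))
    got <- nrow(hbondDefinitions(ann, includeBifurcated = bif))
    expect_equal(got, 8 * nt + 3 * np + bif * 4 * nt)
  }
})

test_that("hbondDefinitions orients GC pairs by sequence and rejects non-GC", {
  seq28 <- parseSequence("d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]")
  ann <- StructuralAnnotation(duplexPairs = rbind(c(13, 5)))  # C first
  defs <- hbondDefinitions(ann, sequence = seq28)
  expect_equal(defs$donorRes[defs$class == "N1-N3"], 5)  # guanine donates

  bad <- StructuralAnnotation(duplexPairs = rbind(c(4, 14)))  # A-T
  expect_error(hbondDefinitions(bad, sequence = seq28), "4-14")
})

test_that("backboneDihedrals applies the terminal convention", {
  seq28 <- parseSequence("d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]")
  defs <- backboneDihedrals(seq28)
  expect_equal(nrow(defs), 28 * 6)
  expect_equal(sum(defs$defined), 164)
  expect_false(any(defs$defined[defs$resid == 1 & defs$name %in% c("alpha", "beta")]))
  expect_false(any(defs$defined[defs$resid == 28 & defs$name %in% c("epsilon", "zeta")]))

  d1 <- backboneDihedrals(parseSequence("G"))
  expect_equal(sort(d1$name[d1$defined]), c("delta", "gamma"))

  d2 <- backboneDihedrals(parseSequence("GG"))
  expect_true(all(d2$defined[d2$resid == 1 & d2$name %in% c("epsilon", "zeta")]))
  expect_true(all(d2$defined[d2$resid == 2 & d2$name %in% c("alpha", "beta")]))
  ## cross-residue atoms reference adjacent residues only
  eps1 <- d2[d2$resid == 1 & d2$name == "epsilon", ]
  expect_equal(eps1$res4, 2L)
  expect_equal(eps1$atom4, "P")
})

test_that("every residue referenced by definitions exists in the sequence", {
  seqs <- list(parseSequence("GGGG"), parseSequence("GCGCGC"))
  for (s in seqs) {
    defs <- backboneDihedrals(s)
    refs <- na.omit(c(defs$res1, defs$res2, defs$res3, defs$res4))
    expect_true(all(refs %in% s$index))
  }
})

test_that("annotations round-trip through YAML", {
  sys <- fixture_system()
  path <- tempfile(fileext = ".yaml")
  writeAnnotation(sys$annotation, path)
  back <- readAnnotation(path)
  expect_equal(tetrads(back), tetrads(sys$annotation))
  expect_equal(duplexPairs(back), duplexPairs(sys$annotation))
})

test_that("the packaged LTR-III annotation matches the published layout", {
  ann <- ltr3Annotation()
  lp <- loops(ann)
  diag <- lp[lp$class == "diagonal", ]
  expect_equal(diag$to - diag$from + 1L, 12L)  # 12-nt diagonal loop
  expect_equal(lp[lp$class == "propeller", "from"], 18L)
  expect_equal(unname(junction(ann)), c(4L, 14L))
  expect_equal(nrow(duplexPairs(ann)), 3)
  seq_ltr <- parseSequence(attr(ann, "sequence"))
  expect_equal(nrow(seq_ltr), 28)
  ## annotated duplex pairs are really G-C in the sequence
  expect_silent(hbondDefinitions(ann, sequence = seq_ltr))
})
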