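test_that("toy PDB parses to the expected model", {
  m <- readStructure(system.file("extdata", "toy_gag.pdb",
                                 package = "kinsaap"))
  expect_s4_class(m, "StructureModel")
  expect_equal(nResidues(m), 3L)
  expect_equal(modelSequence(m), "GAG")
  expect_equal(nrow(m@het), 0L)
})

test_that("waters are excluded and ligand groups are collected", {
  f <- writeTempPdb(c(
    pdbLine("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdbLine("ATOM", 2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdbLine("HETATM", 3, "PA", "ATP", "A", 90, 8, 0, 0, element = "P"),
    pdbLine("HETATM", 4, "O1A", "ATP", "A", 90, 9, 0, 0, element = "O"),
    pdbLine("HETATM", 5, "O", "HOH", "A", 101, 20, 0, 0),
    pdbLine("HETATM", 6, "O", "HOH", "A", 102, 21, 0, 0),
    "END"))
  m <- readStructure(f)
  expect_equal(nResidues(m), 2L)
  expect_equal(length(unique(m@het$group)), 1L)
  expect_setequal(m@het$resid, "ATP")
})

test_that("altloc is resolved to the highest-occupancy copy", {
  f <- writeTempPdb(c(
    pdbLine("ATOM", 1, "CA", "ALA", "A", 1, 1.111, 0, 0, occ = 0.6,
            alt = "A"),
    pdbLine("ATOM", 2, "CA", "ALA", "A", 1, 9.999, 0, 0, occ = 0.4,
            alt = "B"),
    pdbLine("ATOM", 3, "CB", "ALA", "A", 1, 2.0, 0, 0),
    "END"))
  m <- readStructure(f)
  ca <- m@atoms[m@atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.111)
})

test_that("modified residues map to parents; unknown polymers are dropped", {
  f <- writeTempPdb(c(
    pdbLine("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdbLine("HETATM", 2, "CA", "MSE", "A", 2, 3.8, 0, 0),
    pdbLine("ATOM", 3, "CA", "XYZ", "A", 3, 7.6, 0, 0),
    "END"))
  expect_warning(m <- readStructure(f), "XYZ")
  expect_equal(modelSequence(m), "GM")
})

test_that("min residue distance: identity, 3-4-5, and brute-force oracle", {
  m <- toyModel(list(atomRow(1, "G", "CA", "C", 0, 0, 0),
                     atomRow(2, "G", "CA", "C", 3, 4, 0)))
  expect_equal(minResidueDistance(m, 1, 1), 0)
  expect_equal(minResidueDistance(m, 1, 2), 5)
  expect_equal(minResidueDistance(m, 2, 1), 5)

  spec <- syntheticSpec(n_residues = 20, geometry = "helix", seed = 4)
  hx <- generateStructure(spec)
  for (pair in list(c(1, 5), c(2, 17), c(9, 10))) {
    a <- kinsaap:::residueAtoms(hx, pair[1])
    b <- kinsaap:::residueAtoms(hx, pair[2])
    brute <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      brute <- min(brute, sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                                 (a$z[i] - b$z[j])^2))
    expect_equal(minResidueDistance(hx, pair[1], pair[2]), brute,
                 tolerance = 1e-12)
  }
})

test_that("write/read round trip preserves sequence and coordinates", {
  spec <- syntheticSpec(n_residues = 15, geometry = "helix", seed = 8)
  m <- generateStructure(spec)
  f <- tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  expect_equal(modelSequence(m2), modelSequence(m))
  expect_equal(nrow(m2@atoms), nrow(m@atoms))
  expect_lt(max(abs(m2@atoms$x - m@atoms$x), abs(m2@atoms$y - m@atoms$y),
                abs(m2@atoms$z - m@atoms$z)), 1e-3)
})

test_that("distance function is symmetric and obeys the triangle inequality
           on centroids", {
  spec <- syntheticSpec(n_residues = 25, seed = 11)
  m <- generateStructure(spec)
  set.seed(1)
  cent <- aggregate(cbind(x, y, z) ~ pos, m@atoms, mean)
  for (k in 1:20) {
    ijk <- sample(25, 3)
    dmat <- as.matrix(dist(cent[ijk, c("x", "y", "z")]))
    expect_lte(dmat[1, 2], dmat[1, 3] + dmat[3, 2] + 1e-9)
    expect_equal(minResidueDistance(m, ijk[1], ijk[2]),
                 minResidueDistance(m, ijk[2], ijk[1]))
    expect_gte(minResidueDistance(m, ijk[1], ijk[2]), 0)
  }
})
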