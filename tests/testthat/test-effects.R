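# one hand-built fixture per effect category; each should trigger exactly
# its intended flag (the interface fixture necessarily also satisfies the
# binding-residue definition, which subsumes inter-chain contacts)

test_that("core hydrophilic: buried Leu to Gln fires only that rule", {
  m <- soloModel("L")
  eff <- classifyOne(m, effectRecord(1, "L", "Q"), buried_pos = 1)
  expectFlags(eff, "core_hydrophilic")
  expect_true(eff$structurally_explained)
  expect_true(eff$explained)
})

test_that("surface hydrophobic: exposed Ser to Ile fires only that rule", {
  m <- soloModel("S")
  eff <- classifyOne(m, effectRecord(1, "S", "I"), buried_pos = integer())
  expectFlags(eff, "surface_hydrophobic")
})

test_that("a conservative surface substitution fires nothing", {
  m <- soloModel("S")
  eff <- classifyOne(m, effectRecord(1, "S", "T"), buried_pos = integer())
  expectFlags(eff, character())
  expect_false(eff$structurally_explained)
  expect_false(eff$explained)
})

test_that("buried charge shift: Glu to Gln", {
  m <- soloModel("E")
  eff <- classifyOne(m, effectRecord(1, "E", "Q"), buried_pos = 1)
  expectFlags(eff, "charge_shift_buried")
})

test_that("disulphide disruption requires the SG pair geometry", {
  m <- toyModel(list(atomRow(1, "C", "CA", "C", 0, 0, 0),
                     atomRow(1, "C", "SG", "S", 1.8, 0, 0),
                     atomRow(2, "C", "CA", "C", 5.0, 1.5, 0),
                     atomRow(2, "C", "SG", "S", 3.85, 0, 0)))
  # SG-SG = 2.05 A
  eff <- classifyOne(m, effectRecord(1, "C", "S"), buried_pos = integer())
  expectFlags(eff, "disulphide_disrupted")
  # same geometry but mutation keeps the cysteine elsewhere: nothing fires
  far <- toyModel(list(atomRow(1, "C", "CA", "C", 0, 0, 0),
                       atomRow(1, "C", "SG", "S", 1.8, 0, 0),
                       atomRow(2, "C", "CA", "C", 9.0, 0, 0),
                       atomRow(2, "C", "SG", "S", 10.8, 0, 0)))
  eff2 <- classifyOne(far, effectRecord(1, "C", "S"), buried_pos = integer())
  expectFlags(eff2, character())
})

test_that("cavity: burying a much smaller side chain", {
  m <- soloModel("W", atoms = list(c("CA", "C"), c("CB", "C")))
  eff <- classifyOne(m, effectRecord(1, "W", "A"), buried_pos = 1)
  expectFlags(eff, "cavity_introduced")
})

test_that("clash: burying a much larger side chain", {
  m <- soloModel("S", atoms = list(c("CA", "C"), c("CB", "C")))
  eff <- classifyOne(m, effectRecord(1, "S", "F"), buried_pos = 1)
  expectFlags(eff, "clash")
})

test_that("hydrogen bond broken: polar contact lost by an apolar mutant", {
  m <- toyModel(list(atomRow(1, "S", "CA", "C", 0, 0, 0),
                     atomRow(1, "S", "OG", "O", 1.4, 0, 0),
                     atomRow(2, "A", "CA", "C", 5.5, 0, 0),
                     atomRow(2, "A", "O", "O", 4.2, 0, 0)))
  # OG..O = 2.8 A across residues
  eff <- classifyOne(m, effectRecord(1, "S", "A"), buried_pos = 1)
  expectFlags(eff, "hbond_broken")
  # polar mutant keeps the bond
  eff2 <- classifyOne(m, effectRecord(1, "S", "T"), buried_pos = 1)
  expectFlags(eff2, character())
})

test_that("cis-proline rule uses the omega torsion", {
  cis <- backboneWithPhi(phi = -60, aa2 = "P", omega = 0)
  eff <- classifyOne(cis, effectRecord(2, "P", "A"), buried_pos = 2)
  expectFlags(eff, "from_cis_proline")
  trans <- backboneWithPhi(phi = -60, aa2 = "P", omega = 180)
  eff2 <- classifyOne(trans, effectRecord(2, "P", "A"), buried_pos = 2)
  expectFlags(eff2, character())
})

test_that("glycine rule fires for backbone conformations closed to others", {
  m <- backboneWithPhi(phi = 60, aa2 = "G")
  eff <- classifyOne(m, effectRecord(2, "G", "A"), buried_pos = 2)
  expectFlags(eff, "from_glycine")
  helix <- backboneWithPhi(phi = -60, aa2 = "G")
  eff2 <- classifyOne(helix, effectRecord(2, "G", "A"), buried_pos = 2)
  expectFlags(eff2, character())
})

test_that("to-proline rule fires outside the proline phi window", {
  m <- backboneWithPhi(phi = 60, aa2 = "A")
  eff <- classifyOne(m, effectRecord(2, "A", "P"), buried_pos = integer())
  expectFlags(eff, "to_proline")
  ok <- backboneWithPhi(phi = -60, aa2 = "A")
  eff2 <- classifyOne(ok, effectRecord(2, "A", "P"), buried_pos = integer())
  expectFlags(eff2, character())
})

test_that("annotated-functional and conserved flags come from feature sets", {
  m <- soloModel("T")
  ann <- classifyOne(m, effectRecord(1, "T", "S"), integer(),
                     features = list(annotated = featureSet("ann", 1)))
  expectFlags(ann, "annotated_functional")
  cons <- classifyOne(m, effectRecord(1, "T", "S"), integer(),
                      features = list(conserved = featureSet("cons", 1)))
  expectFlags(cons, "sequence_conserved")
  # conservation alone does not count as structurally explained
  expect_false(cons$structurally_explained)
  expect_true(cons$explained)
})

test_that("ligand contacts set the binding flag", {
  het <- data.frame(group = 1L, resid = "ATP", chain = "A", atom = "PA",
                    element = "P", x = 3.0, y = 0, z = 0)
  m <- toyModel(list(atomRow(1, "T", "CA", "C", 0, 0, 0)), het = het)
  eff <- classifyOne(m, effectRecord(1, "T", "S"), integer())
  expectFlags(eff, "binding_residue")
})

test_that("inter-chain contacts set interface and binding together", {
  m <- toyModel(list(atomRow(1, "T", "CA", "C", 0, 0, 0, chain = "A"),
                     atomRow(2, "G", "CA", "C", 3.5, 0, 0, chain = "B")))
  eff <- classifyOne(m, effectRecord(1, "T", "S"), integer())
  expectFlags(eff, c("binding_residue", "interface_quaternary"))
})

test_that("summary flags are consistent on a full synthetic bundle", {
  spec <- syntheticSpec(n_residues = 80, class_sizes = c(30, 25), seed = 17)
  b <- generateBundle(spec)
  mapped <- suppressMessages(mapMutationsToModel(b$mutations, b$model))
  acc <- computeSasa(b$model, sasaParams(n_points = 240))
  cons <- conservedPositions(b$msa, b$model)
  eff <- suppressMessages(
    classifyEffects(mapped, b$model, acc, features = list(conserved = cons)))
  expect_true(all(eff$explained >= eff$structurally_explained))
  # rule columns are all logical and complete
  expect_true(all(vapply(eff[kinsaap:::EFFECT_FLAGS], is.logical,
                         logical(1))))
  # classification is deterministic
  eff2 <- suppressMessages(
    classifyEffects(mapped, b$model, acc, features = list(conserved = cons)))
  expect_identical(eff, eff2)
})

test_that("effect contingency tables have class-sized margins", {
  spec <- syntheticSpec(n_residues = 100, class_sizes = c(62, 36), seed = 19)
  b <- generateBundle(spec)
  mapped <- suppressMessages(mapMutationsToModel(b$mutations, b$model))
  acc <- computeSasa(b$model, sasaParams(n_points = 240))
  eff <- suppressMessages(classifyEffects(mapped, b$model, acc))
  tabs <- effectMatrix(eff)
  expect_length(tabs, length(kinsaap:::EFFECT_FLAGS) + 2L)
  for (m in tabs) {
    expect_equal(unname(rowSums(m)), c(62, 36))
  }
  only_pd <- eff[eff$class == "PD", ]
  expect_error(effectMatrix(only_pd), "both mutation classes")
})

test_that("dihedral computation agrees with an independent oracle", {
  set.seed(33)
  for (k in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(kinsaap:::dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedralOracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})
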