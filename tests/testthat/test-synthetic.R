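test_that("helix geometry: consecutive C-alpha spacing near 3.8 A", {
  m <- generateStructure(syntheticSpec(n_residues = 100, geometry = "helix",
                                       seed = 2))
  ca <- m@atoms[m@atoms$atom == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(d - 3.8) < 0.1))
})

test_that("globule packing respects the minimum separation", {
  m <- generateStructure(syntheticSpec(n_residues = 200, seed = 3))
  ca <- m@atoms[m@atoms$atom == "CA", c("x", "y", "z")]
  dm <- as.matrix(dist(ca))
  diag(dm) <- Inf
  expect_gte(min(dm), 3.5)
})

test_that("generation is deterministic under the seed", {
  s <- syntheticSpec(n_residues = 60, class_sizes = c(15, 10), seed = 42)
  b1 <- generateBundle(s)
  b2 <- generateBundle(s)
  expect_identical(b1$model@atoms, b2$model@atoms)
  expect_identical(b1$mutations, b2$mutations)
  expect_identical(as.character(b1$msa), as.character(b2$msa))
  s2 <- syntheticSpec(n_residues = 60, class_sizes = c(15, 10), seed = 43)
  expect_false(identical(generateBundle(s2)$model@atoms, b1$model@atoms))
})

test_that("bundle files are byte-identical across writes", {
  s <- syntheticSpec(n_residues = 40, class_sizes = c(10, 8), seed = 5)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  generateBundle(s, d1)
  generateBundle(s, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the uniform limit of the placement bias is uniform", {
  s <- syntheticSpec(n_residues = 250, class_sizes = c(5000, 5),
                     proximity_lambda = Inf, pair_enrichment = NULL,
                     n_proteins = 150, seed = 23)
  b <- generateBundle(s)
  pos <- b$mutations$seq_pos[b$mutations$class == "PD"]
  gof <- chisq.test(tabulate(pos, nbins = 250),
                    p = rep(1 / 250, 250))
  expect_gt(gof$p.value, 0.01)
})

test_that("the distance-decay bias places PD closer in every seeded run", {
  closer <- logical(20)
  for (s in 1:20) {
    sp <- syntheticSpec(n_residues = 150, class_sizes = c(40, 30),
                        proximity_lambda = 2, seed = s + 300)
    b <- generateBundle(sp)
    d <- distancesToFeature(seq_len(150), b$feature, b$model)
    pd <- unique(b$mutations$seq_pos[b$mutations$class == "PD"])
    snp <- unique(b$mutations$seq_pos[b$mutations$class == "SNP"])
    closer[s] <- mean(d[pd]) < mean(d[snp])
  }
  expect_true(all(closer))
})

test_that("the planted pair reaches its target fold within sampling error", {
  s <- syntheticSpec(n_residues = 250, class_sizes = c(10000, 10000),
                     proximity_lambda = Inf, n_proteins = 200, seed = 5)
  b <- generateBundle(s)
  mu <- b$mutations
  fa <- sum(mu$class == "PD" & mu$native == "L" & mu$mutant == "P") / 10000
  fb <- sum(mu$class == "SNP" & mu$native == "L" & mu$mutant == "P") / 10000
  expect_gt(fa / fb, 7.5)
  expect_lt(fa / fb, 13)
})

test_that("mutation records are valid by construction", {
  s <- syntheticSpec(n_residues = 80, class_sizes = c(30, 20), seed = 29)
  b <- generateBundle(s)
  mu <- b$mutations
  expect_true(all(substr(mu$sequence, mu$seq_pos, mu$seq_pos) == mu$native))
  expect_true(all(mu$native != mu$mutant))
  key <- paste(mu$protein_id, mu$seq_pos, mu$native, mu$mutant)
  expect_false(anyDuplicated(key) > 0)
  # they survive the reader's hygiene filters unchanged
  f <- tempfile(fileext = ".tsv")
  write.table(mu, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(readMutationTable(f)), nrow(mu))
})

test_that("planted conserved columns are invariant, others reach the
           expected entropy", {
  sp <- syntheticSpec(n_residues = 60, msa_depth = 50,
                      conserved_columns = c(5, 25, 45), seed = 31)
  m <- generateStructure(sp)
  msa <- generateMsa(sp, m)
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  for (j in c(5, 25, 45))
    expect_equal(shannonEntropy(mat[, j]), 0)
  # expected sample entropy: population entropy of the substitution
  # mixture minus the Miller-Madow finite-depth bias
  f <- kinsaap:::NATURAL_AA_FREQ / sum(kinsaap:::NATURAL_AA_FREQ)
  s <- 0.8
  target <- mean(vapply(kinsaap:::AA1, function(ref) {
    p <- s * f
    p[ref] <- p[ref] + (1 - s)
    -sum(p * log2(p))
  }, numeric(1))) - 19 / (2 * 50 * log(2))
  others <- setdiff(seq_len(60), c(5, 25, 45))
  ent <- vapply(others, function(j) shannonEntropy(mat[, j]), numeric(1))
  expect_lt(abs(mean(ent) - target), 0.3)
  expect_true(all(ent >= 1.5))
})

test_that("shallow alignments round-trip through FASTA", {
  sp <- syntheticSpec(n_residues = 30, msa_depth = 5, seed = 37)
  m <- generateStructure(sp)
  msa <- generateMsa(sp, m)
  f <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(msa, f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(as.character(back), as.character(msa))
  expect_equal(names(back)[1], "model")
})

test_that("spec validation rejects impossible parameters", {
  expect_error(syntheticSpec(n_residues = 5), "n_residues")
  expect_error(syntheticSpec(proximity_lambda = 0), "proximity_lambda")
  expect_error(syntheticSpec(class_sizes = c(0, 5)), "class sizes")
  expect_error(syntheticSpec(conserved_columns = 999, n_residues = 50),
               "conserved_columns")
  expect_error(syntheticSpec(pair_enrichment =
                               list(native = "L", mutant = "P", fold = 0.5)),
               "fold")
})
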