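# Fixtures built in code: tiny structures, hand-placed geometry and
# independent oracles used across the test files.

# atom-table row constructor
atomRow <- function(resno, aa, atom, element, x, y, z, chain = "A") {
  data.frame(chain = chain, resno = resno, icode = "", aa = aa, atom = atom,
             element = element, x = x, y = y, z = z)
}

toyModel <- function(rows, het = kinsaap:::emptyHetTable()) {
  StructureModel(do.call(rbind, rows), het)
}

# an AccessibilityResult with hand-chosen burial, bypassing the quadrature,
# for tests that exercise rules downstream of accessibility
fakeAccessibility <- function(model, buried_pos, threshold = 0.16) {
  n <- nResidues(model)
  aa <- strsplit(modelSequence(model), "")[[1]]
  rel <- ifelse(seq_len(n) %in% buried_pos, 0.05, 0.50)
  new("AccessibilityResult",
      atomArea = numeric(nrow(model@atoms)),
      residues = data.frame(pos = seq_len(n), aa = aa,
                            area = rel * unname(kinsaap:::REF_MAX_AREA[aa]),
                            rel_acc = rel, buried = rel <= threshold),
      params = sasaParams(burial_threshold = threshold))
}

# minimal mutation record for classifyEffects
effectRecord <- function(model_pos, native, mutant, class = "PD") {
  data.frame(protein_id = "FIX", seq_pos = model_pos, native = native,
             mutant = mutant, class = class, model_pos = model_pos)
}

# single-residue model with configurable atoms, for effect-rule fixtures
soloModel <- function(aa, atoms = list(c("CA", "C"))) {
  rows <- lapply(seq_along(atoms), function(i)
    atomRow(1, aa, atoms[[i]][1], atoms[[i]][2], i * 0.8, 0, 0))
  toyModel(rows)
}

classifyOne <- function(model, rec, buried_pos, features = list()) {
  acc <- fakeAccessibility(model, buried_pos)
  suppressMessages(classifyEffects(rec, model, acc, features = features))
}

expectFlags <- function(eff, expected_true) {
  for (fl in kinsaap:::EFFECT_FLAGS) {
    if (fl %in% expected_true)
      testthat::expect_true(eff[[fl]], label = paste(fl, "should fire"))
    else
      testthat::expect_false(eff[[fl]], label = paste(fl, "should not fire"))
  }
}

# NeRF placement: point D such that |CD| = len, angle(B,C,D) = ang (deg) and
# dihedral(A,B,C,D) = chi (deg); used to build backbones with exact torsions
placeAtom <- function(A, B, C, len, ang, chi) {
  ang <- ang * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-len * cos(ang), len * sin(ang) * cos(chi), len * sin(ang) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# two-residue backbone with a chosen phi for residue 2 (and psi-less end);
# returns the atom rows. Residue 1 contributes CA and C; residue 2 gets
# N, CA, C (phi = dihedral C1-N2-CA2-C2) and optionally CB.
backboneWithPhi <- function(phi, aa1 = "A", aa2 = "A", omega = 180) {
  CA1 <- c(0, 0, 0)
  C1 <- c(1.52, 0, 0)
  N2 <- placeAtom(c(-0.5, 1.2, 0), CA1, C1, 1.33, 116, omega * 0 + 180)
  # omega = dihedral(CA1, C1, N2, CA2)
  CA2 <- placeAtom(CA1, C1, N2, 1.46, 122, omega)
  C2 <- placeAtom(C1, N2, CA2, 1.52, 111, phi)
  rows <- list(
    atomRow(1, aa1, "CA", "C", CA1[1], CA1[2], CA1[3]),
    atomRow(1, aa1, "C", "C", C1[1], C1[2], C1[3]),
    atomRow(2, aa2, "N", "N", N2[1], N2[2], N2[3]),
    atomRow(2, aa2, "CA", "C", CA2[1], CA2[2], CA2[3]),
    atomRow(2, aa2, "C", "C", C2[1], C2[2], C2[3]))
  toyModel(rows)
}

# independent dihedral oracle (textbook formula, written separately from the
# package's implementation)
dihedralOracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cx(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test
fisherOracle <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct-summation oracle for the Xd statistic
xdOracle <- function(upper, obs, bg, normalize = TRUE) {
  s <- 0
  for (i in seq_along(upper)) s <- s + (obs[i] - bg[i]) / upper[i]
  if (normalize) s / length(upper) else s
}

# random percentage vector on n bins, strictly positive so no bin is trimmed
randomPercentages <- function(n) {
  x <- runif(n, 0.05, 1)
  100 * x / sum(x)
}

writeTempPdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdbLine <- function(type, serial, atom, res, chain, resno, x, y, z,
                    occ = 1, alt = " ", element = substr(atom, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, ifelse(nchar(atom) < 4, paste0(" ", atom), atom),
          alt, res, chain, resno, x, y, z, occ, 0, element)
}
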