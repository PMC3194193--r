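# Fixed physico-chemical lookup tables used by the effect rules, the SASA
# calculation and the synthetic generator. All tables cover the 20 standard
# amino acids; values are widely used published constants (sources in the
# package vignette).

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

AA3TO1 <- setNames(names(AA3), AA3)

# common non-standard polymer residues mapped to their parent amino acid
NONSTANDARD_AA <- c(MSE = "M", SEC = "C", SEP = "S", TPO = "T", PTR = "Y",
                    CSO = "C", CME = "C", MLY = "K", HYP = "P", PCA = "E",
                    KCX = "K", LLP = "K", CSD = "C", OCS = "C")

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

# Kyte-Doolittle hydropathy
HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                Y = -1.3, V = 4.2)

# formal side-chain charge at physiological pH (His treated as neutral)
FORMAL_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
                   H = 0, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
                   T = 0, W = 0, Y = 0, V = 0)

# residue volumes (A^3), Zamyatnin (1972)
SIDECHAIN_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                      Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                      L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                      S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# side-chain hydrogen-bond donor/acceptor heavy atoms by PDB atom name
POLAR_SIDECHAIN_ATOMS <- list(
  A = character(), R = c("NE", "NH1", "NH2"), N = c("OD1", "ND2"),
  D = c("OD1", "OD2"), C = character(), Q = c("OE1", "NE2"),
  E = c("OE1", "OE2"), G = character(), H = c("ND1", "NE2"), I = character(),
  L = character(), K = "NZ", M = character(), F = character(),
  P = character(), S = "OG", T = "OG1", W = "NE1", Y = "OH", V = character())

# element van der Waals radii (A) for the SASA calculation
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# theoretical maximum accessible areas (A^2) in an extended Gly-X-Gly
# context, Tien et al. (2013), used to normalise relative accessibility
REF_MAX_AREA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
                  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
                  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
                  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# average amino-acid frequencies in proteins (Robinson & Robinson 1991),
# used by the synthetic sequence generator
NATURAL_AA_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                     Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
                     L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                     S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

# standard genetic code (DNA codons)
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Physico-chemical tables for the structural-effect rules
#'
#' Returns the lookup tables the effect classifier consumes: Kyte-Doolittle
#' hydropathy, formal side-chain charge, residue volume and the side-chain
#' polar (H-bond donor/acceptor) heavy-atom names, each covering all 20
#' standard residues. Supply a modified copy to [classifyEffects()] to use
#' different scales.
#'
#' @return list with elements `hydropathy`, `formal_charge`, `volume`,
#'   `polar_atoms`.
#' @export
chemistryTables <- function() {
  list(hydropathy = HYDROPATHY, formal_charge = FORMAL_CHARGE,
       volume = SIDECHAIN_VOLUME, polar_atoms = POLAR_SIDECHAIN_ATOMS)
}

# 20x20 matrix of single-nucleotide missense path counts: entry [native,
# mutant] is the number of (codon, single-base change) pairs turning a codon
# of `native` into a codon of `mutant`, codons weighted uniformly. Used as
# the background substitution spectrum of the synthetic generator, mirroring
# the single-base origin of real SNP-derived substitutions.
missenseNeighborMatrix <- function() {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 20, 20, dimnames = list(AA1, AA1))
  for (codon in names(GENETIC_CODE_DNA)) {
    aa <- GENETIC_CODE_DNA[[codon]]
    if (aa == "*") next
    cs <- strsplit(codon, "")[[1]]
    for (i in 1:3) for (b in setdiff(bases, cs[i])) {
      mut <- cs; mut[i] <- b
      aa2 <- GENETIC_CODE_DNA[[paste(mut, collapse = "")]]
      if (aa2 != "*" && aa2 != aa) m[aa, aa2] <- m[aa, aa2] + 1
    }
  }
  m
}
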