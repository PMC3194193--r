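# Reading, constructing and writing StructureModel objects.

#' Build a StructureModel from an atom table
#'
#' Low-level constructor used by [readStructure()] and the synthetic
#' generator. Assigns contiguous model positions in the order residues first
#' appear and derives the one-letter sequence.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `aa`
#'   (one-letter), `atom`, `element`, `x`, `y`, `z` (polymer heavy atoms).
#' @param het optional data.frame of heteroatom rows (`group`, `resid`,
#'   `chain`, `atom`, `element`, `x`, `y`, `z`).
#' @return a [StructureModel-class]
#' @export
StructureModel <- function(atoms, het = emptyHetTable()) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode)
  atoms$pos <- as.integer(factor(key, levels = unique(key)))
  atoms <- atoms[, c("pos", "chain", "resno", "icode", "aa", "atom",
                     "element", "x", "y", "z")]
  rownames(atoms) <- NULL
  seq1 <- paste(atoms$aa[!duplicated(atoms$pos)], collapse = "")
  new("StructureModel", atoms = atoms, het = het, sequence = seq1)
}

emptyHetTable <- function() {
  data.frame(group = integer(), resid = character(), chain = character(),
             atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric())
}

inferElement <- function(elety, elesy = NA_character_) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fallback <- toupper(gsub("[^A-Za-z].*$|[0-9]", "", elety))
  fallback <- ifelse(fallback %in% c("SE", "CL", "BR", "MG", "ZN", "FE", "NA"),
                     fallback, substr(fallback, 1, 1))
  ifelse(el == "", fallback, el)
}

#' Parse a PDB file into a StructureModel
#'
#' Reads the first model of a PDB file. Hydrogens are dropped, alternate
#' locations are resolved to the highest-occupancy copy (ties: first record
#' wins), common modified residues (MSE, SEP, ...) are mapped to their parent
#' amino acid, and unmappable polymer residues are excluded with a warning.
#' Non-water HETATM groups (ligands, ions) are collected separately and used
#' by the binding-residue effect rule.
#'
#' @param path path to a PDB file with at least one ATOM record.
#' @param keep_het keep non-water heteroatom groups (default TRUE).
#' @return a [StructureModel-class]
#' @examples
#' pdb <- system.file("extdata", "toy_gag.pdb", package = "kinsaap")
#' readStructure(pdb)
#' @export
readStructure <- function(path, keep_het = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in PDB file: ", path)
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "A", at$chain)
  at$element <- inferElement(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  # altloc: keep the highest-occupancy copy of each (residue, atom name)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    akey <- paste(at$chain, at$resno, at$icode, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), akey), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  resid <- toupper(at$resid)
  aa <- AA3TO1[resid]
  aa[is.na(aa)] <- NONSTANDARD_AA[resid[is.na(aa)]]
  is_water <- resid %in% WATER_RESIDS
  is_polymer <- (at$type == "ATOM" & !is.na(aa)) |
    (at$type == "HETATM" & resid %in% names(NONSTANDARD_AA))
  unmappable <- at$type == "ATOM" & is.na(aa) & !is_water
  if (any(unmappable)) {
    bad <- unique(resid[unmappable])
    warning("excluding unmappable polymer residue(s): ",
            paste(bad, collapse = ", "))
  }

  pol <- at[is_polymer, , drop = FALSE]
  if (nrow(pol) == 0L) stop("no polymer residues in PDB file: ", path)
  atoms <- data.frame(chain = pol$chain, resno = pol$resno, icode = pol$icode,
                      aa = unname(AA3TO1[toupper(pol$resid)]),
                      atom = pol$elety, element = pol$element,
                      x = pol$x, y = pol$y, z = pol$z)
  miss <- is.na(atoms$aa)
  atoms$aa[miss] <- unname(NONSTANDARD_AA[toupper(pol$resid)[miss]])

  het <- emptyHetTable()
  if (keep_het) {
    hsel <- at$type == "HETATM" & !is_water & !is_polymer
    if (any(hsel)) {
      h <- at[hsel, , drop = FALSE]
      gkey <- paste(h$chain, h$resno, h$icode, h$resid)
      het <- data.frame(group = as.integer(factor(gkey, levels = unique(gkey))),
                        resid = toupper(h$resid), chain = h$chain,
                        atom = h$elety, element = h$element,
                        x = h$x, y = h$y, z = h$z)
    }
  }
  StructureModel(atoms, het)
}

#' Write a StructureModel to a PDB file
#'
#' Emits standard fixed-width ATOM records (and HETATM records for het
#' groups) with occupancy 1.00 and B-factor 0.00. Coordinates are written at
#' 3 decimals, so a write/read round trip preserves them to 1e-3 A.
#'
#' @param model a [StructureModel-class]
#' @param path output file path
#' @return invisibly, `path`
#' @export
writeStructure <- function(model, path) {
  a <- model@atoms
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  pad_atom <- function(nm) ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  lines <- sprintf(fmt, "ATOM", seq_len(nrow(a)), pad_atom(a$atom), "",
                   unname(AA3[a$aa]), a$chain, a$resno,
                   ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, 1, 0, a$element)
  h <- model@het
  if (nrow(h)) {
    hl <- sprintf(fmt, "HETATM", nrow(a) + seq_len(nrow(h)), pad_atom(h$atom),
                  "", substr(h$resid, 1, 3), h$chain, 9000L + h$group, " ",
                  h$x, h$y, h$z, 1, 0, h$element)
    lines <- c(lines, hl)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

residueAtoms <- function(model, pos) {
  model@atoms[model@atoms$pos %in% pos, , drop = FALSE]
}

coordMatrix <- function(df) cbind(df$x, df$y, df$z)

# all pairwise Euclidean distances between the rows of two n x 3 matrices
crossDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Minimum inter-residue distance
#'
#' Minimum Euclidean distance between two residues of a model, over all
#' heavy-atom pairs (default) or between C-alpha atoms only. Symmetric, zero
#' when `i == j`.
#'
#' @param model a [StructureModel-class]
#' @param i,j model positions (1-based)
#' @param method `"heavy"` (all heavy atoms) or `"ca"` (C-alpha only)
#' @return distance in Angstrom
#' @export
minResidueDistance <- function(model, i, j, method = c("heavy", "ca")) {
  method <- match.arg(method)
  if (i == j) return(0)
  a <- residueAtoms(model, i)
  b <- residueAtoms(model, j)
  if (method == "ca") {
    a <- a[a$atom == "CA", , drop = FALSE]
    b <- b[b$atom == "CA", , drop = FALSE]
  }
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("residue without usable atoms (positions ", i, ", ", j, ")")
  min(crossDist(coordMatrix(a), coordMatrix(b)))
}

# N x N matrix of minimum heavy-atom (or CA) distances between all residues
residueDistanceMatrix <- function(model, method = c("heavy", "ca")) {
  method <- match.arg(method)
  a <- model@atoms
  if (method == "ca") a <- a[a$atom == "CA", , drop = FALSE]
  n <- nResidues(model)
  D <- crossDist(coordMatrix(a), coordMatrix(a))
  grp <- a$pos
  M <- matrix(Inf, n, n)
  idx <- split(seq_along(grp), grp)
  for (i in seq_len(n)) {
    block <- D[idx[[i]], , drop = FALSE]
    # column minima over this residue's atom rows
    cm <- block[1, ]
    if (nrow(block) > 1L)
      for (r in 2:nrow(block)) cm <- pmin(cm, block[r, ])
    M[i, ] <- vapply(idx, function(k) min(cm[k]), numeric(1))
  }
  diag(M) <- 0
  M
}
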