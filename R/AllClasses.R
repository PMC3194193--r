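#' StructureModel: a parsed single-model protein structure
#'
#' Holds the polymer residues of one structural model in file order, with one
#' row per heavy atom, plus non-water heteroatom groups (ligands, ions).
#' Residues are indexed by contiguous 1-based model positions that all other
#' analyses (features, mutations, distances) refer to.
#'
#' @slot atoms data.frame of polymer heavy atoms with columns
#'   `pos` (model position, 1..N), `chain`, `resno`, `icode`, `aa`
#'   (one-letter code), `atom` (PDB atom name), `element`, `x`, `y`, `z`.
#' @slot het data.frame of non-water HETATM heavy atoms with columns
#'   `group` (1-based het group index), `resid`, `chain`, `atom`, `element`,
#'   `x`, `y`, `z`. Zero rows when the file has no ligands.
#' @slot sequence single string, one-letter sequence of length N.
#'
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", het = "data.frame",
                 sequence = "character"),
  validity = function(object) {
    msg <- character()
    a <- object@atoms
    need <- c("pos", "chain", "resno", "icode", "aa", "atom", "element",
              "x", "y", "z")
    if (!all(need %in% names(a)))
      msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
    else {
      if (nrow(a) == 0L) msg <- c(msg, "structure has no polymer atoms")
      if (!all(is.finite(c(a$x, a$y, a$z))))
        msg <- c(msg, "atom coordinates must be finite")
      n <- length(unique(a$pos))
      if (!identical(sort(unique(a$pos)), seq_len(n)))
        msg <- c(msg, "model positions must be contiguous 1..N")
      if (nchar(object@sequence) != n)
        msg <- c(msg, "sequence length must equal the number of residues")
      if (any(a$element == "")) msg <- c(msg, "empty element symbols")
    }
    if (length(msg)) msg else TRUE
  })

#' FeatureSet: a named set of model positions
#'
#' A label plus a set of 1-based model positions (catalytic residues,
#' tree-determinants, buried residues, conserved columns, ...). Positions are
#' stored sorted and unique.
#'
#' @slot name character label, e.g. `"catalytic_firedb"`.
#' @slot positions sorted unique integer vector of model positions.
#' @export
setClass("FeatureSet",
  representation(name = "character", positions = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || object@name == "")
      msg <- c(msg, "name must be a single non-empty string")
    p <- object@positions
    if (anyNA(p) || any(p < 1L)) msg <- c(msg, "positions must be >= 1")
    if (is.unsorted(p, strictly = TRUE) && length(p) > 1L)
      msg <- c(msg, "positions must be sorted and unique")
    if (length(msg)) msg else TRUE
  })

#' AccessibilityResult: solvent-accessible surface areas for one model
#'
#' Per-atom and per-residue accessible areas from the probe-rolling
#' calculation, with relative accessibilities against an extended-state
#' reference and the derived burial flag.
#'
#' @slot atomArea numeric vector, one area (A^2) per polymer atom, in the
#'   row order of the model's `atoms` slot.
#' @slot residues data.frame with columns `pos`, `aa`, `area` (A^2),
#'   `rel_acc` (fraction of the reference maximum) and `buried` (logical).
#' @slot params list of the parameters used (probe radius, points, radii,
#'   reference areas, burial threshold).
#' @export
setClass("AccessibilityResult",
  representation(atomArea = "numeric", residues = "data.frame",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    r <- object@residues
    need <- c("pos", "aa", "area", "rel_acc", "buried")
    if (!all(need %in% names(r)))
      msg <- c(msg, paste("residues must have columns:", paste(need, collapse = ", ")))
    else {
      if (any(r$area < -1e-9)) msg <- c(msg, "negative residue areas")
      if (any(object@atomArea < -1e-9)) msg <- c(msg, "negative atom areas")
    }
    if (length(msg)) msg else TRUE
  })

#' DistanceDistribution: binned observed vs background distance percentages
#'
#' Distances are binned on (d[i-1], d[i]] with the first bin closed at zero,
#' so a residue inside the feature set (distance 0) falls in bin 1. Both the
#' observed set and the all-residue background are expressed as percentages
#' summing to 100.
#'
#' @slot upper numeric, strictly increasing bin upper limits d_i (A).
#' @slot observed numeric, percentage of the observed set per bin.
#' @slot background numeric, percentage of all model residues per bin.
#' @export
setClass("DistanceDistribution",
  representation(upper = "numeric", observed = "numeric",
                 background = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- object@upper
    if (length(d) < 1L || any(d <= 0) || is.unsorted(d, strictly = TRUE))
      msg <- c(msg, "bin upper limits must be positive and strictly increasing")
    if (length(object@observed) != length(d) ||
        length(object@background) != length(d))
      msg <- c(msg, "observed/background must have one entry per bin")
    for (nm in c("observed", "background")) {
      p <- slot(object, nm)
      if (anyNA(p) || any(p < -1e-9)) msg <- c(msg, paste(nm, "has negative entries"))
      else if (abs(sum(p) - 100) > 1e-6)
        msg <- c(msg, paste(nm, "percentages must sum to 100"))
    }
    if (length(msg)) msg else TRUE
  })
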