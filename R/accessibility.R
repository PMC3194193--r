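# Probe-rolling solvent-accessible surface area (Shrake-Rupley style with a
# deterministic golden-spiral quadrature) and the relative-accessibility
# burial rule.

#' Parameters for the accessibility calculation
#'
#' @param probe_radius probe (solvent) radius in Angstrom; 1.4 approximates a
#'   water molecule.
#' @param n_points quadrature points per atom sphere. The point set is a
#'   deterministic golden-section spiral, so results are bit-reproducible;
#'   960 points give per-atom areas accurate to well under 1 %.
#' @param radii named element -> van der Waals radius table (A).
#' @param ref_max_area named residue -> maximum accessible area table (A^2),
#'   the extended Gly-X-Gly reference used to normalise relative
#'   accessibility.
#' @param burial_threshold relative accessibility at or below which a residue
#'   counts as buried (default 0.16, i.e. 16 % or less of the reference
#'   surface exposed).
#' @return list of validated parameters for [computeSasa()]
#' @export
sasaParams <- function(probe_radius = 1.4, n_points = 960L,
                       radii = VDW_RADII, ref_max_area = REF_MAX_AREA,
                       burial_threshold = 0.16) {
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (n_points < 100L) stop("n_points must be >= 100")
  missing_aa <- setdiff(AA1, names(ref_max_area))
  if (length(missing_aa))
    stop("ref_max_area missing residue(s): ", paste(missing_aa, collapse = ", "))
  if (burial_threshold <= 0 || burial_threshold >= 1)
    stop("burial_threshold must be in (0, 1)")
  list(probe_radius = probe_radius, n_points = as.integer(n_points),
       radii = radii, ref_max_area = ref_max_area,
       burial_threshold = burial_threshold)
}

# deterministic golden-section spiral on the unit sphere
spiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(theta), r * sin(theta), z)
}

# core quadrature: exposed fraction of each expanded-radius atom sphere
sasaAreas <- function(xyz, radius_exp, n_points) {
  n <- nrow(xyz)
  pts <- spiralPoints(n_points)
  areas <- numeric(n)
  # neighbour candidates: centre distance below sum of expanded radii
  D <- crossDist(xyz, xyz)
  rmax <- max(radius_exp)
  for (i in seq_len(n)) {
    ri <- radius_exp[i]
    nb <- which(D[i, ] < ri + radius_exp & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- p[exposed, 1] - xyz[j, 1]
      dy <- p[exposed, 2] - xyz[j, 2]
      dz <- p[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz > radius_exp[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * ri^2
  }
  areas
}

#' Solvent-accessible surface area of a model
#'
#' Rolls a spherical probe over the heavy atoms of the polymer (het groups
#' and hydrogens are excluded): each atom is expanded by the probe radius,
#' sampled with a deterministic spiral point set, and the fraction of points
#' not inside any neighbouring expanded sphere gives the accessible area
#' fraction. Per-residue areas are the sums over the residue's atoms;
#' relative accessibility divides by the extended-reference maximum for the
#' residue type, and residues at or below the burial threshold are flagged
#' buried.
#'
#' @param model a [StructureModel-class]
#' @param params parameter list from [sasaParams()]
#' @return an [AccessibilityResult-class]
#' @export
computeSasa <- function(model, params = sasaParams()) {
  a <- model@atoms
  unknown <- setdiff(unique(a$element), names(params$radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  rexp <- unname(params$radii[a$element]) + params$probe_radius
  atom_area <- sasaAreas(coordMatrix(a), rexp, params$n_points)
  res_area <- as.numeric(tapply(atom_area, a$pos, sum))
  aa <- a$aa[!duplicated(a$pos)]
  bad <- setdiff(unique(aa), names(params$ref_max_area))
  if (length(bad))
    stop("ref_max_area missing residue type(s): ", paste(bad, collapse = ", "))
  rel <- res_area / unname(params$ref_max_area[aa])
  residues <- data.frame(pos = sort(unique(a$pos)), aa = aa, area = res_area,
                         rel_acc = rel,
                         buried = rel <= params$burial_threshold)
  new("AccessibilityResult", atomArea = atom_area, residues = residues,
      params = params)
}

#' Buried residues of a model
#'
#' Returns the positions whose relative accessibility is at or below the
#' threshold (boundary inclusive: exactly 16 % counts as buried).
#'
#' @param result an [AccessibilityResult-class]
#' @param threshold burial threshold as a fraction in (0, 1); defaults to the
#'   threshold stored in the result's parameters.
#' @return a [FeatureSet-class] named `"buried"`
#' @export
classifyBuried <- function(result, threshold = NULL) {
  if (is.null(threshold)) threshold <- result@params$burial_threshold
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  r <- result@residues
  featureSet("buried", r$pos[r$rel_acc <= threshold])
}

#' Write the per-residue accessibility table as TSV
#' @param result an [AccessibilityResult-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeAccessibility <- function(result, path) {
  writeTsv(result@residues, path)
}
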