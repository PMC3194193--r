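# Rule-based classification of hypothesized structural effects of
# substitutions, producing the per-mutation binary explanatory vector.

EFFECT_FLAGS <- c("surface_hydrophobic", "core_hydrophilic",
                  "charge_shift_buried", "disulphide_disrupted",
                  "cavity_introduced", "hbond_broken", "from_cis_proline",
                  "from_glycine", "to_proline", "clash",
                  "annotated_functional", "binding_residue",
                  "interface_quaternary", "sequence_conserved")

#' Thresholds for the structural-effect rules
#'
#' All cutoffs used by [classifyEffects()]. Defaults are this package's
#' documented conventions: a hydropathy change of 2.0 units
#' (Kyte-Doolittle scale) for the surface/core stability rules, a 40 A^3
#' volume change for cavity/clash, 3.5 A for polar (hydrogen-bond) contacts,
#' 4.0 A for ligand/interface contacts, 2.5 A between SG atoms for a
#' disulphide, phi outside \[-90, -40\] degrees for the to-proline rule,
#' |omega| <= 30 degrees for cis-proline and phi > -20 degrees as the
#' glycine-only backbone region.
#'
#' @param delta_hydropathy minimum hydropathy shift
#' @param delta_volume minimum side-chain volume change (A^3)
#' @param polar_contact polar-contact distance (A)
#' @param binding_contact ligand/interface contact distance (A)
#' @param disulphide_sg SG-SG distance for a disulphide bond (A)
#' @param to_proline_phi allowed phi window (degrees) for proline
#' @param cis_omega |omega| bound (degrees) defining cis peptide bonds
#' @param glycine_phi_min phi (degrees) above which only glycine is
#'   comfortable
#' @return named list of thresholds
#' @export
effectThresholds <- function(delta_hydropathy = 2.0, delta_volume = 40,
                             polar_contact = 3.5, binding_contact = 4.0,
                             disulphide_sg = 2.5,
                             to_proline_phi = c(-90, -40), cis_omega = 30,
                             glycine_phi_min = -20) {
  list(delta_hydropathy = delta_hydropathy, delta_volume = delta_volume,
       polar_contact = polar_contact, binding_contact = binding_contact,
       disulphide_sg = disulphide_sg, to_proline_phi = to_proline_phi,
       cis_omega = cis_omega, glycine_phi_min = glycine_phi_min)
}

# dihedral angle (degrees) defined by four points
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # IUPAC sign convention (matches bio3d::torsion.xyz)
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# per-residue backbone torsions; NA where backbone atoms are missing or the
# neighbouring residue is on a different chain
backboneTorsions <- function(model) {
  a <- model@atoms
  n <- nResidues(model)
  getAtom <- function(pos, name) {
    r <- a[a$pos == pos & a$atom == name, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  chain_of <- a$chain[!duplicated(a$pos)]
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- getAtom(i, "N"); CAi <- getAtom(i, "CA"); Ci <- getAtom(i, "C")
    if (i > 1L && chain_of[i - 1] == chain_of[i]) {
      Cp <- getAtom(i - 1L, "C"); CAp <- getAtom(i - 1L, "CA")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
        phi[i] <- dihedralAngle(Cp, Ni, CAi, Ci)
      if (!is.null(CAp) && !is.null(Cp) && !is.null(Ni) && !is.null(CAi))
        omega[i] <- dihedralAngle(CAp, Cp, Ni, CAi)
    }
    if (i < n && chain_of[i + 1] == chain_of[i]) {
      Nn <- getAtom(i + 1L, "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
        psi[i] <- dihedralAngle(Ni, CAi, Ci, Nn)
    }
  }
  data.frame(pos = seq_len(n), phi = phi, psi = psi, omega = omega)
}

# position-level geometric predicates shared by all records at a position
positionGeometry <- function(model, thresholds) {
  a <- model@atoms
  n <- nResidues(model)
  xyz <- coordMatrix(a)
  chain_of <- a$chain[!duplicated(a$pos)]
  aa_of <- strsplit(model@sequence, "")[[1]]

  D <- crossDist(xyz, xyz)

  # disulphide geometry: SG within cutoff of another residue's SG
  sg <- which(a$atom == "SG")
  ss_geom <- rep(FALSE, n)
  if (length(sg) > 1L) {
    Dss <- D[sg, sg, drop = FALSE]
    diag(Dss) <- Inf
    same_res <- outer(a$pos[sg], a$pos[sg], "==")
    Dss[same_res] <- Inf
    ss_geom[unique(a$pos[sg][apply(Dss <= thresholds$disulphide_sg, 1, any)])] <- TRUE
  }

  # polar side-chain contact: a polar side-chain atom of the residue within
  # the polar cutoff of a polar atom (side-chain polar or backbone N/O) of a
  # different residue
  polar_sc <- mapply(function(aa, nm) nm %in% POLAR_SIDECHAIN_ATOMS[[aa]],
                     a$aa, a$atom)
  polar_any <- polar_sc | a$atom %in% c("N", "O")
  hb_geom <- rep(FALSE, n)
  psc_idx <- which(polar_sc)
  if (length(psc_idx)) {
    pan_idx <- which(polar_any)
    Dp <- D[psc_idx, pan_idx, drop = FALSE]
    diff_res <- outer(a$pos[psc_idx], a$pos[pan_idx], "!=")
    hit <- (Dp <= thresholds$polar_contact) & diff_res
    hb_geom[unique(a$pos[psc_idx][apply(hit, 1, any)])] <- TRUE
  }

  # interface: heavy atom within cutoff of an atom on a different chain
  iface <- rep(FALSE, n)
  if (length(unique(a$chain)) > 1L) {
    diff_chain <- outer(a$chain, a$chain, "!=")
    hit <- (D <= thresholds$binding_contact) & diff_chain
    iface[unique(a$pos[apply(hit, 1, any)])] <- TRUE
  }

  # ligand binding: within cutoff of a non-water het-group atom
  lig <- rep(FALSE, n)
  if (nrow(model@het)) {
    Dh <- crossDist(xyz, coordMatrix(model@het))
    lig[unique(a$pos[apply(Dh <= thresholds$binding_contact, 1, any)])] <- TRUE
  }

  tor <- backboneTorsions(model)
  data.frame(pos = seq_len(n), aa = aa_of, chain = chain_of,
             ss_geom = ss_geom, hb_geom = hb_geom,
             interface = iface, ligand = lig,
             phi = tor$phi, psi = tor$psi, omega = tor$omega)
}

#' Classify structural effects of mapped mutations
#'
#' Evaluates the full set of structural-effect hypotheses for every mapped
#' mutation record and returns the binary explanatory vector per record,
#' with the two summary flags: `structurally_explained` (any flag except
#' sequence conservation) and `explained` (any flag at all). Records without
#' a model position are skipped with a message. Torsion-based rules
#' (cis-proline, glycine, to-proline) are set to FALSE when backbone atoms
#' are missing.
#'
#' The categories: unfavourable hydrophobicity on the surface
#' (hydrophilic-to-hydrophobic on exposed residues) and in the core
#' (hydrophobic-to-hydrophilic on buried residues); buried charge shifts;
#' disrupted disulphides; cavities introduced by burying a much smaller side
#' chain and clashes from a much larger one; broken side-chain hydrogen
#' bonds; torsionally unfavourable changes from cis-proline, from glycine
#' and to proline; mutations at annotated functional residues, at
#' ligand-binding residues, at inter-chain interfaces; and mutations at
#' sequence-conserved positions.
#'
#' @param records mapped mutation data.frame (see [mapMutationsToModel()];
#'   rows with `NA` `model_pos` are skipped)
#' @param model a [StructureModel-class]
#' @param acc an [AccessibilityResult-class] for the model
#' @param features named list of [FeatureSet-class]; recognised names:
#'   `conserved`, `annotated`, `binding_extra` (additional binding positions
#'   from external interaction annotations). Missing entries disable the
#'   corresponding flags.
#' @param tables chemistry tables from [chemistryTables()]
#' @param thresholds rule thresholds from [effectThresholds()]
#' @return the classified records with one logical column per effect flag
#'   plus `structurally_explained` and `explained`
#' @export
classifyEffects <- function(records, model, acc, features = list(),
                            tables = chemistryTables(),
                            thresholds = effectThresholds()) {
  mapped <- !is.na(records$model_pos)
  if (any(!mapped))
    message("skipping ", sum(!mapped), " unmapped record(s)")
  rec <- records[mapped, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no mapped records to classify")

  geo <- positionGeometry(model, thresholds)
  racc <- residueAccessibility(acc)
  buried <- racc$buried[match(rec$model_pos, racc$pos)]
  g <- geo[match(rec$model_pos, geo$pos), ]

  hyd <- tables$hydropathy
  chg <- tables$formal_charge
  vol <- tables$volume
  dh <- unname(hyd[rec$mutant] - hyd[rec$native])
  dv <- unname(vol[rec$mutant] - vol[rec$native])
  mutant_polar <- vapply(rec$mutant,
                         function(m) length(tables$polar_atoms[[m]]) > 0L,
                         logical(1))
  native_polar <- vapply(rec$native,
                         function(m) length(tables$polar_atoms[[m]]) > 0L,
                         logical(1))

  in_set <- function(name) {
    fs <- features[[name]]
    if (is.null(fs)) rep(FALSE, nrow(rec))
    else rec$model_pos %in% positions(fs)
  }

  phi_ok <- !is.na(g$phi)
  out <- rec
  out$surface_hydrophobic <- !buried & dh >= thresholds$delta_hydropathy
  out$core_hydrophilic <- buried & dh <= -thresholds$delta_hydropathy
  out$charge_shift_buried <- buried &
    unname(chg[rec$native]) != unname(chg[rec$mutant])
  out$disulphide_disrupted <- g$ss_geom & rec$native == "C" & rec$mutant != "C"
  out$cavity_introduced <- buried & (-dv) >= thresholds$delta_volume
  out$hbond_broken <- g$hb_geom & native_polar & !mutant_polar
  out$from_cis_proline <- rec$native == "P" & !is.na(g$omega) &
    abs(g$omega) <= thresholds$cis_omega
  out$from_glycine <- rec$native == "G" & phi_ok &
    g$phi > thresholds$glycine_phi_min
  out$to_proline <- rec$mutant == "P" & phi_ok &
    (g$phi < thresholds$to_proline_phi[1] | g$phi > thresholds$to_proline_phi[2])
  out$clash <- buried & dv >= thresholds$delta_volume
  out$annotated_functional <- in_set("annotated")
  out$binding_residue <- g$ligand | g$interface | in_set("binding_extra")
  out$interface_quaternary <- g$interface
  out$sequence_conserved <- in_set("conserved")

  structural <- setdiff(EFFECT_FLAGS, "sequence_conserved")
  out$structurally_explained <- Reduce(`|`, out[structural])
  out$explained <- out$structurally_explained | out$sequence_conserved
  rownames(out) <- NULL
  out
}

#' Contingency tables of effect flags by mutation class
#'
#' For every effect category (and the two summary flags) builds the 2x2
#' class-by-flag table used by the Fisher comparisons; rows are the PD and
#' SNP classes, columns the records with and without the flag.
#'
#' @param effects classified records from [classifyEffects()]
#' @return named list of 2x2 integer matrices
#' @export
effectMatrix <- function(effects) {
  counts <- table(effects$class)
  if (length(counts) < 2L || any(counts == 0L))
    stop("both mutation classes must have classified records")
  cols <- c(EFFECT_FLAGS, "structurally_explained", "explained")
  out <- lapply(cols, function(fl) {
    f <- effects[[fl]]
    m <- rbind(PD = c(sum(f[effects$class == "PD"]),
                      sum(!f[effects$class == "PD"])),
               SNP = c(sum(f[effects$class == "SNP"]),
                       sum(!f[effects$class == "SNP"])))
    colnames(m) <- c("flag", "no_flag")
    m
  })
  names(out) <- cols
  out
}
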