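# Seeded generator of synthetic inputs: structures, alignments, feature
# sets and two mutation classes with planted proximity and composition
# signal. Defaults mirror the shape of the study dataset this package is
# built to analyse: 62 structure-mapped pathogenic vs 36 neutral records,
# a 32-residue functional site, and a Leu-to-Proline excess in the
# pathogenic class.

#' Specification of a synthetic data bundle
#'
#' @param n_residues residues in the generated structure (default 250)
#' @param geometry `"globule"` (self-avoiding packing in a sphere) or
#'   `"helix"` (ideal alpha-helical trace)
#' @param n_features size of the planted functional feature set (default 32)
#' @param class_sizes c(PD, SNP) record counts (default 62, 36; use
#'   c(130, 200) for sequence-level studies)
#' @param proximity_lambda distance-decay scale (A) for placing PD records
#'   near the feature set; `Inf` gives uniform placement (default 2)
#' @param pair_enrichment list(native, mutant, fold) planting an excess of
#'   one substitution pair in the PD class (default L>P at 10-fold);
#'   `NULL` disables it
#' @param msa_depth alignment rows including the model row (default 50)
#' @param n_conserved number of planted invariant alignment columns
#'   (default 12); alternatively give `conserved_columns` explicitly
#' @param conserved_columns explicit model positions to keep invariant
#' @param substitution_rate per-column substitution probability of
#'   non-conserved MSA columns (default 0.8)
#' @param n_proteins number of synthetic protein accessions the mutation
#'   records are spread over (default 8)
#' @param seed integer fixing all randomness
#' @return validated spec list for the `generate*` functions
#' @export
syntheticSpec <- function(n_residues = 250L, geometry = c("globule", "helix"),
                          n_features = 32L, class_sizes = c(62L, 36L),
                          proximity_lambda = 2, pair_enrichment =
                            list(native = "L", mutant = "P", fold = 10),
                          msa_depth = 50L, n_conserved = 12L,
                          conserved_columns = NULL, substitution_rate = 0.8,
                          n_proteins = 8L, seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 10L) stop("n_residues must be >= 10")
  if (any(class_sizes < 1L)) stop("class sizes must be >= 1")
  if (proximity_lambda <= 0) stop("proximity_lambda must be > 0 (may be Inf)")
  if (!is.null(pair_enrichment) && pair_enrichment$fold < 1)
    stop("pair_enrichment fold must be >= 1")
  if (msa_depth < 5L) stop("msa_depth must be >= 5")
  if (!is.null(conserved_columns) &&
      any(conserved_columns < 1L | conserved_columns > n_residues))
    stop("conserved_columns outside 1..n_residues")
  list(n_residues = as.integer(n_residues), geometry = geometry,
       n_features = as.integer(n_features),
       class_sizes = as.integer(class_sizes),
       proximity_lambda = proximity_lambda,
       pair_enrichment = pair_enrichment, msa_depth = as.integer(msa_depth),
       n_conserved = as.integer(n_conserved),
       conserved_columns = conserved_columns,
       substitution_rate = substitution_rate,
       n_proteins = as.integer(n_proteins), seed = as.integer(seed))
}

randomSequence <- function(n) {
  sample(AA1, n, replace = TRUE, prob = NATURAL_AA_FREQ)
}

# sequence with the natural composition held fixed (largest-remainder
# apportionment of the target frequencies), residues shuffled: emulates one
# protein-family domain, whose composition does not vary run to run
compositionSequence <- function(n) {
  f <- NATURAL_AA_FREQ / sum(NATURAL_AA_FREQ)
  counts <- floor(f * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(f * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(AA1, counts))
}

helixCoords <- function(n, rise = 1.5, twist = 100, ca_radius = 2.3) {
  t <- seq_len(n) - 1L
  th <- t * twist * pi / 180
  cbind(ca_radius * cos(th), ca_radius * sin(th), rise * t)
}

#' Generate a synthetic structure
#'
#' Helix mode builds an ideal alpha-helical trace (rise 1.5 A per residue,
#' 100 degrees twist, C-alpha radius 2.3 A) with a pseudo backbone (N, C, O
#' interpolated along the trace) and one outward side-chain pseudo-atom per
#' non-glycine residue. Globule mode packs C-alpha positions self-avoidingly
#' (minimum separation 3.5 A) inside a sphere sized for about 0.005 residues
#' per cubic Angstrom, each with a side-chain pseudo-atom in a random
#' direction. Sequences are drawn from natural amino-acid frequencies.
#' Deterministic under `spec$seed`.
#'
#' @param spec a [syntheticSpec()]
#' @return a [StructureModel-class]
#' @export
generateStructure <- function(spec) {
  withSeed(spec$seed, {
    n <- spec$n_residues
    seq1 <- compositionSequence(n)
    if (spec$geometry == "helix") {
      ca <- helixCoords(n)
      nb <- ca + 0.45 * (rbind(ca[1, ] * 2 - ca[2, ], ca[-n, ]) - ca)
      cb <- ca + 0.45 * (rbind(ca[-1, ], ca[n, ] * 2 - ca[n - 1, ]) - ca)
      rad <- ca[, 1:2] / sqrt(rowSums(ca[, 1:2]^2))
      ob <- cb + 1.23 * cbind(rad, 0)
      sc <- cbind(ca[, 1:2] * (3.4 / 2.3), ca[, 3])
      rows <- list()
      for (i in seq_len(n)) {
        at <- rbind(N = nb[i, ], CA = ca[i, ], C = cb[i, ], O = ob[i, ])
        el <- c("N", "C", "C", "O")
        if (seq1[i] != "G") {
          at <- rbind(at, CB = sc[i, ])
          el <- c(el, "C")
        }
        rows[[i]] <- data.frame(chain = "A", resno = i, icode = "",
                                aa = seq1[i], atom = rownames(at),
                                element = el, x = at[, 1], y = at[, 2],
                                z = at[, 3])
      }
    } else {
      radius <- (3 * n / (4 * pi * 0.005))^(1/3)
      pts <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          p <- runif(3, -radius, radius)
          if (sum(p^2) > radius^2) next
          if (i == 1L || min(crossDist(matrix(p, 1), pts[seq_len(i - 1L), ,
                                                         drop = FALSE])) >= 3.5) {
            pts[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not pack ", n, " residues; use fewer residues or a ",
               "larger sphere (lower density)")
      }
      rows <- list()
      for (i in seq_len(n)) {
        at <- matrix(pts[i, ], 1)
        nm <- "CA"; el <- "C"
        if (seq1[i] != "G") {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          at <- rbind(at, pts[i, ] + 1.5 * u)
          nm <- c(nm, "CB"); el <- c(el, "C")
        }
        rows[[i]] <- data.frame(chain = "A", resno = i, icode = "",
                                aa = seq1[i], atom = nm, element = el,
                                x = at[, 1], y = at[, 2], z = at[, 3])
      }
    }
    StructureModel(do.call(rbind, rows))
  })
}

#' Plant a functional feature set on a synthetic model
#'
#' Emulates a binding pocket: picks a random anchor residue and takes the
#' `n_features` residues closest to it (minimum heavy-atom distance), so the
#' planted set forms a spatial cluster the way real catalytic sites do.
#' The proximity bias of the PD class is planted toward this set.
#'
#' @param spec a [syntheticSpec()]
#' @param model the generated [StructureModel-class]
#' @return a [FeatureSet-class] named `"catalytic"`
#' @export
generateFeatureSet <- function(spec, model) {
  withSeed(spec$seed + 1L, {
    n <- nResidues(model)
    anchor <- sample(n, 1L)
    d <- distancesToFeature(seq_len(n), featureSet("anchor", anchor), model)
    featureSet("catalytic", order(d)[seq_len(spec$n_features)], model)
  })
}

# background mutant distribution given a native residue: single-nucleotide
# missense path counts from the native's codons
mutantProbs <- function(native, neighbor) {
  w <- neighbor[native, ]
  w / sum(w)
}

#' Plant the two mutation classes
#'
#' PD-class positions are sampled with probability proportional to
#' `exp(-d / lambda)` where d is the position's minimum distance to the
#' feature set (`lambda = Inf` gives the uniform limit); SNP-class positions
#' are sampled uniformly. Native residues are read off the model sequence;
#' mutant residues are drawn from a genetic-code-aware background (weights =
#' number of single-nucleotide missense paths from the native's codons).
#' The pair enrichment is planted as a record-level mixture in the PD class:
#' a PD record is, with the appropriate probability, replaced by the planted
#' (native, mutant) pair at a position carrying that native residue, so that
#' the PD-class pair frequency is `fold` times the background pair frequency
#' in expectation. Records are unique under the (protein id, position,
#' native, mutant) key by construction.
#'
#' @param spec a [syntheticSpec()]
#' @param model the generated [StructureModel-class]
#' @param feature the planted [FeatureSet-class]
#' @return mutation data.frame as produced by [readMutationTable()]
#' @export
plantMutationClasses <- function(spec, model, feature) {
  if (is.finite(spec$proximity_lambda) && length(positions(feature)) == 0L)
    stop("feature set must be non-empty when proximity_lambda is finite")
  withSeed(spec$seed + 2L, {
    n <- nResidues(model)
    seq1 <- strsplit(modelSequence(model), "")[[1]]
    d <- distancesToFeature(seq_len(n), feature, model)
    w_pd <- if (is.finite(spec$proximity_lambda))
      exp(-d / spec$proximity_lambda) else rep(1, n)
    neighbor <- missenseNeighborMatrix()
    ids <- sprintf("SYNKIN%03d", seq_len(spec$n_proteins))

    # mixture weight making the planted pair `fold` x the background pair
    # frequency: q_A = pi + (1 - pi) q_B = fold * q_B
    enrich <- spec$pair_enrichment
    pi_plant <- 0
    if (!is.null(enrich)) {
      nat_idx <- which(seq1 == enrich$native)
      if (length(nat_idx) == 0L) {
        warning("native residue '", enrich$native,
                "' absent from the model sequence; pair enrichment disabled")
        enrich <- NULL
      } else {
        q_b <- (length(nat_idx) / n) *
          mutantProbs(enrich$native, neighbor)[enrich$mutant]
        pi_plant <- min((enrich$fold - 1) * q_b / (1 - q_b), 0.95)
      }
    }

    sampleClass <- function(nrec, weights, label, planted) {
      got <- data.frame()
      for (round in seq_len(50L)) {
        need <- nrec - nrow(got)
        if (need <= 0L) break
        take <- 2L * need + 10L
        pos <- sample(n, take, replace = TRUE, prob = weights)
        nat <- seq1[pos]
        mut <- vapply(nat, function(x) {
          p <- mutantProbs(x, neighbor)
          sample(names(p), 1L, prob = p)
        }, character(1))
        if (planted && pi_plant > 0) {
          plant <- runif(take) < pi_plant
          if (any(plant)) {
            idx <- which(seq1 == enrich$native)
            pos[plant] <- idx[sample.int(length(idx), sum(plant),
                                         replace = TRUE,
                                         prob = weights[idx])]
            nat[plant] <- enrich$native
            mut[plant] <- enrich$mutant
          }
        }
        df <- data.frame(protein_id = sample(ids, take, replace = TRUE),
                         seq_pos = pos, native = nat, mutant = unname(mut),
                         class = label)
        got <- rbind(got, df)
        got <- got[!duplicated(paste(got$protein_id, got$seq_pos,
                                     got$native, got$mutant)), , drop = FALSE]
      }
      if (nrow(got) < nrec)
        stop("could not draw ", nrec, " unique records; enlarge the model")
      got[seq_len(nrec), , drop = FALSE]
    }

    pd <- sampleClass(spec$class_sizes[1], w_pd, "PD", TRUE)
    snp <- sampleClass(spec$class_sizes[2], rep(1, n), "SNP", FALSE)
    out <- rbind(pd, snp)
    out$sequence <- modelSequence(model)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic multiple sequence alignment
#'
#' The model sequence is the first (reference) row; planted conserved
#' columns are invariant across all rows, other columns substitute the
#' reference residue with probability `substitution_rate`, drawing
#' replacements from natural amino-acid frequencies. No gaps are introduced.
#' Deterministic under `spec$seed`.
#'
#' @param spec a [syntheticSpec()]
#' @param model the generated [StructureModel-class]
#' @return an `AAStringSet` (first row named `"model"`); the planted
#'   conserved positions are attached as `attr(, "conserved")`
#' @export
generateMsa <- function(spec, model) {
  withSeed(spec$seed + 3L, {
    n <- nResidues(model)
    cons <- spec$conserved_columns
    if (is.null(cons)) cons <- sort(sample(n, spec$n_conserved))
    seq1 <- strsplit(modelSequence(model), "")[[1]]
    rows <- matrix(rep(seq1, each = spec$msa_depth), nrow = spec$msa_depth)
    for (j in setdiff(seq_len(n), cons)) {
      mut <- runif(spec$msa_depth - 1L) < spec$substitution_rate
      if (any(mut))
        rows[1L + which(mut), j] <- randomSequence(sum(mut))
    }
    out <- Biostrings::AAStringSet(apply(rows, 1, paste, collapse = ""))
    names(out) <- c("model", sprintf("hom%03d", seq_len(spec$msa_depth - 1L)))
    attr(out, "conserved") <- cons
    out
  })
}

#' Generate and write a complete synthetic bundle
#'
#' Produces the structure, feature set, mutation classes and alignment for a
#' spec and, when `dir` is given, writes them as the file formats the rest
#' of the package reads (PDB, TSV, FASTA) together with a JSON truth
#' manifest recording every generating parameter.
#'
#' @param spec a [syntheticSpec()]
#' @param dir optional output directory (created if needed)
#' @return list with `model`, `feature`, `mutations`, `msa`, `truth` and,
#'   when written, `paths`
#' @export
generateBundle <- function(spec, dir = NULL) {
  model <- generateStructure(spec)
  feature <- generateFeatureSet(spec, model)
  mutations <- plantMutationClasses(spec, model, feature)
  msa <- generateMsa(spec, model)
  truth <- spec
  truth$feature_positions <- positions(feature)
  truth$conserved_columns <- attr(msa, "conserved")
  out <- list(model = model, feature = feature, mutations = mutations,
              msa = msa, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(model = file.path(dir, "model.pdb"),
                  features = file.path(dir, "features.tsv"),
                  mutations = file.path(dir, "mutations.tsv"),
                  msa = file.path(dir, "msa.fasta"),
                  truth = file.path(dir, "truth.json"))
    writeStructure(model, paths$model)
    writeFeatureLists(list(feature), paths$features)
    writeTsv(mutations, paths$mutations)
    Biostrings::writeXStringSet(msa, paths$msa)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}
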