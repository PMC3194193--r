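# Shannon-entropy conservation from a multiple sequence alignment and its
# projection onto model positions.

#' Shannon entropy of an alignment column
#'
#' Entropy in bits over the observed residue frequencies of one column.
#' Gap characters (`-`, `.`) are excluded from the frequency counts; a column
#' consisting only of gaps is an error.
#'
#' @param column character vector of single-letter residue codes (one per
#'   aligned sequence).
#' @return entropy in bits, in `[0, log2(20)]` for standard residues.
#' @examples
#' shannonEntropy(rep("A", 10))          # 0
#' shannonEntropy(c("A", "V"))           # 1 bit
#' @export
shannonEntropy <- function(column) {
  res <- toupper(column)
  res <- res[!(res %in% c("-", ".", ""))]
  if (length(res) == 0L) stop("all-gap alignment column has no entropy")
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

readMsa <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  if (inherits(msa, "AAStringSet")) {
    if (length(unique(Biostrings::width(msa))) != 1L)
      stop("alignment rows have unequal widths; not a valid MSA")
    mat <- do.call(rbind, strsplit(as.character(msa), ""))
    rownames(mat) <- names(msa)
    return(mat)
  }
  if (is.matrix(msa)) return(msa)
  stop("msa must be a FASTA path, AAStringSet or character matrix")
}

#' Conserved model positions from a multiple sequence alignment
#'
#' Locates the alignment row whose ungapped sequence equals the model
#' sequence, maps alignment columns to model positions through it, computes
#' per-column Shannon entropy and returns the positions whose entropy is at
#' or below the threshold. Columns with more than `max_gap_frac` gaps are
#' never reported as conserved.
#'
#' @param msa aligned FASTA path, `AAStringSet`, or character matrix
#'   (rows = sequences).
#' @param model a [StructureModel-class]; one row's ungapped sequence must
#'   equal `modelSequence(model)`.
#' @param threshold conservation cutoff in bits (default 0.5); a column is
#'   conserved when its entropy `<=` threshold.
#' @param ref_id optional row name of the model sequence; by default the
#'   first row whose ungapped sequence matches the model is used.
#' @param max_gap_frac columns with a higher gap fraction are excluded
#'   (default 0.5).
#' @return a [FeatureSet-class] named `"conserved_shannon"`
#' @export
conservedPositions <- function(msa, model, threshold = 0.5, ref_id = NULL,
                               max_gap_frac = 0.5) {
  mat <- readMsa(msa)
  ungap <- function(v) paste(v[!(v %in% c("-", "."))], collapse = "")
  target <- modelSequence(model)
  if (is.null(ref_id)) {
    hits <- which(apply(mat, 1, ungap) == target)
    if (length(hits) == 0L)
      stop("no alignment row matches the model sequence")
    ref <- hits[1]
  } else {
    if (!(ref_id %in% rownames(mat))) stop("ref_id not found in alignment")
    ref <- which(rownames(mat) == ref_id)[1]
    if (ungap(mat[ref, ]) != target)
      stop("alignment row '", ref_id, "' does not match the model sequence")
  }
  refrow <- mat[ref, ]
  is_res <- !(refrow %in% c("-", "."))
  col_to_model <- integer(ncol(mat))
  col_to_model[is_res] <- seq_len(sum(is_res))
  keep <- which(is_res)
  ent <- vapply(keep, function(j) shannonEntropy(mat[, j]), numeric(1))
  gapfrac <- vapply(keep, function(j) mean(mat[, j] %in% c("-", ".")),
                    numeric(1))
  cons <- col_to_model[keep][ent <= threshold & gapfrac <= max_gap_frac]
  featureSet("conserved_shannon", cons, model)
}

#' Per-column conservation profile
#'
#' Entropy and model-position mapping for every alignment column covered by
#' the model row; useful for reporting and plotting.
#'
#' @inheritParams conservedPositions
#' @return data.frame with columns `column`, `model_pos`, `entropy`,
#'   `gap_frac`
#' @export
conservationProfile <- function(msa, model, ref_id = NULL) {
  mat <- readMsa(msa)
  fs <- conservedPositions(msa, model, threshold = log2(20), ref_id = ref_id,
                           max_gap_frac = 1)  # validates the mapping
  ungap <- function(v) paste(v[!(v %in% c("-", "."))], collapse = "")
  ref <- if (is.null(ref_id))
    which(apply(mat, 1, ungap) == modelSequence(model))[1]
  else which(rownames(mat) == ref_id)[1]
  is_res <- !(mat[ref, ] %in% c("-", "."))
  keep <- which(is_res)
  data.frame(
    column = keep,
    model_pos = seq_along(keep),
    entropy = vapply(keep, function(j) shannonEntropy(mat[, j]), numeric(1)),
    gap_frac = vapply(keep, function(j) mean(mat[, j] %in% c("-", ".")),
                      numeric(1)))
}
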