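# Mutation tables: loading, hygiene (unique missense records) and mapping
# from protein sequence coordinates onto model positions.

#' Load a mutation table
#'
#' Reads a TSV with columns `protein_id`, `seq_pos`, `native`, `mutant`,
#' `class` and either a `sequence` column or a `sequences` argument keyed by
#' protein id. Applies the dataset hygiene rules: records whose native
#' residue does not match the sequence are rejected with a warning;
#' synonymous (`native == mutant`) and nonsense (`mutant == "*"`) records are
#' excluded; duplicates under the four-field key (protein id, position,
#' native, mutant) are dropped keeping the first.
#'
#' @param path TSV file path
#' @param sequences optional named character vector (or FASTA path) of
#'   protein sequences keyed by `protein_id`; used when the table has no
#'   `sequence` column.
#' @return data.frame of unique missense mutation records
#' @export
readMutationTable <- function(path, sequences = NULL) {
  df <- readTsv(path)
  need <- c("protein_id", "seq_pos", "native", "mutant", "class")
  if (!all(need %in% names(df)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  if (!("sequence" %in% names(df))) {
    if (is.null(sequences))
      stop("mutation table has no 'sequence' column and no sequences given")
    if (is.character(sequences) && length(sequences) == 1L &&
        file.exists(sequences)) {
      ss <- Biostrings::readAAStringSet(sequences)
      sequences <- setNames(as.character(ss), names(ss))
    }
    df$sequence <- unname(sequences[df$protein_id])
    if (anyNA(df$sequence))
      stop("no sequence for protein id(s): ",
           paste(unique(df$protein_id[is.na(df$sequence)]), collapse = ", "))
  }
  df$native <- toupper(df$native)
  df$mutant <- toupper(df$mutant)
  validateMutationRecords(df)
}

validateMutationRecords <- function(df) {
  bad_class <- !(df$class %in% c("PD", "SNP"))
  if (any(bad_class))
    stop("class labels must be PD or SNP; found: ",
         paste(unique(df$class[bad_class]), collapse = ", "))
  at <- substr(df$sequence, df$seq_pos, df$seq_pos)
  mism <- at != df$native | df$seq_pos < 1 | df$seq_pos > nchar(df$sequence)
  if (any(mism)) {
    warning(sum(mism), " record(s) rejected: native residue does not match ",
            "the sequence at seq_pos")
    df <- df[!mism, , drop = FALSE]
  }
  not_missense <- df$native == df$mutant | df$mutant == "*" |
    !(df$mutant %in% AA1) | !(df$native %in% AA1)
  if (any(not_missense)) {
    message("excluding ", sum(not_missense),
            " non-missense record(s) (synonymous, nonsense or non-standard)")
    df <- df[!not_missense, , drop = FALSE]
  }
  key <- paste(df$protein_id, df$seq_pos, df$native, df$mutant)
  if (anyDuplicated(key)) {
    message("dropping ", sum(duplicated(key)), " duplicate record(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid mutation records left after filtering")
  rownames(df) <- NULL
  df
}

blosum62Matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# align one protein sequence to the model sequence; returns identity over
# aligned (non-gap) columns and the seq_pos -> model_pos map
alignToModel <- function(seq, model_seq, gap_open = 10, gap_extend = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(model_seq),
    type = "global", substitutionMatrix = blosum62Matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- p != "-" & s != "-"
  identity <- if (any(both)) mean(p[both] == s[both]) else 0
  map <- integer(nchar(seq))
  ip <- 0L; is <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") ip <- ip + 1L
    if (s[k] != "-") is <- is + 1L
    if (p[k] != "-") map[ip] <- if (s[k] != "-") is else NA_integer_
  }
  list(identity = identity, map = map)
}

#' Map mutation records onto model positions
#'
#' Globally aligns each distinct protein sequence against the model sequence
#' (BLOSUM62, affine gaps) and transfers each record's sequence position to
#' the model. A record is mapped only when the alignment's percent identity
#' over aligned columns reaches `min_identity` and its position aligns to a
#' non-gap model column; otherwise it is flagged with the reason.
#'
#' @param records mutation data.frame from [readMutationTable()]
#' @param model a [StructureModel-class]
#' @param min_identity minimum fractional identity (default 0.95)
#' @param gap_open,gap_extend affine gap penalties of the alignment
#' @return `records` with added columns `model_pos` (NA when unmapped),
#'   `identity` and `map_status` (`"mapped"`,
#'   `"below identity threshold"` or `"position not aligned"`).
#' @export
mapMutationsToModel <- function(records, model, min_identity = 0.95,
                                gap_open = 10, gap_extend = 0.5) {
  model_seq <- modelSequence(model)
  seqs <- unique(records$sequence)
  alns <- lapply(seqs, alignToModel, model_seq = model_seq,
                 gap_open = gap_open, gap_extend = gap_extend)
  names(alns) <- seqs
  records$model_pos <- NA_integer_
  records$identity <- NA_real_
  records$map_status <- NA_character_
  for (i in seq_len(nrow(records))) {
    a <- alns[[records$sequence[i]]]
    records$identity[i] <- a$identity
    if (a$identity < min_identity) {
      records$map_status[i] <- "below identity threshold"
    } else {
      mp <- a$map[records$seq_pos[i]]
      if (is.na(mp)) {
        records$map_status[i] <- "position not aligned"
      } else {
        records$model_pos[i] <- mp
        records$map_status[i] <- "mapped"
      }
    }
  }
  n_map <- sum(records$map_status == "mapped")
  message("mapped ", n_map, " of ", nrow(records), " mutation records ",
          "onto the model")
  records
}
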