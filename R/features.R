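# FeatureSet construction and TSV feature lists.

#' Create a feature set
#'
#' @param name label for the set (e.g. `"catalytic_firedb"`,
#'   `"tree_determinants"`).
#' @param positions 1-based model positions; duplicates are removed.
#' @param model optional [StructureModel-class]; when given, positions are
#'   validated against 1..N.
#' @return a [FeatureSet-class]
#' @export
featureSet <- function(name, positions, model = NULL) {
  p <- sort(unique(as.integer(positions)))
  if (!is.null(model)) {
    n <- nResidues(model)
    bad <- p[p < 1L | p > n]
    if (length(bad))
      stop("feature '", name, "' has out-of-range position(s): ",
           paste(bad, collapse = ", "), " (model has ", n, " residues)")
  }
  new("FeatureSet", name = name, positions = p)
}

#' Load feature sets from a TSV file
#'
#' The file must have a header with columns `feature` and `position`
#' (1-based model positions). Positions are validated against the model and
#' deduplicated per set.
#'
#' @param path TSV file path
#' @param model a [StructureModel-class] used for validation
#' @param required names that must be present and non-empty; an informative
#'   error is raised otherwise.
#' @return named list of [FeatureSet-class] objects
#' @export
readFeatureLists <- function(path, model, required = character()) {
  df <- readTsv(path)
  if (!all(c("feature", "position") %in% names(df)))
    stop("feature file needs columns 'feature' and 'position': ", path)
  sets <- lapply(split(df$position, df$feature), function(p)
    p[!is.na(p)])
  out <- Map(function(nm, p) featureSet(nm, p, model), names(sets), sets)
  missing <- setdiff(required, names(out))
  empty <- names(out)[vapply(out, function(f) length(positions(f)) == 0L,
                             logical(1))]
  bad <- union(missing, intersect(required, empty))
  if (length(bad))
    stop("required feature set(s) missing or empty in ", path, ": ",
         paste(bad, collapse = ", "))
  out
}

#' Write feature sets to a TSV file
#' @param sets list of [FeatureSet-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeFeatureLists <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(f)
    data.frame(feature = featureName(f), position = positions(f))))
  writeTsv(df, path)
}
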