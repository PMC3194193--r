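#' Number of polymer residues in a model
#' @param x a [StructureModel-class]
#' @return integer N
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' One-letter sequence of a model
#' @param x a [StructureModel-class]
#' @return a single character string of length N
#' @export
setGeneric("modelSequence", function(x) standardGeneric("modelSequence"))

#' Positions held by a feature set
#' @param x a [FeatureSet-class]
#' @return integer vector of model positions
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Label of a feature set
#' @param x a [FeatureSet-class]
#' @return character label
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "StructureModel",
          function(x) length(unique(x@atoms$pos)))

#' @rdname modelSequence
#' @export
setMethod("modelSequence", "StructureModel", function(x) x@sequence)

#' @rdname positions
#' @export
setMethod("positions", "FeatureSet", function(x) x@positions)

#' @rdname featureName
#' @export
setMethod("featureName", "FeatureSet", function(x) x@name)

setMethod("show", "StructureModel", function(object) {
  nhet <- if (nrow(object@het)) length(unique(object@het$group)) else 0L
  cat(sprintf("StructureModel: %d residues, %d heavy atoms, %d het group(s)\n",
              nResidues(object), nrow(object@atoms), nhet))
  s <- object@sequence
  cat("  sequence: ", if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s,
      "\n", sep = "")
})

setMethod("show", "FeatureSet", function(object) {
  p <- object@positions
  cat(sprintf("FeatureSet '%s': %d position(s)\n", object@name, length(p)))
  if (length(p))
    cat("  ", paste(head(p, 12), collapse = " "),
        if (length(p) > 12) "..." else "", "\n", sep = "")
})

setMethod("show", "AccessibilityResult", function(object) {
  r <- object@residues
  cat(sprintf(
    "AccessibilityResult: %d residues, total area %.1f A^2, %d buried (<= %.2f)\n",
    nrow(r), sum(r$area), sum(r$buried), object@params$burial_threshold))
})

setMethod("show", "DistanceDistribution", function(object) {
  cat(sprintf("DistanceDistribution: %d bins, upper limits %.1f..%.1f A\n",
              length(object@upper), object@upper[1],
              object@upper[length(object@upper)]))
})

#' Extract the per-residue accessibility table
#' @param x an [AccessibilityResult-class]
#' @return data.frame with columns pos, aa, area, rel_acc, buried
#' @export
setGeneric("residueAccessibility", function(x) standardGeneric("residueAccessibility"))

#' @rdname residueAccessibility
#' @export
setMethod("residueAccessibility", "AccessibilityResult", function(x) x@residues)
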