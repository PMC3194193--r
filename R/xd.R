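# Distance distributions of mutation sets to feature sets and the Xd
# harmonic-deviation statistic with its class comparison.

#' Minimum distances from positions to a feature set
#'
#' For every query position, the minimum inter-residue distance (heavy-atom
#' minimum by default) to any residue of the feature set. Positions inside
#' the feature get distance 0.
#'
#' @param pos integer vector of query model positions
#' @param feature a [FeatureSet-class] (non-empty)
#' @param model a [StructureModel-class]
#' @param method `"heavy"` or `"ca"`, see [minResidueDistance()]
#' @return numeric vector of distances (A), one per query position
#' @export
distancesToFeature <- function(pos, feature, model,
                               method = c("heavy", "ca")) {
  method <- match.arg(method)
  fpos <- positions(feature)
  if (length(fpos) == 0L)
    stop("feature set '", featureName(feature), "' is empty")
  a <- model@atoms
  if (method == "ca") a <- a[a$atom == "CA", , drop = FALSE]
  fa <- a[a$pos %in% fpos, , drop = FALSE]
  out <- numeric(length(pos))
  inside <- pos %in% fpos
  todo <- which(!inside)
  if (length(todo)) {
    qa <- a[a$pos %in% pos[todo], , drop = FALSE]
    D <- crossDist(coordMatrix(qa), coordMatrix(fa))
    dmin <- vapply(split(seq_len(nrow(qa)), qa$pos),
                   function(k) min(D[k, ]), numeric(1))
    out[todo] <- dmin[as.character(pos[todo])]
  }
  out
}

#' Bin distances into a percentage distribution
#'
#' Percentages on bins (0, w], (w, 2w], ... up to `max_dist`; the first bin
#' is closed at zero so exact zeros are counted, and distances beyond
#' `max_dist` accumulate in the last bin.
#'
#' @param distances non-negative distances (A)
#' @param bin_width bin width (A), default 4
#' @param max_dist upper limit of the last regular bin (A), default 60
#' @return numeric vector of percentages, named by bin upper limit
#' @export
binDistances <- function(distances, bin_width = 4, max_dist = 60) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(distances < 0)) stop("distances must be non-negative")
  upper <- seq(bin_width, max_dist, by = bin_width)
  if (max(upper) < max_dist) upper <- c(upper, max_dist)
  idx <- findInterval(distances, c(0, upper), left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[distances == 0] <- 1L          # first bin is [0, w]
  idx[idx > length(upper)] <- length(upper)
  pct <- 100 * tabulate(idx, nbins = length(upper)) / length(distances)
  names(pct) <- upper
  pct
}

#' Observed-vs-background distance distribution
#'
#' The distribution spans the bins the data actually occupy: trailing bins
#' in which both the observed and the background percentages are zero are
#' dropped, so the bin count (the n of [xdStatistic()]) reflects the
#' distance range of the data rather than the `max_dist` padding.
#'
#' @param observed distances of the residue set of interest (A)
#' @param background distances of all model residues (A)
#' @param bin_width,max_dist binning, see [binDistances()]
#' @return a [DistanceDistribution-class]
#' @export
distanceDistribution <- function(observed, background, bin_width = 4,
                                 max_dist = 60) {
  po <- binDistances(observed, bin_width, max_dist)
  pa <- binDistances(background, bin_width, max_dist)
  last <- max(c(1L, which(po > 0 | pa > 0)))
  keep <- seq_len(last)
  new("DistanceDistribution", upper = as.numeric(names(po))[keep],
      observed = unname(po)[keep], background = unname(pa)[keep])
}

#' The Xd harmonic-deviation statistic
#'
#' Xd = (1/n) * sum_i (P_ic - P_ia) / d_i over the n distance bins, where
#' P_ic and P_ia are the observed and background percentages in bin i and
#' d_i is the bin's upper limit in Angstrom; n is the number of bins the
#' distribution spans (see [distanceDistribution()]). Positive values
#' indicate that the observed set sits at smaller distances than the
#' background. Set `normalize = FALSE` to omit the 1/n factor.
#'
#' @param dist a [DistanceDistribution-class]
#' @param normalize divide by the number of bins (default TRUE)
#' @return the Xd value
#' @examples
#' d <- new("DistanceDistribution", upper = c(4, 8),
#'          observed = c(100, 0), background = c(50, 50))
#' xdStatistic(d)  # (1/2) * (50/4 - 50/8) = 3.125
#' @export
xdStatistic <- function(dist, normalize = TRUE) {
  x <- sum((dist@observed - dist@background) / dist@upper)
  if (normalize) x / length(dist@upper) else x
}

#' Compare two mutation classes by proximity to a feature set
#'
#' Computes, for each class, the minimum distances of its positions to the
#' feature set, the mean distance, and the Xd statistic against the
#' all-residue background; reports the difference
#' `delta_xd = Xd(class A) - Xd(class B)` (positive when class A is the one
#' shifted toward the feature) and flags significance when
#' `|delta_xd| >= threshold` (0.75 by default). With
#' `paper_sign = TRUE` the difference is reported with the opposite
#' orientation, `Xd(class B) - Xd(class A)`, matching reports where the
#' proximal first class carries a negative sign.
#'
#' @param class_a,class_b integer vectors of model positions (by default
#'   duplicated positions are collapsed; set `unique_positions = FALSE` to
#'   weight positions by their number of mutations)
#' @param feature a [FeatureSet-class]
#' @param model a [StructureModel-class]
#' @param bin_width,max_dist binning, see [binDistances()]
#' @param threshold significance convention on |delta Xd| (default 0.75)
#' @param unique_positions collapse repeated positions (default TRUE)
#' @param paper_sign report `Xd(B) - Xd(A)` instead (default FALSE)
#' @param method distance convention, see [minResidueDistance()]
#' @return one-row data.frame: feature, n_a, n_b, mean_dist_a, mean_dist_b,
#'   xd_a, xd_b, delta_xd, significant
#' @export
compareClasses <- function(class_a, class_b, feature, model, bin_width = 4,
                           max_dist = 60, threshold = 0.75,
                           unique_positions = TRUE, paper_sign = FALSE,
                           method = "heavy") {
  if (length(class_a) == 0L || length(class_b) == 0L)
    stop("both classes must be non-empty")
  if (unique_positions) {
    class_a <- unique(class_a)
    class_b <- unique(class_b)
  }
  bg_pos <- seq_len(nResidues(model))
  d_bg <- distancesToFeature(bg_pos, feature, model, method)
  d_a <- d_bg[class_a]
  d_b <- d_bg[class_b]
  xa <- xdStatistic(distanceDistribution(d_a, d_bg, bin_width, max_dist))
  xb <- xdStatistic(distanceDistribution(d_b, d_bg, bin_width, max_dist))
  delta <- if (paper_sign) xb - xa else xa - xb
  data.frame(feature = featureName(feature),
             n_a = length(class_a), n_b = length(class_b),
             mean_dist_a = mean(d_a), mean_dist_b = mean(d_b),
             xd_a = xa, xd_b = xb, delta_xd = delta,
             significant = abs(delta) >= threshold)
}

#' Per-class distance histograms for a feature set
#'
#' The binned percentage distributions underlying the Xd comparison, shaped
#' for plotting: one row per bin with the class A, class B and background
#' percentages.
#'
#' @inheritParams compareClasses
#' @return data.frame with columns feature, bin_upper, pct_a, pct_b,
#'   pct_background
#' @export
classHistograms <- function(class_a, class_b, feature, model, bin_width = 4,
                            max_dist = 60, unique_positions = TRUE,
                            method = "heavy") {
  if (unique_positions) {
    class_a <- unique(class_a)
    class_b <- unique(class_b)
  }
  bg_pos <- seq_len(nResidues(model))
  d_bg <- distancesToFeature(bg_pos, feature, model, method)
  pa <- binDistances(d_bg[class_a], bin_width, max_dist)
  pb <- binDistances(d_bg[class_b], bin_width, max_dist)
  pg <- binDistances(d_bg, bin_width, max_dist)
  data.frame(feature = featureName(feature),
             bin_upper = as.numeric(names(pg)),
             pct_a = unname(pa), pct_b = unname(pb),
             pct_background = unname(pg))
}
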