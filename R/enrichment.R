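# Two-sided Fisher exact enrichment of amino-acid compositions and effect
# flags, contrasting the two mutation classes.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability two-sided convention: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. A table
#' with a zero row or zero column carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = classes,
#'   columns = has/lacks property)
#' @return two-sided p-value in (0, 1]
#' @export
fisherTwoSided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
    stop("need a 2x2 table of non-negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("degenerate table (zero margin): p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Per-property contingency tables of mutation composition
#'
#' Builds one 2x2 class-by-property table per amino acid (native or mutant
#' mode) or per observed native-to-mutant ordered pair. Row sums equal the
#' class sizes.
#'
#' @param records mutation data.frame with columns `native`, `mutant`,
#'   `class` (both PD and SNP present)
#' @param mode `"native"`, `"mutant"` or `"pair"`
#' @return named list of 2x2 matrices; names like `"native:G"` or
#'   `"pair:L>P"`
#' @export
compositionTables <- function(records, mode = c("native", "mutant", "pair")) {
  mode <- match.arg(mode)
  counts <- table(records$class)
  if (length(counts) < 2L || any(counts == 0L))
    stop("both mutation classes must be present")
  prop <- switch(mode,
                 native = records$native,
                 mutant = records$mutant,
                 pair = paste0(records$native, ">", records$mutant))
  values <- if (mode == "pair") sort(unique(prop)) else AA1
  is_pd <- records$class == "PD"
  out <- lapply(values, function(v) {
    m <- rbind(PD = c(sum(is_pd & prop == v), sum(is_pd & prop != v)),
               SNP = c(sum(!is_pd & prop == v), sum(!is_pd & prop != v)))
    colnames(m) <- c("has", "lacks")
    m
  })
  names(out) <- paste0(mode, ":", values)
  out
}

reportFromTables <- function(tables, alpha, adjust) {
  p <- vapply(tables, function(m) suppressMessages(fisherTwoSided(m)),
              numeric(1))
  dir <- vapply(tables, function(m) {
    f1 <- m[1, 1] / sum(m[1, ]); f2 <- m[2, 1] / sum(m[2, ])
    if (f1 > f2) rownames(m)[1] else if (f2 > f1) rownames(m)[2] else "none"
  }, character(1))
  df <- data.frame(property = names(tables),
                   a = vapply(tables, function(m) m[1, 1], numeric(1)),
                   b = vapply(tables, function(m) m[1, 2], numeric(1)),
                   c = vapply(tables, function(m) m[2, 1], numeric(1)),
                   d = vapply(tables, function(m) m[2, 2], numeric(1)),
                   p_two_sided = unname(p), direction = unname(dir))
  if (adjust) df$p_adjusted <- stats::p.adjust(df$p_two_sided, "BH")
  crit <- if (adjust) df$p_adjusted else df$p_two_sided
  df$flagged <- crit < alpha
  df <- df[order(df$p_two_sided, df$property), ]
  rownames(df) <- NULL
  df
}

#' Scan mutation compositions for class enrichment
#'
#' Runs the two-sided Fisher exact test for every property in the requested
#' modes (native residue, mutant residue, native-to-mutant pair) and returns
#' all reports sorted by p-value, flagged at `alpha`. Raw p-values are
#' reported by default; set `adjust = TRUE` for Benjamini-Hochberg control.
#'
#' @param records mutation data.frame with `native`, `mutant`, `class`
#' @param modes subset of `c("native", "mutant", "pair")`
#' @param alpha significance level for flagging (default 0.05)
#' @param adjust apply Benjamini-Hochberg correction before flagging
#' @return data.frame: property, counts a-d, p_two_sided, direction, flagged
#' @export
enrichmentScan <- function(records, modes = c("native", "mutant", "pair"),
                           alpha = 0.05, adjust = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  tables <- do.call(c, lapply(modes, function(m)
    compositionTables(records, m)))
  reportFromTables(tables, alpha, adjust)
}

#' Fisher enrichment of structural-effect flags
#'
#' Applies the two-sided Fisher exact test to the class-by-flag tables of
#' [effectMatrix()].
#'
#' @param effects classified records from [classifyEffects()]
#' @param alpha significance level for flagging
#' @param adjust apply Benjamini-Hochberg correction before flagging
#' @return data.frame as in [enrichmentScan()], one row per effect category
#' @export
effectEnrichment <- function(effects, alpha = 0.05, adjust = FALSE) {
  tables <- effectMatrix(effects)
  names(tables) <- paste0("effect:", names(tables))
  reportFromTables(tables, alpha, adjust)
}
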