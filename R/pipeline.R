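# End-to-end driver: parse -> accessibility/burial -> features and mapping
# -> structural effects -> Xd proximity -> Fisher enrichment, with all
# conventions recorded in a JSON manifest so a run is reproducible from the
# manifest alone.

#' Run configuration with documented defaults
#'
#' Builds the full configuration for [runAnalysis()]. Either give input file
#' paths (`model`, `mutations`, and optionally `features` and `msa`) or a
#' `synthetic` spec from [syntheticSpec()]. Every threshold is serialized
#' into the run manifest even when defaulted.
#'
#' @param model path to the reference PDB structure
#' @param mutations path to the mutation TSV
#' @param features path to a feature-list TSV (optional)
#' @param msa path to an aligned FASTA for conservation (optional)
#' @param synthetic a [syntheticSpec()] replacing all file inputs
#' @param out_dir report directory
#' @param seed integer seed recorded in the manifest (drives the synthetic
#'   generator)
#' @param burial_threshold relative accessibility cutoff (default 0.16)
#' @param delta_xd_threshold |delta Xd| significance convention (default 0.75)
#' @param alpha Fisher flagging level (default 0.05)
#' @param bin_width,max_dist Xd binning (default 4 A, 60 A)
#' @param min_identity mapping identity cutoff (default 0.95)
#' @param conservation_threshold Shannon-entropy cutoff in bits (default 0.5)
#' @param n_points SASA quadrature points (default 960)
#' @param required_features feature-set names that must be present and
#'   non-empty in the feature file; validation fails naming the file
#' @param paper_sign report delta Xd as Xd(SNP) - Xd(PD) (default FALSE)
#' @param unique_positions collapse repeated positions in Xd (default TRUE)
#' @param distance_method `"heavy"` or `"ca"`
#' @param effect_thresholds list from [effectThresholds()]
#' @return config list for [runAnalysis()]
#' @export
runConfig <- function(model = NULL, mutations = NULL, features = NULL,
                      msa = NULL, synthetic = NULL, out_dir = "kinsaap_run",
                      seed = 1L, burial_threshold = 0.16,
                      delta_xd_threshold = 0.75, alpha = 0.05, bin_width = 4,
                      max_dist = 60, min_identity = 0.95,
                      conservation_threshold = 0.5, n_points = 960L,
                      required_features = character(),
                      paper_sign = FALSE, unique_positions = TRUE,
                      distance_method = "heavy",
                      effect_thresholds = effectThresholds()) {
  if (is.null(synthetic) && (is.null(model) || is.null(mutations)))
    stop("give either a synthetic spec or model + mutations paths")
  list(model = model, mutations = mutations, features = features, msa = msa,
       synthetic = synthetic, out_dir = out_dir, seed = as.integer(seed),
       burial_threshold = burial_threshold,
       delta_xd_threshold = delta_xd_threshold, alpha = alpha,
       bin_width = bin_width, max_dist = max_dist,
       min_identity = min_identity,
       conservation_threshold = conservation_threshold,
       n_points = as.integer(n_points),
       required_features = required_features, paper_sign = paper_sign,
       unique_positions = unique_positions,
       distance_method = distance_method,
       effect_thresholds = effect_thresholds)
}

#' Run the full comparative analysis
#'
#' Executes all stages in order and writes the report files into
#' `config$out_dir`: `accessibility.tsv` (per-residue SASA and burial),
#' `mapping.tsv` (records with model positions and mapping status),
#' `effects.tsv` (per-mutation effect vectors), `xd_table.tsv` (one row per
#' feature set: mean distances per class, delta Xd, significance),
#' `histograms.tsv` (binned distance distributions per feature set),
#' `enrichment_sequence.tsv` and `enrichment_effects.tsv` (Fisher reports)
#' and `manifest.json`. Output is deterministic for a fixed config and seed.
#'
#' @param config list from [runConfig()], or a path to a YAML/JSON file of
#'   the same keys
#' @return invisibly, a list with all report tables and the manifest
#' @export
runAnalysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readConfigFile(config)
  cfg <- applyConfigDefaults(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    spec <- cfg$synthetic
    spec$seed <- cfg$seed
    spec <- do.call(syntheticSpec, spec)
    cfg$synthetic <- spec        # manifest records the fully expanded spec
    bundle <- generateBundle(spec, file.path(out_dir, "bundle"))
    model <- bundle$model
    mutations <- bundle$mutations
    feature_sets <- list(catalytic = bundle$feature)
    msa <- bundle$msa
  } else {
    model <- readStructure(cfg$model)
    mutations <- readMutationTable(cfg$mutations)
    feature_sets <- if (!is.null(cfg$features))
      readFeatureLists(cfg$features, model,
                       required = cfg$required_features) else list()
    msa <- cfg$msa
  }

  # --- accessibility ------------------------------------------------------
  acc <- computeSasa(model, sasaParams(n_points = cfg$n_points,
                                       burial_threshold = cfg$burial_threshold))
  buried <- classifyBuried(acc)
  feature_sets$buried <- buried

  # --- conservation -------------------------------------------------------
  if (!is.null(msa)) {
    conserved <- conservedPositions(msa, model,
                                    threshold = cfg$conservation_threshold)
    feature_sets$conserved_shannon <- conserved
  }

  # --- mapping ------------------------------------------------------------
  mapped <- suppressMessages(
    mapMutationsToModel(mutations, model, min_identity = cfg$min_identity))
  n_mapped <- sum(mapped$map_status == "mapped")
  message(sprintf("records: %d read, %d mapped, %d unmapped",
                  nrow(mapped), n_mapped, nrow(mapped) - n_mapped))

  # --- structural effects -------------------------------------------------
  eff_features <- list(conserved = feature_sets$conserved_shannon,
                       annotated = feature_sets$annotated,
                       binding_extra = feature_sets$binding)
  effects <- suppressMessages(
    classifyEffects(mapped, model, acc, features = eff_features,
                    thresholds = cfg$effect_thresholds))

  # --- Xd proximity -------------------------------------------------------
  pd_pos <- mapped$model_pos[mapped$class == "PD" &
                               mapped$map_status == "mapped"]
  snp_pos <- mapped$model_pos[mapped$class == "SNP" &
                                mapped$map_status == "mapped"]
  xd_features <- feature_sets[vapply(feature_sets,
                                     function(f) length(positions(f)) > 0L,
                                     logical(1))]
  xd_rows <- lapply(xd_features, function(f)
    compareClasses(pd_pos, snp_pos, f, model, bin_width = cfg$bin_width,
                   max_dist = cfg$max_dist,
                   threshold = cfg$delta_xd_threshold,
                   unique_positions = cfg$unique_positions,
                   paper_sign = cfg$paper_sign,
                   method = cfg$distance_method))
  xd_table <- do.call(rbind, xd_rows)
  rownames(xd_table) <- NULL
  hist_rows <- lapply(xd_features, function(f)
    classHistograms(pd_pos, snp_pos, f, model, bin_width = cfg$bin_width,
                    max_dist = cfg$max_dist,
                    unique_positions = cfg$unique_positions,
                    method = cfg$distance_method))
  histograms <- do.call(rbind, hist_rows)
  rownames(histograms) <- NULL

  # --- enrichment ---------------------------------------------------------
  enr_seq <- enrichmentScan(mutations, alpha = cfg$alpha)
  enr_eff <- effectEnrichment(effects, alpha = cfg$alpha)

  # --- reports ------------------------------------------------------------
  writeAccessibility(acc, file.path(out_dir, "accessibility.tsv"))
  writeTsv(mapped, file.path(out_dir, "mapping.tsv"))
  writeTsv(effects, file.path(out_dir, "effects.tsv"))
  writeTsv(xd_table, file.path(out_dir, "xd_table.tsv"))
  writeTsv(histograms, file.path(out_dir, "histograms.tsv"))
  writeTsv(enr_seq, file.path(out_dir, "enrichment_sequence.tsv"))
  writeTsv(enr_eff, file.path(out_dir, "enrichment_effects.tsv"))
  manifest <- list(package = "kinsaap",
                   version = as.character(utils::packageVersion("kinsaap")),
                   config = cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(model = model, accessibility = acc, mapped = mapped,
                 effects = effects, xd_table = xd_table,
                 histograms = histograms, enrichment_sequence = enr_seq,
                 enrichment_effects = enr_eff, manifest = manifest))
}

# fill unspecified keys with the documented runConfig() defaults
applyConfigDefaults <- function(config) {
  f <- formals(runConfig)
  defaults <- lapply(f, function(x) if (is.language(x)) eval(x) else x)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$synthetic) && (is.null(cfg$model) || is.null(cfg$mutations)))
    stop("config needs either a synthetic spec or model + mutations paths")
  cfg
}

readConfigFile <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Re-run an analysis from its manifest
#'
#' Reads the manifest written by [runAnalysis()] and repeats the run with
#' the identical configuration into a new directory.
#'
#' @param manifest_path path to a `manifest.json`
#' @param out_dir new report directory
#' @return invisibly, the [runAnalysis()] result
#' @export
runFromManifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$out_dir <- out_dir
  if (!is.null(cfg$synthetic))
    cfg$synthetic <- cfg$synthetic[!vapply(cfg$synthetic, is.null, logical(1))]
  runAnalysis(cfg)
}
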