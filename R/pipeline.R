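#' Run the full profiling pipeline
#'
#' Executes every analysis stage in order -- feature curation, vehicle
#' normalization, correlation-distance matrix, uniformity scores, disruption
#' scores, dependency adjustment, localization summary, growth summary -- and
#' writes the eight stage artifacts plus a manifest (config hash, seed,
#' package version, per-artifact checksums) to `out_dir`. Inputs are either
#' CSV paths or, when `inputs` is NULL, tables freshly generated by the
#' synthetic-data module from `config`. A fixed config/seed gives
#' byte-identical artifacts and manifest.
#'
#' Stage failures abort with the stage name; missing input paths are
#' reported before any stage runs.
#'
#' @param config A [synthetic_config()] (also the source of curation /
#'   normalization settings).
#' @param out_dir Output directory (created if needed).
#' @param inputs Optional named list of CSV paths: `feature_matrix`,
#'   `cell_table`, `growth_tracks`.
#' @param variance_threshold,correlation_threshold Curation settings.
#' @return Invisibly, the manifest as a named character vector.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         inputs = NULL, variance_threshold = 1e-8,
                         correlation_threshold = 0.9) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(inputs)) {
    missing <- Filter(function(p) !file.exists(p), unlist(inputs))
    if (length(missing) > 0) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(inputs)) {
    profiles <- stage("simulate", generate_feature_matrix(config)$profiles)
    cells <- stage("simulate", generate_cell_table(config)$cells)
    tracks <- stage("simulate", generate_growth_tracks(config, "confluency")$tracks)
    input_desc <- paste0("synthetic(seed=", config$seed, ")")
  } else {
    profiles <- stage("load", read_feature_matrix(inputs$feature_matrix))
    cells <- stage("load", read_cell_table(inputs$cell_table))
    tracks <- stage("load", read_growth_tracks(inputs$growth_tracks))
    input_desc <- paste(unlist(inputs), collapse = ", ")
  }

  cur <- stage("curate", curate_features(profiles, variance_threshold,
                                         correlation_threshold))
  norm <- stage("normalize", normalize_to_control(
    cur$profiles, control_genotype = unname(config$genotypes[["WT"]])))
  d <- stage("profile", distance_matrix(norm$profiles))
  unif <- stage("uniformity", uniformity_scores(d, norm$profiles))
  disr <- stage("disrupt", disruption_table(norm$profiles))
  dep <- stage("dependency", dependency_adjust(
    disr, wt = unname(config$genotypes[["WT"]]),
    ko = unname(config$genotypes[["KO"]])))
  loc <- stage("localize", {
    filt <- contact_filter(cells)
    well_summary(filt)
  })
  grow <- stage("growth", growth_table(tracks))

  artifacts <- c(
    curated_matrix = "curated_matrix.csv",
    normalized_matrix = "normalized_matrix.csv",
    distance_matrix = "distance_matrix.csv",
    uniformity = "uniformity.csv",
    disruption = "disruption.csv",
    dependency = "dependency.csv",
    localization_summary = "localization_summary.csv",
    growth_summary = "growth_summary.csv")
  paths <- file.path(out_dir, artifacts)
  names(paths) <- names(artifacts)

  write_feature_matrix(cur$profiles, paths["curated_matrix"])
  write_feature_matrix(norm$profiles, paths["normalized_matrix"])
  utils::write.csv(d, paths["distance_matrix"], row.names = TRUE)
  write_csv_plain(unif, paths["uniformity"])
  write_csv_plain(disr, paths["disruption"])
  write_csv_plain(dep, paths["dependency"])
  write_csv_plain(loc, paths["localization_summary"])
  write_csv_plain(grow, paths["growth_summary"])

  cfg_hash <- config_hash(config)
  manifest <- c(
    package = "morphoscreen",
    version = as.character(utils::packageVersion("morphoscreen")),
    seed = as.character(config$seed),
    config_hash = cfg_hash,
    inputs = input_desc,
    stats::setNames(
      paste0(artifacts, " md5=", unname(tools::md5sum(paths))),
      paste0("artifact.", names(artifacts))))
  writeLines(paste(names(manifest), manifest, sep = " = "),
             file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(unclass(config)))]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}
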