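# End-to-end pipeline orchestration: simulate? -> read -> filter ->
# annotate -> statistics -> associations, with manifest, exclusion log and
# resolved-config provenance.

#' Build a pipeline configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed (passed to the simulator stage).
#' @param simulate `NULL` to read existing inputs, otherwise a list of
#'   [simulation_config()] arguments for the simulate stage.
#' @param repertoire,metadata Input TSV paths (required when `simulate` is
#'   `NULL`).
#' @param count_column Read-count column name in the input table.
#' @param min_d_match Minimum D match length for junction decomposition.
#' @param features Features passed to [enrichment_by_class()].
#' @param compare Optional list of subset contrasts, each a list with
#'   `subset_a`, `subset_b`, `metrics` (character vector).
#' @param allow_unequal_cells Permit diversity comparisons across unequal
#'   sorted cell counts.
#' @return A pipeline config list (class `cdr3delta_pipeline_config`).
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = list(),
                            repertoire = NULL, metadata = NULL,
                            count_column = "duplicate_count",
                            min_d_match = 3L,
                            features = c("j1", "inv_t", "haa5", "germline",
                                         "public"),
                            compare = NULL,
                            allow_unequal_cells = FALSE) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              repertoire = repertoire, metadata = metadata,
              count_column = count_column, min_d_match = min_d_match,
              features = features, compare = compare,
              allow_unequal_cells = allow_unequal_cells)
  if (is.null(simulate) && (is.null(repertoire) || is.null(metadata))) {
    stop("either enable the simulate stage or supply repertoire and metadata paths",
         call. = FALSE)
  }
  structure(cfg, class = "cdr3delta_pipeline_config")
}

#' Run the full repertoire analysis pipeline
#'
#' Stages run in order: simulate (optional), read, singleton filter,
#' annotate, diversity, publicity, enrichment, subset comparisons.  Every
#' output TSV carries a comment header with the package version and the
#' hash of the resolved configuration; a manifest lists every output file
#' with its content hash, and an exclusion log records row-level filtering
#' counts.  Reruns with the same configuration produce identical manifest
#' hashes.
#'
#' @param config A [pipeline_config()] or the path to a YAML file with the
#'   same fields.
#' @return Invisibly, a list with `manifest` (tibble of file, md5) and
#'   `exclusions` (named counts).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg)
  }
  stopifnot(inherits(config, "cdr3delta_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  # the resolved config (and its hash) excludes the output location, so a
  # rerun of the same analysis into a different directory is recognisably
  # identical
  resolved <- unclass(config)
  resolved$outdir <- NULL
  resolved_path <- out("config_resolved.yaml")
  yaml::write_yaml(resolved, resolved_path)
  cfg_hash <- unname(tools::md5sum(resolved_path))
  header <- c(sprintf("cdr3delta %s",
                      as.character(utils::packageVersion("cdr3delta"))),
              sprintf("config_md5 %s", cfg_hash))
  exclusions <- list()

  # --- simulate / read ------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed), config$simulate))
    sim <- simulate_cohort(sim_cfg)
    write_repertoire(sim$samples, out("repertoire.tsv"), out("metadata.tsv"),
                     header = header)
    write_tidy_table(sim$truth$clones, out("truth_clones.tsv"),
                     header = header)
    write_tidy_table(sim$truth$fractions, out("truth_fractions.tsv"),
                     header = header)
    rep_path <- out("repertoire.tsv")
    meta_path <- out("metadata.tsv")
  } else {
    rep_path <- config$repertoire
    meta_path <- config$metadata
  }
  repertoire <- withCallingHandlers(
    read_repertoire(rep_path, meta_path, count_column = config$count_column),
    warning = function(w) invokeRestart("muffleWarning"))
  exclusions$rejected_rows <- nrow(attr(repertoire, "rejected"))
  exclusions$nonproductive <- attr(repertoire, "n_nonproductive")

  # --- filter + annotate ----------------------------------------------
  n_before <- nrow(repertoire)
  filtered <- suppressWarnings(filter_singletons(repertoire))
  exclusions$singletons_removed <- n_before - nrow(filtered)
  annotated <- annotate_repertoire(filtered, min_d_match = config$min_d_match)
  exclusions$short_junctions <- sum(is.na(annotated$aa5) &
                                      annotated$productive)
  exclusions$unknown_j <- sum(is.na(annotated$j_region))

  concordant <- replicate_concordant_nucleotypes(
    annotated[annotated$productive, , drop = FALSE])
  publicity <- publicity_table(concordant)
  annotated <- flag_public(annotated, publicity)
  write_tidy_table(annotated, out("annotated.tsv"), header = header)
  write_tidy_table(publicity, out("publicity.tsv"), header = header)

  # --- statistics ------------------------------------------------------
  write_tidy_table(diversity_metrics(filtered), out("diversity.tsv"),
                   header = header)
  enrich <- dplyr::bind_rows(lapply(config$features, function(f) {
    enrichment_by_class(annotated, feature = f)
  }))
  write_tidy_table(enrich, out("enrichment.tsv"), header = header)
  lengths <- length_distribution_by_class(annotated, restrict_to = "J1")
  write_tidy_table(lengths, out("length_distribution.tsv"), header = header)

  # --- subset contrasts -----------------------------------------------
  comparisons <- config$compare
  if (is.null(comparisons)) {
    subsets <- unique(annotated$subset_label)
    if (length(subsets) >= 2L) {
      comparisons <- list(list(subset_a = subsets[1L], subset_b = subsets[2L],
                               metrics = c("shannon", "richness", "d75",
                                           "mean_cdr3_length",
                                           "mean_n_insertions")))
    }
  }
  if (!is.null(comparisons)) {
    tests <- dplyr::bind_rows(lapply(comparisons, function(cmp) {
      dplyr::bind_rows(lapply(cmp$metrics, function(mt) {
        suppressWarnings(compare_subsets(
          annotated, cmp$subset_a, cmp$subset_b, metric = mt,
          allow_unequal_cells = config$allow_unequal_cells))
      }))
    }))
    write_tidy_table(tests, out("subset_tests.tsv"), header = header)
  }

  # --- provenance -----------------------------------------------------
  jsonlite::write_json(exclusions, out("exclusions.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- setdiff(list.files(config$outdir, full.names = FALSE),
                   "manifest.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files))))
  jsonlite::write_json(manifest, out("manifest.json"), pretty = TRUE)
  invisible(list(manifest = manifest, exclusions = exclusions))
}
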