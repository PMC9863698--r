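# End-to-end orchestration: ingest -> scaffolding -> set mining -> cliffs ->
# representative MMPs -> network export.

#' Pipeline configuration
#'
#' @param input Path to the activity table (CSV/TSV), or `NULL` when
#'   `records` are passed to [run_pipeline()] directly.
#' @param out_dir Output directory for stage outputs and the run report.
#' @param col_map Optional column mapping for [read_activity_table()].
#' @param relations,relationship_type,confidence_score,standard_types Record
#'   filters, see [filter_records()].
#' @param aggregate `"median"` or `"mean"` replicate aggregation.
#' @param ac_threshold,trend_threshold Cliff/trend thresholds, see
#'   [annotate_cliffs()].
#' @param tiers Fold-change tier thresholds for the summary.
#' @param subfamily_map Data frame (`target_id`, `subfamily`) or path to a
#'   TSV with those columns; defaults to the built-in panel.
#' @param style Optional style list (or path to a YAML file) passed to
#'   [export_network()].
#' @param seed Seed for layout and any stochastic step.
#' @return A `fisar_pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out_dir = "fisar-out",
                            col_map = NULL,
                            relations = "=", relationship_type = "D",
                            confidence_score = 9L,
                            standard_types = POTENCY_TYPES,
                            aggregate = "median",
                            ac_threshold = 1.7, trend_threshold = 0.3,
                            tiers = c(1.0, 1.48, 1.7),
                            subfamily_map = NULL, style = NULL, seed = 1L) {
  stopifnot(ac_threshold > 0, trend_threshold > 0)
  structure(as.list(environment()), class = "fisar_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `fisar_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full fluorine-isomer SAR pipeline
#'
#' Executes ingest, structure standardization, scaffold keying, analog-set
#' mining, cliff annotation, representative MMP computation and network
#' export, writing each stage's table under `config$out_dir` together with a
#' machine-readable JSON run report. Outputs are deterministic: two runs on
#' identical inputs produce byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param records Optional raw records tibble; when given, `config$input` is
#'   ignored (useful with [generate_library()]).
#' @return Invisibly, the run report (also written as `run-report.json`): a
#'   list of per-stage record counts and the configuration echo.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "fisar_pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(records)) {
    records <- stage("ingest",
                     read_activity_table(config$input, config$col_map))
  }
  message(sprintf("[ingest] %d raw records", nrow(records)))

  filtered <- stage("filter", filter_records(
    records, relations = config$relations,
    relationship_type = config$relationship_type,
    confidence_score = config$confidence_score,
    standard_types = config$standard_types, quiet = TRUE
  ))
  potencies <- stage("aggregate",
                     aggregate_potency(filtered, method = config$aggregate))
  readr::write_tsv(potencies, file.path(out_dir, "potencies.tsv"),
                   progress = FALSE)
  message(sprintf("[aggregate] %d potencies (%d records kept)",
                  nrow(potencies), nrow(filtered)))

  structures <- dplyr::distinct(filtered, .data$compound_id, .data$smiles)
  mols <- stage("standardize", {
    if (nrow(structures) == 0) {
      tibble::tibble(compound_id = character(0),
                     canonical_smiles = character(0),
                     heavy_atom_count = integer(0),
                     fluorine_count = integer(0))
    } else {
      standardize_molecules(structures)
    }
  })
  keyed <- stage("scaffold_key", {
    if (nrow(mols) == 0) {
      dplyr::mutate(mols, defluor_smiles = character(0))
    } else {
      scaffold_key(mols)
    }
  })
  readr::write_tsv(keyed, file.path(out_dir, "structures.tsv"),
                   progress = FALSE)
  message(sprintf("[scaffold] %d structures, %d fluorinated",
                  nrow(keyed), sum(keyed$fluorine_count > 0)))

  sets <- stage("mine_sets", {
    if (nrow(keyed) == 0) empty_fisar_sets() else
      mine_fisar_sets(keyed, potencies)
  })
  readr::write_tsv(sets, file.path(out_dir, "fisar-sets.tsv"),
                   progress = FALSE)
  histogram <- set_size_histogram(sets)
  message(sprintf("[mine] %d sets over %d targets",
                  dplyr::n_distinct(sets$set_id),
                  dplyr::n_distinct(sets$target_id)))

  annotations <- stage("cliffs", annotate_cliffs(
    sets, ac_threshold = config$ac_threshold,
    trend_threshold = config$trend_threshold
  ))
  readr::write_tsv(annotations, file.path(out_dir, "cliff-annotations.tsv"),
                   progress = FALSE)
  summary <- stage("summarize", summarize_cliffs(annotations,
                                                 tiers = config$tiers))
  jsonlite::write_json(
    list(n_sets = summary$n_sets, n_ac_sets = summary$n_ac_sets,
         n_significant_trend = summary$n_significant_trend,
         n_flat_trend = summary$n_flat_trend,
         fold_tier_counts = summary$fold_tier_counts,
         set_size_histogram = histogram),
    file.path(out_dir, "cliff-summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  message(sprintf("[cliffs] %d of %d sets are AC sets",
                  summary$n_ac_sets, summary$n_sets))

  subfam <- config$subfamily_map
  if (is.character(subfam) && length(subfam) == 1) {
    subfam <- readr::read_tsv(subfam, show_col_types = FALSE,
                              progress = FALSE)
  }
  if (is.null(subfam)) subfam <- gpcr_subfamily_map()
  nodes <- stage("merge_sets",
                 merge_multitarget_sets(sets, annotations, subfam))

  rep_pairs <- stage("mmp", {
    reps <- dplyr::transmute(nodes, compound_id = .data$node_id,
                             canonical_smiles = .data$defluor_smiles)
    if (nrow(reps) >= 2) find_mmps(reps) else
      find_mmps(tibble::tibble(compound_id = character(0),
                               canonical_smiles = character(0)))
  })
  readr::write_tsv(rep_pairs, file.path(out_dir, "representative-mmps.tsv"),
                   progress = FALSE)

  graph <- stage("network", build_mmp_network(nodes, rep_pairs))
  style <- config$style
  if (is.character(style) && length(style) == 1) {
    style <- yaml::read_yaml(style)
  }
  stage("export", export_network(graph, out_dir, "network", style = style))
  message(sprintf("[network] %d nodes, %d edges",
                  igraph::vcount(graph), igraph::ecount(graph)))

  report <- list(
    counts = list(
      raw_records = nrow(records),
      filtered_records = nrow(filtered),
      potencies = nrow(potencies),
      structures = nrow(keyed),
      fluorinated = sum(keyed$fluorine_count > 0),
      n_sets = summary$n_sets,
      n_ac_sets = summary$n_ac_sets,
      n_nodes = igraph::vcount(graph),
      n_edges = igraph::ecount(graph)
    ),
    set_size_histogram = histogram,
    package_version = as.character(utils::packageVersion("fisar")),
    config = config[!vapply(config, is.function, logical(1))]
  )
  jsonlite::write_json(report, file.path(out_dir, "run-report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(report)
}
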