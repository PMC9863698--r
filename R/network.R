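# Multitarget set merging and MMP network construction/export.

SUBFAMILY_ORDER <- c("serotoninergic", "dopaminergic", "adrenergic",
                     "histaminic", "muscarinic", "other")

#' Built-in aminergic GPCR subfamily map
#'
#' A small panel of aminergic class A GPCR identifiers and their subfamilies,
#' used by default for network coloring and by the synthetic library
#' generator.
#'
#' @return A tibble with `target_id` and `subfamily`.
#' @export
gpcr_subfamily_map <- function() {
  tibble::tribble(
    ~target_id, ~subfamily,
    "HTR1A", "serotoninergic", "HTR1B", "serotoninergic",
    "HTR1D", "serotoninergic", "HTR2A", "serotoninergic",
    "HTR2B", "serotoninergic", "HTR2C", "serotoninergic",
    "HTR6",  "serotoninergic", "HTR7",  "serotoninergic",
    "DRD1",  "dopaminergic",   "DRD2",  "dopaminergic",
    "DRD3",  "dopaminergic",   "DRD4",  "dopaminergic",
    "ADRA1A", "adrenergic",    "ADRA2A", "adrenergic",
    "ADRB1", "adrenergic",     "ADRB2", "adrenergic",
    "HRH1",  "histaminic",     "HRH3",  "histaminic",
    "CHRM1", "muscarinic",     "CHRM2", "muscarinic",
    "CHRM3", "muscarinic",     "CHRM4", "muscarinic",
    "CHRM5", "muscarinic"
  )
}

#' Merge target-based analog sets into multitarget network nodes
#'
#' Target-based sets sharing a scaffold key (same defluorinated structure and
#' fluorine count) are merged into one node. A node carries an activity-cliff
#' flag if any member set does, a shape class by target count (single/dual/
#' multi), and the modal receptor subfamily of its targets (ties broken in
#' the fixed order serotoninergic > dopaminergic > adrenergic > histaminic >
#' muscarinic > other).
#'
#' @param sets Long-format set table from [mine_fisar_sets()].
#' @param annotations Output of [annotate_cliffs()] covering `sets`.
#' @param subfamily_map Data frame with `target_id`, `subfamily`; targets not
#'   covered map to `"other"`. Defaults to [gpcr_subfamily_map()].
#' @return A tibble of nodes: `node_id`, `defluor_smiles`, `fluorine_count`,
#'   `member_set_ids` (list), `targets` (list), `n_targets`, `shape_class`,
#'   `has_ac`, `predominant_subfamily`, `n_compounds`.
#' @export
merge_multitarget_sets <- function(sets, annotations,
                                   subfamily_map = gpcr_subfamily_map()) {
  set_ac <- dplyr::distinct(annotations, .data$set_id, .data$is_ac)
  missing <- setdiff(unique(sets$set_id), set_ac$set_id)
  if (length(missing) > 0) {
    stop("annotations do not cover set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(sets) == 0) {
    return(tibble::tibble(
      node_id = character(0), defluor_smiles = character(0),
      fluorine_count = integer(0), member_set_ids = list(),
      targets = list(), n_targets = integer(0), shape_class = character(0),
      has_ac = logical(0), predominant_subfamily = character(0),
      n_compounds = integer(0)
    ))
  }
  subfam_of <- function(targets) {
    sf <- subfamily_map$subfamily[match(targets, subfamily_map$target_id)]
    sf[is.na(sf)] <- "other"
    tab <- table(factor(sf, levels = SUBFAMILY_ORDER))
    names(tab)[which.max(tab)]  # which.max takes the first, i.e. tie order
  }
  sets |>
    dplyr::left_join(set_ac, by = "set_id") |>
    dplyr::summarise(
      member_set_ids = list(sort(unique(.data$set_id))),
      targets = list(sort(unique(.data$target_id))),
      n_targets = dplyr::n_distinct(.data$target_id),
      has_ac = any(.data$is_ac),
      n_compounds = dplyr::n_distinct(.data$compound_id),
      .by = c("defluor_smiles", "fluorine_count")
    ) |>
    dplyr::mutate(
      node_id = paste0("N-", substr(purrr::map_chr(
        paste(.data$defluor_smiles, .data$fluorine_count, sep = "|"),
        rlang::hash), 1, 12)),
      shape_class = dplyr::case_when(
        .data$n_targets == 1 ~ "single",
        .data$n_targets == 2 ~ "dual",
        .default = "multi"
      ),
      predominant_subfamily = purrr::map_chr(.data$targets, subfam_of)
    ) |>
    dplyr::select("node_id", "defluor_smiles", "fluorine_count",
                  "member_set_ids", "targets", "n_targets", "shape_class",
                  "has_ac", "predominant_subfamily", "n_compounds") |>
    dplyr::arrange(.data$node_id) |>
    tibble::as_tibble()
}

#' Build the MMP network over multitarget nodes
#'
#' Each node is represented by its defluorinated parent structure; two nodes
#' are connected when the representatives form at least one matched molecular
#' pair. Multiple pairs between two representatives collapse to one edge,
#' typed `substructure` if any underlying pair exchanges a hydrogen for a
#' moiety, else `transformation`. Isolated nodes are retained.
#'
#' @param nodes Node table from [merge_multitarget_sets()].
#' @param representative_pairs MMPs computed between node representatives,
#'   i.e. [find_mmps()] run on `compound_id = node_id`,
#'   `canonical_smiles = defluor_smiles`.
#' @return An [igraph::igraph] object with the node attributes and an
#'   `edge_type` edge attribute.
#' @export
build_mmp_network <- function(nodes, representative_pairs) {
  unknown <- setdiff(unique(c(representative_pairs$compound_a,
                              representative_pairs$compound_b)),
                     nodes$node_id)
  if (length(unknown) > 0) {
    stop("pairs reference unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- representative_pairs |>
    dplyr::filter(.data$compound_a != .data$compound_b) |>
    dplyr::mutate(
      from = pmin(.data$compound_a, .data$compound_b),
      to = pmax(.data$compound_a, .data$compound_b)
    ) |>
    dplyr::summarise(
      edge_type = ifelse(any(.data$is_substructure_pair),
                         "substructure", "transformation"),
      n_pairs = dplyr::n(),
      .by = c("from", "to")
    ) |>
    dplyr::arrange(.data$from, .data$to)
  vertices <- nodes |>
    dplyr::transmute(
      name = .data$node_id,
      defluor_smiles = .data$defluor_smiles,
      fluorine_count = .data$fluorine_count,
      shape_class = .data$shape_class,
      has_ac = .data$has_ac,
      predominant_subfamily = .data$predominant_subfamily,
      n_targets = .data$n_targets,
      n_sets = purrr::map_int(.data$member_set_ids, length),
      n_compounds = .data$n_compounds,
      member_set_ids = purrr::map_chr(.data$member_set_ids, paste,
                                      collapse = ";"),
      targets = purrr::map_chr(.data$targets, paste, collapse = ";")
    )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export the MMP network for Cytoscape
#'
#' Writes GraphML (primary), a SIF file, and node/edge attribute TSVs.
#' Attributes are semantic values (shape class, subfamily, AC flag, edge
#' type), leaving colors and shapes to a style mapping, which can be supplied
#' as a YAML file and is copied alongside the export.
#'
#' @param graph Network from [build_mmp_network()].
#' @param dir Output directory (created if needed).
#' @param basename File basename (default `"network"`).
#' @param style Optional named list mapping attribute values to visual
#'   properties; written as `<basename>-style.yaml`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(graph, dir, basename = "network", style = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    graphml = file.path(dir, paste0(basename, ".graphml")),
    sif = file.path(dir, paste0(basename, ".sif")),
    nodes = file.path(dir, paste0(basename, "-nodes.tsv")),
    edges = file.path(dir, paste0(basename, "-edges.tsv"))
  )
  igraph::write_graph(graph, paths[["graphml"]], format = "graphml")
  nodes <- tibble::as_tibble(igraph::as_data_frame(graph, what = "vertices"))
  edges <- tibble::as_tibble(igraph::as_data_frame(graph, what = "edges"))
  sif_lines <- if (nrow(edges) > 0) {
    sprintf("%s\t%s\t%s", edges$from, edges$edge_type, edges$to)
  } else {
    character(0)
  }
  isolated <- setdiff(nodes$name, unique(c(edges$from, edges$to)))
  writeLines(c(sif_lines, isolated), paths[["sif"]])
  readr::write_tsv(nodes, paths[["nodes"]], progress = FALSE)
  readr::write_tsv(edges, paths[["edges"]], progress = FALSE)
  if (!is.null(style)) {
    paths[["style"]] <- file.path(dir, paste0(basename, "-style.yaml"))
    yaml::write_yaml(style, paths[["style"]])
  }
  invisible(paths)
}

#' Plot the MMP network
#'
#' A ggplot rendering of the network using a force-directed layout:
#' node shape encodes the target count class, color the predominant receptor
#' subfamily, a black outline marks nodes whose sets contain an activity
#' cliff, and edge color distinguishes substructure from transformation
#' relationships.
#'
#' @param graph Network from [build_mmp_network()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_mmp_network <- function(graph, seed = 42L) {
  lay <- withr::with_seed(seed, igraph::layout_with_fr(graph))
  nodes <- tibble::as_tibble(igraph::as_data_frame(graph, what = "vertices"))
  nodes$x <- lay[, 1]
  nodes$y <- lay[, 2]
  edges <- tibble::as_tibble(igraph::as_data_frame(graph, what = "edges"))
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::left_join(dplyr::select(nodes, "name", xa = "x", ya = "y"),
                       by = c(from = "name")) |>
      dplyr::left_join(dplyr::select(nodes, "name", xb = "x", yb = "y"),
                       by = c(to = "name"))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, color = .data$edge_type),
      linewidth = 0.4
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = .data$predominant_subfamily,
                   shape = .data$shape_class,
                   stroke = ifelse(.data$has_ac, 1.6, 0.3)),
      size = 3, color = "black"
    ) +
    ggplot2::scale_shape_manual(values = c(single = 21, dual = 22,
                                           multi = 23)) +
    ggplot2::labs(color = "edge", fill = "subfamily", shape = "targets") +
    ggplot2::theme_void()
}
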