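table_two_nodes <- function() {
  sets <- worked_example_tables()$table_two
  ann <- annotate_cliffs(sets)
  merge_multitarget_sets(sets, ann)
}

test_that("sets sharing a key merge into one multitarget node", {
  nodes <- table_two_nodes()
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$shape_class, "multi")
  expect_true(nodes$has_ac)  # only the 5-HT1a member set carries the cliff
  expect_equal(nodes$predominant_subfamily, "serotoninergic")
  expect_setequal(nodes$targets[[1]], c("HTR1A", "HTR1B", "HTR1D"))
  expect_equal(length(nodes$member_set_ids[[1]]), 3)
})

test_that("shape classes follow the target count and ties follow the fixed order", {
  sets <- dplyr::bind_rows(
    tibble::tibble(set_id = "s1", target_id = "HTR1A", defluor_smiles = "A",
                   fluorine_count = 1L, compound_id = c("a1", "a2"),
                   canonical_smiles = c("x1", "x2"), ppot = c(8, 7)),
    tibble::tibble(set_id = "s2", target_id = "DRD2", defluor_smiles = "A",
                   fluorine_count = 1L, compound_id = c("a1", "a2"),
                   canonical_smiles = c("x1", "x2"), ppot = c(6, 7)),
    tibble::tibble(set_id = "s3", target_id = "ZZZ9", defluor_smiles = "B",
                   fluorine_count = 1L, compound_id = c("b1", "b2"),
                   canonical_smiles = c("y1", "y2"), ppot = c(6, 9))
  )
  nodes <- merge_multitarget_sets(sets, annotate_cliffs(sets))
  a <- nodes[nodes$defluor_smiles == "A", ]
  expect_equal(a$shape_class, "dual")
  expect_equal(a$predominant_subfamily, "serotoninergic")  # 1-1 tie
  b <- nodes[nodes$defluor_smiles == "B", ]
  expect_equal(b$shape_class, "single")
  expect_equal(b$predominant_subfamily, "other")  # unmapped target
  expect_true(b$has_ac)
  # merging loses nothing
  expect_equal(sum(lengths(nodes$member_set_ids)),
               dplyr::n_distinct(sets$set_id))
  expect_error(merge_multitarget_sets(sets, annotate_cliffs(sets[1:4, ])),
               "do not cover")
})

test_that("representative MMPs become typed, collapsed edges", {
  nodes <- tibble::tibble(
    node_id = c("n1", "n2", "n3"),
    defluor_smiles = canonical_smiles(c("c1ccccc1", "Cc1ccccc1",
                                        "c1ccncc1")),
    fluorine_count = 1L,
    member_set_ids = list("s1", "s2", "s3"),
    targets = list("T1", "T1", "T2"), n_targets = 1L,
    shape_class = "single", has_ac = c(TRUE, FALSE, FALSE),
    predominant_subfamily = "other", n_compounds = 2L
  )
  reps <- tibble::tibble(compound_id = nodes$node_id,
                         canonical_smiles = nodes$defluor_smiles)
  pairs <- find_mmps(reps)
  g <- build_mmp_network(nodes, pairs)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$edge_type, "substructure")  # benzene H<->methyl
  expect_equal(igraph::degree(g)[["n3"]], 0)  # isolated node retained
  # shuffled pair input gives the same graph
  g2 <- build_mmp_network(nodes, pairs[rev(seq_len(nrow(pairs))), ])
  expect_identical(igraph::as_data_frame(g), igraph::as_data_frame(g2))
  bad <- dplyr::mutate(pairs, compound_a = "nope")
  expect_error(build_mmp_network(nodes, bad), "unknown node")
})

test_that("transformation edges arise when neither fragment is hydrogen", {
  nodes <- tibble::tibble(
    node_id = c("n1", "n2"),
    defluor_smiles = canonical_smiles(c("Cc1ccccc1", "CCc1ccccc1")),
    fluorine_count = 1L, member_set_ids = list("s1", "s2"),
    targets = list("T1", "T1"), n_targets = 1L, shape_class = "single",
    has_ac = FALSE, predominant_subfamily = "other", n_compounds = 2L
  )
  reps <- tibble::tibble(compound_id = nodes$node_id,
                         canonical_smiles = nodes$defluor_smiles)
  g <- build_mmp_network(nodes, find_mmps(reps))
  # toluene/ethylbenzene relate both by H<->ethyl-ish cuts and methyl<->ethyl;
  # the collapsed edge is typed substructure when any pair exchanges an H
  expect_equal(igraph::ecount(g), 1)
  pairs <- find_mmps(reps)
  expect_true(any(!pairs$is_substructure_pair))
  g2 <- build_mmp_network(nodes, pairs[!pairs$is_substructure_pair, ])
  expect_equal(igraph::E(g2)$edge_type, "transformation")
})

test_that("GraphML and attribute exports round-trip the network", {
  nodes <- table_two_nodes()
  reps <- tibble::tibble(compound_id = nodes$node_id,
                         canonical_smiles = nodes$defluor_smiles)
  g <- build_mmp_network(nodes, find_mmps(reps))
  dir <- withr::local_tempdir()
  paths <- export_network(g, dir, style = list(ac_border = "black"))
  expect_true(all(file.exists(paths)))
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_identical(igraph::V(g2)$shape_class, igraph::V(g)$shape_class)
  expect_identical(igraph::V(g2)$has_ac, igraph::V(g)$has_ac)
  nodes_tsv <- readr::read_tsv(paths[["nodes"]], show_col_types = FALSE)
  expect_equal(nrow(nodes_tsv), igraph::vcount(g))

  # an empty network still exports a valid GraphML file
  g0 <- build_mmp_network(nodes[0, ], find_mmps(reps[0, ]))
  p0 <- export_network(g0, dir, "empty")
  g0b <- igraph::read_graph(p0[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g0b), 0)
})

test_that("network plotting returns a ggplot", {
  nodes <- table_two_nodes()
  g <- build_mmp_network(nodes, find_mmps(tibble::tibble(
    compound_id = nodes$node_id, canonical_smiles = nodes$defluor_smiles)))
  expect_s3_class(plot_mmp_network(g), "ggplot")
})
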