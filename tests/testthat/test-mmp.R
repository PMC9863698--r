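std <- function(ids, smis) {
  tibble::tibble(compound_id = ids, canonical_smiles = canonical_smiles(smis))
}

test_that("single-cut fragmentation enumerates acyclic bonds and H cuts", {
  tol <- fragment_single_cut(std("tol", "Cc1ccccc1"))
  heavy_cuts <- tol[!tol$is_h_cut, ]
  expect_equal(nrow(heavy_cuts), 2)  # one bond, two orientations
  expect_setequal(heavy_cuts$core_heavy, c(1, 6))
  h_cuts <- tol[tol$is_h_cut, ]
  expect_equal(nrow(h_cuts), 6)  # five aromatic CH + the methyl carbon
  expect_true(all(h_cuts$fragment_heavy == 0))

  benzene <- fragment_single_cut(std("bz", "c1ccccc1"))
  expect_equal(sum(!benzene$is_h_cut), 0)  # all bonds are in the ring
  expect_equal(sum(benzene$is_h_cut), 6)
  expect_equal(dplyr::n_distinct(benzene$core_smiles), 1)

  eb <- fragment_single_cut(std("eb", "CCc1ccccc1"))
  expect_equal(sum(!eb$is_h_cut), 4)  # two acyclic bonds, two orientations
})

test_that("core and fragment sizes always sum to the parent", {
  for (smi in toy_library()$smiles) {
    parent_heavy <- standardize_molecules(
      tibble::tibble(compound_id = "x", smiles = smi))$heavy_atom_count
    fr <- fragment_single_cut(std("x", smi))
    expect_true(all(fr$core_heavy + fr$fragment_heavy == parent_heavy))
    # each side carries exactly one attachment point
    expect_true(all(stringr::str_count(fr$core_smiles, "\\*") == 1))
  }
})

test_that("size restrictions implement the three admissibility rules", {
  expect_true(mmp_restrict(6, 1, 2))
  expect_false(mmp_restrict(100, 13, 22))   # fragment too large, diff > 8
  expect_false(mmp_restrict(10, 5, 6))      # core below twice the larger frag
  # boundary: core exactly twice the larger fragment
  expect_true(mmp_restrict(4, 2, 1))
  expect_false(mmp_restrict(3, 2, 1))
  # boundary: size difference exactly 8
  expect_true(mmp_restrict(26, 13, 5))
  expect_false(mmp_restrict(26, 13, 4))
  # boundary: fragment size exactly 13
  expect_true(mmp_restrict(26, 13, 13))
  expect_false(mmp_restrict(28, 14, 13))
  # lax mode only requires the core rule to hold in one parent
  expect_true(mmp_restrict(9, 5, 2, per_fragment = TRUE))
  expect_false(mmp_restrict(9, 5, 2))
})

test_that("shared cores yield pairs, hydrogen cuts yield substructure pairs", {
  mols <- std(c("toluene", "ethylbenzene", "benzene", "pyridine"),
              c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1", "c1ccncc1"))
  pairs <- find_mmps(mols)
  te <- pairs[pairs$compound_a == "ethylbenzene" &
                pairs$compound_b == "toluene", ]
  expect_gte(nrow(te), 1)
  expect_true(any(!te$is_substructure_pair))  # methyl <-> ethyl on phenyl
  bt <- pairs[pairs$compound_a == "benzene" & pairs$compound_b == "toluene", ]
  expect_equal(nrow(bt), 1)
  expect_true(bt$is_substructure_pair)        # H <-> methyl
  expect_false(any(pairs$compound_a == "pyridine" |
                     pairs$compound_b == "pyridine"))
})

test_that("pairs are unordered, deduplicated and order-invariant", {
  mols <- std(toy_library()$compound_id, toy_library()$smiles)
  p1 <- find_mmps(mols)
  expect_true(all(p1$compound_a < p1$compound_b))
  expect_equal(anyDuplicated(p1[, c("compound_a", "compound_b",
                                    "core_smiles")]), 0L)
  p2 <- find_mmps(mols[rev(seq_len(nrow(mols))), ])
  expect_identical(p1, p2)
})

test_that("every emitted pair reassembles to both parent structures", {
  mols <- std(c("toluene", "ethylbenzene", "fluorobenzene", "benzene"),
              c("Cc1ccccc1", "CCc1ccccc1", "Fc1ccccc1", "c1ccccc1"))
  pairs <- find_mmps(mols)
  expect_gte(nrow(pairs), 3)
  for (i in seq_len(nrow(pairs))) {
    sa <- fisar:::mmp_reassemble(pairs$core_smiles[i], pairs$frag_a_smiles[i])
    sb <- fisar:::mmp_reassemble(pairs$core_smiles[i], pairs$frag_b_smiles[i])
    expect_identical(
      sa, mols$canonical_smiles[mols$compound_id == pairs$compound_a[i]])
    expect_identical(
      sb, mols$canonical_smiles[mols$compound_id == pairs$compound_b[i]])
  }
})

test_that("the core-indexed engine agrees with the brute-force oracle", {
  mols <- std(toy_library()$compound_id, toy_library()$smiles)
  engine <- find_mmps(mols) |>
    dplyr::distinct(compound_a, compound_b, core_smiles,
                    is_substructure_pair) |>
    dplyr::arrange(compound_a, compound_b, core_smiles)
  oracle <- brute_force_mmps(mols)
  expect_identical(as.data.frame(engine), as.data.frame(oracle))
})
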