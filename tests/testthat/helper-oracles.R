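# Fixtures and independent oracles used across test files.

# Small, hand-checkable molecules for fragmentation/MMP tests.
toy_library <- function() {
  tibble::tibble(
    compound_id = c("benzene", "toluene", "ethylbenzene", "propylbenzene",
                    "fluorobenzene", "chlorobenzene", "anisole", "phenol",
                    "pyridine", "picoline", "styrene", "benzonitrile"),
    smiles = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
               "Fc1ccccc1", "Clc1ccccc1", "COc1ccccc1", "Oc1ccccc1",
               "c1ccncc1", "Cc1ccccn1", "C=Cc1ccccc1", "N#Cc1ccccc1")
  )
}

# Brute-force MMP oracle: enumerate every pair of molecules, compare all of
# their single-cut fragmentations directly (no core index), and apply the
# size-restriction arithmetic inline. Returns the same key columns as
# find_mmps() for set comparison.
brute_force_mmps <- function(mols, core_factor = 2, max_size_diff = 8,
                             max_fragment = 13) {
  frag_list <- lapply(seq_len(nrow(mols)), function(i) {
    unique(fragment_single_cut(mols[i, , drop = FALSE]))
  })
  out <- list()
  n <- nrow(mols)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fi <- frag_list[[i]]; fj <- frag_list[[j]]
      for (a in seq_len(nrow(fi))) {
        for (b in seq_len(nrow(fj))) {
          if (fi$core_smiles[a] != fj$core_smiles[b]) next
          if (fi$fragment_smiles[a] == fj$fragment_smiles[b]) next
          fa <- fi$fragment_heavy[a]; fb <- fj$fragment_heavy[b]
          ch <- fi$core_heavy[a]
          if (!(ch >= core_factor * max(fa, fb) &&
                  abs(fa - fb) <= max_size_diff &&
                  fa <= max_fragment && fb <= max_fragment)) next
          ids <- sort(c(mols$compound_id[i], mols$compound_id[j]))
          out[[length(out) + 1]] <- tibble::tibble(
            compound_a = ids[1], compound_b = ids[2],
            core_smiles = fi$core_smiles[a],
            is_substructure_pair = fa == 0L || fb == 0L
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(compound_a = character(0),
                          compound_b = character(0),
                          core_smiles = character(0),
                          is_substructure_pair = logical(0)))
  }
  dplyr::distinct(dplyr::bind_rows(out)) |>
    dplyr::arrange(compound_a, compound_b, core_smiles)
}

# O(n^2) Kendall tau-b from explicit concordant/discordant pair counts.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Molecular formula as a named count vector (heavy atoms + hydrogens),
# derived from the molblock graph independently of any grouping logic.
molecular_formula <- function(smiles) {
  mol <- fisar:::mol_from_smiles(smiles)
  h <- sum(fisar:::mol_h_counts(smiles))
  counts <- table(mol$symbol)
  counts <- counts[order(names(counts))]
  paste0(paste0(names(counts), as.integer(counts), collapse = ""), "H", h)
}

# Raw-record constructor with the standard ChEMBL-like defaults.
make_record <- function(compound_id, smiles, target_id, value,
                        standard_type = "Ki", relation = "=", units = "nM",
                        confidence_score = 9L, relationship_type = "D") {
  tibble::tibble(compound_id = compound_id, smiles = smiles,
                 target_id = target_id, standard_type = standard_type,
                 relation = relation, value = value, units = units,
                 confidence_score = confidence_score,
                 relationship_type = relationship_type)
}
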