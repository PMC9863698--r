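#' Standardize compound structures
#'
#' Canonicalizes SMILES with OpenBabel after keeping the largest covalent
#' fragment (salt/solvate stripping) and counts heavy atoms and fluorines on
#' the kept fragment. Stereochemistry and formal charges are preserved.
#'
#' @param data A data frame with one row per compound.
#' @param id_col,smiles_col Column names (strings) holding the compound
#'   identifier and the input SMILES. Defaults `"compound_id"` and `"smiles"`.
#' @return A tibble with columns `compound_id`, `canonical_smiles`,
#'   `heavy_atom_count`, `fluorine_count`, one row per input row.
#' @details Unparseable SMILES abort with an error naming the offending
#'   compound identifiers ("invalid structure"). When a record contains several
#'   covalent species the fragment with the most heavy atoms is kept; ties are
#'   broken by the lexicographically smallest canonical SMILES so the result
#'   does not depend on input atom order.
#' @examples
#' standardize_molecules(
#'   data.frame(compound_id = c("a", "b"),
#'              smiles = c("Fc1ccccc1.Cl", "c1ccccc1"))
#' )
#' @export
standardize_molecules <- function(data, id_col = "compound_id",
                                  smiles_col = "smiles") {
  for (col in c(id_col, smiles_col)) {
    if (!col %in% names(data)) {
      stop("column `", col, "` not found in `data`", call. = FALSE)
    }
  }
  ids <- as.character(data[[id_col]])
  smiles <- as.character(data[[smiles_col]])
  res <- purrr::map(smiles, standardize_one)
  bad <- ids[purrr::map_lgl(res, is.null)]
  if (length(bad) > 0) {
    stop("invalid structure for compound(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    compound_id = ids,
    canonical_smiles = purrr::map_chr(res, "canonical_smiles"),
    heavy_atom_count = purrr::map_int(res, "heavy_atom_count"),
    fluorine_count = purrr::map_int(res, "fluorine_count")
  )
}

# Largest covalent fragment, canonicalized; NULL when unparseable.
standardize_one <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  if (is.null(mol) || length(mol$symbol) == 0) return(NULL)
  memb <- mol_components(mol)
  if (max(memb) > 1L) {
    sizes <- vapply(seq_len(max(memb)), function(k) {
      mol_n_heavy(mol_subset(mol, which(memb == k)))
    }, integer(1))
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      smis <- vapply(best, function(k) {
        mol_to_smiles(mol_subset(mol, which(memb == k)))
      }, character(1))
      best <- best[order(smis)[1]]
    }
    mol <- mol_subset(mol, which(memb == best))
  }
  can <- mol_to_smiles(mol)
  if (is.na(can)) return(NULL)
  list(canonical_smiles = can,
       heavy_atom_count = mol_n_heavy(mol),
       fluorine_count = sum(mol$symbol == "F"))
}

#' Compute defluorinated scaffold keys
#'
#' The scaffold key of a fluorinated compound is the canonical SMILES of the
#' structure with every fluorine atom replaced by hydrogen, paired with the
#' fluorine count. Two compounds are fluorine positional isomers exactly when
#' their keys are identical.
#'
#' @param data Output of [standardize_molecules()] (needs `canonical_smiles`
#'   and `fluorine_count`).
#' @param strip_stereo If `TRUE`, stereochemistry is removed before keying so
#'   that stereoisomeric fluorine analogs group together. Default `FALSE`:
#'   enantiomers/diastereomers are pharmacologically distinct ligands and are
#'   kept apart.
#' @return The input tibble with an added `defluor_smiles` column (`NA` for
#'   non-fluorinated compounds, which have no key).
#' @examples
#' mols <- standardize_molecules(
#'   data.frame(compound_id = c("o", "p"),
#'              smiles = c("Cc1ccccc1F", "Cc1ccc(F)cc1"))
#' )
#' scaffold_key(mols)
#' @export
scaffold_key <- function(data, strip_stereo = FALSE) {
  stopifnot(all(c("canonical_smiles", "fluorine_count") %in% names(data)))
  defluor <- vapply(seq_len(nrow(data)), function(i) {
    if (data$fluorine_count[i] == 0L) return(NA_character_)
    defluorinate(data$canonical_smiles[i], strip_stereo = strip_stereo)
  }, character(1))
  out <- tibble::as_tibble(data)
  out$defluor_smiles <- defluor
  out
}

# Replace every fluorine by (implicit) hydrogen and re-canonicalize.
defluorinate <- function(smiles, strip_stereo = FALSE) {
  mol <- mol_from_smiles(smiles)
  if (is.null(mol)) return(NA_character_)
  keep <- which(mol$symbol != "F")
  if (length(keep) == 0) return(NA_character_)
  can <- mol_to_smiles(mol_subset(mol, keep))
  if (strip_stereo && !is.na(can)) {
    can <- canonical_smiles(gsub("[/\\\\]", "", gsub("@", "", can, fixed = TRUE)))
  }
  can
}

# Enumerate the structurally distinct ways of placing `n_f` fluorines on the
# substitutable aromatic CH positions of a scaffold. Returns a tibble of
# distinct canonical isomer SMILES; used by the synthetic library generator
# and handy for fluorine-scan design.
enumerate_fluorine_placements <- function(scaffold_smiles, n_f = 1L) {
  mol <- mol_from_smiles(scaffold_smiles)
  if (is.null(mol)) stop("invalid structure: ", scaffold_smiles, call. = FALSE)
  hc <- mol_h_counts(scaffold_smiles)
  ring <- mol_ring_bonds(mol)
  ring_atoms <- unique(c(mol$bonds$a1[ring], mol$bonds$a2[ring]))
  # aromatic CH: ring carbon with >=1 H carrying one double bond (Kekule form)
  has_double <- seq_along(mol$symbol) %in%
    c(mol$bonds$a1[mol$bonds$order == 2L], mol$bonds$a2[mol$bonds$order == 2L])
  sites <- which(mol$symbol == "C" & seq_along(mol$symbol) %in% ring_atoms &
                   hc >= 1L & has_double)
  if (length(sites) < n_f) {
    return(tibble::tibble(positions = list(), isomer_smiles = character(0)))
  }
  combos <- utils::combn(sites, n_f, simplify = FALSE)
  smis <- vapply(combos, function(pos) {
    m <- mol
    for (p in pos) m <- mol_add_atom(m, "F", p, x = m$x[p], y = m$y[p])
    mol_to_smiles(m)
  }, character(1))
  keep <- !is.na(smis) & !duplicated(smis)
  tibble::tibble(positions = combos[keep], isomer_smiles = smis[keep])
}
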