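# Mining fluorine positional isomer (F_iSAR) analog sets.

#' Mine target-based fluorine-isomer analog sets
#'
#' Groups potency records by (defluorinated scaffold key, target) and keeps
#' every group with at least two structurally distinct fluorine positional
#' isomers. Non-fluorinated compounds (which have no key) and singleton
#' groups are excluded. Set identifiers are content hashes of the key and
#' target, so re-runs on the same data yield the same ids.
#'
#' @param mols Standardized structures with scaffold keys, as returned by
#'   [scaffold_key()].
#' @param potencies Aggregated potencies, as returned by
#'   [aggregate_potency()].
#' @return A long-format tibble with one row per set member: `set_id`,
#'   `target_id`, `defluor_smiles`, `fluorine_count`, `compound_id`,
#'   `canonical_smiles`, `ppot`.
#' @export
mine_fisar_sets <- function(mols, potencies) {
  missing <- setdiff(unique(potencies$compound_id), mols$compound_id)
  if (length(missing) > 0) {
    stop("no standardized structure for compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long <- potencies |>
    dplyr::inner_join(
      dplyr::select(mols, "compound_id", "canonical_smiles",
                    "fluorine_count", "defluor_smiles"),
      by = "compound_id"
    ) |>
    dplyr::filter(!is.na(.data$defluor_smiles))
  if (nrow(long) == 0) return(empty_fisar_sets())

  # one potency per (compound, target) is guaranteed upstream; assert it
  stopifnot(!anyDuplicated(long[, c("compound_id", "target_id")]))

  long |>
    dplyr::mutate(.key = paste(.data$defluor_smiles, .data$fluorine_count,
                               sep = "|")) |>
    dplyr::filter(
      dplyr::n_distinct(.data$canonical_smiles) >= 2,
      .by = c(".key", "target_id")
    ) |>
    dplyr::mutate(
      set_id = fisar_set_id(.data$.key[1], .data$target_id[1]),
      .by = c(".key", "target_id")
    ) |>
    dplyr::arrange(.data$set_id, .data$compound_id) |>
    dplyr::select("set_id", "target_id", "defluor_smiles", "fluorine_count",
                  "compound_id", "canonical_smiles", "ppot") |>
    tibble::as_tibble()
}

fisar_set_id <- function(key, target_id) {
  paste0("FS-", substr(rlang::hash(paste(key, target_id, sep = "@")), 1, 12))
}

empty_fisar_sets <- function() {
  tibble::tibble(set_id = character(0), target_id = character(0),
                 defluor_smiles = character(0), fluorine_count = integer(0),
                 compound_id = character(0), canonical_smiles = character(0),
                 ppot = numeric(0))
}

#' Distribution of analog-set sizes
#'
#' @param sets Long-format set table from [mine_fisar_sets()].
#' @return A tibble with `size` (number of isomers in a set) and `n_sets`.
#' @export
set_size_histogram <- function(sets) {
  if (nrow(sets) == 0) {
    return(tibble::tibble(size = integer(0), n_sets = integer(0)))
  }
  sets |>
    dplyr::summarise(size = dplyr::n(), .by = "set_id") |>
    dplyr::count(.data$size, name = "n_sets") |>
    dplyr::arrange(.data$size) |>
    tibble::as_tibble()
}
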