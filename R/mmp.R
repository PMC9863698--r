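# Single-cut, transformation-size-restricted matched molecular pairs
# (fragment-and-index approach of Hussain and Rea).

# Canonical SMILES of the single-hydrogen fragment used for virtual
# hydrogen cuts; cached after the first OpenBabel call.
h_fragment_smiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- canonical_smiles("[H][*]")
    cache
  }
})

#' Single-cut fragmentations of standardized molecules
#'
#' Cuts every acyclic single bond between two heavy atoms, yielding a core
#' and a fragment that each carry one labeled attachment point (`*`); both
#' orientations are emitted. In addition a virtual hydrogen cut is emitted
#' for every heavy atom bearing at least one hydrogen (the fragment is a
#' single hydrogen, 0 heavy atoms), which enables hydrogen-vs-moiety pairs.
#'
#' @param mols Data frame with `compound_id` and `canonical_smiles` (see
#'   [standardize_molecules()]).
#' @return A tibble with `parent_id`, `core_smiles`, `fragment_smiles`,
#'   `core_heavy`, `fragment_heavy`, `is_h_cut`. For every row,
#'   `core_heavy + fragment_heavy` equals the parent's heavy atom count.
#' @export
fragment_single_cut <- function(mols) {
  stopifnot(all(c("compound_id", "canonical_smiles") %in% names(mols)))
  res <- purrr::map2(mols$compound_id, mols$canonical_smiles,
                     fragment_one)
  dplyr::bind_rows(c(list(empty_fragmentations()), res))
}

empty_fragmentations <- function() {
  tibble::tibble(parent_id = character(0), core_smiles = character(0),
                 fragment_smiles = character(0), core_heavy = integer(0),
                 fragment_heavy = integer(0), is_h_cut = logical(0))
}

fragment_one <- function(id, smiles) {
  mol <- mol_from_smiles(smiles)
  if (is.null(mol)) stop("invalid structure: ", id, call. = FALSE)
  heavy <- !mol$symbol %in% c(HYDROGEN_SYMBOLS, "*")
  ring <- mol_ring_bonds(mol)
  rows <- list()

  piece <- function(keep, attach, dummy_x, dummy_y) {
    m <- mol_subset(mol, keep)
    at <- match(attach, sort(unique(keep)))
    m <- mol_add_atom(m, "*", at, x = dummy_x, y = dummy_y)
    list(smiles = mol_to_smiles(m), heavy = mol_n_heavy(m))
  }

  eligible <- which(mol$bonds$order == 1L &
                      !(seq_len(nrow(mol$bonds)) %in% ring) &
                      heavy[mol$bonds$a1] & heavy[mol$bonds$a2])
  for (b in eligible) {
    u <- mol$bonds$a1[b]; v <- mol$bonds$a2[b]
    m_cut <- mol
    m_cut$bonds <- m_cut$bonds[-b, , drop = FALSE]
    memb <- mol_components(m_cut)
    side_u <- which(memb == memb[u])
    side_v <- which(memb == memb[v])
    pu <- piece(side_u, u, mol$x[v], mol$y[v])
    pv <- piece(side_v, v, mol$x[u], mol$y[u])
    if (is.na(pu$smiles) || is.na(pv$smiles)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      parent_id = id,
      core_smiles = c(pu$smiles, pv$smiles),
      fragment_smiles = c(pv$smiles, pu$smiles),
      core_heavy = c(pu$heavy, pv$heavy),
      fragment_heavy = c(pv$heavy, pu$heavy),
      is_h_cut = FALSE
    )
  }

  hc <- mol_h_counts(smiles)
  for (a in which(heavy & hc >= 1L)) {
    m <- mol_add_atom(mol, "*", a, x = mol$x[a] + 0.5, y = mol$y[a] + 0.5)
    core <- mol_to_smiles(m)
    if (is.na(core)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      parent_id = id, core_smiles = core,
      fragment_smiles = h_fragment_smiles(),
      core_heavy = mol_n_heavy(m), fragment_heavy = 0L, is_h_cut = TRUE
    )
  }
  if (length(rows) == 0) empty_fragmentations() else dplyr::bind_rows(rows)
}

#' Transformation-size restriction for matched molecular pairs
#'
#' A candidate pair is admissible when the shared core has at least
#' `core_factor` times as many heavy atoms as the larger exchanged fragment,
#' the exchanged fragments differ by at most `max_size_diff` heavy atoms, and
#' neither fragment exceeds `max_fragment` heavy atoms.
#'
#' @param core_heavy,frag_a_heavy,frag_b_heavy Heavy-atom counts (vectorized).
#' @param core_factor Core-to-fragment size factor (default 2).
#' @param max_size_diff Maximum heavy-atom difference between the exchanged
#'   fragments (default 8).
#' @param max_fragment Maximum heavy atoms per exchanged fragment (default 13).
#' @param per_fragment If `TRUE`, the core-size rule only needs to hold
#'   against the smaller exchanged fragment, i.e. in at least one of the two
#'   parent molecules (a laxer reading). The default requires it against the
#'   larger fragment, i.e. in both parents (conservative).
#' @return Logical vector.
#' @export
mmp_restrict <- function(core_heavy, frag_a_heavy, frag_b_heavy,
                         core_factor = 2, max_size_diff = 8,
                         max_fragment = 13, per_fragment = FALSE) {
  ref <- if (per_fragment) {
    pmin(frag_a_heavy, frag_b_heavy)
  } else {
    pmax(frag_a_heavy, frag_b_heavy)
  }
  core_ok <- core_heavy >= core_factor * ref
  core_ok &
    abs(frag_a_heavy - frag_b_heavy) <= max_size_diff &
    frag_a_heavy <= max_fragment & frag_b_heavy <= max_fragment
}

#' Find transformation-size-restricted matched molecular pairs
#'
#' Indexes single-cut fragmentations by canonical core; two molecules form a
#' matched molecular pair (MMP) when they share a core and exchange different
#' fragments, subject to [mmp_restrict()]. Pairs are unordered
#' (`compound_a < compound_b`) and deduplicated per (pair, core); distinct
#' cores relating the same two compounds are all kept.
#'
#' @param mols Data frame with `compound_id` and `canonical_smiles`.
#' @inheritParams mmp_restrict
#' @return A tibble with `compound_a`, `compound_b`, `core_smiles`,
#'   `frag_a_smiles`, `frag_b_smiles`, `frag_a_heavy`, `frag_b_heavy`,
#'   `core_heavy`, `is_substructure_pair` (one exchanged fragment is a single
#'   hydrogen).
#' @export
find_mmps <- function(mols, core_factor = 2, max_size_diff = 8,
                      max_fragment = 13, per_fragment = FALSE) {
  frags <- fragment_single_cut(mols) |>
    dplyr::distinct(.data$parent_id, .data$core_smiles,
                    .data$fragment_smiles, .data$core_heavy,
                    .data$fragment_heavy)
  empty <- tibble::tibble(
    compound_a = character(0), compound_b = character(0),
    core_smiles = character(0), frag_a_smiles = character(0),
    frag_b_smiles = character(0), frag_a_heavy = integer(0),
    frag_b_heavy = integer(0), core_heavy = integer(0),
    is_substructure_pair = logical(0)
  )
  if (nrow(frags) == 0) return(empty)
  pairs <- dplyr::inner_join(
    frags, frags,
    by = c("core_smiles", "core_heavy"),
    suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$parent_id_a < .data$parent_id_b,
                  .data$fragment_smiles_a != .data$fragment_smiles_b) |>
    dplyr::transmute(
      compound_a = .data$parent_id_a, compound_b = .data$parent_id_b,
      core_smiles = .data$core_smiles,
      frag_a_smiles = .data$fragment_smiles_a,
      frag_b_smiles = .data$fragment_smiles_b,
      frag_a_heavy = .data$fragment_heavy_a,
      frag_b_heavy = .data$fragment_heavy_b,
      core_heavy = .data$core_heavy
    ) |>
    dplyr::distinct(.data$compound_a, .data$compound_b, .data$core_smiles,
                    .keep_all = TRUE) |>
    dplyr::filter(mmp_restrict(.data$core_heavy, .data$frag_a_heavy,
                               .data$frag_b_heavy, core_factor,
                               max_size_diff, max_fragment, per_fragment)) |>
    dplyr::mutate(is_substructure_pair = .data$frag_a_heavy == 0L |
                    .data$frag_b_heavy == 0L) |>
    dplyr::arrange(.data$compound_a, .data$compound_b, .data$core_smiles)
  if (nrow(pairs) == 0) empty else tibble::as_tibble(pairs)
}

# Reattach a fragment to a core at their attachment points; used to verify
# that fragmentations reassemble to the parent structure.
mmp_reassemble <- function(core_smiles, fragment_smiles) {
  core <- mol_from_smiles(core_smiles)
  if (is.null(core)) return(NA_character_)
  d_core <- which(core$symbol == "*")
  stopifnot(length(d_core) == 1)
  if (identical(fragment_smiles, h_fragment_smiles())) {
    return(mol_to_smiles(mol_subset(core, setdiff(seq_along(core$symbol),
                                                  d_core))))
  }
  frag <- mol_from_smiles(fragment_smiles)
  if (is.null(frag)) return(NA_character_)
  d_frag <- which(frag$symbol == "*")
  stopifnot(length(d_frag) == 1)
  off <- length(core$symbol)
  u <- core$bonds$a1[core$bonds$a2 == d_core]
  u <- c(u, core$bonds$a2[core$bonds$a1 == d_core])
  v <- frag$bonds$a1[frag$bonds$a2 == d_frag]
  v <- c(v, frag$bonds$a2[frag$bonds$a1 == d_frag])
  stopifnot(length(u) == 1, length(v) == 1)
  fb <- frag$bonds
  fb$a1 <- fb$a1 + off
  fb$a2 <- fb$a2 + off
  fchg <- frag$chg; fchg$atom <- fchg$atom + off
  fiso <- frag$iso; fiso$atom <- fiso$atom + off
  combined <- structure(
    list(symbol = c(core$symbol, frag$symbol),
         atom_lines = c(core$atom_lines, frag$atom_lines),
         x = c(core$x, frag$x), y = c(core$y, frag$y),
         bonds = rbind(core$bonds, fb,
                       data.frame(a1 = u, a2 = v + off, order = 1L,
                                  rest = "  0  0  0  0")),
         chg = rbind(core$chg, fchg), iso = rbind(core$iso, fiso),
         chiral = core$chiral),
    class = "fisar_mol"
  )
  keep <- setdiff(seq_along(combined$symbol), c(d_core, d_frag + off))
  mol_to_smiles(mol_subset(combined, keep))
}
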