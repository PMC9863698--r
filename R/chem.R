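# Internal molecular-graph layer.
#
# All chemical perception (SMILES parsing, aromaticity, stereo, canonical
# SMILES) is delegated to OpenBabel through ChemmineOB. This file only edits
# molecular graphs as V2000 molblock text: atom lines written by OpenBabel are
# kept verbatim so that stereo parity fields and the 2D coordinates that carry
# E/Z geometry survive graph edits. Dummy (attachment-point) atoms inherit the
# coordinates of the atom they replace for the same reason.

ob_opts <- function(...) {
  nm <- c(...)
  if (length(nm) == 0) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

ob_convert <- function(from, to, source, opts = NULL) {
  if (is.null(opts)) {
    ChemmineOB::convertFormat(from, to, source)
  } else {
    ChemmineOB::convertFormat(from, to, source, options = opts)
  }
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparseable inputs yield
#' `NA` rather than an error, so callers can report offending identifiers.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonical_smiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ob_convert("SMI", "CAN", s), error = function(e) "")
    out <- trimws(sub("\t.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# ---- V2000 molblock codec ----------------------------------------------

# Parse one molblock (single string or character lines) into a graph list.
parse_molblock <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  chiral <- substr(counts, 13, 15)
  atom_lines <- if (natoms > 0) lines[5:(4 + natoms)] else character(0)
  symbol <- trimws(substr(atom_lines, 32, 34))
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  bonds <- if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)),
      rest = substr(bl, 10, 1000L)
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
               rest = character(0))
  }
  parse_m_pairs <- function(tag) {
    ml <- grep(paste0("^M  ", tag), lines, value = TRUE)
    if (length(ml) == 0) {
      return(data.frame(atom = integer(0), value = integer(0)))
    }
    out <- lapply(ml, function(l) {
      n <- as.integer(substr(l, 7, 9))
      atom <- value <- integer(n)
      for (i in seq_len(n)) {
        off <- 10 + (i - 1) * 8
        atom[i] <- as.integer(substr(l, off, off + 3))
        value[i] <- as.integer(substr(l, off + 4, off + 7))
      }
      data.frame(atom = atom, value = value)
    })
    do.call(rbind, out)
  }
  structure(
    list(symbol = symbol, atom_lines = atom_lines, x = x, y = y,
         bonds = bonds, chg = parse_m_pairs("CHG"), iso = parse_m_pairs("ISO"),
         chiral = chiral),
    class = "fisar_mol"
  )
}

write_m_pairs <- function(tag, df) {
  if (nrow(df) == 0) return(character(0))
  chunks <- split(df, (seq_len(nrow(df)) - 1) %/% 8)
  vapply(chunks, function(ch) {
    paste0("M  ", tag, sprintf("%3d", nrow(ch)),
           paste0(sprintf("%4d%4d", ch$atom, ch$value), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

write_molblock <- function(mol) {
  counts <- sprintf("%3d%3d  0  0%s  0  0  0  0  0999 V2000",
                    length(mol$symbol), nrow(mol$bonds), mol$chiral)
  bond_lines <- sprintf("%3d%3d%3d%s",
                        mol$bonds$a1, mol$bonds$a2, mol$bonds$order,
                        mol$bonds$rest)
  paste(c("", " fisar", "", counts, mol$atom_lines, bond_lines,
          write_m_pairs("CHG", mol$chg), write_m_pairs("ISO", mol$iso),
          "M  END", "$$$$"),
        collapse = "\n")
}

# Parse a SMILES string into a graph; NULL if OpenBabel cannot read it.
mol_from_smiles <- function(smiles, add_h = FALSE) {
  opts <- if (add_h) ob_opts("h") else NULL
  out <- tryCatch(ob_convert("SMI", "SDF", smiles, opts),
                  error = function(e) "")
  if (!grepl("V2000", out, fixed = TRUE)) return(NULL)
  parse_molblock(out)
}

mol_to_smiles <- function(mol) {
  out <- tryCatch(ob_convert("SDF", "CAN", write_molblock(mol)),
                  error = function(e) "")
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

HYDROGEN_SYMBOLS <- c("H", "D", "T")

mol_n_heavy <- function(mol) sum(!mol$symbol %in% c(HYDROGEN_SYMBOLS, "*"))

# Keep only the atoms in `keep` (integer indices); bonds and charge/isotope
# annotations are remapped, bonds touching removed atoms are dropped.
mol_subset <- function(mol, keep) {
  keep <- sort(unique(keep))
  map <- integer(length(mol$symbol))
  map[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]
  b$a2 <- map[b$a2]
  remap_pairs <- function(df) {
    df <- df[df$atom %in% keep, , drop = FALSE]
    df$atom <- map[df$atom]
    df
  }
  structure(
    list(symbol = mol$symbol[keep], atom_lines = mol$atom_lines[keep],
         x = mol$x[keep], y = mol$y[keep], bonds = b,
         chg = remap_pairs(mol$chg), iso = remap_pairs(mol$iso),
         chiral = mol$chiral),
    class = "fisar_mol"
  )
}

make_atom_line <- function(symbol, x, y) {
  paste0(sprintf("%10.4f%10.4f%10.4f ", x, y, 0),
         sprintf("%-3s", symbol),
         " 0  0  0  0  0  0  0  0  0  0  0  0")
}

# Append one atom bonded to `bond_to` with a single bond.
mol_add_atom <- function(mol, symbol, bond_to, x = 0, y = 0) {
  n <- length(mol$symbol) + 1L
  mol$symbol <- c(mol$symbol, symbol)
  mol$atom_lines <- c(mol$atom_lines, make_atom_line(symbol, x, y))
  mol$x <- c(mol$x, x)
  mol$y <- c(mol$y, y)
  mol$bonds <- rbind(mol$bonds,
                     data.frame(a1 = bond_to, a2 = n, order = 1L,
                                rest = "  0  0  0  0"))
  mol
}

# Connected-component membership over the bond graph (isolated atoms kept).
mol_components <- function(mol) {
  n <- length(mol$symbol)
  g <- igraph::graph_from_data_frame(
    d = mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  memb <- igraph::components(g)$membership
  memb[as.character(seq_len(n))]
}

# Bond indices (rows of mol$bonds) that lie on a cycle.
mol_ring_bonds <- function(mol) {
  n <- length(mol$symbol)
  g <- igraph::graph_from_data_frame(
    d = mol$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  setdiff(seq_len(nrow(mol$bonds)), igraph::bridges(g))
}

# Hydrogen counts per heavy atom, via an explicit-hydrogen parse of the same
# SMILES (OpenBabel appends hydrogens after the heavy atoms, which is asserted).
mol_h_counts <- function(smiles) {
  molh <- mol_from_smiles(smiles, add_h = TRUE)
  if (is.null(molh)) return(NULL)
  is_h <- molh$symbol %in% HYDROGEN_SYMBOLS
  heavy <- which(!is_h)
  if (length(heavy) > 0 && max(heavy) != length(heavy)) {
    stop("internal: explicit hydrogens not appended after heavy atoms")
  }
  counts <- integer(length(heavy))
  for (i in seq_len(nrow(molh$bonds))) {
    a1 <- molh$bonds$a1[i]; a2 <- molh$bonds$a2[i]
    if (is_h[a1] && !is_h[a2]) counts[a2] <- counts[a2] + 1L
    if (is_h[a2] && !is_h[a1]) counts[a1] <- counts[a1] + 1L
  }
  counts
}
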