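# Reading and standardizing potency records.

POTENCY_TYPES_LINEAR <- c("Ki", "IC50", "EC50", "Kb", "Kd")
POTENCY_TYPES_LOG <- c("pKi", "pIC50", "pEC50", "pKb", "pKd", "LogKi")
POTENCY_TYPES <- c(POTENCY_TYPES_LINEAR, POTENCY_TYPES_LOG)

# unit -> multiplier to molar
UNIT_TO_MOLAR <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                   "nM" = 1e-9, "pM" = 1e-12)

#' Read an activity table
#'
#' Reads a ChEMBL-style activity export (CSV or TSV, UTF-8, header row) into
#' the raw record layout used by the rest of the pipeline. Column names can be
#' remapped through `col_map`, e.g. when the export uses
#' `molecule_chembl_id` instead of `compound_id`.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical names
#'   (`compound_id`, `smiles`, `target_id`, `standard_type`, `relation`,
#'   `value`, `units`, `confidence_score`, `relationship_type`) to the column
#'   names present in the file.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return A tibble of raw activity records.
#' @export
read_activity_table <- function(path, col_map = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  required <- c("compound_id", "smiles", "target_id", "standard_type",
                "relation", "value", "units", "confidence_score",
                "relationship_type")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(dat)) {
        names(dat)[names(dat) == col_map[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    stop("activity table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- dplyr::select(dat, dplyr::all_of(required))
  dat$value <- suppressWarnings(as.numeric(dat$value))
  dat$confidence_score <- suppressWarnings(as.integer(dat$confidence_score))
  tibble::as_tibble(dat)
}

#' Filter raw activity records
#'
#' Applies the four record-level filters used when curating potency data:
#' exact measurements only, direct target relationship, highest target
#' confidence, and a whitelist of well-defined potency types. Records with an
#' unknown standard type or a malformed value are dropped with a warning
#' count rather than an error. Per-filter drop counts are reported via
#' [message()].
#'
#' @param records Tibble of raw records (see [read_activity_table()]).
#' @param relations Allowed relation symbols (default exact measurements,
#'   `"="`).
#' @param relationship_type Required target relationship type (default `"D"`,
#'   direct interaction). `NULL` disables the filter.
#' @param confidence_score Required target confidence score (default `9`).
#'   `NULL` disables the filter.
#' @param standard_types Allowed potency types.
#' @param quiet Suppress the per-filter messages.
#' @return The retained records, in input order.
#' @export
filter_records <- function(records,
                           relations = "=",
                           relationship_type = "D",
                           confidence_score = 9L,
                           standard_types = POTENCY_TYPES,
                           quiet = FALSE) {
  n0 <- nrow(records)
  say <- function(label, before, after) {
    if (!quiet) {
      message(sprintf("filter %-20s dropped %d of %d", label,
                      before - after, before))
    }
  }
  keep <- records$relation %in% relations
  r <- records[keep, , drop = FALSE]; say("relation", n0, nrow(r))

  n <- nrow(r)
  if (!is.null(relationship_type)) {
    r <- r[r$relationship_type %in% relationship_type, , drop = FALSE]
  }
  say("relationship_type", n, nrow(r))

  n <- nrow(r)
  if (!is.null(confidence_score)) {
    r <- r[!is.na(r$confidence_score) &
             r$confidence_score %in% confidence_score, , drop = FALSE]
  }
  say("confidence_score", n, nrow(r))

  n <- nrow(r)
  unknown <- !r$standard_type %in% standard_types
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown standard_type dropped",
            call. = FALSE)
  }
  r <- r[!unknown, , drop = FALSE]
  say("standard_type", n, nrow(r))

  n <- nrow(r)
  bad_value <- !is.finite(r$value) |
    (r$standard_type %in% POTENCY_TYPES_LINEAR & r$value <= 0)
  if (any(bad_value)) {
    warning(sum(bad_value), " record(s) with malformed value dropped",
            call. = FALSE)
  }
  r <- r[!bad_value, , drop = FALSE]
  say("value", n, nrow(r))

  tibble::as_tibble(r)
}

#' Convert a potency measurement to the pPot scale
#'
#' pPot is the negative decadic logarithm of a molar potency, which places
#' Ki, IC50, EC50, Kb and Kd measurements on one common log scale. Values
#' already reported as logarithms (pKi, pIC50, pEC50, pKb, pKd, LogKi) are
#' returned unchanged; `LogKi` is interpreted as being on the pKi scale.
#'
#' @param value Numeric vector of measurements.
#' @param units Units for linear-scale types (`"nM"`, `"uM"`, `"mM"`, `"pM"`,
#'   `"M"`); ignored for log-scale types.
#' @param standard_type Potency type, recycled against `value`.
#' @return Numeric vector of pPot values.
#' @examples
#' to_ppot(10, "nM", "Ki")   # 8
#' to_ppot(7.5, "", "pKi")   # 7.5
#' @export
to_ppot <- function(value, units, standard_type) {
  n <- max(length(value), length(units), length(standard_type))
  value <- rep_len(value, n)
  units <- rep_len(as.character(units), n)
  standard_type <- rep_len(as.character(standard_type), n)
  is_log <- standard_type %in% POTENCY_TYPES_LOG
  is_lin <- standard_type %in% POTENCY_TYPES_LINEAR
  if (any(!is_log & !is_lin)) {
    stop("unknown standard_type: ",
         paste(unique(standard_type[!is_log & !is_lin]), collapse = ", "),
         call. = FALSE)
  }
  out <- numeric(n)
  out[is_log] <- value[is_log]
  if (any(is_lin)) {
    if (any(value[is_lin] <= 0 | !is.finite(value[is_lin]))) {
      stop("nonpositive potency", call. = FALSE)
    }
    mult <- UNIT_TO_MOLAR[units[is_lin]]
    if (anyNA(mult)) {
      stop("unknown units: ",
           paste(unique(units[is_lin][is.na(mult)]), collapse = ", "),
           call. = FALSE)
    }
    out[is_lin] <- -log10(value[is_lin] * unname(mult))
  }
  out
}

#' Aggregate replicate measurements per compound and target
#'
#' Converts each surviving record to pPot and collapses replicates to one
#' potency per (compound, target) pair. The median is the default aggregate:
#' it is robust to a single discordant replicate.
#'
#' @param records Filtered raw records.
#' @param method `"median"` (default) or `"mean"`.
#' @return A tibble with `compound_id`, `target_id`, `ppot`,
#'   `n_measurements`.
#' @export
aggregate_potency <- function(records, method = c("median", "mean")) {
  method <- match.arg(method)
  agg <- if (method == "median") stats::median else mean
  if (nrow(records) == 0) {
    return(tibble::tibble(compound_id = character(0), target_id = character(0),
                          ppot = numeric(0), n_measurements = integer(0)))
  }
  records |>
    dplyr::mutate(.ppot = to_ppot(.data$value, .data$units,
                                  .data$standard_type)) |>
    dplyr::summarise(
      ppot = agg(.data$.ppot),
      n_measurements = dplyr::n(),
      .by = c("compound_id", "target_id")
    ) |>
    tibble::as_tibble()
}
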