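# Synthetic ChEMBL-like activity tables with planted fluorine-isomer sets,
# cliffs, decoys and noise, plus a ground-truth manifest.

# Scaffold space: an amine-bearing tail prefixed to an aromatic ring system.
# Concatenating a prefix tail and a ring SMILES bonds the tail's last atom to
# the ring's first atom, so every combination is a valid structure.
SCAFFOLD_TAILS <- c("C", "CC", "OC", "CCN(C)C", "CN1CCN(CC1)C", "CC(=O)N",
                    "CCOC", "CN(C)C(=O)C")
SCAFFOLD_RINGS <- c("c1ccccc1", "c1cccnc1", "c1ccc2ccccc2c1",
                    "c1ccc2ncccc2c1", "c1cccs1", "c1ccc2scnc2c1")

scaffold_templates <- function() {
  grid <- expand.grid(ring = SCAFFOLD_RINGS, tail = SCAFFOLD_TAILS,
                      stringsAsFactors = FALSE)
  paste0(grid$tail, grid$ring)
}

# Decoy scaffolds use a tert-butyl-started tail reserved for them, so their
# defluorinated keys can never collide with planted scaffold keys.
decoy_template <- function(i) {
  ring <- SCAFFOLD_RINGS[(i - 1) %% length(SCAFFOLD_RINGS) + 1]
  paste0("CC(C)(C)", strrep("C", 1 + (i - 1) %/% length(SCAFFOLD_RINGS)), ring)
}

#' Configuration for the synthetic library generator
#'
#' Defaults emulate the statistical structure of a fluorine-scan SAR corpus:
#' small analog sets of two to four positional isomers, potencies on a
#' 5-10 pPot scale, a minority of sets carrying a planted activity cliff, and
#' sub-threshold potency spreads in the remaining sets.
#'
#' @param n_scaffolds Number of planted scaffolds (max 48).
#' @param positions_per_scaffold Integer range (length 2) of isomers per set.
#' @param fluorine_count Fluorines per compound (default 1).
#' @param targets_per_scaffold Integer range of targets annotated per
#'   scaffold.
#' @param base_ppot_range Range the per-(scaffold, target) base pPot is drawn
#'   from, in log units.
#' @param position_effect_sd SD of the per-position potency effect (log
#'   units).
#' @param planted_ac_fraction Fraction of (scaffold, target) sets designated
#'   as activity-cliff sets.
#' @param planted_ac_magnitude Potency drop (log units) planted at the cliff
#'   position; must reach the cliff threshold to be recoverable.
#' @param noise_sd SD of measurement noise added to observed values (log
#'   units).
#' @param decoy_fraction Decoy compounds (non-isomeric singletons) as a
#'   fraction of planted compounds.
#' @param flat_spread_max Cap on the true potency spread of non-cliff sets
#'   (default 0.3, the flat-trend threshold; set to `Inf` to disable).
#' @param seed Integer seed; the whole library is reproducible from it.
#' @return A `fisar_synth_config` list.
#' @export
synthetic_config <- function(n_scaffolds = 20,
                             positions_per_scaffold = c(2L, 4L),
                             fluorine_count = 1L,
                             targets_per_scaffold = c(1L, 3L),
                             base_ppot_range = c(5, 10),
                             position_effect_sd = 0.5,
                             planted_ac_fraction = 0.15,
                             planted_ac_magnitude = 2.0,
                             noise_sd = 0.1,
                             decoy_fraction = 0.1,
                             flat_spread_max = 0.3,
                             seed = 1L) {
  stopifnot(
    n_scaffolds >= 1, n_scaffolds <= length(scaffold_templates()),
    length(positions_per_scaffold) == 2,
    positions_per_scaffold[1] <= positions_per_scaffold[2],
    fluorine_count >= 1,
    length(targets_per_scaffold) == 2,
    planted_ac_fraction >= 0, planted_ac_fraction <= 1,
    planted_ac_magnitude > 0,
    noise_sd >= 0,
    decoy_fraction >= 0, decoy_fraction <= 1,
    flat_spread_max > 0
  )
  if (positions_per_scaffold[1] < 2) {
    stop("positions_per_scaffold must allow at least 2 isomers per set",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "fisar_synth_config")
}

#' Generate a synthetic activity library with ground truth
#'
#' Builds fluorine positional isomers on bundled scaffold templates, draws a
#' base potency per (scaffold, target) and a potency effect per fluorine
#' position, plants activity cliffs of stated magnitude in designated sets,
#' adds measurement noise and decoy compounds, and emits linear-scale Ki
#' records (nM) consistent with the true pPot values. A truth manifest
#' records planted memberships, cliff flags and true potencies for recovery
#' testing.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `fisar_simulation` with elements `records` (raw
#'   activity tibble in the layout of [read_activity_table()]) and `truth`
#'   (manifest: `scaffolds`, `members`, `set_truth`, `true_ppots`, `config`).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "fisar_synth_config"))
  withr::with_seed(config$seed, generate_library_impl(config))
}

generate_library_impl <- function(config) {
  templates <- scaffold_templates()[seq_len(config$n_scaffolds)]
  panel <- gpcr_subfamily_map()

  scaffolds <- vector("list", config$n_scaffolds)
  for (s in seq_len(config$n_scaffolds)) {
    placements <- enumerate_fluorine_placements(templates[s],
                                                config$fluorine_count)
    if (nrow(placements) < 2) {
      stop("scaffold ", templates[s], " has fewer than 2 distinct ",
           "fluorine placements", call. = FALSE)
    }
    k <- sample(seq(config$positions_per_scaffold[1],
                    config$positions_per_scaffold[2]), 1)
    k <- min(k, nrow(placements))
    idx <- sort(sample(nrow(placements), k))
    n_t <- sample(seq(config$targets_per_scaffold[1],
                      config$targets_per_scaffold[2]), 1)
    n_t <- min(n_t, nrow(panel))
    targets <- sort(sample(panel$target_id, n_t))
    scaffolds[[s]] <- list(
      idx = s, template = templates[s],
      members = tibble::tibble(
        compound_id = sprintf("S%03d-P%02d", s, idx),
        smiles = placements$isomer_smiles[idx]
      ),
      targets = targets
    )
  }

  members_rows <- list()
  set_rows <- list()
  ppot_rows <- list()
  for (sc in scaffolds) {
    k <- nrow(sc$members)
    for (t in sc$targets) {
      base <- stats::runif(1, config$base_ppot_range[1],
                           config$base_ppot_range[2])
      eff <- stats::rnorm(k, 0, config$position_effect_sd)
      is_ac <- stats::runif(1) < config$planted_ac_fraction
      cliff_compound <- NA_character_
      if (is_ac) {
        cliff <- sample(k, 1)
        eff[cliff] <- max(eff[-cliff]) - config$planted_ac_magnitude
        cliff_compound <- sc$members$compound_id[cliff]
      } else {
        spread <- max(eff) - min(eff)
        if (spread > config$flat_spread_max && is.finite(config$flat_spread_max)) {
          target_spread <- stats::runif(1, 0.3, 0.9) * config$flat_spread_max
          eff <- (eff - mean(eff)) * target_spread / spread
        }
      }
      true_ppot <- base + eff
      obs_ppot <- true_ppot + stats::rnorm(k, 0, config$noise_sd)
      members_rows[[length(members_rows) + 1]] <- tibble::tibble(
        scaffold_idx = sc$idx, target_id = t,
        compound_id = sc$members$compound_id,
        smiles = sc$members$smiles,
        true_effect = eff, true_ppot = true_ppot, obs_ppot = obs_ppot
      )
      set_rows[[length(set_rows) + 1]] <- tibble::tibble(
        scaffold_idx = sc$idx, target_id = t, n_members = k,
        is_ac = is_ac, cliff_compound = cliff_compound,
        true_max_abs_delta = max(true_ppot) - min(true_ppot)
      )
    }
  }
  members <- dplyr::bind_rows(members_rows)
  set_truth <- dplyr::bind_rows(set_rows)

  n_planted_compounds <- dplyr::n_distinct(members$compound_id)
  n_decoys <- round(config$decoy_fraction * n_planted_compounds)
  decoys <- NULL
  if (n_decoys > 0) {
    decoys <- purrr::map(seq_len(n_decoys), function(i) {
      scaffold <- decoy_template(i)
      smi <- scaffold
      fluorinated <- i %% 2 == 1
      if (fluorinated) {
        pl <- enumerate_fluorine_placements(scaffold, 1L)
        smi <- pl$isomer_smiles[1]
      }
      tibble::tibble(
        compound_id = sprintf("DCY-%03d", i), smiles = smi,
        target_id = sample(panel$target_id, 1),
        obs_ppot = stats::runif(1, config$base_ppot_range[1],
                                config$base_ppot_range[2])
      )
    }) |>
      dplyr::bind_rows()
  }

  as_record <- function(compound_id, smiles, target_id, obs_ppot) {
    tibble::tibble(
      compound_id = compound_id, smiles = smiles, target_id = target_id,
      standard_type = "Ki", relation = "=",
      value = 10^(9 - obs_ppot), units = "nM",
      confidence_score = 9L, relationship_type = "D"
    )
  }
  records <- as_record(members$compound_id, members$smiles,
                       members$target_id, members$obs_ppot)
  if (!is.null(decoys)) {
    records <- dplyr::bind_rows(
      records,
      as_record(decoys$compound_id, decoys$smiles, decoys$target_id,
                decoys$obs_ppot)
    )
  }

  truth <- list(
    scaffolds = tibble::tibble(
      scaffold_idx = purrr::map_int(scaffolds, "idx"),
      scaffold_smiles = purrr::map_chr(scaffolds, "template")
    ),
    members = members,
    set_truth = set_truth,
    true_ppots = dplyr::select(members, "compound_id", "target_id",
                               "true_ppot"),
    decoys = decoys,
    config = config
  )
  structure(list(records = records, truth = truth),
            class = "fisar_simulation")
}

#' @export
print.fisar_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic activity library: %d records, %d planted sets (%d with cliffs), %d decoys\n",
    nrow(x$records), nrow(x$truth$set_truth), sum(x$truth$set_truth$is_ac),
    if (is.null(x$truth$decoys)) 0L else nrow(x$truth$decoys)))
  invisible(x)
}

#' Worked-example analog sets
#'
#' Two bundled fixtures reproducing published potency vectors of exemplary
#' fluorine-isomer analog sets: a muscarinic M1 set of five isomers and a
#' serotonin 5-HT2a set of three (both containing an activity cliff), and a
#' three-target serotonin set of four isomers measured on 5-HT1b, 5-HT1d and
#' 5-HT1a (where only the 5-HT1a set contains a cliff). The structures are
#' synthetic placeholders (fluorine scans of quinoline, phenylpiperazine and
#' methylnaphthalene); the potency vectors are the published ones.
#'
#' @return A list with `table_one` and `table_two`, each a long-format set
#'   table as produced by [mine_fisar_sets()].
#' @export
worked_example_tables <- function() {
  build_set <- function(scaffold, target_id, prefix, ppots) {
    pl <- enumerate_fluorine_placements(scaffold, 1L)
    stopifnot(nrow(pl) >= length(ppots))
    smiles <- pl$isomer_smiles[seq_along(ppots)]
    key <- paste(canonical_smiles(scaffold), 1L, sep = "|")
    tibble::tibble(
      set_id = fisar_set_id(key, target_id),
      target_id = target_id,
      defluor_smiles = canonical_smiles(scaffold),
      fluorine_count = 1L,
      compound_id = sprintf("%s-%d", prefix, seq_along(ppots)),
      canonical_smiles = smiles,
      ppot = ppots
    )
  }
  table_one <- dplyr::bind_rows(
    build_set("c1ccc2ncccc2c1", "CHRM1", "M1",
              c(8.10, 7.90, 7.60, 6.30, 5.60)),
    build_set("C1CN(CCN1)c1ccccc1", "HTR2A", "HT2A", c(8.82, 7.80, 6.49))
  )
  table_two <- dplyr::bind_rows(
    build_set("Cc1cccc2ccccc12", "HTR1B", "T2", c(9.10, 8.60, 7.70, 7.50)),
    build_set("Cc1cccc2ccccc12", "HTR1D", "T2", c(9.40, 9.10, 8.50, 8.60)),
    build_set("Cc1cccc2ccccc12", "HTR1A", "T2", c(8.30, 8.60, 9.30, 7.30))
  )
  list(table_one = table_one, table_two = table_two)
}
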