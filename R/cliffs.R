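# Activity-cliff detection and potency-trend classification within
# fluorine-isomer analog sets.

#' Annotate analog sets with potency differences and activity cliffs
#'
#' Within each set, potency differences (delta pPot) are computed against the
#' most potent member, so every delta is <= 0 and the reference carries 0.
#' A set is an activity cliff (AC) set when the largest absolute difference
#' reaches `ac_threshold` (1.7 log units, about a 50-fold potency change; the
#' usual 2.0 MMP-cliff criterion is relaxed because a fluorine shift is a
#' minimal structural change). Sets whose spread stays within
#' `trend_threshold` (0.3 log units, about 2-fold) are classified as `flat`,
#' all others as `significant`.
#'
#' @param sets Long-format set table from [mine_fisar_sets()] (needs
#'   `set_id`, `target_id`, `compound_id`, `ppot`).
#' @param ac_threshold Activity-cliff threshold on |delta pPot| (default 1.7).
#' @param trend_threshold Flat-trend threshold on |delta pPot| (default 0.3).
#' @param pairwise If `TRUE`, `max_abs_delta` additionally considers all
#'   member pairs; with a single reference this equals the max-vs-min spread,
#'   so the flag only changes which deltas are reported, not the AC calls.
#' @return A tibble with one row per set member: the member columns plus
#'   `delta_ppot`, `reference_compound`, `max_abs_delta`, `is_ac`, `trend`.
#'   Ties for the reference are broken by the lexicographically smallest
#'   compound identifier.
#' @examples
#' sets <- tibble::tibble(
#'   set_id = "s1", target_id = "M1",
#'   compound_id = paste0("c", 1:5),
#'   ppot = c(8.10, 7.90, 7.60, 6.30, 5.60)
#' )
#' annotate_cliffs(sets)
#' @export
annotate_cliffs <- function(sets, ac_threshold = 1.7, trend_threshold = 0.3,
                            pairwise = FALSE) {
  stopifnot(ac_threshold > 0, trend_threshold > 0)
  if (nrow(sets) == 0) {
    out <- dplyr::mutate(sets, delta_ppot = numeric(0),
                         reference_compound = character(0),
                         max_abs_delta = numeric(0), is_ac = logical(0),
                         trend = character(0))
    class(out) <- c("fisar_cliffs", class(out))
    return(out)
  }
  out <- sets |>
    dplyr::mutate(
      reference_compound = {
        top <- .data$ppot == max(.data$ppot)
        min(.data$compound_id[top])
      },
      delta_ppot = .data$ppot - max(.data$ppot),
      max_abs_delta = max(.data$ppot) - min(.data$ppot),
      .by = "set_id"
    ) |>
    dplyr::mutate(
      is_ac = .data$max_abs_delta >= ac_threshold,
      trend = ifelse(.data$max_abs_delta <= trend_threshold,
                     "flat", "significant")
    )
  out <- tibble::as_tibble(out)
  class(out) <- c("fisar_cliffs", class(out))
  out
}

#' Potency fold change of a log-scale difference
#'
#' @param delta_ppot Numeric vector of pPot differences.
#' @return `10^|delta_ppot|`, the corresponding potency fold change
#'   (1.7 -> ~50-fold, 0.3 -> ~2-fold).
#' @export
fold_change <- function(delta_ppot) 10^abs(delta_ppot)

#' Summarize cliff annotations across sets
#'
#' Counts analog sets overall and per fold-change tier, and tallies compounds
#' and sets per target. Default tiers are 10-fold (1.0), 30-fold (1.48) and
#' 50-fold (1.7) potency changes.
#'
#' @param annotations Output of [annotate_cliffs()].
#' @param tiers Numeric |delta pPot| thresholds for the tier counts.
#' @return An object of class `fisar_cliff_summary`; see [tidy()] and
#'   [glance()] methods.
#' @export
summarize_cliffs <- function(annotations, tiers = c(1.0, 1.48, 1.7)) {
  per_set <- dplyr::distinct(annotations, .data$set_id, .data$target_id,
                             .data$max_abs_delta, .data$is_ac, .data$trend)
  if (anyDuplicated(per_set$set_id)) {
    stop("annotations contain conflicting rows for the same set_id",
         call. = FALSE)
  }
  tier_counts <- tibble::tibble(
    threshold = sort(tiers),
    fold_change = 10^sort(tiers),
    n_sets = vapply(sort(tiers),
                    function(th) sum(per_set$max_abs_delta >= th), integer(1))
  )
  per_target <- annotations |>
    dplyr::summarise(
      n_compounds = dplyr::n_distinct(.data$compound_id),
      n_sets = dplyr::n_distinct(.data$set_id),
      .by = "target_id"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_compounds))
  structure(
    list(
      n_sets = nrow(per_set),
      n_ac_sets = sum(per_set$is_ac),
      n_significant_trend = sum(per_set$trend == "significant"),
      n_flat_trend = sum(per_set$trend == "flat"),
      fold_tier_counts = tier_counts,
      per_target_counts = tibble::as_tibble(per_target)
    ),
    class = "fisar_cliff_summary"
  )
}

#' @export
print.fisar_cliff_summary <- function(x, ...) {
  cat("Fluorine-isomer analog set summary\n")
  cat(sprintf("  sets: %d  (AC: %d, significant trend: %d, flat: %d)\n",
              x$n_sets, x$n_ac_sets, x$n_significant_trend, x$n_flat_trend))
  cat("  fold-change tiers:\n")
  with(x$fold_tier_counts,
       cat(sprintf("    |dpPot| >= %.2f (%5.1f-fold): %d sets\n",
                   threshold, fold_change, n_sets), sep = ""))
  invisible(x)
}

#' @rdname summarize_cliffs
#' @param x A `fisar_cliff_summary` object.
#' @param ... Unused.
#' @method tidy fisar_cliff_summary
#' @export
tidy.fisar_cliff_summary <- function(x, ...) x$fold_tier_counts

#' @rdname summarize_cliffs
#' @method glance fisar_cliff_summary
#' @export
glance.fisar_cliff_summary <- function(x, ...) {
  tibble::tibble(
    n_sets = x$n_sets, n_ac_sets = x$n_ac_sets,
    n_significant_trend = x$n_significant_trend,
    n_flat_trend = x$n_flat_trend,
    prop_significant = if (x$n_sets > 0) x$n_significant_trend / x$n_sets
                       else NA_real_
  )
}

#' Concordance of a computed ranking with experimental potencies
#'
#' Compares computed relative binding free energies (delta delta G, more
#' negative = predicted tighter binding relative to the reference) against
#' experimental potencies on the pPot scale. Correlations are computed
#' between pPot and -ddG so that a perfect prediction gives +1.
#'
#' @param experimental Data frame with `compound_id` and `ppot`, or a named
#'   numeric vector of pPots.
#' @param computed Data frame with `compound_id` and `ddg`, or a named
#'   numeric vector of delta delta G values.
#' @return An object of class `fisar_concordance` with Kendall's tau,
#'   Spearman's rho, top-1 agreement, and a degeneracy flag (constant input:
#'   correlations are reported as 0 with `degenerate = TRUE`). Rank
#'   correlations require at least 3 compounds; below that only top-1
#'   agreement is reported.
#' @export
compare_rankings <- function(experimental, computed) {
  as_map <- function(x, value_col) {
    if (is.numeric(x) && !is.null(names(x))) {
      tibble::tibble(compound_id = names(x), value = unname(x))
    } else {
      tibble::tibble(compound_id = as.character(x$compound_id),
                     value = x[[value_col]])
    }
  }
  exp_df <- as_map(experimental, "ppot")
  cmp_df <- as_map(computed, "ddg")
  if (length(intersect(exp_df$compound_id, cmp_df$compound_id)) == 0) {
    stop("experimental and computed rankings share no compounds",
         call. = FALSE)
  }
  diff_keys <- c(setdiff(exp_df$compound_id, cmp_df$compound_id),
                 setdiff(cmp_df$compound_id, exp_df$compound_id))
  if (length(diff_keys) > 0) {
    stop("rankings must cover the same compounds; differing: ",
         paste(diff_keys, collapse = ", "), call. = FALSE)
  }
  m <- dplyr::inner_join(exp_df, cmp_df, by = "compound_id",
                         suffix = c("_exp", "_cmp"))
  n <- nrow(m)
  degenerate <- stats::sd(m$value_exp) == 0 || stats::sd(m$value_cmp) == 0
  tau <- rho <- NA_real_
  if (n >= 3) {
    if (degenerate) {
      tau <- 0
      rho <- 0
    } else {
      tau <- stats::cor(m$value_exp, -m$value_cmp, method = "kendall")
      rho <- stats::cor(m$value_exp, -m$value_cmp, method = "spearman")
    }
  }
  top_exp <- m$compound_id[m$value_exp == max(m$value_exp)]
  top_cmp <- m$compound_id[m$value_cmp == min(m$value_cmp)]
  structure(
    list(n = n, kendall_tau = tau, spearman_rho = rho,
         top1_agreement = length(intersect(top_exp, top_cmp)) > 0,
         degenerate = degenerate,
         sign_convention = "correlations computed between pPot and -ddG"),
    class = "fisar_concordance"
  )
}

#' @export
print.fisar_concordance <- function(x, ...) {
  cat(sprintf(
    "Ranking concordance over %d compounds\n  Kendall tau: %s  Spearman rho: %s  top-1 agreement: %s%s\n  (%s)\n",
    x$n, format(x$kendall_tau, digits = 3), format(x$spearman_rho, digits = 3),
    x$top1_agreement, if (x$degenerate) "  [degenerate]" else "",
    x$sign_convention))
  invisible(x)
}

#' @rdname compare_rankings
#' @param x A `fisar_concordance` object.
#' @param ... Unused.
#' @method glance fisar_concordance
#' @export
glance.fisar_concordance <- function(x, ...) {
  tibble::tibble(n = x$n, kendall_tau = x$kendall_tau,
                 spearman_rho = x$spearman_rho,
                 top1_agreement = x$top1_agreement,
                 degenerate = x$degenerate)
}

#' Waterfall plot of within-set potency differences
#'
#' @param object Output of [annotate_cliffs()].
#' @param ac_threshold Threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object: one panel per set, bars of delta pPot per member.
#' @method autoplot fisar_cliffs
#' @export
autoplot.fisar_cliffs <- function(object, ac_threshold = 1.7, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$compound_id,
                                                  -.data$delta_ppot),
                               y = .data$delta_ppot,
                               fill = .data$delta_ppot <= -ac_threshold)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -ac_threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~set_id, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(Delta * pPot)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
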