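set_fixture <- function(ppots, set_id = "s1", target_id = "T1") {
  tibble::tibble(set_id = set_id, target_id = target_id,
                 compound_id = sprintf("%s-c%d", set_id, seq_along(ppots)),
                 ppot = ppots)
}

test_that("within-set deltas are taken against the most potent member", {
  ann <- annotate_cliffs(set_fixture(c(8.10, 7.90, 7.60, 6.30, 5.60)))
  expect_equal(sort(round(ann$delta_ppot, 10)),
               c(-2.5, -1.8, -0.5, -0.2, 0))
  expect_true(all(ann$delta_ppot <= 0))
  expect_true(all(ann$is_ac))
  expect_equal(unique(ann$reference_compound), "s1-c1")
  expect_equal(unique(ann$trend), "significant")
})

test_that("flat sets and reference ties are handled deterministically", {
  ann <- annotate_cliffs(set_fixture(c(7, 7, 7)))
  expect_equal(ann$delta_ppot, c(0, 0, 0))
  expect_false(any(ann$is_ac))
  expect_equal(unique(ann$trend), "flat")
  expect_equal(unique(ann$reference_compound), "s1-c1")  # lexicographic tie
  ann2 <- annotate_cliffs(set_fixture(c(7, 7.2, 7.2)))
  expect_equal(unique(ann2$reference_compound), "s1-c2")
})

test_that("annotation is invariant to member order", {
  s <- set_fixture(c(9.3, 8.6, 8.3, 7.3))
  a1 <- annotate_cliffs(s)
  a2 <- annotate_cliffs(s[c(4, 2, 1, 3), ])
  expect_identical(dplyr::arrange(tibble::as_tibble(a1), compound_id),
                   dplyr::arrange(tibble::as_tibble(a2), compound_id))
})

test_that("fold-change matches the log-scale equivalences", {
  expect_equal(round(fold_change(1.7)), 50)
  expect_equal(round(fold_change(0.3)), 2)
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(-2), 100)  # sign-free
})

test_that("the cliff flag tracks the 50-fold equivalence at the default", {
  for (delta in c(1.2, 1.6999, 1.7, 1.8, 2.5)) {
    ann <- annotate_cliffs(set_fixture(c(8, 8 - delta)))
    expect_identical(
      unique(ann$is_ac),
      fold_change(unique(ann$max_abs_delta)) >= fold_change(1.7) - 1e-9)
  }
})

test_that("raising the cliff threshold never adds cliff sets", {
  sets <- dplyr::bind_rows(lapply(1:8, function(i) {
    set_fixture(c(8, 8 - i * 0.35), set_id = paste0("s", i))
  }))
  counts <- vapply(seq(0.5, 3, by = 0.25), function(th) {
    sum(dplyr::distinct(annotate_cliffs(sets, ac_threshold = th),
                        set_id, is_ac)$is_ac)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summaries count sets per fold-change tier", {
  sets <- dplyr::bind_rows(
    set_fixture(c(8.10, 7.90, 7.60, 6.30, 5.60), "m1"),
    set_fixture(c(8.82, 7.80, 6.49), "ht2a")
  )
  s <- summarize_cliffs(annotate_cliffs(sets))
  expect_equal(s$n_sets, 2)
  expect_equal(s$n_ac_sets, 2)
  expect_true(all(diff(s$fold_tier_counts$n_sets) <= 0))
  g <- glance(s)
  expect_equal(g$n_ac_sets, 2)
  expect_equal(tidy(s)$threshold, c(1.0, 1.48, 1.7))
  lone <- summarize_cliffs(annotate_cliffs(set_fixture(c(8, 7.5))),
                           tiers = 1.0)
  expect_equal(lone$fold_tier_counts$n_sets, 0L)
})

test_that("ranking concordance handles monotone, degenerate and small cases", {
  pp <- c(a = 9.0, b = 8.2, c = 7.5, d = 6.9)
  perfect <- compare_rankings(pp, c(a = -3, b = -2, c = -1, d = 0))
  expect_equal(perfect$kendall_tau, 1)
  expect_equal(perfect$spearman_rho, 1)
  expect_true(perfect$top1_agreement)

  flat <- compare_rankings(pp, c(a = 1, b = 1, c = 1, d = 1))
  expect_true(flat$degenerate)
  expect_equal(flat$kendall_tau, 0)

  tiny <- compare_rankings(pp[1:2], c(a = -1, b = 0))
  expect_true(is.na(tiny$kendall_tau))
  expect_true(tiny$top1_agreement)

  expect_error(compare_rankings(pp, c(x = 1, y = 2)), "no compounds")
  expect_error(compare_rankings(pp, c(a = 1, b = 2, c = 3)), "differing")
})

test_that("Kendall tau matches a brute-force pair-count oracle", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- sample(4:8, 1)
      pp <- stats::setNames(runif(n, 5, 10), paste0("c", seq_len(n)))
      ddg <- stats::setNames(sample(seq_len(n)) + rnorm(n, 0, 0.1),
                             names(pp))
      got <- compare_rankings(pp, ddg)$kendall_tau
      expect_equal(got, kendall_tau_oracle(unname(pp), -unname(ddg)),
                   tolerance = 1e-12)
    }
  })
})
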