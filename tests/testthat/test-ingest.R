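test_that("record filters keep exactly the curated subset, in order", {
  recs <- dplyr::bind_rows(
    make_record("c1", "CCO", "T1", 10),                       # keep
    make_record("c2", "CCO", "T1", 10, relation = ">"),       # relation
    make_record("c3", "CCO", "T1", 10, relationship_type = "H"),
    make_record("c4", "CCO", "T1", 10, confidence_score = 8L),
    make_record("c5", "CCO", "T1", 7.5, standard_type = "pKi",
                units = ""),                                   # keep
    make_record("c6", "CCO", "T1", 10, standard_type = "Potency"),
    make_record("c7", "CCO", "T1", -4),                        # bad value
    make_record("c8", "CCO", "T1", 25)                         # keep
  )
  suppressWarnings(kept <- filter_records(recs, quiet = TRUE))
  expect_identical(kept$compound_id, c("c1", "c5", "c8"))
  expect_warning(
    expect_warning(filter_records(recs, quiet = TRUE),
                   "unknown standard_type"),
    "malformed value")
})

test_that("filtering is idempotent and returns a subset of its input", {
  recs <- dplyr::bind_rows(
    make_record(paste0("c", 1:4), "CCO", "T1", c(1, 10, 100, 1000)),
    make_record("c5", "CCO", "T2", 3, relation = "<")
  )
  once <- filter_records(recs, quiet = TRUE)
  twice <- filter_records(once, quiet = TRUE)
  expect_identical(once, twice)
  expect_true(all(once$compound_id %in% recs$compound_id))
  expect_identical(nrow(filter_records(recs[0, ], quiet = TRUE)), 0L)
})

test_that("pPot standardization matches hand-computed values", {
  expect_equal(to_ppot(10, "nM", "Ki"), 8)
  expect_equal(to_ppot(3, "nM", "EC50"), 8.52, tolerance = 0.005 / 8.52)
  expect_equal(to_ppot(7.5, "", "pKi"), 7.5)
  expect_equal(to_ppot(1, "uM", "IC50"), 6)
  expect_equal(to_ppot(c(10, 6.2), c("nM", ""), c("Kd", "LogKi")),
               c(8, 6.2))
  expect_error(to_ppot(-1, "nM", "Ki"), "nonpositive potency")
  expect_error(to_ppot(10, "mg/mL", "Ki"), "unknown units")
  expect_error(to_ppot(10, "nM", "Potency"), "unknown standard_type")
})

test_that("pPot conversion is strictly decreasing and round-trips", {
  withr::with_seed(11, {
    p <- sort(runif(25, 3, 11))
    nm <- 10^(9 - p)
    expect_equal(to_ppot(nm, rep("nM", 25), rep("Ki", 25)), p,
                 tolerance = 1e-9)
    back <- to_ppot(sort(nm), rep("nM", 25), rep("IC50", 25))
    expect_true(all(diff(back) < 0))  # larger concentration, lower pPot
  })
})

test_that("replicates aggregate to one potency per compound-target pair", {
  recs <- dplyr::bind_rows(
    make_record("c1", "CCO", "T1", 8.0, standard_type = "pKi", units = ""),
    make_record("c1", "CCO", "T1", 8.4, standard_type = "pKi", units = ""),
    make_record("c1", "CCO", "T2", 10),
    make_record("c2", "CCO", "T1", 100)
  )
  agg <- aggregate_potency(recs)
  expect_equal(nrow(agg), 3)
  c1t1 <- agg[agg$compound_id == "c1" & agg$target_id == "T1", ]
  expect_equal(c1t1$ppot, 8.2)
  expect_equal(c1t1$n_measurements, 2L)
  expect_equal(agg$n_measurements[agg$target_id == "T2"], 1L)
  # output pair set equals distinct input pair set
  expect_identical(
    dplyr::arrange(dplyr::distinct(recs[, c("compound_id", "target_id")]),
                   compound_id, target_id),
    dplyr::arrange(agg[, c("compound_id", "target_id")],
                   compound_id, target_id)
  )
  # median is robust where mean is not
  recs3 <- make_record(rep("c9", 3), "CCO", "T1", c(8, 8.1, 3),
                       standard_type = "pKi", units = "")
  expect_equal(aggregate_potency(recs3)$ppot, 8)
  expect_equal(aggregate_potency(recs3, method = "mean")$ppot,
               mean(c(8, 8.1, 3)))
})

test_that("activity tables read with column remapping and delimiter guess", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- make_record("c1", "CCO", "T1", 10)
  names(df)[1] <- "molecule_chembl_id"
  readr::write_csv(df, tmp)
  got <- read_activity_table(tmp,
                             col_map = c(compound_id = "molecule_chembl_id"))
  expect_equal(got$compound_id, "c1")
  expect_equal(got$value, 10)
  expect_error(read_activity_table(tmp), "compound_id")
})
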