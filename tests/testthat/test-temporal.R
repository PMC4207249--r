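test_that("exactly 14 ordered intervals with saturating edges", {
  labels <- interval_labels()
  expect_length(labels, 14L)
  expect_equal(labels[1], "2000")
  expect_equal(labels[14], ">2012")
  got <- assign_interval(c(1997L, 1981L, 2000L, 2001L, 2005L, 2012L, 2013L, 2020L))
  expect_equal(as.character(got),
               c("2000", "2000", "2000", "2001", "2005", "2012", ">2012", ">2012"))
  expect_true(is.ordered(got))
  expect_true(all(diff(as.integer(assign_interval(1995:2020))) >= 0))
})

test_that("the three-target worked example yields rates 1, 2, 3", {
  p <- build_cumulative_profiles(worked_example_interactions())
  rate_at <- function(int) {
    p$profile$n_targets[p$profile$interval == int]
  }
  expect_equal(rate_at("2001"), 1L)
  expect_equal(rate_at("2004"), 1L)
  expect_equal(rate_at("2005"), 2L)
  expect_equal(rate_at("2008"), 2L)
  expect_equal(rate_at("2009"), 3L)
  expect_equal(rate_at(">2012"), 3L)
  expect_equal(as.character(p$summary$entry_interval), "2001")
  # the drug is absent from intervals before entry
  expect_false("2000" %in% as.character(p$profile$interval))
})

test_that("a target reported twice counts once, from its first interval", {
  di <- tibble::tibble(drug_id = "D", target_id = c("A", "A"),
                       first_year = c(2003L, 2007L))
  p <- build_cumulative_profiles(di)
  expect_equal(p$summary$final_rate, 1L)
  expect_equal(as.character(p$summary$entry_interval), "2003")
})

test_that("pre-2000 single-target drugs enter at interval 2000 with rate 1", {
  di <- tibble::tibble(drug_id = "D", target_id = "A", first_year = 1981L)
  p <- build_cumulative_profiles(di)
  expect_equal(nrow(p$profile), 14L)  # present in all 14 intervals
  expect_true(all(p$profile$n_targets == 1L))
  expect_equal(as.character(p$summary$entry_interval), "2000")
})

test_that("record spans use raw years, not interval labels", {
  di <- tibble::tibble(
    drug_id = c("captopril-like", "single", "late"),
    target_id = "A",
    first_year = c(1981L, 2004L, 2002L),
    last_year = c(2005L, 2004L, 2012L)
  )
  spans <- record_span(build_cumulative_profiles(di))
  expect_equal(spans$span_years[spans$drug_id == "captopril-like"], 24L)
  expect_equal(spans$span_years[spans$drug_id == "single"], 0L)
  expect_equal(spans$span_years[spans$drug_id == "late"], 10L)
})

test_that("cumulative drug counts accumulate entry intervals", {
  di <- tibble::tibble(
    drug_id = c("D1", "D2", "D3"), target_id = "A",
    first_year = c(2000L, 1998L, 2005L)
  )
  counts <- cumulative_drug_counts(build_cumulative_profiles(di))
  expect_equal(counts$n_drugs, c(2L, 2L, 2L, 2L, 2L, rep(3L, 9)))
  expect_true(all(diff(counts$n_drugs) >= 0))
})

test_that("profiles are monotone, order-invariant and match the brute-force oracle", {
  for (seed in c(2L, 9L)) {
    ds <- small_dataset(seed = seed)
    act <- with_nM(ds$activities)
    act$canonical_smiles <- standardize_structure(act$smiles)
    ints <- curate_interactions(act, "high")
    drugs <- ds$drugs
    drugs$canonical_smiles <- standardize_structure(drugs$smiles)
    di <- match_drugs_to_compounds(drugs, ints)$drug_interactions

    p <- build_cumulative_profiles(di)
    # monotone non-decreasing target sets per drug
    mono <- p$profile |>
      dplyr::summarise(ok = all(diff(n_targets) >= 0),
                       .by = "drug_id")
    expect_true(all(mono$ok))

    # brute-force oracle: rescan all records for every interval
    oracle <- brute_force_profile(di)
    got <- p$profile |>
      dplyr::mutate(interval = as.character(interval)) |>
      dplyr::arrange(drug_id, match(interval, interval_labels()))
    oracle <- oracle |>
      dplyr::arrange(drug_id, match(interval, interval_labels()))
    expect_equal(got, oracle)

    # permutation invariance
    set.seed(seed)
    p2 <- build_cumulative_profiles(di[sample(nrow(di)), ])
    expect_equal(p$profile, p2$profile)
    expect_equal(p$summary, p2$summary)
  }
})

test_that("drugs without dated interactions are excluded with a warning", {
  di <- tibble::tibble(drug_id = c("D1", "D2"), target_id = "A",
                       first_year = c(2005L, NA))
  expect_warning(p <- build_cumulative_profiles(di), "without dated")
  expect_equal(p$summary$drug_id, "D1")
  expect_error(
    suppressWarnings(build_cumulative_profiles(di[2, ])), "no dated"
  )
})
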