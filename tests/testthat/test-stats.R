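# Build a profiles object whose final-interval rates are exactly `rates`,
# with every drug entering at "2000".
profiles_with_rates <- function(rates) {
  di <- dplyr::bind_rows(lapply(seq_along(rates), function(i) {
    tibble::tibble(
      drug_id = sprintf("D%03d", i),
      target_id = sprintf("T%03d", seq_len(rates[i])),
      first_year = 2000L
    )
  }))
  build_cumulative_profiles(di)
}

test_that("interval distributions report five-number summary plus mean", {
  p <- profiles_with_rates(c(1, 1, 2, 10))
  d <- interval_distribution(p, "2000")
  expect_equal(d$n_drugs, 4L)
  expect_equal(d$median, 1.5)
  expect_equal(d$mean, 3.5)

  # heavy tail: a few promiscuous drugs lift the mean but not the median
  p2 <- profiles_with_rates(c(rep(1, 90), rep(20, 10)))
  d2 <- interval_distribution(p2, "2000")
  expect_equal(d2$median, 1)
  expect_equal(d2$mean, 2.9)

  p3 <- profiles_with_rates(3)
  d3 <- interval_distribution(p3, "2000")
  expect_equal(unlist(d3[c("min", "lower_quartile", "median",
                           "upper_quartile", "max", "mean")]),
               c(min = 3, lower_quartile = 3, median = 3,
                 upper_quartile = 3, max = 3, mean = 3))

  expect_error(interval_distribution(p, "1999"), "unknown interval")
})

test_that("summary statistics stay within the observed rate range", {
  ds <- small_dataset(seed = 13L)
  act <- with_nM(ds$activities)
  act$canonical_smiles <- standardize_structure(act$smiles)
  drugs <- ds$drugs
  drugs$canonical_smiles <- standardize_structure(drugs$smiles)
  di <- match_drugs_to_compounds(drugs, curate_interactions(act, "high"))$drug_interactions
  d <- interval_distribution(build_cumulative_profiles(di))
  expect_true(all(d$min <= d$lower_quartile))
  expect_true(all(d$lower_quartile <= d$median))
  expect_true(all(d$median <= d$upper_quartile))
  expect_true(all(d$upper_quartile <= d$max))
  expect_true(all(d$mean >= d$min & d$mean <= d$max))
})

test_that("promiscuity increase is final minus entry rate, never negative", {
  p <- build_cumulative_profiles(worked_example_interactions())
  expect_equal(promiscuity_increase(p)$increase, 2L)

  constant <- profiles_with_rates(1)
  expect_equal(promiscuity_increase(constant)$increase, 0L)

  # imatinib-like trajectory: one target in 2002 growing to 24 by >2012
  di <- tibble::tibble(
    drug_id = "imatinib-like",
    target_id = sprintf("T%02d", 1:24),
    first_year = c(2002L, sample(c(2003:2014), 23, replace = TRUE))
  )
  p3 <- build_cumulative_profiles(di)
  expect_equal(promiscuity_increase(p3)$increase, 23L)
})

test_that("increase histograms conserve counts and match table formatting", {
  # the published distribution: 282 of 518 drugs with no increase
  counts <- c(282, 84, 44, 39, 15, 15, 5, 8, 6, 6, 8, 6)
  increases <- rep(c(0:10, 12), counts)
  h <- increase_histogram(increases, max_bin = 10L)
  expect_equal(sum(h$n), 518L)
  expect_equal(h$pct[h$increase == "0"], 54.4)
  expect_equal(h$n[h$increase == ">10"], 6L)

  h0 <- increase_histogram(rep(0L, 25))
  expect_equal(h0$pct[h0$increase == "0"], 100.0)
  expect_equal(sum(h0$n), 25L)

  set.seed(1)
  random <- rpois(200, 3)
  expect_equal(sum(increase_histogram(random)$n), 200L)
  expect_error(increase_histogram(integer()))
})

test_that("family profiles count distinct families over time", {
  # imatinib's published family profile: 24 targets across 7 families
  fams <- c("ATP binding cassette transporters", "Carbonic anhydrases",
            "Multi antimicrobial extrusion (MATE) transporters",
            "NAD(P)H dehydrogenases (quinone)", "Organic cation transporters",
            "Ser_Thr protein kinases", "Tyr protein kinases")
  # first record in the Tyr kinase family, the rest accruing later
  family_of_target <- c("Tyr protein kinases",
                        sample(fams, 23, replace = TRUE))
  family_of_target <- replace(family_of_target, 2:8, fams)  # ensure all seen
  di <- tibble::tibble(
    drug_id = "imatinib-like", target_id = sprintf("T%02d", 1:24),
    first_year = c(2002L, rep(2005:2014, length.out = 23))
  )
  p <- build_cumulative_profiles(di)
  fm <- tibble::tibble(target_id = di$target_id, family = family_of_target)
  fp <- family_promiscuity(p, fm)
  expect_equal(fp$increase$final_families, 7L)
  expect_equal(fp$first_family$family, "Tyr protein kinases")
  # family count never exceeds target count at any interval
  joined <- dplyr::inner_join(fp$per_interval, p$profile,
                              by = c("drug_id", "interval"))
  expect_true(all(joined$n_families <= joined$n_targets))
})

test_that("one-family drugs show zero family increase despite target growth", {
  di <- tibble::tibble(drug_id = "D", target_id = c("A", "B", "C"),
                       first_year = c(2001L, 2005L, 2009L))
  fm <- tibble::tibble(target_id = c("A", "B", "C"), family = "Monoamine GPCRs")
  fp <- family_promiscuity(build_cumulative_profiles(di), fm)
  expect_equal(fp$increase$increase, 0L)
  # unmapped targets fall back to "unassigned"
  fp2 <- family_promiscuity(build_cumulative_profiles(di), fm[1:2, ])
  expect_setequal(unique(fp2$per_interval$n_families), c(1L, 2L))
})

test_that("cross-database comparison counts both sides and their overlap", {
  db <- tibble::tibble(drug_id = "D",
                       target_id = sprintf("P%02d", 1:10))
  act <- tibble::tibble(drug_id = "D",
                        target_id = sprintf("P%02d", 5:10))
  cmp <- compare_profiles(db, act)
  expect_equal(cmp$n_db_targets, 10L)
  expect_equal(cmp$n_activity_targets, 6L)
  expect_equal(cmp$delta, 4L)
  expect_equal(cmp$n_common, 6L)

  same <- compare_profiles(db, db)
  expect_equal(same$delta, 0L)
  expect_equal(same$n_common, 10L)

  disjoint <- compare_profiles(
    tibble::tibble(drug_id = "D", target_id = c("A", "B")),
    tibble::tibble(drug_id = "D", target_id = "C")
  )
  expect_equal(disjoint$n_common, 0L)
  expect_equal(disjoint$delta, 1L)
})

test_that("overlap never exceeds either side on random set pairs", {
  set.seed(99)
  for (i in 1:50) {
    universe <- sprintf("P%03d", 1:30)
    db <- tibble::tibble(drug_id = "D",
                         target_id = sample(universe, sample(1:20, 1)))
    act <- tibble::tibble(drug_id = "D",
                          target_id = sample(universe, sample(1:20, 1)))
    cmp <- compare_profiles(db, act)
    expect_lte(cmp$n_common, min(cmp$n_db_targets, cmp$n_activity_targets))
  }
})

test_that("potency box statistics use 1.5 IQR whiskers and list outliers", {
  ints <- tibble::tibble(
    tier = "high", measurement_type = "Ki",
    potency_nM = 10^(9 - c(5, 5, 5, 5, 12))  # p-scale values 5,5,5,5,12
  )
  d <- potency_distribution(ints)
  expect_equal(d$lower_quartile, 5)
  expect_equal(d$upper_quartile, 5)
  expect_equal(d$whisker_low, 5)
  expect_equal(d$whisker_high, 5)
  expect_equal(d$outliers[[1]], 12)

  ints2 <- tibble::tibble(tier = "t", measurement_type = "IC50",
                          potency_nM = 10^(9 - c(4, 5, 6, 7, 8)))
  expect_equal(potency_distribution(ints2)$median, 6)

  single <- tibble::tibble(tier = "t", measurement_type = "Ki",
                           potency_nM = 100)
  d3 <- potency_distribution(single)
  expect_equal(d3$median, 7)
  expect_equal(d3$whisker_low, 7)
  expect_length(d3$outliers[[1]], 0L)

  # non-concentration measurement types are never included
  none <- tibble::tibble(tier = "t", measurement_type = "%max",
                         potency_nM = 50)
  expect_error(potency_distribution(none), "no Ki/IC50")
})
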