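test_that("tier filters admit records per the stringency rules", {
  recs <- with_nM(dplyr::bind_rows(
    activity_record(target_id = "A"),                                  # D,9,Ki,=
    activity_record(target_id = "B", measurement_type = "IC50",
                    relation = ">", value = 10000),                    # approx
    activity_record(target_id = "C", relationship_type = "H",
                    confidence_score = 7L, measurement_type = "EC50",
                    value = 200)                                       # low conf
  ))
  expect_equal(filter_tier(recs, "high")$target_id, "A")
  expect_setequal(filter_tier(recs, "low1")$target_id, c("A", "B"))
  expect_setequal(filter_tier(recs, "low2")$target_id, c("A", "B", "C"))
  expect_error(filter_tier(recs, "bogus"))
})

test_that("tier nesting holds at interaction level on synthetic data", {
  ds <- small_dataset(seed = 3L)
  act <- with_nM(ds$activities)
  act$canonical_smiles <- standardize_structure(act$smiles)
  keys <- lapply(confidence_tiers(), function(t) {
    ci <- curate_interactions(act, t)
    paste(ci$compound_id, ci$target_id)
  })
  names(keys) <- confidence_tiers()
  expect_true(all(keys$high %in% keys$low1))
  expect_true(all(keys$low1 %in% keys$low2))
})

test_that("order-of-magnitude consolidation follows the worked examples", {
  ok <- consolidate_measurements(c(50, 120), "high")
  expect_true(ok$retained)                       # ratio 2.4 <= 10
  expect_equal(ok$potency_nM, sqrt(50 * 120), tolerance = 1e-12)  # ~77.46

  bad <- consolidate_measurements(c(20, 500), "high")
  expect_false(bad$retained)                     # ratio 25 > 10: pair omitted
  low <- consolidate_measurements(c(20, 500), "low1")
  expect_true(low$retained)                      # consistency not considered

  single <- consolidate_measurements(10, "high")
  expect_true(single$retained)
  expect_equal(single$potency_nM, 10)

  expect_error(consolidate_measurements(numeric(), "high"))
})

test_that("consistency decision matches a brute-force log10-range oracle", {
  set.seed(42)
  for (i in 1:200) {
    values <- 10^runif(sample(2:5, 1), 0, 3)
    got <- consolidate_measurements(values, "high")$retained
    oracle <- (log10(max(values)) - log10(min(values))) <= 1
    expect_equal(got, oracle, tolerance = 0,
                 label = paste("values:", paste(signif(values, 4), collapse = ",")))
  }
})

test_that("duplicating a record never changes curation decisions or counts", {
  recs <- with_nM(dplyr::bind_rows(
    activity_record(target_id = "A", value = 50),
    activity_record(target_id = "A", value = 120),
    activity_record(target_id = "B", value = 20),
    activity_record(target_id = "B", value = 900)
  ))
  recs$canonical_smiles <- recs$smiles
  base <- curate_interactions(recs, "high")
  dup <- curate_interactions(dplyr::bind_rows(recs, recs[1, ]), "high")
  expect_equal(dup$target_id, base$target_id)
  expect_equal(nrow(dup), nrow(base))
})

test_that("Ki and IC50 are consistency-checked separately per pair", {
  # IC50 values discordant, Ki consistent: the pair survives through Ki
  recs <- with_nM(dplyr::bind_rows(
    activity_record(target_id = "A", measurement_type = "Ki", value = 40),
    activity_record(target_id = "A", measurement_type = "Ki", value = 60),
    activity_record(target_id = "A", measurement_type = "IC50", value = 5),
    activity_record(target_id = "A", measurement_type = "IC50", value = 5000)
  ))
  recs$canonical_smiles <- recs$smiles
  out <- curate_interactions(recs, "high")
  expect_equal(nrow(out), 1L)
  expect_equal(out$measurement_type, "Ki")
  expect_equal(out$potency_nM, sqrt(40 * 60), tolerance = 1e-12)
})

test_that("p-scale conversion matches its closed form", {
  expect_equal(potency_to_pscale(100), 7.0)
  expect_equal(potency_to_pscale(32000), 4.49485, tolerance = 1e-5)
  expect_equal(potency_to_pscale(1e9), 0.0)
  expect_error(potency_to_pscale(0), "positive")
  expect_error(potency_to_pscale(-1), "positive")
})

test_that("dataset summaries report entity, target and interaction counts", {
  ints <- tibble::tibble(
    compound_id = c("C1", "C2"), target_id = c("T1", "T1")
  )
  s <- summarize_dataset(ints)
  expect_equal(unlist(s), c(n_entities = 2, n_targets = 1,
                            n_interactions = 2, mean_targets_per_entity = 1.0))
  expect_error(summarize_dataset(ints[0, ]), "no entities")
})
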