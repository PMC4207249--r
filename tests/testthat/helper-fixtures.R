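# Fixture builders shared across test files. Everything is generated in code;
# no stored data files.

# A single well-formed activity record, with overridable fields.
activity_record <- function(compound_id = "C1", smiles = "CCNCCO",
                            target_id = "T1", target_family = "",
                            relationship_type = "D", confidence_score = 9L,
                            measurement_type = "Ki", relation = "=",
                            value = 50, units = "nM", year = 2005L) {
  tibble::tibble(
    compound_id = compound_id, smiles = smiles, target_id = target_id,
    target_family = target_family, relationship_type = relationship_type,
    confidence_score = confidence_score, measurement_type = measurement_type,
    relation = relation, value = value, units = units, year = year
  )
}

# Records with value_nM attached, as curate_interactions() expects.
with_nM <- function(records) {
  factor_map <- c("nM" = 1, "uM" = 1e3, "M" = 1e9)
  records$value_nM <- records$value * unname(factor_map[records$units])
  records
}

# Write an activity tibble to a session-lifetime temp TSV, returning the path.
write_activity_tsv <- function(records) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(records, path)
  path
}

# Small synthetic dataset for property tests (fast, deterministic).
small_dataset <- function(seed = 11L, n_drugs = 60L, ...) {
  generate_dataset(synthetic_config(
    n_drugs = n_drugs, n_decoy_compounds = 20L, seed = seed, ...
  ))
}

# Drug-interaction table for the three-target worked example: one new target
# reported in each of 2001, 2005 and 2009.
worked_example_interactions <- function() {
  tibble::tibble(
    drug_id = "D",
    target_id = c("I", "II", "III"),
    first_year = c(2001L, 2005L, 2009L)
  )
}

# Brute-force cumulative-profile oracle: for every interval, rescan all
# interactions and count targets whose first report falls at or before it.
brute_force_profile <- function(drug_interactions) {
  labels <- interval_labels()
  out <- list()
  for (d in unique(drug_interactions$drug_id)) {
    di <- drug_interactions[drug_interactions$drug_id == d, ]
    idx <- as.integer(assign_interval(di$first_year))
    entry <- min(idx)
    for (t in seq(entry, length(labels))) {
      n <- length(unique(di$target_id[idx <= t]))
      out[[length(out) + 1L]] <- tibble::tibble(
        drug_id = d, interval = labels[t], n_targets = n
      )
    }
  }
  dplyr::bind_rows(out)
}
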