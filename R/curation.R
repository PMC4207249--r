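# Confidence-tier filtering and consolidation of repeated measurements into
# curated (compound, target) interactions.

# Measurement types that carry a concentration and hence a p-scale value.
CONC_TYPES <- c("Ki", "IC50")

#' Confidence tier names
#'
#' Three nested tiers of curation stringency. `high` keeps direct assays
#' (relationship type "D") at confidence score 9 with explicitly defined
#' (`"="`) Ki or IC50 values; `low1` keeps type "D" score 9 but any
#' measurement type and relation; `low2` keeps every record. At interaction
#' level high ⊆ low1 ⊆ low2.
#'
#' @return character vector `c("high", "low1", "low2")`.
#' @export
confidence_tiers <- function() c("high", "low1", "low2")

#' Filter activity records to a confidence tier
#'
#' @param records activity-record tibble as from [read_activity_table()].
#' @param tier one of `"high"`, `"low1"`, `"low2"`.
#' @return the subset of `records` admitted by the tier.
#' @export
filter_tier <- function(records, tier = c("high", "low1", "low2")) {
  tier <- match.arg(tier)
  switch(tier,
    high = records |>
      filter(.data$relationship_type == "D", .data$confidence_score == 9L,
             .data$measurement_type %in% CONC_TYPES, .data$relation == "="),
    low1 = records |>
      filter(.data$relationship_type == "D", .data$confidence_score == 9L),
    low2 = records
  )
}

# Inclusive order-of-magnitude consistency check. A small tolerance on the
# log10 range keeps the x/min(x) == 10 boundary decision stable under
# floating-point noise.
same_order_of_magnitude <- function(values) {
  v <- values[is.finite(values) & values > 0]
  if (length(v) <= 1L) return(TRUE)
  (log10(max(v)) - log10(min(v))) <= 1 + 1e-9
}

#' Consolidate repeated measurements for one (compound, target, type) triple
#'
#' In the high-confidence tier, repeated Ki or IC50 measurements for the same
#' pair are retained only if all values fall within the same order of
#' magnitude (max/min ≤ 10, boundary inclusive); otherwise the target
#' activity is omitted. In the low tiers measurement consistency is not
#' considered and the pair is always retained. The consolidated potency is
#' the geometric mean of the contributing concentration values.
#'
#' @param values_nM numeric vector of measurements in nM for one
#'   (compound, target, measurement type) triple.
#' @param tier confidence tier name.
#' @return list with `retained` (logical) and `potency_nM` (geometric mean,
#'   `NA` when no finite concentration values are present).
#' @export
consolidate_measurements <- function(values_nM, tier = c("high", "low1", "low2")) {
  tier <- match.arg(tier)
  if (length(values_nM) == 0L) abort("no measurements to consolidate")
  conc <- values_nM[is.finite(values_nM)]
  retained <- if (tier == "high") same_order_of_magnitude(conc) else TRUE
  list(
    retained = retained,
    potency_nM = if (retained && length(conc) > 0L) geometric_mean(conc) else NA_real_
  )
}

#' Convert a concentration to the negative log molar (p) scale
#'
#' `potency_to_pscale(100)` is 7.0 (100 nM = 1e-7 M, pKi/pIC50 = 7).
#'
#' @param value_nM concentration in nM, strictly positive.
#' @return unitless p-scale value, `-log10(value_nM * 1e-9)`.
#' @export
potency_to_pscale <- function(value_nM) {
  if (any(!is.na(value_nM) & value_nM <= 0)) {
    abort("p-scale conversion requires strictly positive concentrations")
  }
  -log10(value_nM * 1e-9)
}

#' Curate activity records into consolidated interactions for one tier
#'
#' Applies the tier filter, then consolidates measurements per
#' (compound, target) pair. In the high tier each measurement type (Ki, IC50)
#' is consistency-checked separately and the pair is retained if at least one
#' type passes; the reported potency comes from the passing type with the
#' most measurements (ties favour Ki, the assay-independent constant). In the
#' low tiers every pair is retained; potency, when reported, is the geometric
#' mean of available Ki/IC50 concentrations (only those types carry p-scale
#' values).
#'
#' @param records activity-record tibble; a `canonical_smiles` column is
#'   carried through when present.
#' @param tier confidence tier name.
#' @return tibble of curated interactions: `compound_id`, `canonical_smiles`
#'   (when available), `target_id`, `target_family`, `tier`, `first_year`,
#'   `last_year`, `potency_nM`, `measurement_type`, `n_records`.
#' @export
curate_interactions <- function(records, tier = c("high", "low1", "low2")) {
  tier <- match.arg(tier)
  recs <- filter_tier(records, tier)
  if (!"canonical_smiles" %in% names(recs)) recs$canonical_smiles <- recs$smiles
  if (nrow(recs) == 0L) {
    return(tibble(
      compound_id = character(), canonical_smiles = character(),
      target_id = character(), target_family = character(),
      tier = character(), first_year = integer(), last_year = integer(),
      potency_nM = double(), measurement_type = character(),
      n_records = integer()
    ))
  }

  # per-(pair, measurement type) consolidation
  by_type <- recs |>
    summarise(
      n = n(),
      n_conc = sum(is.finite(.data$value_nM)),
      potency_nM = if (any(is.finite(.data$value_nM))) {
        geometric_mean(.data$value_nM[is.finite(.data$value_nM)])
      } else NA_real_,
      consistent = same_order_of_magnitude(.data$value_nM),
      .by = c("compound_id", "target_id", "measurement_type")
    )

  if (tier == "high") {
    by_type <- by_type |> filter(.data$consistent)
    if (nrow(by_type) == 0L) return(curate_interactions(recs[0, ], tier))
    # one interaction per pair; potency from the best-supported passing type
    chosen <- by_type |>
      mutate(pref = match(.data$measurement_type, CONC_TYPES)) |>
      arrange(desc(.data$n), .data$pref) |>
      slice_head(n = 1, by = c("compound_id", "target_id"))
    contributing <- recs |>
      semi_join(by_type, by = c("compound_id", "target_id", "measurement_type"))
  } else {
    conc_types <- by_type |>
      filter(.data$measurement_type %in% CONC_TYPES, .data$n_conc > 0L)
    pooled <- recs |>
      filter(.data$measurement_type %in% CONC_TYPES,
             is.finite(.data$value_nM)) |>
      summarise(potency_nM = geometric_mean(.data$value_nM),
                .by = c("compound_id", "target_id"))
    chosen <- by_type |>
      mutate(pref = match(.data$measurement_type, CONC_TYPES),
             pref = ifelse(is.na(.data$pref), length(CONC_TYPES) + 1L, .data$pref)) |>
      arrange(desc(.data$n_conc > 0L), desc(.data$n), .data$pref,
              .data$measurement_type) |>
      slice_head(n = 1, by = c("compound_id", "target_id")) |>
      select(-"potency_nM") |>
      left_join(pooled, by = c("compound_id", "target_id"))
    contributing <- recs
  }

  meta <- contributing |>
    summarise(
      canonical_smiles = .data$canonical_smiles[1],
      target_family = {
        fam <- .data$target_family[nzchar(.data$target_family)]
        if (length(fam) > 0L) fam[1] else ""
      },
      first_year = min(.data$year),
      last_year = max(.data$year),
      n_records = n(),
      .by = c("compound_id", "target_id")
    )

  chosen |>
    select("compound_id", "target_id", "measurement_type", "potency_nM") |>
    left_join(meta, by = c("compound_id", "target_id")) |>
    mutate(tier = tier) |>
    select("compound_id", "canonical_smiles", "target_id", "target_family",
           "tier", "first_year", "last_year", "potency_nM",
           "measurement_type", "n_records") |>
    arrange(.data$compound_id, .data$target_id)
}

#' Summarize a curated data set
#'
#' Reports the number of entities (compounds or drugs), distinct targets,
#' interactions, and the mean number of targets per entity (interactions per
#' entity, rounded half-up to one decimal, the convention used for
#' database-scale summary tables).
#'
#' @param interactions curated-interaction tibble (one row per interaction).
#' @param id_col column identifying the entity, default `"compound_id"`.
#' @return one-row tibble: `n_entities`, `n_targets`, `n_interactions`,
#'   `mean_targets_per_entity`.
#' @export
summarize_dataset <- function(interactions, id_col = "compound_id") {
  stopifnot(id_col %in% names(interactions))
  n_entities <- n_distinct(interactions[[id_col]])
  if (n_entities == 0L) abort("no entities to summarize")
  tibble(
    n_entities = n_entities,
    n_targets = n_distinct(interactions$target_id),
    n_interactions = nrow(interactions),
    mean_targets_per_entity = round_half_up(nrow(interactions) / n_entities, 1)
  )
}
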