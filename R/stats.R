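# Promiscuity statistics: per-interval distributions, per-drug increases,
# cross-database comparison, target-family profiles, potency distributions.

#' Distribution of promiscuity rates per interval
#'
#' Five-number summary (min, type-7 quartiles, median, max) plus mean of the
#' cumulative promiscuity rates of all drugs that have entered the analysis
#' by each interval. Box plots over these summaries show how drug
#' promiscuity develops over time; means and medians can diverge strongly
#' because a small subset of highly promiscuous drugs inflates the mean.
#'
#' @param profiles a `cumulative_profiles` object.
#' @param interval optional single interval label; default summarizes all 14.
#' @return tibble `interval`, `n_drugs`, `min`, `lower_quartile`, `median`,
#'   `upper_quartile`, `max`, `mean`.
#' @export
interval_distribution <- function(profiles, interval = NULL) {
  stopifnot(inherits(profiles, "cumulative_profiles"))
  prof <- profiles$profile
  if (!is.null(interval)) {
    if (!interval %in% interval_labels()) {
      abort(paste0("unknown interval: ", interval))
    }
    prof <- prof |> filter(.data$interval == !!interval)
    if (nrow(prof) == 0L) {
      abort(paste0("no drugs entered by interval ", interval))
    }
  }
  prof |>
    summarise(
      n_drugs = n(),
      five_number_summary(.data$n_targets),
      mean = mean(.data$n_targets),
      .by = "interval"
    ) |>
    arrange(.data$interval)
}

#' Per-drug promiscuity increase
#'
#' The increase in a drug's cumulative promiscuity rate from its first to
#' its most recent activity records: rate at the last interval minus rate at
#' the entry interval. Always non-negative because profiles are cumulative.
#'
#' @param profiles a `cumulative_profiles` object.
#' @return tibble `drug_id`, `increase`.
#' @export
promiscuity_increase <- function(profiles) {
  stopifnot(inherits(profiles, "cumulative_profiles"))
  profiles$summary |>
    transmute(.data$drug_id,
              increase = .data$final_rate - .data$entry_rate)
}

#' Histogram of promiscuity increases
#'
#' Bins per-drug increases into 0, 1, ..., `max_bin` and an open top bin
#' `"> max_bin"`, with percentages rounded half-up to one decimal.
#'
#' @param increases integer vector, or the tibble from
#'   [promiscuity_increase()].
#' @param max_bin largest individual bin (default 10, giving a ">10" top
#'   bin; family-level analyses conventionally use 5).
#' @return tibble `increase` (character bin label), `n`, `pct`; counts sum
#'   to the number of drugs.
#' @export
increase_histogram <- function(increases, max_bin = 10L) {
  if (is.data.frame(increases)) increases <- increases$increase
  if (length(increases) == 0L) abort("no increase values to bin")
  stopifnot(all(increases >= 0))
  labels <- c(as.character(0:max_bin), paste0(">", max_bin))
  binned <- ifelse(increases > max_bin, paste0(">", max_bin),
                   as.character(increases))
  n <- as.integer(table(factor(binned, levels = labels)))
  tibble(
    increase = labels,
    n = n,
    pct = round_half_up(100 * n / length(increases), 1)
  )
}

#' Target-family promiscuity profiles
#'
#' Assigns every target in a drug's cumulative profile to a protein family
#' and follows the number of distinct families over time. Targets missing
#' from the family map are labelled `"unassigned"`.
#'
#' @param profiles a `cumulative_profiles` object.
#' @param family_map tibble `target_id`, `family`.
#' @return list:
#'   \describe{
#'     \item{per_interval}{tibble `drug_id`, `interval`, `n_families`}
#'     \item{increase}{tibble `drug_id`, `first_families`, `final_families`,
#'       `increase`}
#'     \item{first_family}{tibble `drug_id`, `family` — families of the
#'       targets in the drug's first activity records}
#'   }
#' @export
family_promiscuity <- function(profiles, family_map) {
  stopifnot(inherits(profiles, "cumulative_profiles"),
            all(c("target_id", "family") %in% names(family_map)))
  fam <- profiles$targets |>
    left_join(family_map |> distinct(.data$target_id, .data$family),
              by = "target_id") |>
    mutate(family = ifelse(is.na(.data$family) | !nzchar(.data$family),
                           "unassigned", .data$family),
           first_idx = as.integer(.data$first_interval))

  n_int <- length(interval_labels())
  per_drug <- fam |>
    summarise(
      entry_idx = min(.data$first_idx),
      # distinct families among targets first seen at or before each interval
      n_families = list(vapply(
        seq(min(.data$first_idx), n_int),
        function(t) n_distinct(.data$family[.data$first_idx <= t]), 0L
      )),
      idx = list(seq(min(.data$first_idx), n_int)),
      .by = "drug_id"
    )

  per_interval <- per_drug |>
    select("drug_id", "idx", "n_families") |>
    unnest(c("idx", "n_families")) |>
    mutate(interval = factor(interval_labels()[.data$idx],
                             levels = interval_labels(), ordered = TRUE)) |>
    select("drug_id", "interval", "n_families") |>
    arrange(.data$drug_id, .data$interval)

  increase <- per_drug |>
    transmute(
      .data$drug_id,
      first_families = vapply(.data$n_families, function(v) v[1], 0L),
      final_families = vapply(.data$n_families, function(v) v[length(v)], 0L),
      increase = .data$final_families - .data$first_families
    )

  first_family <- fam |>
    filter(.data$first_idx == min(.data$first_idx), .by = "drug_id") |>
    distinct(.data$drug_id, .data$family) |>
    arrange(.data$drug_id, .data$family)

  list(per_interval = per_interval, increase = increase,
       first_family = first_family)
}

#' Compare annotation-derived and activity-derived target sets
#'
#' For each drug, compares its expanded accession set from the annotation
#' database (DrugBank-like) with the accession set derived from curated
#' activity records (ChEMBL-like): counts on both sides, their difference
#' (the delta-activities statistic), and the intersection size. A drug with
#' "10 | 6" annotations has delta 4; about a third of real drugs share no
#' target at all between the two sources.
#'
#' @param db_targets long tibble `drug_id`, `target_id` (annotation side).
#' @param activity_targets long tibble `drug_id`, `target_id` (activity
#'   side). Both sides must use the same accession namespace.
#' @return tibble `drug_id`, `n_db_targets`, `n_activity_targets`, `delta`
#'   (db minus activity; may be negative), `n_common`.
#' @export
compare_profiles <- function(db_targets, activity_targets) {
  stopifnot(all(c("drug_id", "target_id") %in% names(db_targets)),
            all(c("drug_id", "target_id") %in% names(activity_targets)))
  db <- db_targets |> distinct(.data$drug_id, .data$target_id)
  act <- activity_targets |> distinct(.data$drug_id, .data$target_id)
  counts_db <- db |> count(.data$drug_id, name = "n_db_targets")
  counts_act <- act |> count(.data$drug_id, name = "n_activity_targets")
  common <- db |>
    inner_join(act, by = c("drug_id", "target_id")) |>
    count(.data$drug_id, name = "n_common")
  full_join(counts_db, counts_act, by = "drug_id") |>
    left_join(common, by = "drug_id") |>
    mutate(across(c("n_db_targets", "n_activity_targets", "n_common"),
                  ~ replace_na(.x, 0L)),
           delta = .data$n_db_targets - .data$n_activity_targets) |>
    select("drug_id", "n_db_targets", "n_activity_targets", "delta",
           "n_common") |>
    arrange(.data$drug_id)
}

#' Potency distributions on the p-scale
#'
#' Tukey box statistics of pKi/pIC50 values per confidence tier. Only Ki and
#' IC50 measurements carry a p-scale value, so in every tier only those
#' types are included. Whiskers extend to the most extreme data points
#' within 1.5 interquartile ranges of the quartiles; values outside are
#' listed as outliers.
#'
#' @param interactions curated-interaction tibble with `tier`,
#'   `measurement_type` and `potency_nM` columns (several tiers may be
#'   stacked).
#' @return tibble per tier: `tier`, `n`, `whisker_low`, `lower_quartile`,
#'   `median`, `upper_quartile`, `whisker_high`, `outliers` (list column).
#' @export
potency_distribution <- function(interactions) {
  stopifnot(all(c("tier", "measurement_type", "potency_nM") %in%
                  names(interactions)))
  eligible <- interactions |>
    filter(.data$measurement_type %in% CONC_TYPES,
           is.finite(.data$potency_nM), .data$potency_nM > 0)
  if (nrow(eligible) == 0L) abort("no Ki/IC50 potency values available")
  eligible |>
    mutate(p = potency_to_pscale(.data$potency_nM)) |>
    summarise(tukey_box_stats(.data$p), .by = "tier") |>
    arrange(.data$tier)
}

# Tukey box statistics as a one-row tibble with an outlier list column.
tukey_box_stats <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  iqr <- q[3] - q[1]
  inside <- x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr
  tibble(
    n = length(x),
    whisker_low = min(x[inside]),
    lower_quartile = q[1],
    median = q[2],
    upper_quartile = q[3],
    whisker_high = max(x[inside]),
    outliers = list(sort(x[!inside]))
  )
}
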