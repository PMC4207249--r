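# Time-interval binning of activity records and cumulative per-drug
# promiscuity profiles.

#' The 14 release-year intervals
#'
#' Activity records are organized into 14 ordered intervals: "2000" (which
#' absorbs everything reported up to and including 2000, the starting point
#' of the analysis), the individual years 2001–2012, and ">2012" for
#' everything later.
#'
#' @return character vector of the 14 interval labels, in order.
#' @export
interval_labels <- function() c("2000", as.character(2001:2012), ">2012")

#' Assign release years to time intervals
#'
#' @param year integer vector of 4-digit release years.
#' @return ordered factor over [interval_labels()].
#' @examples
#' assign_interval(c(1997, 2005, 2013))
#' @export
assign_interval <- function(year) {
  lab <- ifelse(year <= 2000L, "2000",
         ifelse(year > 2012L, ">2012", as.character(year)))
  factor(lab, levels = interval_labels(), ordered = TRUE)
}

#' Build cumulative promiscuity profiles
#'
#' For each drug, every target's first report is binned to a time interval;
#' the cumulative profile at an interval is the set of targets first reported
#' at or before it. The drug enters the analysis at the interval of its first
#' record and is absent (not zero-valued) from earlier intervals. Target sets
#' are monotone non-decreasing, so the promiscuity rate at the last interval
#' equals the drug's total number of distinct targets.
#'
#' @param drug_interactions tibble with columns `drug_id`, `target_id`,
#'   `first_year` (per-target year of first report) and optionally
#'   `last_year` (latest contributing record, used for the raw record span).
#' @return list of class `cumulative_profiles`:
#'   \describe{
#'     \item{profile}{long tibble `drug_id`, `interval` (ordered factor),
#'       `n_targets`, from each drug's entry interval onward}
#'     \item{targets}{tibble `drug_id`, `target_id`, `first_interval`}
#'     \item{summary}{tibble `drug_id`, `entry_interval`, `entry_rate`,
#'       `final_rate`, `raw_first_year`, `raw_last_year`}
#'   }
#' @export
build_cumulative_profiles <- function(drug_interactions) {
  needed <- c("drug_id", "target_id", "first_year")
  stopifnot(all(needed %in% names(drug_interactions)))
  di <- as_tibble(drug_interactions)
  undated <- di |> filter(is.na(.data$first_year))
  if (nrow(undated) > 0L) {
    warn(paste0("excluding ", n_distinct(undated$drug_id),
                " drug(s) without dated interactions"))
    di <- di |> filter(!is.na(.data$first_year))
  }
  if (nrow(di) == 0L) abort("no dated drug interactions to profile")
  if (!"last_year" %in% names(di)) di$last_year <- di$first_year

  targets <- di |>
    distinct(.data$drug_id, .data$target_id, .keep_all = TRUE) |>
    mutate(first_interval = assign_interval(.data$first_year))

  n_int <- length(interval_labels())
  profile <- targets |>
    mutate(first_idx = as.integer(.data$first_interval)) |>
    summarise(
      entry_idx = min(.data$first_idx),
      idx = list(seq(min(.data$first_idx), n_int)),
      n_targets = list(cumsum(tabulate(.data$first_idx, nbins = n_int))[
        seq(min(.data$first_idx), n_int)]),
      .by = "drug_id"
    )

  long <- profile |>
    select("drug_id", "idx", "n_targets") |>
    unnest(c("idx", "n_targets")) |>
    mutate(interval = factor(interval_labels()[.data$idx],
                             levels = interval_labels(), ordered = TRUE)) |>
    select("drug_id", "interval", "n_targets") |>
    arrange(.data$drug_id, .data$interval)

  summary <- profile |>
    transmute(
      .data$drug_id,
      entry_interval = factor(interval_labels()[.data$entry_idx],
                              levels = interval_labels(), ordered = TRUE),
      entry_rate = vapply(.data$n_targets, function(v) v[1], 0L),
      final_rate = vapply(.data$n_targets, function(v) v[length(v)], 0L)
    ) |>
    left_join(
      di |> summarise(raw_first_year = min(.data$first_year),
                      raw_last_year = max(.data$last_year),
                      .by = "drug_id"),
      by = "drug_id"
    ) |>
    arrange(.data$drug_id)

  structure(
    list(profile = long,
         targets = targets |>
           select("drug_id", "target_id", "first_interval"),
         summary = summary),
    class = "cumulative_profiles"
  )
}

#' @export
print.cumulative_profiles <- function(x, ...) {
  cat("cumulative promiscuity profiles:\n")
  cat("  drugs:           ", nrow(x$summary), "\n")
  cat("  final rate range:", min(x$summary$final_rate), "-",
      max(x$summary$final_rate), "\n")
  invisible(x)
}

#' Raw record span per drug
#'
#' Years elapsed between a drug's first and last activity record, computed
#' on raw release years (interval binning collapses pre-2000 years, so a
#' drug first reported in 1981 and last in 2005 spans 24 years even though
#' both bound intervals are within the analysis window).
#'
#' @param profiles a `cumulative_profiles` object.
#' @return tibble `drug_id`, `span_years`.
#' @export
record_span <- function(profiles) {
  stopifnot(inherits(profiles, "cumulative_profiles"))
  profiles$summary |>
    transmute(.data$drug_id,
              span_years = .data$raw_last_year - .data$raw_first_year)
}

#' Cumulative number of drugs with activity data over time
#'
#' @param profiles a `cumulative_profiles` object.
#' @return tibble `interval`, `n_drugs`, where `n_drugs` at an interval is
#'   the number of drugs whose entry interval is at or before it
#'   (non-decreasing).
#' @export
cumulative_drug_counts <- function(profiles) {
  stopifnot(inherits(profiles, "cumulative_profiles"))
  entry_idx <- as.integer(profiles$summary$entry_interval)
  n_int <- length(interval_labels())
  tibble(
    interval = factor(interval_labels(), levels = interval_labels(),
                      ordered = TRUE),
    n_drugs = cumsum(tabulate(entry_idx, nbins = n_int))
  )
}
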