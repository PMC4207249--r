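# PAINS substructure screening and promiscuity-trend comparison of flagged
# drugs against the full drug set.

#' Read a PAINS SMARTS pattern file
#'
#' Loads substructure patterns used to flag pan-assay interference compounds
#' (PAINS). The package ships a small default list covering well-known PAINS
#' motif classes (rhodanines, catechols, quinones, phenolic Mannich bases,
#' hydroxyphenyl hydrazones, alkylidene barbiturates, ...); any custom list
#' can be supplied as a TSV. Every pattern must parse as valid SMARTS.
#'
#' @param path TSV with columns `pattern_id`, `smarts` and optionally
#'   `description`; `NULL` loads the packaged default list.
#' @return tibble `pattern_id`, `smarts`, `description`.
#' @export
read_pains_patterns <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pains_smarts.tsv",
                                package = "promiscuitrack", mustWork = TRUE)
  pat <- read_tsv(path, col_types = cols(.default = col_character()),
                  progress = FALSE, show_col_types = FALSE)
  if (!all(c("pattern_id", "smarts") %in% names(pat))) {
    abort("pattern file needs columns 'pattern_id' and 'smarts'")
  }
  if (!"description" %in% names(pat)) pat$description <- ""
  ok <- vapply(pat$smarts, smarts_is_valid, TRUE)
  if (!all(ok)) {
    abort(paste0("unparsable SMARTS pattern(s): ",
                 paste(pat$pattern_id[!ok], collapse = ", ")))
  }
  pat |> select("pattern_id", "smarts", "description")
}

#' Screen structures for PAINS substructures
#'
#' Matches each structure against every pattern; a drug is PAINS-positive if
#' and only if at least one pattern matches. Screening is deterministic and
#' independent of row order. Structures that failed standardization are
#' skipped with a warning and reported as negative with no matches.
#'
#' @param structures tibble with columns `drug_id` and `canonical_smiles`.
#' @param patterns pattern tibble from [read_pains_patterns()].
#' @return tibble `drug_id`, `positive`, `matched_ids` (semicolon-joined
#'   pattern ids, empty string when negative).
#' @export
screen_structures <- function(structures, patterns = read_pains_patterns()) {
  stopifnot(all(c("drug_id", "canonical_smiles") %in% names(structures)))
  structures <- structures |>
    distinct(.data$drug_id, .data$canonical_smiles)
  if (nrow(patterns) == 0L) {
    return(tibble(drug_id = structures$drug_id, positive = FALSE,
                  matched_ids = ""))
  }
  bad <- is.na(structures$canonical_smiles)
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " drug(s) without a valid structure"))
  }
  valid <- structures[!bad, , drop = FALSE]
  matched <- rep("", nrow(valid))
  if (nrow(valid) > 0L) {
    counts <- smarts_match_counts(valid$canonical_smiles,
                                  setNames(patterns$smarts, patterns$pattern_id))
    matched <- apply(counts > 0L, 1L, function(hit) {
      paste(patterns$pattern_id[hit], collapse = ";")
    })
  }
  bind_rows(
    tibble(drug_id = valid$drug_id, matched_ids = unname(matched)),
    tibble(drug_id = structures$drug_id[bad], matched_ids = "")
  ) |>
    mutate(positive = nzchar(.data$matched_ids)) |>
    select("drug_id", "positive", "matched_ids") |>
    arrange(.data$drug_id)
}

#' Promiscuity trend of PAINS-positive drugs vs all drugs
#'
#' Compares average cumulative promiscuity rates over time for the
#' PAINS-positive subset against the full drug set. Subset statistics are
#' pure projections: restricting to the positive subset never changes any
#' individual drug's rates.
#'
#' @param profiles a `cumulative_profiles` object.
#' @param screen_results tibble from [screen_structures()]; must cover every
#'   profiled drug.
#' @return tibble `interval`, `group` (`"all"` or `"pains"`), `n_drugs`,
#'   `mean_rate`. When no drug is positive the `"pains"` series is empty.
#' @export
pains_trend_comparison <- function(profiles, screen_results) {
  stopifnot(inherits(profiles, "cumulative_profiles"),
            all(c("drug_id", "positive") %in% names(screen_results)))
  missing <- setdiff(profiles$summary$drug_id, screen_results$drug_id)
  if (length(missing) > 0L) {
    abort(paste0("screen results missing for ", length(missing), " drug(s)"))
  }
  mean_series <- function(prof, group) {
    prof |>
      summarise(n_drugs = n(), mean_rate = mean(.data$n_targets),
                .by = "interval") |>
      mutate(group = group)
  }
  positives <- screen_results$drug_id[screen_results$positive]
  all_series <- mean_series(profiles$profile, "all")
  pains_prof <- profiles$profile |> filter(.data$drug_id %in% positives)
  pains_series <- if (nrow(pains_prof) > 0L) {
    mean_series(pains_prof, "pains")
  } else {
    inform("no PAINS-positive drugs among profiled drugs")
    all_series[0, ]
  }
  bind_rows(all_series, pains_series) |>
    select("interval", "group", "n_drugs", "mean_rate") |>
    arrange(.data$group, .data$interval)
}
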