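# End-to-end orchestration: ingest -> curation -> mapping -> temporal ->
# stats -> pains, with all report tables written as TSV.

stage_msg <- function(stage, ...) {
  inform(paste0("[", stage, "] ", paste0(...)))
}

#' Run the full promiscuity-monitoring analysis
#'
#' Orchestrates the whole pipeline for one confidence tier: reads (or
#' accepts) the activity and drug tables, standardizes structures, curates
#' interactions, maps drugs to compounds by canonical SMILES, builds
#' cumulative profiles over the 14 time intervals, and derives the report
#' tables: data set summary, cumulative drug counts, per-interval
#' promiscuity distributions, increase histograms (target and family level),
#' top promiscuity gainers, cross-database annotation comparison, potency
#' box statistics, and the PAINS trend comparison.
#'
#' @param activities activity table: a file path (TSV/CSV) or a tibble as
#'   from [read_activity_table()].
#' @param drugs drug-annotation table: a file path or a long tibble as from
#'   [read_drug_table()].
#' @param tier confidence tier to analyze.
#' @param activity_dialect,drug_dialect column dialects used when reading
#'   from file paths.
#' @param pains_patterns PAINS pattern tibble or file path; `NULL` uses the
#'   packaged default list.
#' @param increase_max_bin top closed bin of the target-level increase
#'   histogram (default 10).
#' @param family_max_bin top closed bin of the family-level increase
#'   histogram (default 5).
#' @param top_k number of drugs reported in the largest-increase table.
#' @param out_dir optional directory; when given, every report table is
#'   written as TSV along with a run manifest (`manifest.yaml`).
#' @return (invisibly when `out_dir` is set) a list of report tables:
#'   `summary`, `drug_summary`, `matches`, `unmatched`, `drug_counts`,
#'   `interval_summary`, `increase_histogram`, `family_histogram`,
#'   `top_increases`, `crossdb`, `potency_boxstats`, `pains_screen`,
#'   `pains_trend`, `profiles` (the `cumulative_profiles` object).
#' @export
run_analysis <- function(activities, drugs,
                         tier = c("high", "low1", "low2"),
                         activity_dialect = promiscuitrack::activity_dialect(),
                         drug_dialect = promiscuitrack::drug_dialect(),
                         pains_patterns = NULL,
                         increase_max_bin = 10L,
                         family_max_bin = 5L,
                         top_k = 5L,
                         out_dir = NULL) {
  tier <- match.arg(tier)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  stage_msg("ingest", "reading inputs")
  act <- run_stage("ingest", {
    if (is.character(activities)) {
      read_activity_table(activities, activity_dialect)
    } else as_tibble(activities)
  })
  drg <- run_stage("ingest", {
    if (is.character(drugs)) read_drug_table(drugs, drug_dialect)
    else as_tibble(drugs)
  })
  if (!"value_nM" %in% names(act)) {
    act$value_nM <- act$value * unname(unit_to_nM[act$units])
  }
  stage_msg("ingest", nrow(act), " activity records, ",
            n_distinct(drg$drug_id), " drugs")

  stage_msg("standardize", "canonicalizing structures")
  act$canonical_smiles <- standardize_structure(act$smiles)
  drg$canonical_smiles <- standardize_structure(drg$smiles)
  n_bad <- sum(is.na(act$canonical_smiles))
  if (n_bad > 0L) {
    warn(paste0("excluding ", n_bad, " activity record(s) with invalid structures"))
    act <- act |> filter(!is.na(.data$canonical_smiles))
  }

  stage_msg("curation", "tier = ", tier)
  interactions <- run_stage("curation", curate_interactions(act, tier))
  summary_tbl <- run_stage("curation", summarize_dataset(interactions))

  stage_msg("mapping", "matching drugs to compounds by canonical SMILES")
  mapping <- run_stage("mapping", match_drugs_to_compounds(drg, interactions))

  stage_msg("temporal", "building cumulative profiles")
  profiles <- run_stage("temporal",
                        build_cumulative_profiles(mapping$drug_interactions))
  spans <- record_span(profiles)
  drug_counts <- cumulative_drug_counts(profiles)
  drug_summary <- profiles$summary |>
    left_join(spans, by = "drug_id")

  stage_msg("stats", "promiscuity statistics")
  interval_summary <- run_stage("stats", interval_distribution(profiles))
  increases <- promiscuity_increase(profiles)
  inc_hist <- increase_histogram(increases, max_bin = increase_max_bin)
  family_map <- act |>
    filter(nzchar(.data$target_family)) |>
    distinct(.data$target_id, family = .data$target_family)
  fam <- run_stage("stats", family_promiscuity(profiles, family_map))
  fam_hist <- increase_histogram(fam$increase, max_bin = family_max_bin)
  top_increases <- increases |>
    arrange(desc(.data$increase), .data$drug_id) |>
    head(top_k) |>
    left_join(profiles$summary, by = "drug_id")
  crossdb <- run_stage("stats", compare_profiles(
    drg |> select("drug_id", "target_id"),
    mapping$drug_interactions |>
      semi_join(mapping$matches, by = "drug_id") |>
      select("drug_id", "target_id")
  ) |> semi_join(mapping$matches, by = "drug_id"))
  potency <- run_stage("stats", potency_distribution(interactions))

  stage_msg("pains", "substructure screening")
  patterns <- run_stage("pains", {
    if (is.null(pains_patterns)) read_pains_patterns()
    else if (is.character(pains_patterns)) read_pains_patterns(pains_patterns)
    else pains_patterns
  })
  screen <- run_stage("pains", screen_structures(
    drg |> distinct(.data$drug_id, .data$canonical_smiles), patterns))
  pains_trend <- run_stage("pains", pains_trend_comparison(profiles, screen))

  reports <- list(
    tier = tier,
    summary = summary_tbl,
    drug_summary = drug_summary,
    matches = mapping$matches,
    unmatched = mapping$unmatched,
    drug_counts = drug_counts,
    interval_summary = interval_summary,
    increase_histogram = inc_hist,
    family_histogram = fam_hist,
    top_increases = top_increases,
    crossdb = crossdb,
    potency_boxstats = potency,
    pains_screen = screen,
    pains_trend = pains_trend,
    profiles = profiles
  )

  if (!is.null(out_dir)) {
    write_reports(reports, out_dir)
    return(invisible(reports))
  }
  reports
}

# Write every tabular report plus a run manifest.
write_reports <- function(reports, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("summary", "drug_summary", "matches", "unmatched",
              "drug_counts", "interval_summary", "increase_histogram",
              "family_histogram", "top_increases", "crossdb",
              "pains_screen", "pains_trend")
  for (nm in tables) {
    write_tsv(reports[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  pot <- reports$potency_boxstats |>
    mutate(outliers = vapply(.data$outliers, function(o) {
      paste(signif(o, 6), collapse = ";")
    }, ""))
  write_tsv(pot, file.path(out_dir, "potency_boxstats.tsv"))
  write_tsv(reports$profiles$profile, file.path(out_dir, "profiles_long.tsv"))
  manifest <- list(
    package = "promiscuitrack",
    version = as.character(utils::packageVersion("promiscuitrack")),
    tier = reports$tier,
    n_drugs_profiled = nrow(reports$profiles$summary),
    n_interactions = reports$summary$n_interactions,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
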