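# Structure-based mapping of drugs to bioactive compounds.

#' Map drugs to bioactive compounds by canonical-SMILES identity
#'
#' Drug and compound names are not comparable across databases, so drugs are
#' matched to compounds purely by exact equality of standardized canonical
#' SMILES strings. Each matched drug inherits the union of curated
#' interactions over all compounds sharing its structure, with per-target
#' first year taken as the minimum across compounds. Drugs whose structure
#' appears in no compound record (or failed standardization) are reported as
#' unmatched and excluded from temporal analysis.
#'
#' @param drugs long drug-annotation tibble with columns `drug_id` and
#'   `canonical_smiles` (one structure per drug).
#' @param interactions curated-interaction tibble from
#'   [curate_interactions()], carrying `canonical_smiles`.
#' @return list of class `drug_compound_match`:
#'   \describe{
#'     \item{matches}{tibble `drug_id`, `canonical_smiles`, `n_compounds`,
#'       `n_interactions`}
#'     \item{drug_interactions}{tibble `drug_id`, `target_id`,
#'       `target_family`, `first_year`, `last_year` — the union of attached
#'       interactions}
#'     \item{unmatched}{tibble `drug_id`, `reason`}
#'   }
#' @export
match_drugs_to_compounds <- function(drugs, interactions) {
  stopifnot(all(c("drug_id", "canonical_smiles") %in% names(drugs)),
            all(c("compound_id", "canonical_smiles", "target_id") %in%
                  names(interactions)))
  structures <- drugs |>
    distinct(.data$drug_id, .data$canonical_smiles)
  if (anyDuplicated(structures$drug_id) > 0L) {
    abort("a drug maps to more than one canonical structure")
  }

  invalid <- structures |>
    filter(is.na(.data$canonical_smiles)) |>
    transmute(.data$drug_id, reason = "invalid structure")
  valid <- structures |> filter(!is.na(.data$canonical_smiles))

  attached <- valid |>
    inner_join(interactions, by = "canonical_smiles",
               relationship = "many-to-many")

  drug_interactions <- attached |>
    summarise(
      target_family = {
        fam <- .data$target_family[nzchar(.data$target_family)]
        if (length(fam) > 0L) fam[1] else ""
      },
      first_year = min(.data$first_year),
      last_year = max(.data$last_year),
      .by = c("drug_id", "target_id")
    ) |>
    arrange(.data$drug_id, .data$target_id)

  matches <- attached |>
    summarise(
      canonical_smiles = .data$canonical_smiles[1],
      n_compounds = n_distinct(.data$compound_id),
      n_interactions = n_distinct(.data$target_id),
      .by = "drug_id"
    ) |>
    arrange(.data$drug_id)

  no_match <- valid |>
    anti_join(matches, by = "drug_id") |>
    transmute(.data$drug_id, reason = "no compound with matching structure")

  structure(
    list(
      matches = matches,
      drug_interactions = drug_interactions,
      unmatched = bind_rows(invalid, no_match) |> arrange(.data$drug_id)
    ),
    class = "drug_compound_match"
  )
}

#' @export
print.drug_compound_match <- function(x, ...) {
  cat("drug-compound structure matching:\n")
  cat("  matched drugs:   ", nrow(x$matches), "\n")
  cat("  unmatched drugs: ", nrow(x$unmatched), "\n")
  cat("  attached interactions:", nrow(x$drug_interactions), "\n")
  invisible(x)
}
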