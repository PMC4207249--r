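# Reading and validating the two input table kinds: dated activity records
# (ChEMBL-like) and drug annotations (DrugBank-like).

#' Column dialect for activity-record tables
#'
#' Maps the internal activity-record fields to the column names used by an
#' input file. Any mapping can be overridden, e.g.
#' `activity_dialect(compound_id = "molregno")`.
#'
#' @param compound_id,smiles,target_id,target_family,relationship_type,confidence_score,measurement_type,relation,value,units,year
#'   column names in the input file for each field.
#' @return a named list of class `promiscuitrack_dialect`.
#' @export
activity_dialect <- function(compound_id = "compound_id",
                             smiles = "smiles",
                             target_id = "target_id",
                             target_family = "target_family",
                             relationship_type = "relationship_type",
                             confidence_score = "confidence_score",
                             measurement_type = "measurement_type",
                             relation = "relation",
                             value = "value",
                             units = "units",
                             year = "year") {
  structure(
    list(
      compound_id = compound_id, smiles = smiles, target_id = target_id,
      target_family = target_family, relationship_type = relationship_type,
      confidence_score = confidence_score, measurement_type = measurement_type,
      relation = relation, value = value, units = units, year = year
    ),
    class = "promiscuitrack_dialect", kind = "activity"
  )
}

#' Column dialect for drug-annotation tables
#'
#' @param drug_id,name,smiles,category,targets column names in the input file;
#'   `targets` holds the (possibly grouped) accession list.
#' @param target_sep separator between accessions within the `targets` column.
#' @return a named list of class `promiscuitrack_dialect`.
#' @export
drug_dialect <- function(drug_id = "drug_id", name = "name",
                         smiles = "smiles", category = "category",
                         targets = "targets", target_sep = ";") {
  structure(
    list(drug_id = drug_id, name = name, smiles = smiles,
         category = category, targets = targets, target_sep = target_sep),
    class = "promiscuitrack_dialect", kind = "drug"
  )
}

#' Read a column dialect from a YAML or JSON file
#'
#' The file holds a mapping from internal field names to input column names;
#' unknown keys are rejected.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @param kind `"activity"` or `"drug"`.
#' @return a dialect as from [activity_dialect()] or [drug_dialect()].
#' @export
read_dialect <- function(path, kind = c("activity", "drug")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("dialect file not found: ", path))
  spec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  ctor <- if (kind == "activity") activity_dialect else drug_dialect
  known <- names(formals(ctor))
  bad <- setdiff(names(spec), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown dialect keys: ", paste(bad, collapse = ", ")))
  }
  do.call(ctor, spec)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read_csv else read_tsv
  tbl <- suppressWarnings(
    reader(path, col_types = cols(.default = col_character()),
           progress = FALSE, show_col_types = FALSE)
  )
  if (nrow(tbl) == 0L) abort(paste0("empty input file: ", path))
  tbl
}

require_columns <- function(tbl, wanted, path) {
  missing <- setdiff(unlist(wanted, use.names = FALSE), names(tbl))
  if (length(missing) > 0L) {
    abort(paste0("missing required column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
}

# Concentration units accepted at ingest; everything is normalized to nM.
unit_to_nM <- c("nM" = 1, "nm" = 1, "uM" = 1e3, "µM" = 1e3, "um" = 1e3,
                "mM" = 1e6, "M" = 1e9)

#' Read and validate an activity-record table
#'
#' Reads a TSV/CSV of dated compound-to-target activity measurements, applying
#' a column dialect, coercing year and potency value, normalizing
#' concentration units to nM (`value_nM`), and defaulting a blank relation to
#' `"="`. Rows with an unparsable year or value, or a confidence score outside
#' 0–9, are dropped and counted in a rejection log attached as the
#' `"rejections"` attribute (a tibble of `row_number`, `reason`).
#'
#' @param path TSV or CSV file with a header row.
#' @param dialect column mapping from [activity_dialect()].
#' @param rejection_log optional path; when given, the rejection log is also
#'   written there as TSV.
#' @return a tibble of activity records with columns `compound_id`, `smiles`,
#'   `target_id`, `target_family`, `relationship_type`, `confidence_score`,
#'   `measurement_type`, `relation`, `value`, `units`, `value_nM`, `year`.
#' @export
read_activity_table <- function(path, dialect = activity_dialect(),
                                rejection_log = NULL) {
  stopifnot(inherits(dialect, "promiscuitrack_dialect"))
  raw <- read_delim_auto(path)
  # target_family is optional; an absent column means "no family labels"
  require_columns(raw, dialect[setdiff(names(dialect), "target_family")], path)

  tbl <- tibble(
    row_number = seq_len(nrow(raw)),
    compound_id = raw[[dialect$compound_id]],
    smiles = raw[[dialect$smiles]],
    target_id = raw[[dialect$target_id]],
    target_family = raw[[dialect$target_family]] %||% "",
    relationship_type = raw[[dialect$relationship_type]],
    confidence_score = suppressWarnings(as.integer(raw[[dialect$confidence_score]])),
    measurement_type = raw[[dialect$measurement_type]],
    relation = raw[[dialect$relation]],
    value = suppressWarnings(as.numeric(raw[[dialect$value]])),
    units = raw[[dialect$units]],
    year = suppressWarnings(as.integer(raw[[dialect$year]]))
  )
  tbl$target_family[is.na(tbl$target_family)] <- ""
  tbl$relation[is.na(tbl$relation) | !nzchar(trimws(tbl$relation))] <- "="

  value_given <- !is.na(raw[[dialect$value]]) & nzchar(trimws(raw[[dialect$value]]))
  reason <- rep(NA_character_, nrow(tbl))
  reason[is.na(tbl$year) | tbl$year < 1000L | tbl$year > 9999L] <- "unparsable year"
  reason[value_given & is.na(tbl$value)] <- "unparsable value"
  reason[!is.na(tbl$value) & tbl$value < 0] <- "negative value"
  reason[is.na(tbl$confidence_score) | tbl$confidence_score < 0L |
           tbl$confidence_score > 9L] <- "confidence score outside 0-9"

  rejections <- tibble(row_number = tbl$row_number[!is.na(reason)],
                       reason = reason[!is.na(reason)])
  out <- tbl[is.na(reason), , drop = FALSE]
  out$value_nM <- out$value * unname(unit_to_nM[out$units])
  out$row_number <- NULL

  if (!is.null(rejection_log)) write_tsv(rejections, rejection_log)
  if (nrow(rejections) > 0L) {
    inform(paste0("read_activity_table: dropped ", nrow(rejections),
                  " of ", nrow(raw), " rows (see attr 'rejections')"))
  }
  attr(out, "rejections") <- rejections
  out
}

#' Expand grouped target annotations to individual accessions
#'
#' Drug annotations sometimes name a protein group (e.g. a receptor with
#' several subunits) rather than a single protein; each group is expanded to
#' its member accessions, one row per accession, with duplicates removed.
#' Annotations with an empty group are dropped with a warning.
#'
#' @param drugs tibble with columns `drug_id`, `name`, `smiles`, `category`,
#'   `targets` (separator-joined accession list).
#' @param sep separator between accessions within `targets`.
#' @return long tibble with one row per (annotation, accession):
#'   `drug_id`, `name`, `smiles`, `category`, `target_id`.
#' @export
expand_target_groups <- function(drugs, sep = ";") {
  stopifnot(is.data.frame(drugs), "targets" %in% names(drugs))
  drugs <- as_tibble(drugs)
  empty <- is.na(drugs$targets) | !nzchar(trimws(drugs$targets))
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty),
                " drug annotation(s) with an empty target group"))
    drugs <- drugs[!empty, , drop = FALSE]
  }
  out <- drugs |>
    mutate(target_id = strsplit(.data$targets, sep, fixed = TRUE)) |>
    select(-"targets") |>
    unnest_longer("target_id") |>
    mutate(target_id = trimws(.data$target_id)) |>
    filter(nzchar(.data$target_id)) |>
    distinct()
  out
}

#' Read and validate a drug-annotation table
#'
#' Reads a TSV/CSV of drug annotations (drug id, name, structure, annotation
#' category, grouped target accessions) and expands target groups to one row
#' per accession via [expand_target_groups()].
#'
#' @param path TSV or CSV file with a header row.
#' @param dialect column mapping from [drug_dialect()].
#' @return long tibble with columns `drug_id`, `name`, `smiles`, `category`,
#'   `target_id`.
#' @export
read_drug_table <- function(path, dialect = drug_dialect()) {
  stopifnot(inherits(dialect, "promiscuitrack_dialect"))
  raw <- read_delim_auto(path)
  require_columns(raw, dialect[setdiff(names(dialect), "target_sep")], path)
  tbl <- tibble(
    drug_id = raw[[dialect$drug_id]],
    name = raw[[dialect$name]],
    smiles = raw[[dialect$smiles]],
    category = raw[[dialect$category]],
    targets = raw[[dialect$targets]]
  )
  expand_target_groups(tbl, sep = dialect$target_sep)
}
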