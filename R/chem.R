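# Chemistry backend: canonical SMILES standardization and SMARTS substructure
# search, via OpenBabel (ChemmineOB) and ChemmineR.

# Session-level cache: canonicalization is deterministic, so repeated pipeline
# runs over the same structures skip the OpenBabel round trip.
.canon_cache <- new.env(parent = emptyenv())

# Canonical SMILES of a single (single-fragment) SMILES string, optionally
# neutralizing common protonation states. Returns NA for unparsable input.
ob_canonical <- function(smi, neutralize = FALSE) {
  out <- tryCatch(
    if (neutralize) {
      ChemmineOB::convertFormat("SMI", "CAN", source = smi,
                                options = data.frame(names = "neutralize",
                                                     args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "CAN", source = smi)
    },
    error = function(e) ""
  )
  out <- strsplit(out, "[ \t\n]")[[1]]
  if (length(out) == 0L || !nzchar(out[1])) NA_character_ else out[1]
}

# Heavy-atom count parsed from a SMILES string; used only to rank fragments
# by size when reducing multi-fragment (salt) inputs.
smiles_heavy_atoms <- function(smi) {
  brackets <- gregexpr("\\[[^]]*\\]", smi)[[1]]
  n_br <- if (brackets[1] == -1L) 0L else {
    atoms <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
    sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", atoms))  # skip explicit H
  }
  bare <- gsub("\\[[^]]*\\]", "", smi)
  # organic-subset symbols outside brackets (two-letter symbols first)
  m <- gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", bare)[[1]]
  n_bare <- if (m[1] == -1L) 0L else length(m)
  n_br + n_bare
}

# TRUE if the fragment contains carbon (Cl is not carbon).
smiles_has_carbon <- function(smi) {
  grepl("C|c", gsub("Cl", "", smi))
}

standardize_one <- function(smi) {
  if (is.na(smi) || !nzchar(trimws(smi))) return(NA_character_)
  smi <- trimws(smi)
  hit <- get0(smi, envir = .canon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(NA_character_)
  # validate every fragment; an unparsable fragment invalidates the structure
  canon <- vapply(frags, ob_canonical, "", neutralize = FALSE)
  if (anyNA(canon)) {
    assign(smi, NA_character_, envir = .canon_cache)
    return(NA_character_)
  }
  sizes <- vapply(canon, smiles_heavy_atoms, 0L)
  organic <- vapply(canon, smiles_has_carbon, TRUE)
  keep <- if (any(organic)) which(organic) else seq_along(canon)
  # largest fragment; ties broken by canonical string for determinism
  keep <- keep[order(-sizes[keep], canon[keep])][1]
  out <- ob_canonical(canon[keep], neutralize = TRUE)
  assign(smi, out, envir = .canon_cache)
  out
}

#' Standardize structures to canonical SMILES
#'
#' Applies an open, deterministic standardization recipe: parse, reduce
#' multi-fragment inputs (salts) to the largest organic fragment, neutralize
#' common protonation states, and emit the OpenBabel canonical SMILES.
#' Canonicalization is a congruence for structure matching: two inputs denote
#' the same molecule if and only if their standardized strings are equal,
#' regardless of input atom ordering or aromaticity notation. Stereochemistry
#' annotations are preserved, so stereoisomers remain distinct.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` marks structures that
#'   failed to parse (these are excluded downstream).
#' @examples
#' \dontrun{
#' standardize_structure(c("C1=CC=CC=C1", "c1ccccc1"))  # identical output
#' standardize_structure("CC(=O)[O-].[Na+]")            # acetic acid
#' }
#' @export
standardize_structure <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  u <- unique(smiles)
  canon <- vapply(u, standardize_one, "", USE.NAMES = TRUE)
  unname(canon[match(smiles, u)])
}

# SMARTS substructure search over a set of SMILES. Returns an integer matrix
# of match counts, structures in rows, patterns in columns. Input structures
# must be valid (pre-standardized) SMILES.
smarts_match_counts <- function(smiles, patterns) {
  stopifnot(length(patterns) > 0L)
  ids <- sprintf("s%06d", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, ids))
  out <- matrix(0L, nrow = length(smiles), ncol = length(patterns),
                dimnames = list(ids, names(patterns)))
  for (j in seq_along(patterns)) {
    hits <- ChemmineR::smartsSearchOB(sdf, patterns[[j]], uniqueMatches = FALSE)
    out[names(hits), j] <- as.integer(hits)
  }
  out
}

# Validates that a SMARTS pattern parses, by probing it against methane.
smarts_is_valid <- function(smarts) {
  probe <- ChemmineR::smiles2sdf(c(probe = "CCO"))
  ok <- tryCatch(
    {
      ChemmineR::smartsSearchOB(probe, smarts, uniqueMatches = FALSE)
      TRUE
    },
    error = function(e) FALSE
  )
  ok
}
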