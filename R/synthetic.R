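# Synthetic activity-record and drug-annotation generator with known ground
# truth, emulating the structure of ChEMBL-like and DrugBank-like exports:
# dated activity releases across the 14 analysis intervals, three nested
# confidence tiers, heavy-tailed per-drug target counts with a small highly
# promiscuous subset, partially discordant annotation sets between the two
# table kinds, and a minority of PAINS-substructure-containing structures.

#' Configuration for the synthetic-data generator
#'
#' All fractions are probabilities in `[0, 1]`. The per-drug final target
#' count is a two-component mixture: with probability `tail_fraction` a
#' highly promiscuous drug with a uniform count in `tail_range`, otherwise
#' `1 +` a Poisson draw whose rate is set so that the overall expected count
#' equals `mean_promiscuity`.
#'
#' @param n_drugs number of approved drugs.
#' @param n_decoy_compounds bioactive compounds whose structures match no
#'   drug (exercise mapping exclusion).
#' @param mean_promiscuity expected final number of targets per drug.
#' @param tail_fraction fraction of highly promiscuous drugs.
#' @param tail_range integer range (low, high) of target counts in the
#'   promiscuous tail.
#' @param entry_weights length-14 probability weights of a drug's entry
#'   interval; default front-loads the "2000" interval (which absorbs all
#'   earlier years) the way accumulated legacy data does.
#' @param accrual_gap_mean mean gap in years between successive new targets
#'   of a drug.
#' @param measurement_probs probabilities of 1, 2 or 3 repeated measurements
#'   per (compound, target) pair.
#' @param inconsistency_prob probability that a multi-measurement pair is
#'   given discordant values (ratio > 10), exercising the high-tier
#'   rejection path.
#' @param um_fraction fraction of records expressed in µM instead of nM.
#' @param salt_fraction fraction of drug-table structures written as a
#'   deprotonated sodium salt (exercise standardization).
#' @param multi_compound_fraction fraction of drugs whose records are split
#'   across two compound ids sharing one structure (exercise union mapping).
#' @param unmatched_fraction fraction of drugs with no activity records at
#'   all.
#' @param db_only_mean mean number of annotation-only targets per drug
#'   (present in the drug table, absent from activity records).
#' @param chembl_only_fraction per-target probability that an
#'   activity-derived target is missing from the drug's annotation set.
#' @param low1_extra_mean,low2_extra_mean mean extra targets per drug that
#'   enter only the low1 (non-Ki/IC50 measurement types) or low2 (lower
#'   assay confidence) tier.
#' @param pains_fraction fraction of drugs carrying a grafted PAINS motif
#'   (a rhodanine ring), guaranteeing positive controls for screening.
#' @param potency_prange p-scale range (pKi/pIC50) from which potencies are
#'   drawn.
#' @param n_target_pool,n_families size of the target accession pool and the
#'   number of protein families it is partitioned into.
#' @param seed integer RNG seed; a fixed seed makes the output byte-identical
#'   across runs.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 500L,
                             n_decoy_compounds = 150L,
                             mean_promiscuity = 3.0,
                             tail_fraction = 0.05,
                             tail_range = c(12L, 30L),
                             entry_weights = c(0.15, rep(0.065, 12), 0.07),
                             accrual_gap_mean = 1.5,
                             measurement_probs = c(0.5, 0.3, 0.2),
                             inconsistency_prob = 0.05,
                             um_fraction = 0.15,
                             salt_fraction = 0.1,
                             multi_compound_fraction = 0.1,
                             unmatched_fraction = 0.1,
                             db_only_mean = 2,
                             chembl_only_fraction = 0.2,
                             low1_extra_mean = 2,
                             low2_extra_mean = 4,
                             pains_fraction = 0.05,
                             potency_prange = c(5, 8),
                             n_target_pool = 400L,
                             n_families = 20L,
                             seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(tail_fraction, inconsistency_prob, um_fraction, salt_fraction,
             multi_compound_fraction, unmatched_fraction,
             chembl_only_fraction, pains_fraction, entry_weights)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all fractions and weights must lie in [0, 1]")
  }
  if (length(entry_weights) != 14L || abs(sum(entry_weights) - 1) > 1e-8) {
    abort("entry_weights must be 14 probabilities summing to 1")
  }
  tail_mean <- mean(seq(tail_range[1], tail_range[2]))
  base_mean <- (mean_promiscuity - tail_fraction * tail_mean) /
    (1 - tail_fraction)
  if (base_mean < 1) {
    abort("mean_promiscuity too small for the configured promiscuous tail")
  }
  cfg$base_lambda <- base_mean - 1
  structure(cfg, class = "synthetic_config")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Distinct small-molecule SMILES for entity index i (1-based): an
# asymmetric C/N/O chain whose two arm lengths encode the index. `terminal`
# distinguishes entity classes so drug and decoy structures never collide.
chain_smiles <- function(i, terminal = "CCO") {
  a <- (i - 1L) %/% 41L
  b <- (i - 1L) %% 41L
  paste0(strrep("C", a), "N", strrep("C", b), terminal)
}

PAINS_TERMINAL <- "CC1SC(=S)NC1=O"   # grafted rhodanine ring
SALT_TERMINAL <- "CC[O-].[Na+]"      # deprotonated alkoxide sodium salt

LOW1_KINDS <- c("EC50", "Kd", "%max", "Efficacy", "Residual Activity",
                "Ki_approx")

empty_activity_table <- function() {
  tibble(
    compound_id = character(), smiles = character(), target_id = character(),
    target_family = character(), relationship_type = character(),
    confidence_score = integer(), measurement_type = character(),
    relation = character(), value = double(), units = character(),
    year = integer()
  )
}

#' Generate a synthetic data set with ground truth
#'
#' Produces an activity-record table and a drug-annotation table that
#' round-trip through [read_activity_table()] / [read_drug_table()], plus a
#' per-drug ground-truth table recording the generator's own draws: true
#' final promiscuity per tier, true entry interval and increase in the
#' high-confidence tier (accounting for pairs the consistency rule must
#' reject), and true PAINS status. High-tier interactions are a subset of
#' low1, which is a subset of low2, by construction.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `activities`,
#'   `drugs`, `ground_truth`, `family_map`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  pool <- sprintf("T%05d", seq_len(cfg$n_target_pool))
  family_map <- tibble(
    target_id = pool,
    family = sprintf("FAM%02d", ((seq_along(pool) - 1L) %% cfg$n_families) + 1L)
  )
  fam_of <- setNames(family_map$family, family_map$target_id)

  act_rows <- vector("list", cfg$n_drugs + cfg$n_decoy_compounds)
  drug_rows <- vector("list", cfg$n_drugs)
  truth_rows <- vector("list", cfg$n_drugs)

  measurement_rows <- function(compound_id, smiles, target_id, type,
                               first_year, n_meas, inconsistent, prange,
                               um_fraction) {
    p <- runif(1, prange[1], prange[2])
    base_nM <- 10^(9 - p)
    values_nM <- base_nM * exp(runif(n_meas, -0.5, 0.5))
    if (inconsistent) values_nM[1] <- values_nM[1] * 150
    years <- c(first_year,
               first_year + sample(0:3, n_meas - 1L, replace = TRUE))
    in_um <- runif(n_meas) < um_fraction
    tibble(
      compound_id = compound_id, smiles = smiles, target_id = target_id,
      target_family = unname(fam_of[target_id]),
      relationship_type = "D", confidence_score = 9L,
      measurement_type = type, relation = "=",
      value = ifelse(in_um, values_nM / 1e3, values_nM),
      units = ifelse(in_um, "uM", "nM"),
      year = as.integer(pmin(years, 2014L))
    )
  }

  for (i in seq_len(cfg$n_drugs)) {
    drug_id <- sprintf("DRUG%04d", i)
    pains <- runif(1) < cfg$pains_fraction
    matched <- runif(1) >= cfg$unmatched_fraction
    terminal <- if (pains) PAINS_TERMINAL else "CCO"
    smiles <- chain_smiles(i, terminal)

    # final target count: base + highly promiscuous tail mixture
    in_tail <- runif(1) < cfg$tail_fraction
    n_true <- if (in_tail) {
      sample(seq(cfg$tail_range[1], cfg$tail_range[2]), 1L)
    } else {
      1L + rpois(1L, cfg$base_lambda)
    }
    targets <- sample(pool, n_true)

    # dated accrual of targets from the entry interval onward
    entry_idx <- sample.int(14L, 1L, prob = cfg$entry_weights)
    entry_year <- if (entry_idx == 1L) {
      sample(1985:2000, 1L)
    } else if (entry_idx == 14L) {
      sample(2013:2014, 1L)
    } else {
      1999L + entry_idx
    }
    gaps <- if (n_true > 1L) rpois(n_true - 1L, cfg$accrual_gap_mean) else integer()
    target_years <- pmin(entry_year + cumsum(c(0L, gaps)), 2014L)

    n_meas <- sample(1:3, n_true, replace = TRUE, prob = cfg$measurement_probs)
    types <- sample(c("Ki", "IC50"), n_true, replace = TRUE)
    inconsistent <- n_meas >= 2L & runif(n_true) < cfg$inconsistency_prob

    # ground truth in the high-confidence tier: pairs with discordant
    # repeated measurements are rejected by the consistency rule
    surv <- !inconsistent
    surv_years <- target_years[surv]
    if (any(surv)) {
      entry_int <- min(as.integer(assign_interval(surv_years)))
      entry_rate <- sum(as.integer(assign_interval(surv_years)) == entry_int)
      truth_entry <- interval_labels()[entry_int]
      increase <- sum(surv) - entry_rate
    } else {
      truth_entry <- NA_character_
      entry_rate <- 0L
      increase <- 0L
    }

    # low-tier-only extras on targets disjoint from the drug's true set
    k1 <- rpois(1L, cfg$low1_extra_mean)
    k2 <- rpois(1L, cfg$low2_extra_mean)
    rest <- setdiff(pool, targets)
    low1_targets <- sample(rest, min(k1, length(rest)))
    rest2 <- setdiff(rest, low1_targets)
    low2_targets <- sample(rest2, min(k2, length(rest2)))

    if (matched) {
      cid <- sprintf("CMPD%04d", i)
      recs <- lapply(seq_len(n_true), function(k) {
        measurement_rows(cid, smiles, targets[k], types[k], target_years[k],
                         n_meas[k], inconsistent[k], cfg$potency_prange,
                         cfg$um_fraction)
      })
      recs <- bind_rows(recs)
      # optionally split this structure's targets across two compound ids
      # (whole targets, so per-pair consolidation is unaffected)
      if (n_true >= 2L && runif(1) < cfg$multi_compound_fraction) {
        second <- targets[seq_len(n_true) %% 2L == 0L]
        recs$compound_id[recs$target_id %in% second] <- paste0(cid, "b")
      }

      low1_recs <- if (length(low1_targets) > 0L) {
        kind <- sample(LOW1_KINDS, length(low1_targets), replace = TRUE)
        tibble(
          compound_id = cid, smiles = smiles, target_id = low1_targets,
          target_family = unname(fam_of[low1_targets]),
          relationship_type = "D", confidence_score = 9L,
          measurement_type = ifelse(kind == "Ki_approx", "Ki", kind),
          relation = ifelse(kind == "Ki_approx", ">", "="),
          value = ifelse(kind %in% c("EC50", "Kd", "Ki_approx"),
                         10^(9 - runif(length(low1_targets),
                                       cfg$potency_prange[1],
                                       cfg$potency_prange[2])),
                         runif(length(low1_targets), 0, 100)),
          units = ifelse(kind %in% c("EC50", "Kd", "Ki_approx"), "nM", ""),
          year = sample(2000:2014, length(low1_targets), replace = TRUE)
        )
      } else empty_activity_table()

      low2_recs <- if (length(low2_targets) > 0L) {
        tibble(
          compound_id = cid, smiles = smiles, target_id = low2_targets,
          target_family = unname(fam_of[low2_targets]),
          relationship_type = sample(c("H", "S", "U"), length(low2_targets),
                                     replace = TRUE),
          confidence_score = sample(0:8, length(low2_targets), replace = TRUE),
          measurement_type = sample(c("Ki", "IC50", "EC50", "%max"),
                                    length(low2_targets), replace = TRUE),
          relation = "=",
          value = 10^(9 - runif(length(low2_targets), cfg$potency_prange[1],
                                cfg$potency_prange[2])),
          units = "nM",
          year = sample(2000:2014, length(low2_targets), replace = TRUE)
        )
      } else empty_activity_table()

      act_rows[[i]] <- bind_rows(recs, low1_recs, low2_recs)
    }

    # annotation side: drop activity targets with the discordance
    # probability, add annotation-only extras
    keep_db <- runif(n_true) >= cfg$chembl_only_fraction
    db_extra <- sample(rest, min(rpois(1L, cfg$db_only_mean), length(rest)))
    db_targets <- c(targets[keep_db], db_extra)
    if (length(db_targets) == 0L) db_targets <- targets[1]

    table_smiles <- if (!pains && runif(1) < cfg$salt_fraction) {
      chain_smiles(i, SALT_TERMINAL)
    } else smiles

    drug_rows[[i]] <- tibble(
      drug_id = drug_id, name = paste("Drug", i), smiles = table_smiles,
      category = "drug-action target",
      targets = paste(sort(db_targets), collapse = ";")
    )

    truth_rows[[i]] <- tibble(
      drug_id = drug_id, matched = matched, pains = pains,
      n_targets_drawn = n_true,
      n_targets_high = sum(surv),
      entry_interval_high = truth_entry,
      entry_rate_high = entry_rate,
      increase_high = increase,
      n_targets_low1 = n_true + length(low1_targets),
      n_targets_low2 = n_true + length(low1_targets) + length(low2_targets),
      n_db_targets = length(unique(db_targets))
    )
  }

  # decoy compounds: bioactive structures matching no drug
  for (j in seq_len(cfg$n_decoy_compounds)) {
    cid <- sprintf("DECOY%04d", j)
    smiles <- chain_smiles(j, "C(F)(F)F")
    n_t <- sample(1:3, 1L)
    tg <- sample(pool, n_t)
    yr <- sample(2000:2014, n_t, replace = TRUE)
    act_rows[[cfg$n_drugs + j]] <- bind_rows(lapply(seq_len(n_t), function(k) {
      measurement_rows(cid, smiles, tg[k], sample(c("Ki", "IC50"), 1L), yr[k],
                       1L, FALSE, cfg$potency_prange, cfg$um_fraction)
    }))
  }

  structure(
    list(
      activities = bind_rows(act_rows),
      drugs = bind_rows(drug_rows),
      ground_truth = bind_rows(truth_rows),
      family_map = family_map,
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic data set to TSV files
#'
#' Writes `activities.tsv`, `drugs.tsv`, `ground_truth.tsv` and
#' `family_map.tsv` into a directory; the first two re-read cleanly through
#' the ingest functions with zero rejections.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("activities.tsv", "drugs.tsv",
                            "ground_truth.tsv", "family_map.tsv"))
  write_tsv(dataset$activities, paths[1])
  write_tsv(dataset$drugs, paths[2])
  write_tsv(dataset$ground_truth, paths[3])
  write_tsv(dataset$family_map, paths[4])
  invisible(paths)
}
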