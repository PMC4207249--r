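---
title: "Monitoring drug promiscuity over time: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring drug promiscuity over time: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promiscuitrack)
```

## The problem

A drug's *promiscuity rate* is the number of distinct protein targets it is
reported to be active against. Promiscuity underlies polypharmacology, but
estimates of it vary wildly with the data-selection criteria used: target
counts read off annotation databases (DrugBank-like) are routinely several
times higher than counts derived from high-confidence bioactivity
measurements (ChEMBL-like). Because activity records carry release dates,
one can also ask how apparent promiscuity *grows* as databases accumulate
data — and how much of that growth survives stringent curation.

`promiscuitrack` implements this monitoring analysis as a reusable pipeline:

1. **ingest** — read activity-record and drug-annotation tables, standardize
   structures to canonical SMILES, expand grouped target annotations to
   individual UniProt-style accessions;
2. **curation** — build three nested confidence tiers and consolidate
   repeated measurements per (compound, target) pair;
3. **mapping** — match drugs to bioactive compounds by canonical-SMILES
   identity;
4. **temporal** — bin records into 14 release-year intervals and build
   cumulative per-drug activity profiles;
5. **stats** — per-interval promiscuity distributions, per-drug increases,
   cross-database comparison, target-family profiles, potency distributions;
6. **pains** — flag drugs containing pan-assay-interference (PAINS)
   substructures and compare their trend against all drugs.

## Confidence tiers

Curation stringency is organized as three nested tiers:

* **high** — direct assays (relationship type `"D"`) at confidence score 9,
  with explicitly defined (`"="` relation) Ki or IC50 values. Repeated
  measurements of the same pair and type are retained only if all values
  fall within one order of magnitude (max/min ≤ 10, boundary inclusive);
  otherwise the target activity is omitted.
* **low1** — type `"D"`, score 9, but any measurement type (EC50, Kd, %max,
  Efficacy, Residual Activity, ...), any relation, and no consistency check.
* **low2** — every record.

At interaction level high ⊆ low1 ⊆ low2 always holds, and the package's
property tests assert it on randomized synthetic data.

Two decisions here were genuinely open. First, Ki and IC50 measurements for
one pair are consistency-checked *separately per measurement type*, and the
pair survives the high tier if at least one type passes; the assay-dependent
and assay-independent scales are never mixed in one order-of-magnitude
check. Second, "same order of magnitude" is operationalized as
log10(max) − log10(min) ≤ 1 with the boundary inclusive and a 1e-9 log-scale
tolerance, so the decision is deterministic at the exact 10× boundary.

Consolidated potency is the geometric mean of the contributing
concentrations — potencies are log-distributed, so the arithmetic mean would
be dominated by the weakest value. When both Ki and IC50 pass, the reported
type is the one with more measurements, ties favouring Ki as the
assay-independent constant. All concentrations are normalized to nM at
ingest (µM × 10³, M × 10⁹); p-scale values are −log10(molar), so 100 nM maps
to 7.0.

## Structure standardization and matching

Drug and compound names differ across databases, so drugs are mapped to
compounds purely by exact equality of standardized canonical SMILES. The
standardization recipe is: parse, reduce multi-fragment inputs to the
largest organic fragment (salt stripping; ties broken by canonical string),
neutralize common protonation states, and emit OpenBabel canonical SMILES.
It is idempotent and invariant to input atom ordering. Stereochemistry
annotations are preserved, so stereoisomers deliberately do not match;
tautomer canonicalization is out of scope. A drug matching several compound
entries with the same structure inherits the union of their interactions,
with the per-target first year minimized across compounds.

## Time intervals and cumulative profiles

Records are organized into 14 ordered intervals: `"2000"` (absorbing
everything reported up to 2000, the analysis start), the individual years
2001–2012, and `">2012"`. Each target is anchored at the interval of its
first report; the cumulative profile at an interval is the set of targets
first reported at or before it. Profiles are therefore monotone
non-decreasing, and the rate at the last interval equals the drug's total
distinct-target count. A drug is *absent* from intervals before its entry —
per-interval distributions are over drugs for which data exist, not
zero-padded. Record spans use raw years rather than interval labels: a drug
first reported in 1981 and last in 2005 spans 24 years even though 1981 is
binned to "2000".

The per-drug *increase* is the final-interval rate minus the entry-interval
rate (never negative), binned into 0, 1, ..., 10, ">10" for target-level
histograms and 0, ..., 5, ">5" for family-level histograms; both upper bins
are configurable. Family profiles count distinct families of the cumulative
target set; the family taxonomy is not a built-in ontology but an input
column (or any `target_id` → `family` table), with unmapped targets labelled
`"unassigned"`.

## Statistics conventions

Quartiles use linear interpolation between order statistics (R's default
type 7), stated explicitly because summary conventions differ between
software. Interval box summaries report min/max extremes; potency
distributions report Tukey boxes with whiskers at the most extreme points
within 1.5 interquartile ranges of the quartiles and explicit outlier
lists. Percentages in histogram tables are rounded half-up to one decimal,
matching the usual table formatting convention. Only Ki/IC50-typed values
ever enter potency distributions, in every tier; non-concentration
measurement types count as interactions but carry no p-scale value.

## PAINS screening

Drugs are screened against a SMARTS pattern file; a drug is positive if any
pattern matches. The package ships a small default list covering well-known
PAINS motif classes (rhodanines, para-quinones, catechols, hydroxyphenyl
hydrazones, aromatic azo linkages, alkylidene barbiturates, ...). This
default is deliberately data, not code: published PAINS collections differ
in size and scope, so any curated SMARTS table can be supplied instead, and
the packaged list makes no claim to reproduce any particular published
filter set. The trend comparison contrasts mean cumulative rates of the
positive subset against all drugs; restriction to a subset is a pure
projection and never changes an individual drug's rates.

## The synthetic-data generator

Real ChEMBL/DrugBank snapshots are release-dependent and far beyond desk
scale, so validation runs on a generator whose draws are recorded as ground
truth. It emulates the *structure* of the real inputs:

* per-drug final target counts from a two-component mixture — most drugs
  draw `1 + Poisson`, a small fraction (default 5%) draws uniformly from
  12–30 targets, mirroring the small highly promiscuous subset that
  dominates average rates; the base rate is solved so the overall mean hits
  `mean_promiscuity` (default 3.0 targets per drug);
* entry intervals over all 14 bins, front-loaded at "2000" (default weight
  0.15) the way accumulated legacy data is, with later targets accruing at
  mean gaps of 1.5 years;
* one to three measurements per pair with within-order scatter, a
  configurable fraction (default 5%) made discordant (ratio > 10) to
  exercise the high-tier rejection path;
* tier-only extras per drug (non-Ki/IC50 measurement types or approximate
  relations for low1, sub-threshold assay confidence for low2), so the
  nested tiers differ by construction;
* annotation discordance: each activity-derived target is missing from the
  drug table with probability 0.2, and on average two annotation-only
  targets are added per drug;
* structural realism hooks rather than realistic chemistry: index-encoded
  heteroatom chains give every entity a distinct valid structure; a
  configurable fraction carries a grafted rhodanine ring (a guaranteed
  PAINS-positive control), another is written as a deprotonated sodium salt
  to exercise salt stripping, 15% of records are expressed in µM, and a
  tenth of drugs have records split across two compound ids sharing one
  structure.

These defaults were chosen once, as plausible for a drug-sized corpus, and
the parameter-recovery tests compare pipeline output against the
generator's own draws: exactly where deterministic (per-drug rates, entry
intervals, increases, PAINS flags) and within three standard errors where
sampling is involved (mean promiscuity, PAINS fraction). What the generator
does *not* emulate: realistic medicinal-chemistry structures, assay-level
biology, name ambiguity, or curation errors other than measurement
discordance — so green tests demonstrate the pipeline's correctness on
schema-faithful data, not robustness to every pathology of real exports.

Test suites run at deliberately modest sizes — property suites on 50–80
drug landscapes over a few seeds, parameter recovery on a 500-drug
landscape — which keeps the whole suite under a couple of minutes on one
CPU while leaving sampling error small relative to the three-standard-error
bands.

## Degenerate inputs and edge behaviour

Empty input files, missing required columns, unknown tier names and
unparsable SMARTS patterns are fatal; unparsable years/values, out-of-range
confidence scores, empty target groups, invalid structures and undated
drugs are dropped with logged warnings (rejection logs are returned and
optionally written as TSV). Blank relations are read as `"="`, since
explicit values dominate real exports. Single-measurement pairs are always
consistent; single-value distributions collapse all box statistics onto the
value with no outliers.

## Known limitations

* Matching is exact-string on canonical SMILES: stereoisomers and salts of
  record (after stripping) match or fail deterministically, but no
  InChIKey-style or fuzzy matching is attempted.
* The high-tier per-type consistency decision (retain the pair if one
  measurement type passes) is one defensible reading of the
  order-of-magnitude rule; the alternative — dropping the pair when any
  type is discordant — would give slightly smaller high-tier sets.
* "Human targets" are assumed pre-filtered or flagged upstream; no species
  filter is applied beyond the input columns.
* Sub-year resolution and live database parsing (SQL dumps, XML) are out of
  scope; inputs are pre-normalized tables.
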