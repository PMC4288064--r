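---
title: "Methods: SNP-based risk assessment in snprisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based risk assessment in snprisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprisk)
```

# Scope and model overview

`snprisk` assesses a person's genetic risk for a polygenic disease
(prostate cancer is the motivating case) from two inputs: a curated
knowledge base of SNP–disease associations and a raw direct-to-consumer
genotype file. It deliberately separates three layers that are often
conflated:

* **curation** — which OR to believe for each SNP allele, and how much to
  trust it;
* **matching** — which of the curated SNPs this genome actually carries,
  with missing data (no-calls, off-chip SNPs) kept distinct from absent
  risk;
* **interpretation** — independent per-SNP summaries, small published SNP
  panels with reference-table lookup, decision-tree branch sets, and
  polygenic aggregate scores.

Every number a report shows is recomputable from the recorded inputs; no
stage injects hidden defaults.

# Knowledge-base curation

## Evidence grading

Each association is scored 1–3 on six criteria; the *evidence degree* is
their arithmetic mean, so it lies in [1, 3] and is monotone in every
criterion. The bins:

| criterion | 1 | 2 | 3 |
|---|---|---|---|
| article citations | 1–15 | 16–50 | > 50 |
| study type × authors | research, < 10 | research 10–34; meta-analysis < 7 | research ≥ 35; meta-analysis ≥ 7 |
| population race | other | mixed | Caucasian |
| sample size (smaller arm) | < 100 | 100–1000 | > 1000 |
| PubMed articles | < 7 | 7–19 | ≥ 20 |
| model membership | none | 1–2 | ≥ 3 |

Three conventions were genuinely open and are fixed here:

* **Category thresholds.** The evidence categories partition [1, 3]
  half-open and low-inclusive: weak < 1.5 ≤ moderate < 2.3 ≤ strong. This
  is the only reading under which every degree receives exactly one
  category; the boundaries are tested explicitly.
* **Bin edges at 1000 and 19.** The published bin wordings leave a sample
  size of exactly 1000 and an article count of exactly 19 unassigned; both
  are closed into the middle bin (score 2), keeping each scale a
  partition.
* **Sample size of "each arm".** Scoring uses `min(cases, controls)`, so
  a study only reaches a bin if *both* arms clear it — the conservative
  reading; mean or max would let one large arm mask a tiny one.

Missing metadata is never dropped and never guessed upward: the affected
criterion scores 1 (the floor) and the record is flagged
(`metadata_imputed`).

The *impact degree* categorizes the OR itself: weak < 2.0 ≤ moderate
< 2.5 ≤ strong. Both category axes are deliberately coarse — they exist
so a reader can see at a glance whether a hit list is "many weak, well
replicated" or "few strong, thinly supported", not to feed arithmetic
(the numeric OR is retained for that).

## Identifier and strand hygiene

rsIDs are pushed through a merge map (old → current identifier) by
iterated lookup with cycle detection; reverse-strand risk alleles are
Watson–Crick complemented. A single reported allele cannot prove its own
strand — for A/T and C/G SNPs the complement is itself a plausible allele
— so the per-record `reported_strand` metadata is trusted, and every flip
is reported in a warning rather than silently applied.

## Redundancy resolution

Multiple studies usually report different ORs for one SNP allele. One
value per (rsID, allele) is selected by a lexicographic four-phase
filter: population race (Caucasian > mixed > other, matching the
ancestry of the intended genomes), study type (meta-analysis > single
study), citation count, and finally the higher OR. Two tie-breaks beyond
the four phases — narrower confidence interval, then source tag — make
the build order-independent; permutation invariance and agreement with a
brute-force phase-by-phase oracle are property-tested.

# Genotype handling

The raw format is four tab-separated columns (rsid, chromosome, position,
genotype) with `#` comments. Conventions, each of which affects scores:

* **No-call vs off-chip.** A `--` genotype at a knowledge-base SNP and a
  SNP absent from the file both remove the SNP from every score, but they
  are counted separately (`n_nocall` vs `n_missing`), because model
  abstention ("unknown" verdicts) should be attributable.
* **Hemizygous calls** (single-letter genotypes on X/Y/MT in males — one
  shipped panel includes an X-linked SNP) count as risk-carrying for both
  dominant and recessive evaluation but weigh 1 in additive scores: one
  allele cannot be carried twice.
* **Duplicates / vendor IDs / indels.** Duplicate rsID lines keep the
  first occurrence with a warning; `i`-prefixed vendor IDs are retained
  but can never match the knowledge base; D/I (indel) genotypes are
  treated as carrying no risk, with a warning, since indels are out of
  scope.
* **Genome build.** Positions are carried as opaque metadata; all
  matching is by rsID, so build 36 and build 37 files behave identically.
  This is also the main limitation: a file whose rsIDs predate the merge
  map's coverage can silently fail to match.

# Independent association scores

Four summaries are computed over the risk-carrying hits: SNP count and
evidence-impact degree, each dominant (every hit counts once) and
additive (homozygotes weighted 2). The evidence-impact contribution per
SNP is the **product** of the evidence rank and impact rank (each 1–3),
so one strong/strong SNP (9) outweighs two weak/weak SNPs (2) — the
source method names both ranks but not the operator, so the operator is a
package decision; a sum rule ships behind `combine = "sum"` for
sensitivity checks, and neither is claimed as the original. By
construction additive ≥ dominant, with equality exactly when no hit is
homozygous; this invariant is property-tested.

# Cumulative models

A cumulative model is a panel of SNPs with per-SNP genetic models:
dominant SNPs contribute one unit of impact for one or two risk alleles,
recessive SNPs only when homozygous. Positive family health history adds
one unit when the panel supports it. The total impact indexes a published
reference table of ORs; the table must cover every reachable impact level
and be monotone non-decreasing, both enforced at load.

Decisions made here:

* **Missing data.** Default (`mode = "strict"`) follows abstention
  semantics: if any panel SNP is unassayed or uncalled, the whole model
  returns status `unknown` rather than a biased partial score. An
  exploratory `mode = "bounds"` brackets each missing SNP as 0/1 impact
  and reports the impact and OR ranges, classifying only when the whole
  range falls on one side of the high-risk threshold (OR 2.5).
* **Unknown family history** is evaluated in the without-FHH column and
  flagged `fhh_used = "without_fhh"`; it is never imputed positive.
* **Shipped panels.** Six panels ship under `inst/extdata/models/`. Only
  the 5-SNP panel ("5-SNP_Zheng": dominant rs1447295-A, rs16901979-A,
  rs6983267-G; recessive rs1859962-G, rs4430796-A, with FHH extension)
  carries its published reference table, which the tests reproduce
  column by column. The other five panels have published SNP lists but
  their full reference tables are not available in open text, so they
  ship with clearly labelled synthetic stand-in tables
  (`reference_table_source = "synthetic"`, geometric OR progression) that
  are schema-valid for pipeline and structure testing but must not be
  used for real interpretation.

```{r}
m <- zheng_model()
m$reference_table
```

# Branch-set models

A branch-set model encodes a trained classifier (e.g. a decision tree
distilled from an SVM/ID3 hybrid) as a disjunction of conjunctive
requirement sets over genotypes and, optionally, clinical fields (BMI
class, smoking, alcohol). Requirements come in two forms: exact genotype
(unordered — "AG" matches "GA") and allele presence. Evaluation is
three-valued per requirement (satisfied / violated / unanswerable), which
induces the branch states matched / contradicted / indeterminate and the
verdict: `at_risk` if any branch matches, `risk_free` only if *every*
branch is contradicted by observed data, otherwise `indeterminate`. This
keeps "no evidence of risk" distinct from "evidence of no risk": a missing
smoking datum on an otherwise-matching branch yields `indeterminate`, not
`risk_free`. Published accuracy/precision/recall are carried as display
metadata and never recomputed, since the training data is out of scope.
The shipped branch-set file is a small synthetic example of the structure;
real branch sets load through the same JSON schema.

# Polygenic scores

With allele count $w_i \in \{1,2\}$ and per-allele OR $r_i$: count
$= \sum_i w_i$; log-odds $= \sum_i w_i \ln r_i$; multiplicative OR
$= \prod_i r_i^{w_i}$. The identity
$\exp(\text{log-odds}) = \text{multiplicative OR}$ holds to floating
precision and is tested at $10^{-12}$ over random hit sets. The
multiplicative lifetime risk requires an average population risk — a
quantity that depends on age band and population, so the package ships
**no default**; when supplied, risk $= \text{OR} \times$ baseline, capped
at 1 and flagged when the cap binds (the multiplicative model is a crude
upper-tail approximation and the cap makes that visible). Per-genotype
weighting (every hit once) is available as `weighting = "genotype"`.

# Synthetic data and what the tests show

`generate_synthetic_genome()` writes raw-format genomes with planted
zygosities (hom / het / no-call / absent) at knowledge-base SNPs plus
background records disjoint from the KB; `simulate_cohort()` produces a
seeded cohort (default 4 cases + 15 controls, a realistic small
case-control evaluation design) with a truth manifest. The generator is
deterministic given a seed, restores the caller's RNG state, and draws
het partners uniformly from the non-risk alleles with randomized
character order, so order-symmetry is exercised.

The generator emulates structure, not population genetics: it has no
linkage disequilibrium, no realistic allele frequencies, no genotyping
error, and background SNPs never collide with the KB. Passing tests
therefore demonstrate that extraction, scoring and model evaluation are
*exact* on known inputs — not that the models are calibrated on real
cohorts. Cohort-level published tallies (category distributions over a
real case-control set, model accuracy figures) require the original
subject files and unpublished appendices and are intentionally not
reproduced; the property suites and the verbatim 5-SNP reference table
stand in for them.

Problem sizes used by the test suite were chosen to exercise the
combinatorics while keeping the suite fast: 1000 random candidate sets
(≤ 10 candidates) for selection, 100 synthetic genomes over a 15-SNP KB
for planted-truth recovery, 1000 random hit sets for the polygenic
identity, and 60 random branch-set models (≤ 10 branches) for verdict
equivalence, all under fixed seeds.

# Numerical and degenerate-input choices

* Reference-table ORs are compared and stored at full precision; JSON
  serialization uses `digits = NA` so save/load round trips are exact.
* Empty hit lists are valid everywhere: scores 0, multiplicative OR 1,
  all-zero category grid.
* An impact level outside a reference table is an error (tables are
  validated complete at load, so this can only mean a corrupted model
  file).
* Candidate validation rejects non-positive ORs, ORs outside their own
  confidence interval, negative counts and malformed rsIDs up front, so
  downstream code never defends against them.

# Known limitations

* Curation quality metrics are indirect proxies (citations, sample size);
  they rank reporting quality, not causal credibility.
* rsID-keyed matching inherits dbSNP's merge history; the merge map must
  be supplied and current.
* Strand disambiguation for A/T and C/G SNPs rests entirely on the
  reported-strand metadata.
* The synthetic reference tables for five of the six shipped panels are
  placeholders; conclusions about those panels require their published
  tables.
* No VCF ingestion, imputation, build liftover or indel support.
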