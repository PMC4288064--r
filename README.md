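# snprisk

Personal SNP-based disease risk assessment from direct-to-consumer
genotype data.

Common diseases such as prostate cancer are polygenic: dozens of single
nucleotide polymorphisms (SNPs) each shift the odds of disease by a modest
amount, and the literature reports those shifts as per-allele odds ratios
(ORs) of varying quality. `snprisk` is a toolkit for clinicians,
bioinformaticians and informatics researchers who want to turn (a) a
curated set of SNP–disease association reports and (b) a person's raw
direct-to-consumer genotype file (23andMe-style TSV) into a structured,
reproducible risk report. It covers the whole path from literature
curation to per-person interpretation:

1. **Knowledge-base curation** (`build_kb()`). Association candidates are
   validated, rsIDs updated through dbSNP merge chains, reverse-strand
   risk alleles complemented to the forward strand, and redundant reports
   for the same (rsID, allele) resolved by a four-phase preference order
   (study population race, then meta-analysis over single studies, then
   citation count, then higher OR). Each surviving association is graded
   on six evidence criteria, each scored 1–3 (article citations, study
   type × author count, population race, sample size of the smaller study
   arm, PubMed article volume, membership in published risk models). The
   *evidence degree* is the mean of the six scores, categorized weak
   (< 1.5) / moderate ([1.5, 2.3)) / strong (≥ 2.3); the *impact degree*
   categorizes the OR as weak (< 2.0) / moderate ([2.0, 2.5)) / strong
   (≥ 2.5).
2. **Genotype ingestion** (`parse_genome()`, `genotype_zygosity()`).
   Tolerant parsing of raw genotype files, with explicit handling of
   no-calls (`--`), duplicate lines, hemizygous X/Y/MT calls and
   vendor-internal IDs.
3. **Independent association scoring** (`extract_hits()`,
   `independent_scores()`). The knowledge base is matched against the
   genome; risk-carrying SNPs are scored four ways: SNP count and
   evidence×impact degree, each under *dominant* weighting (every
   risk-carrying genotype counts once) and *additive* weighting
   (homozygotes count twice):
   count_add = Σᵢ wᵢ and EI_add = Σᵢ wᵢ·Eᵢ·Iᵢ, with wᵢ ∈ {1, 2} the
   zygosity weight and Eᵢ, Iᵢ ∈ {1, 2, 3} the category ranks.
4. **Model-based assessment.**
   - *Cumulative models* (`evaluate_cumulative()`): small SNP panels where
     each SNP contributes one unit of impact under a dominant or recessive
     genetic model, plus optionally one unit for positive family health
     history (FHH); the total impact is looked up in a published
     reference table of ORs. Six panels ship with the package, including
     the 5-SNP panel whose reference table is transcribed in full.
   - *Branch-set models* (`match_branches()`): decision-tree style
     disjunctions of genotype (+clinical) requirement sets with a
     three-valued verdict — `at_risk` when any branch is fully matched,
     `risk_free` when every branch is contradicted by available data,
     `indeterminate` when missing data (no-calls, off-chip SNPs, unknown
     smoking/alcohol/BMI status) leaves a branch undecided.
   - *Polygenic scores* (`polygenic_scores()`): count method Σ wᵢ,
     log-odds method Σ wᵢ ln ORᵢ, and the multiplicative model
     Π ORᵢ^wᵢ, optionally scaled by an average population risk into a
     lifetime-risk estimate.

`assess()` runs all stages and returns a deterministic report;
`generate_synthetic_genome()` and `simulate_cohort()` create seeded raw
files with planted genotypes so the whole pipeline can be validated
against known truth.

## Worked example

```r
library(snprisk)

# 1. curate a knowledge base from a candidate table (synthetic example data)
cands <- read_candidates(system.file("extdata",
  "example_candidates_synthetic.tsv", package = "snprisk"))
merge_map <- read_merge_map(system.file("extdata",
  "example_merge_map_synthetic.tsv", package = "snprisk"))
kb <- build_kb(cands, merge_map)
print(kb)
#> <snp_kb> disease C61 | version 0.1.0 | 10 associations
#>           evidence
#> impact     weak moderate strong
#>   weak        1        1      6
#>   moderate    0        0      1
#>   strong      0        0      1

# 2. a synthetic subject homozygous for the risk allele at the 5-SNP panel
genome <- generate_synthetic_genome(
  kb,
  planted = c(rs1447295 = "hom", rs16901979 = "het", rs6983267 = "hom",
              rs1859962 = "hom", rs4430796 = "hom"),
  n_background = 50, seed = 42, subject_id = "demo"
)

# 3. assess against the knowledge base and the shipped 5-SNP panel
report <- assess(genome, kb, models = list(zheng_model()), fhh = "positive")
print(report)
#> == Personal risk report: demo ==
#> Independent association scores
#>    SNP count       dominant: 5  additive: 9
#>    evidence-impact dominant: 15  additive: 27
#>    KB SNPs assayed: 5  missing: 5  no-call: 0
#>   hits by impact x evidence (total 5 ):
#>           evidence
#> impact     strong moderate weak
#>   strong        0        0    0
#>   moderate      0        0    0
#>   weak          5        0    0
#> <cumulative_result> 5-SNP_Zheng | status evaluated
#>   total impact 6 -> OR 9.46 ( high )
#> Polygenic scores: count 9 | log-odds 2.965 | multiplicative OR 19.4
```

Reading the output: the subject carries 5 of the 10 knowledge-base SNPs
(four of them homozygous, hence additive count 9); all five hits are
low-OR ("weak impact") associations backed by strong evidence. On the
5-SNP cumulative panel the subject has all five impact factors plus
positive family health history — total impact 6, which the model's
reference table maps to a 9.46-fold increase in odds relative to a person
with no impact factors. The polygenic multiplicative OR (19.4) aggregates
all ten knowledge-base associations instead of the five-SNP panel, and
would be multiplied by an average population risk (user-supplied) to
produce a lifetime-risk estimate.

A command-line interface with the same functionality is installed at
`exec/snprisk` (verbs `assess`, `build-kb`, `simulate`,
`cohort-summary`).

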