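# Matching a personal genome against the knowledge base and scoring the
# resulting clinically relevant SNPs (CR-SNPs) with the four independent
# approaches: SNP counts and evidence-impact degrees, each under dominant
# and additive weighting.

#' Extract personal clinicogenomic association hits
#'
#' For every knowledge-base association, looks up the rsID in the genome
#' and keeps those carrying at least one risk allele. SNPs assayed but
#' uncalled (`"--"`) and SNPs absent from the chip are excluded from the
#' hits but counted separately: both remove the SNP from all scores, but
#' they have different meanings when a model reports "unknown".
#'
#' @param genome A `personal_genome`.
#' @param kb A `snp_kb`.
#' @return An `assoc_hits` object: data frame with one row per risk-
#'   carrying association (rsid, risk_allele, odds_ratio, evidence/impact
#'   categories, zygosity, zygosity_weight) plus attributes `n_kb_snps`,
#'   `n_assayed`, `n_nocall`, `n_missing` and `subject_id`.
#' @export
extract_hits <- function(genome, kb) {
  stopifnot(inherits(genome, "personal_genome"), inherits(kb, "snp_kb"))
  assoc <- kb$associations
  idx <- match(assoc$rsid, genome$records$rsid)
  assayed <- !is.na(idx)
  genotype <- rep(NA_character_, nrow(assoc))
  genotype[assayed] <- genome$records$genotype[idx[assayed]]

  zyg <- rep("absent", nrow(assoc))
  if (any(assayed)) {
    zyg[assayed] <- genotype_zygosity(genotype[assayed],
                                      assoc$risk_allele[assayed])
  }
  risky <- zyg %in% c("hom_risk", "het_risk", "hemizygous_risk")
  hits <- assoc[risky, c("rsid", "risk_allele", "odds_ratio",
                         "evidence_degree", "evidence_category",
                         "impact_category", "source")]
  hits$genotype <- genotype[risky]
  hits$zygosity <- zyg[risky]
  hits$zygosity_weight <- ifelse(hits$zygosity == "hom_risk", 2L, 1L)
  rownames(hits) <- NULL
  structure(hits, class = c("assoc_hits", "data.frame"),
            n_kb_snps = nrow(assoc),
            n_assayed = sum(assayed),
            n_nocall = sum(zyg == "nocall"),
            n_missing = sum(zyg == "absent"),
            subject_id = genome$subject_id)
}

CATEGORY_RANK <- c(weak = 1L, moderate = 2L, strong = 3L)

check_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  needed <- c("zygosity", "zygosity_weight")
  if (!all(needed %in% names(hits))) {
    stop("hits must carry zygosity and zygosity_weight (see extract_hits)",
         call. = FALSE)
  }
  invisible(hits)
}

#' SNP-count risk score
#'
#' Dominant mode counts each risk-carrying SNP once; additive mode weights
#' homozygous SNPs twice as much as heterozygous ones (hemizygous calls
#' carry a single allele and weigh 1).
#'
#' @param hits Hits from [extract_hits()].
#' @param mode `"dominant"` or `"additive"`.
#' @return Integer score.
#' @export
score_snp_count <- function(hits, mode = c("dominant", "additive")) {
  mode <- match.arg(mode)
  check_hits(hits)
  if (mode == "dominant") nrow(hits) else sum(hits$zygosity_weight)
}

#' Evidence-impact risk score
#'
#' Each risk-carrying SNP contributes a per-SNP degree built from its
#' evidence category and impact category, both ranked weak=1, moderate=2,
#' strong=3. The two ranks are combined by `combine` (product by default,
#' so a strong/strong SNP contributes 9 and outweighs two weak/weak SNPs;
#' `"sum"` is available as an alternative). Additive mode multiplies each
#' contribution by the zygosity weight (het 1, hom 2).
#'
#' @param hits Hits from [extract_hits()].
#' @param mode `"dominant"` or `"additive"`.
#' @param combine `"product"` or `"sum"` of the two category ranks.
#' @return Numeric score.
#' @export
score_evidence_impact <- function(hits, mode = c("dominant", "additive"),
                                  combine = c("product", "sum")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  check_hits(hits)
  if (nrow(hits) == 0L) return(0)
  ev <- CATEGORY_RANK[hits$evidence_category]
  im <- CATEGORY_RANK[hits$impact_category]
  per_snp <- if (combine == "product") ev * im else ev + im
  w <- if (mode == "additive") hits$zygosity_weight else 1L
  sum(per_snp * w)
}

#' All four independent association scores at once
#'
#' @param hits Hits from [extract_hits()].
#' @param combine Passed to [score_evidence_impact()].
#' @return An `independent_scores` list: `snp_count_dominant`,
#'   `snp_count_additive`, `evidence_impact_dominant`,
#'   `evidence_impact_additive`, `n_kb_snps_assayed`, `n_kb_snps_missing`,
#'   `n_kb_snps_nocall`.
#' @export
independent_scores <- function(hits, combine = c("product", "sum")) {
  combine <- match.arg(combine)
  check_hits(hits)
  structure(
    list(
      snp_count_dominant = score_snp_count(hits, "dominant"),
      snp_count_additive = score_snp_count(hits, "additive"),
      evidence_impact_dominant = score_evidence_impact(hits, "dominant",
                                                       combine),
      evidence_impact_additive = score_evidence_impact(hits, "additive",
                                                       combine),
      n_kb_snps_assayed = attr(hits, "n_assayed") %||% NA_integer_,
      n_kb_snps_missing = attr(hits, "n_missing") %||% NA_integer_,
      n_kb_snps_nocall = attr(hits, "n_nocall") %||% NA_integer_
    ),
    class = "independent_scores"
  )
}

#' @export
print.independent_scores <- function(x, ...) {
  cat("Independent association scores\n",
      "  SNP count       dominant:", x$snp_count_dominant,
      " additive:", x$snp_count_additive, "\n",
      "  evidence-impact dominant:", x$evidence_impact_dominant,
      " additive:", x$evidence_impact_additive, "\n",
      "  KB SNPs assayed:", x$n_kb_snps_assayed,
      " missing:", x$n_kb_snps_missing,
      " no-call:", x$n_kb_snps_nocall, "\n")
  invisible(x)
}

#' Cross-tabulate hits by impact and evidence category
#'
#' @param hits Hits from [extract_hits()].
#' @return A `categorical_summary`: 3x3 integer table (rows: impact, cols:
#'   evidence, both ordered strong/moderate/weak) with attribute `total`.
#' @export
categorical_summary <- function(hits) {
  check_hits(hits)
  lev <- rev(CATEGORY_LEVELS) # strong, moderate, weak
  tab <- table(
    impact = factor(hits$impact_category, lev),
    evidence = factor(hits$evidence_category, lev)
  )
  structure(tab, total = nrow(hits),
            class = c("categorical_summary", class(tab)))
}

#' Export hits as TSV or JSON
#'
#' @param hits Hits from [extract_hits()].
#' @param path Destination; format chosen by extension (`.tsv`/`.json`).
#' @return `path`, invisibly.
#' @export
export_hits <- function(hits, path) {
  check_hits(hits)
  df <- as.data.frame(hits)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
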