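# Shared fixtures and independent oracles, all built in code.

make_candidate <- function(rsid = "rs1", risk_allele = "A", odds_ratio = 1.5,
                           race_group = "caucasian",
                           study_type = "research",
                           citation_count = 10L, author_count = 5L,
                           sample_size_cases = 500L,
                           sample_size_controls = 500L,
                           pubmed_article_count = 5L,
                           cumulative_model_count = 1L,
                           source = "src", reported_strand = "forward",
                           ci_low = NA_real_, ci_high = NA_real_) {
  association_candidate(
    rsid = rsid, risk_allele = risk_allele, odds_ratio = odds_ratio,
    ci_low = ci_low, ci_high = ci_high, race_group = race_group,
    study_type = study_type, citation_count = citation_count,
    author_count = author_count, sample_size_cases = sample_size_cases,
    sample_size_controls = sample_size_controls,
    pubmed_article_count = pubmed_article_count,
    cumulative_model_count = cumulative_model_count, source = source,
    reported_strand = reported_strand
  )
}

random_candidate_set <- function(n, rsid = "rs42", allele = "A") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_candidate(
      rsid = rsid, risk_allele = allele,
      odds_ratio = round(stats::runif(1, 1.01, 4), 2),
      race_group = sample(c("caucasian", "mixed", "other"), 1),
      study_type = sample(c("meta_analysis", "research"), 1),
      citation_count = sample(0:60, 1), author_count = sample(1:40, 1),
      sample_size_cases = sample(50:1200, 1),
      sample_size_controls = sample(50:1200, 1),
      pubmed_article_count = sample(0:25, 1),
      cumulative_model_count = sample(0:4, 1),
      source = sprintf("src%02d", sample(1:99, 1)),
      ci_low = NA_real_, ci_high = NA_real_
    )
  }))
}

# Phase-by-phase brute-force selection oracle, written straight from the
# preference order: race, then study type, then citations, then OR, then
# the documented tie-breaks (CI width, source).
oracle_select <- function(cands) {
  race_rank <- c(other = 1, mixed = 2, caucasian = 3)
  keep <- cands[race_rank[cands$race_group] ==
                  max(race_rank[cands$race_group]), , drop = FALSE]
  study_rank <- c(research = 1, meta_analysis = 2)
  keep <- keep[study_rank[keep$study_type] ==
                 max(study_rank[keep$study_type]), , drop = FALSE]
  cites <- ifelse(is.na(keep$citation_count), -Inf, keep$citation_count)
  keep <- keep[cites == max(cites), , drop = FALSE]
  keep <- keep[keep$odds_ratio == max(keep$odds_ratio), , drop = FALSE]
  width <- keep$ci_high - keep$ci_low
  width[is.na(width)] <- Inf
  keep <- keep[width == min(width), , drop = FALSE]
  keep[order(keep$source)[1L], , drop = FALSE]
}

# A small KB with one association per category combination, built by
# steering OR (impact) and metadata (evidence).
tiny_kb <- function(n = 7L, seed = 99L) {
  set.seed(seed)
  cands <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_candidate(
      rsid = paste0("rs", 1000 + i),
      risk_allele = sample(c("A", "C", "G", "T"), 1),
      odds_ratio = round(stats::runif(1, 1.1, 3.2), 2),
      citation_count = sample(0:60, 1),
      pubmed_article_count = sample(0:25, 1),
      cumulative_model_count = sample(0:4, 1),
      sample_size_cases = sample(50:1500, 1),
      sample_size_controls = sample(50:1500, 1),
      race_group = sample(c("caucasian", "mixed", "other"), 1),
      study_type = sample(c("meta_analysis", "research"), 1),
      author_count = sample(1:40, 1)
    )
  }))
  build_kb(cands, version = "test")
}

# Genome built from an explicit rsid -> genotype map.
make_genome <- function(genotypes, subject_id = "test-subject") {
  records <- data.frame(
    rsid = names(genotypes),
    chromosome = as.character(seq_along(genotypes) %% 22 + 1),
    position = seq_along(genotypes) * 1000L,
    genotype = unname(genotypes),
    stringsAsFactors = FALSE
  )
  snprisk:::personal_genome(subject_id, records)
}

# Genome carrying the risk allele homozygously at every SNP of a
# cumulative model.
full_risk_genome <- function(model, subject_id = "full-risk") {
  gt <- paste0(model$snps$risk_allele, model$snps$risk_allele)
  make_genome(stats::setNames(gt, model$snps$rsid), subject_id)
}

non_risk_allele <- function(risk) {
  c(A = "C", C = "A", G = "T", T = "G")[[risk]]
}

# Brute-force recomputation of the four independent scores, written
# directly from the definitions: counts of risk-carrying SNPs (homozygotes
# weighted twice under additive), and evidence-impact degrees as the
# product of the two 1-3 category ranks.
oracle_independent_scores <- function(genome, kb) {
  rank3 <- function(x) c(weak = 1, moderate = 2, strong = 3)[[x]]
  cnt_dom <- 0; cnt_add <- 0; ei_dom <- 0; ei_add <- 0
  for (i in seq_len(nrow(kb$associations))) {
    a <- kb$associations[i, ]
    j <- which(genome$records$rsid == a$rsid)
    if (length(j) == 0L) next
    gt <- genome$records$genotype[j]
    if (gt == "--") next
    chars <- strsplit(gt, "")[[1]]
    n_risk <- sum(chars == a$risk_allele)
    if (n_risk == 0L) next
    w <- if (nchar(gt) == 2L && n_risk == 2L) 2 else 1
    cnt_dom <- cnt_dom + 1
    cnt_add <- cnt_add + w
    ei <- rank3(a$evidence_category) * rank3(a$impact_category)
    ei_dom <- ei_dom + ei
    ei_add <- ei_add + ei * w
  }
  list(snp_count_dominant = cnt_dom, snp_count_additive = cnt_add,
       evidence_impact_dominant = ei_dom, evidence_impact_additive = ei_add)
}

# Random hit tables for polygenic/score properties (shape produced by
# extract_hits).
random_hits <- function(n) {
  zyg <- sample(c("het_risk", "hom_risk", "hemizygous_risk"), n,
                replace = TRUE)
  structure(
    data.frame(
      rsid = sprintf("rs%d", seq_len(n)),
      risk_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      odds_ratio = round(stats::runif(n, 0.8, 3.5), 3),
      evidence_degree = rep(1, n),
      evidence_category = sample(c("weak", "moderate", "strong"), n,
                                 replace = TRUE),
      impact_category = sample(c("weak", "moderate", "strong"), n,
                               replace = TRUE),
      source = rep("sim", n),
      genotype = rep("NN", n),
      zygosity = zyg,
      zygosity_weight = ifelse(zyg == "hom_risk", 2L, 1L),
      stringsAsFactors = FALSE
    ),
    class = c("assoc_hits", "data.frame")
  )
}

empty_hits <- function() random_hits(0L)

# Random branch-set model over a given SNP universe.
random_branch_model <- function(n_branches, rsids, alleles) {
  branches <- lapply(seq_len(n_branches), function(b) {
    n_req <- sample(seq_len(min(4L, length(rsids))), 1)
    idx <- sample(seq_along(rsids), n_req, replace = FALSE)
    snp_reqs <- lapply(idx, function(i) {
      if (stats::runif(1) < 0.5) {
        gt <- paste(sample(c(alleles[i], non_risk_allele(alleles[i])), 2,
                           replace = TRUE), collapse = "")
        list(rsid = rsids[i], genotype = gt)
      } else {
        list(rsid = rsids[i], allele = alleles[i])
      }
    })
    clin <- NULL
    if (stats::runif(1) < 0.4) {
      clin <- list(list(
        field = sample(c("bmi_class", "smoking", "alcohol"), 1),
        value = sample(c("positive", "negative", "obese", "normal"), 1)
      ))
    }
    list(branch_id = paste0("b", b), snp_requirements = snp_reqs,
         clinical_requirements = clin)
  })
  branch_set_model(paste0("random-", n_branches), branches,
                   source = "synthetic")
}

# Independent branch-matching oracle: tabulates each requirement as
# satisfied / violated / unanswerable, then applies the verdict rules.
oracle_match <- function(genome, model, clinical = NULL) {
  req_value <- function(req) {
    if (!is.null(req$field)) { # clinical
      if (is.null(clinical)) return(NA)
      v <- clinical[[req$field]]
      if (is.null(v) || v == "unknown") return(NA)
      return(v == req$value)
    }
    j <- which(genome$records$rsid == req$rsid)
    if (length(j) == 0L) return(NA)
    gt <- genome$records$genotype[j]
    if (gt == "--") return(NA)
    chars <- sort(strsplit(gt, "")[[1]])
    if (!is.null(req$genotype)) {
      return(identical(chars, sort(strsplit(req$genotype, "")[[1]])))
    }
    req$allele %in% chars
  }
  states <- vapply(model$branches, function(b) {
    vals <- vapply(c(b$snp_requirements, b$clinical_requirements),
                   req_value, logical(1))
    if (any(vals %in% FALSE)) "contradicted"
    else if (anyNA(vals)) "indeterminate"
    else "matched"
  }, character(1))
  if (any(states == "matched")) "at_risk"
  else if (all(states == "contradicted")) "risk_free"
  else "indeterminate"
}
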