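# Curation of SNP-disease association candidates into a deduplicated,
# evidence-graded knowledge base.

RACE_LEVELS <- c("other", "mixed", "caucasian")
STUDY_LEVELS <- c("research", "meta_analysis")
CATEGORY_LEVELS <- c("weak", "moderate", "strong")

CANDIDATE_COLUMNS <- c(
  "rsid", "risk_allele", "odds_ratio", "ci_low", "ci_high", "race_group",
  "study_type", "citation_count", "author_count", "sample_size_cases",
  "sample_size_controls", "pubmed_article_count", "cumulative_model_count",
  "source", "reported_strand"
)

SCORE_COLUMNS <- c(
  "citation_score", "study_score", "race_score",
  "sample_score", "pubmed_score", "model_score"
)

#' Construct one association candidate
#'
#' A candidate is a single literature report linking a SNP risk allele to
#' increased disease risk, carrying the study metadata needed for evidence
#' grading and redundancy resolution. Several candidates may exist for the
#' same (rsid, risk allele) pair; [build_kb()] reduces them to one.
#'
#' @param rsid dbSNP identifier, `"rs"` followed by digits.
#' @param risk_allele Risk nucleotide as reported (A/C/G/T).
#' @param odds_ratio Reported odds ratio, must be positive.
#' @param ci_low,ci_high Optional 95% confidence bounds for the OR.
#' @param race_group One of `"caucasian"`, `"mixed"`, `"other"`.
#' @param study_type One of `"meta_analysis"`, `"research"`.
#' @param citation_count Citations of the source article (non-negative).
#' @param author_count Number of authors (positive).
#' @param sample_size_cases,sample_size_controls Study arm sizes.
#' @param pubmed_article_count Articles on this SNP-disease relationship.
#' @param cumulative_model_count Published cumulative models containing
#'   this SNP allele.
#' @param source Free-text provenance tag.
#' @param reported_strand `"forward"` or `"reverse"`; reverse-strand alleles
#'   are complemented to the forward strand during KB construction.
#' @return A one-row data frame with the candidate columns.
#' @export
#' @examples
#' association_candidate("rs1447295", "A", 1.42, race_group = "caucasian",
#'                       study_type = "meta_analysis", citation_count = 60,
#'                       author_count = 12, sample_size_cases = 1500,
#'                       sample_size_controls = 1500)
association_candidate <- function(rsid, risk_allele, odds_ratio,
                                  ci_low = NA_real_, ci_high = NA_real_,
                                  race_group = "other",
                                  study_type = "research",
                                  citation_count = NA_integer_,
                                  author_count = NA_integer_,
                                  sample_size_cases = NA_integer_,
                                  sample_size_controls = NA_integer_,
                                  pubmed_article_count = NA_integer_,
                                  cumulative_model_count = NA_integer_,
                                  source = "unspecified",
                                  reported_strand = "forward") {
  cand <- data.frame(
    rsid = as.character(rsid), risk_allele = toupper(risk_allele),
    odds_ratio = as.numeric(odds_ratio),
    ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
    race_group = race_group, study_type = study_type,
    citation_count = as.integer(citation_count),
    author_count = as.integer(author_count),
    sample_size_cases = as.integer(sample_size_cases),
    sample_size_controls = as.integer(sample_size_controls),
    pubmed_article_count = as.integer(pubmed_article_count),
    cumulative_model_count = as.integer(cumulative_model_count),
    source = as.character(source),
    reported_strand = reported_strand,
    stringsAsFactors = FALSE
  )
  validate_candidates(cand)
  cand
}

validate_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  missing_cols <- setdiff(CANDIDATE_COLUMNS, names(candidates))
  if (length(missing_cols) > 0L) {
    stop("candidate table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) == 0L) stop("empty candidate table", call. = FALSE)
  if (!all(grepl("^rs[0-9]+$", candidates$rsid))) {
    bad <- candidates$rsid[!grepl("^rs[0-9]+$", candidates$rsid)]
    stop("malformed rsID(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (!all(candidates$risk_allele %in% c("A", "C", "G", "T"))) {
    stop("risk_allele must be one of A, C, G, T", call. = FALSE)
  }
  if (any(!is.finite(candidates$odds_ratio)) ||
      any(candidates$odds_ratio <= 0)) {
    stop("odds_ratio must be finite and > 0", call. = FALSE)
  }
  both_ci <- !is.na(candidates$ci_low) & !is.na(candidates$ci_high)
  if (any(both_ci &
          (candidates$ci_low > candidates$odds_ratio |
           candidates$odds_ratio > candidates$ci_high))) {
    stop("odds_ratio outside its confidence interval", call. = FALSE)
  }
  if (!all(candidates$race_group %in% RACE_LEVELS)) {
    stop("race_group must be one of: ", paste(RACE_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(candidates$study_type %in% STUDY_LEVELS)) {
    stop("study_type must be one of: ", paste(STUDY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(candidates$reported_strand %in% c("forward", "reverse"))) {
    stop("reported_strand must be 'forward' or 'reverse'", call. = FALSE)
  }
  counts <- candidates[, c("citation_count", "author_count",
                           "sample_size_cases", "sample_size_controls",
                           "pubmed_article_count", "cumulative_model_count")]
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    stop("count metadata must be non-negative", call. = FALSE)
  }
  if (any(candidates$author_count < 1, na.rm = TRUE)) {
    stop("author_count must be positive", call. = FALSE)
  }
  invisible(candidates)
}

#' Score the six evidence criteria of association candidates
#'
#' Each candidate is scored 1-3 on six criteria: article citation count,
#' study type crossed with author count, race/ethnicity of the study
#' population, sample size (the smaller of the case and control arms, so
#' both arms must clear a bin), PubMed article volume for the SNP-disease
#' relationship, and membership in published cumulative models.
#'
#' Bins: citations (1-15)=1, (16-50)=2, (>50)=3. Study: research with <10
#' authors =1, 10-34 =2, >=35 =3; meta-analysis with <7 authors =2, >=7 =3.
#' Race: other=1, mixed=2, caucasian=3. Sample size: <100=1, 100-1000=2,
#' >1000=3. PubMed articles: <7=1, 7-19=2, >=20=3. Model membership:
#' none=1, 1-2=2, >=3=3.
#'
#' Missing metadata is imputed as the lowest bin (score 1) and the record
#' is flagged via the `"imputed"` attribute.
#'
#' @param candidates Candidate data frame (see [association_candidate()]).
#' @return Data frame with the six integer score columns, one row per
#'   candidate; attribute `imputed` is a logical vector marking rows where
#'   any criterion was imputed.
#' @export
score_evidence <- function(candidates) {
  validate_candidates(candidates)
  bin3 <- function(x, lo, hi) {
    # score 1 below `lo`, 2 in [lo, hi], 3 above `hi`
    ifelse(x > hi, 3L, ifelse(x >= lo, 2L, 1L))
  }
  cit <- bin3(candidates$citation_count, 16L, 50L)
  study <- ifelse(
    candidates$study_type == "meta_analysis",
    ifelse(candidates$author_count >= 7L, 3L, 2L),
    ifelse(candidates$author_count >= 35L, 3L,
           ifelse(candidates$author_count >= 10L, 2L, 1L))
  )
  race <- match(candidates$race_group, RACE_LEVELS)
  samp <- bin3(pmin(candidates$sample_size_cases,
                    candidates$sample_size_controls), 100L, 1000L)
  pub <- bin3(candidates$pubmed_article_count, 7L, 19L)
  mod <- ifelse(candidates$cumulative_model_count >= 3L, 3L,
                ifelse(candidates$cumulative_model_count >= 1L, 2L, 1L))
  scores <- data.frame(
    citation_score = cit, study_score = study, race_score = as.integer(race),
    sample_score = samp, pubmed_score = pub, model_score = mod
  )
  imputed <- Reduce(`|`, lapply(scores, is.na))
  scores[is.na(scores)] <- 1L
  attr(scores, "imputed") <- imputed
  scores
}

#' Evidence degree and category from the six criterion scores
#'
#' The degree of evidence quality is the arithmetic mean of the six
#' criterion scores, so it lies in \[1, 3\]. Categories partition that
#' range half-open: weak below 1.5, moderate in \[1.5, 2.3), strong at
#' 2.3 and above.
#'
#' @param scores Data frame with the six score columns from
#'   [score_evidence()].
#' @return Data frame with columns `evidence_degree` (numeric) and
#'   `evidence_category` (character).
#' @export
compute_evidence_degree <- function(scores) {
  stopifnot(all(SCORE_COLUMNS %in% names(scores)))
  vals <- as.matrix(scores[, SCORE_COLUMNS])
  if (!all(vals %in% 1:3)) stop("scores must be integers in 1..3")
  degree <- rowMeans(vals)
  data.frame(evidence_degree = degree,
             evidence_category = evidence_category(degree))
}

# Half-open partition of [1, 3]: weak < 1.5 <= moderate < 2.3 <= strong.
evidence_category <- function(degree) {
  ifelse(degree >= 2.3, "strong",
         ifelse(degree >= 1.5, "moderate", "weak"))
}

#' Categorize the magnitude of impact of an odds ratio
#'
#' Thresholds: strong for OR >= 2.50, moderate for 2.00 <= OR < 2.50,
#' weak below 2.00.
#'
#' @param odds_ratio Numeric vector of positive odds ratios.
#' @return Character vector in `c("weak", "moderate", "strong")`.
#' @export
#' @examples
#' categorize_impact(c(1.99, 2.0, 2.5)) # weak, moderate, strong
categorize_impact <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be finite and > 0", call. = FALSE)
  }
  ifelse(odds_ratio >= 2.5, "strong",
         ifelse(odds_ratio >= 2.0, "moderate", "weak"))
}

#' Resolve redundant candidates for one SNP allele
#'
#' When several studies report an OR for the same (rsid, risk allele), a
#' four-phase preference order chooses the one retained value: (1) race of
#' the study population, Caucasian over mixed over other; (2) study type,
#' meta-analysis over research; (3) higher citation count; (4) higher odds
#' ratio. Ties surviving all four phases are broken by narrower confidence
#' interval, then by source tag, so the build is reproducible.
#'
#' @param candidates Candidate rows all sharing one (rsid, risk_allele).
#' @return The single winning candidate row.
#' @export
select_association <- function(candidates) {
  validate_candidates(candidates)
  if (length(unique(candidates$rsid)) != 1L ||
      length(unique(candidates$risk_allele)) != 1L) {
    stop("all candidates must share one (rsid, risk_allele)", call. = FALSE)
  }
  ci_width <- candidates$ci_high - candidates$ci_low
  ci_width[is.na(ci_width)] <- Inf
  ord <- order(
    -match(candidates$race_group, RACE_LEVELS),
    -match(candidates$study_type, STUDY_LEVELS),
    -ifelse(is.na(candidates$citation_count), -Inf, candidates$citation_count),
    -candidates$odds_ratio,
    ci_width,
    candidates$source
  )
  candidates[ord[1L], , drop = FALSE]
}

#' Normalize an allele to the forward strand
#'
#' Alleles reported on the reverse strand are replaced by their
#' Watson-Crick complement; forward-strand alleles pass through unchanged.
#' A/T and C/G SNPs are strand-ambiguous (the complement is also a valid
#' allele), so the reported strand metadata is trusted and a warning is
#' emitted for such alleles.
#'
#' @param allele Character vector of A/C/G/T.
#' @param reported_strand `"forward"` or `"reverse"`, recycled.
#' @return Forward-strand alleles.
#' @export
normalize_allele <- function(allele, reported_strand = "forward") {
  allele <- toupper(allele)
  if (!all(allele %in% c("A", "C", "G", "T"))) {
    stop("allele must be A, C, G or T (IUPAC ambiguity codes unsupported)",
         call. = FALSE)
  }
  if (!all(reported_strand %in% c("forward", "reverse"))) {
    stop("reported_strand must be 'forward' or 'reverse'", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- ifelse(reported_strand == "reverse", comp[allele], allele)
  names(out) <- NULL
  out
}

#' Update merged dbSNP identifiers
#'
#' dbSNP occasionally merges reference SNP identifiers; an old rsID then
#' maps to a current one, possibly through a chain of merges. This follows
#' each chain to its terminal identifier. Identifiers absent from the map
#' are returned unchanged.
#'
#' @param rsid Character vector of rsIDs.
#' @param merge_map Named character vector (`old -> current`) or a
#'   two-column data frame (`old_rsid`, `current_rsid`).
#' @return Character vector of current rsIDs.
#' @export
resolve_merged_rsid <- function(rsid, merge_map) {
  map <- as_merge_map(merge_map)
  if (length(map) == 0L) return(rsid)
  vapply(rsid, function(id) {
    seen <- character(0)
    while (!is.na(map[id])) {
      if (id %in% seen) {
        stop("cycle in rsID merge map at ", id, call. = FALSE)
      }
      seen <- c(seen, id)
      id <- unname(map[id])
    }
    id
  }, character(1), USE.NAMES = FALSE)
}

as_merge_map <- function(merge_map) {
  if (is.null(merge_map)) return(character(0))
  if (is.data.frame(merge_map)) {
    stopifnot(ncol(merge_map) >= 2L)
    map <- as.character(merge_map[[2L]])
    names(map) <- as.character(merge_map[[1L]])
    return(map)
  }
  stopifnot(is.character(merge_map))
  merge_map
}

#' Read an rsID merge map from a two-column TSV
#'
#' @param path File with columns `old_rsid`, `current_rsid` (header row).
#' @return Named character vector usable by [resolve_merged_rsid()].
#' @export
read_merge_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  as_merge_map(df[, c("old_rsid", "current_rsid")])
}

#' Build a knowledge base from association candidates
#'
#' Runs the full curation pipeline: candidate validation, rsID merge
#' resolution, strand normalization of risk alleles, per-(rsid, allele)
#' redundancy resolution via [select_association()], evidence scoring and
#' impact categorization.
#'
#' @param candidates Candidate data frame; see [association_candidate()]
#'   and [read_candidates()].
#' @param merge_map Optional rsID merge map (see [resolve_merged_rsid()]).
#' @param disease_code Clinical terminology identifier for the disease the
#'   associations describe (default `"C61"`, the ICD-10 code for malignant
#'   neoplasm of prostate).
#' @param version Free-text KB version tag.
#' @return A `snp_kb` object: list with `disease_code`, `version` and an
#'   `associations` data frame unique by (rsid, risk_allele).
#' @export
build_kb <- function(candidates, merge_map = NULL,
                     disease_code = "C61", version = "0.1.0") {
  validate_candidates(candidates)
  candidates$rsid <- resolve_merged_rsid(candidates$rsid, merge_map)
  # A single reported allele cannot prove its strand (A/T and C/G SNPs are
  # ambiguous under complementation), so the reported_strand metadata is
  # trusted; reverse-strand records are flagged as they are flipped.
  n_rev <- sum(candidates$reported_strand == "reverse")
  if (n_rev > 0L) {
    warning(n_rev, " reverse-strand candidate(s) complemented to the ",
            "forward strand based on reported_strand metadata", call. = FALSE)
  }
  candidates$risk_allele <- normalize_allele(candidates$risk_allele,
                                             candidates$reported_strand)
  candidates$reported_strand <- "forward"

  groups <- split(candidates,
                  paste(candidates$rsid, candidates$risk_allele, sep = "|"))
  winners <- do.call(rbind, lapply(groups, select_association))
  rownames(winners) <- NULL

  scores <- score_evidence(winners)
  degree <- compute_evidence_degree(scores)
  associations <- cbind(
    winners[, c("rsid", "risk_allele", "odds_ratio", "ci_low", "ci_high")],
    scores, degree,
    impact_category = categorize_impact(winners$odds_ratio),
    source = winners$source,
    metadata_imputed = attr(scores, "imputed")
  )
  associations <- associations[order(associations$rsid,
                                     associations$risk_allele), ]
  rownames(associations) <- NULL

  structure(
    list(disease_code = disease_code, version = version,
         associations = associations),
    class = "snp_kb"
  )
}

#' @export
print.snp_kb <- function(x, ...) {
  cat("<snp_kb> disease", x$disease_code, "| version", x$version, "|",
      nrow(x$associations), "associations\n")
  tab <- table(factor(x$associations$impact_category, CATEGORY_LEVELS),
               factor(x$associations$evidence_category, CATEGORY_LEVELS),
               dnn = c("impact", "evidence"))
  print(tab)
  invisible(x)
}

#' Read association candidates from a TSV file
#'
#' Expects a tab-separated file with a header row naming the candidate
#' columns (see [association_candidate()]); empty cells become `NA`.
#'
#' @param path Path to the candidate TSV.
#' @return Validated candidate data frame.
#' @export
read_candidates <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#",
                      na.strings = c("", "NA"), quote = ""),
    error = function(e) stop("cannot parse candidate file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  validate_candidates(df)
  df
}

KB_ASSOCIATION_COLUMNS <- c(
  "rsid", "risk_allele", "odds_ratio", "ci_low", "ci_high",
  SCORE_COLUMNS, "evidence_degree", "evidence_category",
  "impact_category", "source", "metadata_imputed"
)

#' Serialize / restore a knowledge base
#'
#' The canonical on-disk form is JSON with top-level `disease_code`,
#' `version` and `associations`; [load_kb()] validates the shape and field
#' names on read. `save_kb()` writes numbers at full precision so
#' `load_kb(save_kb(kb))` is an exact round trip.
#'
#' @param kb A `snp_kb` object.
#' @param path Destination / source file.
#' @return `load_kb()` returns the `snp_kb`; `save_kb()` returns `path`
#'   invisibly.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "snp_kb"))
  jsonlite::write_json(
    list(disease_code = kb$disease_code, version = kb$version,
         associations = kb$associations),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_kb
#' @export
load_kb <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse KB file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  required <- c("disease_code", "version", "associations")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("KB file '", path, "' lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assoc <- as.data.frame(raw$associations, stringsAsFactors = FALSE)
  missing_cols <- setdiff(KB_ASSOCIATION_COLUMNS, names(assoc))
  if (length(missing_cols) > 0L) {
    stop("KB associations lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("ci_low", "ci_high")) assoc[[col]] <- as.numeric(assoc[[col]])
  for (col in SCORE_COLUMNS) assoc[[col]] <- as.integer(assoc[[col]])
  assoc <- assoc[, KB_ASSOCIATION_COLUMNS]
  if (anyDuplicated(assoc[, c("rsid", "risk_allele")])) {
    stop("KB contains duplicate (rsid, risk_allele) entries", call. = FALSE)
  }
  structure(
    list(disease_code = raw$disease_code, version = raw$version,
         associations = assoc),
    class = "snp_kb"
  )
}

#' Export a knowledge base as flat TSV
#'
#' One row per association; columns as in the `associations` data frame.
#'
#' @param kb A `snp_kb` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_kb_tsv <- function(kb, path) {
  stopifnot(inherits(kb, "snp_kb"))
  utils::write.table(kb$associations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
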