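# Model-based risk assessment: cumulative models with reference-table OR
# lookup, probabilistic branch-set models with three-valued verdicts, and
# polygenic scoring.

GENETIC_MODELS <- c("dominant", "recessive")
CLINICAL_FIELDS <- c("bmi_class", "smoking", "alcohol")

#' Construct a cumulative risk model
#'
#' A cumulative model is a small panel of SNPs, each evaluated under a
#' dominant or recessive genetic model; per-SNP contributions (one unit of
#' impact each) are summed into a total impact, optionally increased by
#' one when family health history (FHH) of the disease is positive, and
#' the total is mapped to an odds ratio through a published reference
#' table.
#'
#' @param name Model name, e.g. `"5-SNP_Zheng"`.
#' @param snps Data frame with columns `rsid`, `risk_allele`,
#'   `genetic_model` (`"dominant"` or `"recessive"`).
#' @param reference_table Data frame with columns `total_impact`,
#'   `or_without_fhh`, `ci_low_without_fhh`, `ci_high_without_fhh` and,
#'   when `supports_fhh`, `or_with_fhh`, `ci_low_with_fhh`,
#'   `ci_high_with_fhh`. The without-FHH column must cover impacts
#'   0..nrow(snps); the with-FHH column 0..nrow(snps)+1. ORs must be
#'   non-decreasing in total impact.
#' @param supports_fhh Whether the model has a family-health-history
#'   extension.
#' @param reference_table_source `"published"` for tables transcribed from
#'   the literature, `"synthetic"` for schema-valid stand-ins.
#' @return A `cumulative_model` object.
#' @export
cumulative_model <- function(name, snps, reference_table,
                             supports_fhh = FALSE,
                             reference_table_source = "published") {
  stopifnot(is.data.frame(snps),
            all(c("rsid", "risk_allele", "genetic_model") %in% names(snps)))
  if (!all(snps$genetic_model %in% GENETIC_MODELS)) {
    stop("genetic_model must be 'dominant' or 'recessive'", call. = FALSE)
  }
  if (!all(snps$risk_allele %in% c("A", "C", "G", "T"))) {
    stop("risk alleles must be forward-strand A/C/G/T", call. = FALSE)
  }
  if (anyDuplicated(snps$rsid)) {
    stop("duplicate rsIDs in model SNP panel", call. = FALSE)
  }
  rt <- reference_table
  stopifnot(is.data.frame(rt),
            all(c("total_impact", "or_without_fhh") %in% names(rt)))
  n <- nrow(snps)
  covered <- rt$total_impact[!is.na(rt$or_without_fhh)]
  if (!all(0:n %in% covered)) {
    stop("reference table incomplete: without-FHH ORs must cover impacts 0..",
         n, call. = FALSE)
  }
  check_monotone <- function(or, label) {
    or <- or[order(rt$total_impact)]
    or <- or[!is.na(or)]
    if (is.unsorted(or)) {
      stop("reference-table ORs (", label, ") must be non-decreasing in ",
           "total impact", call. = FALSE)
    }
  }
  check_monotone(rt$or_without_fhh, "without FHH")
  if (supports_fhh) {
    if (!"or_with_fhh" %in% names(rt)) {
      stop("supports_fhh model needs an or_with_fhh column", call. = FALSE)
    }
    covered_fhh <- rt$total_impact[!is.na(rt$or_with_fhh)]
    if (!all(0:(n + 1L) %in% covered_fhh)) {
      stop("reference table incomplete: with-FHH ORs must cover impacts 0..",
           n + 1L, call. = FALSE)
    }
    check_monotone(rt$or_with_fhh, "with FHH")
  }
  structure(
    list(name = name, type = "cumulative", snps = snps,
         reference_table = rt, supports_fhh = isTRUE(supports_fhh),
         reference_table_source = reference_table_source),
    class = "cumulative_model"
  )
}

#' @export
print.cumulative_model <- function(x, ...) {
  cat("<cumulative_model>", x$name, "|", nrow(x$snps), "SNPs (",
      sum(x$snps$genetic_model == "dominant"), "dominant,",
      sum(x$snps$genetic_model == "recessive"), "recessive ) |",
      if (x$supports_fhh) "FHH extension" else "no FHH extension", "\n")
  if (!identical(x$reference_table_source, "published")) {
    cat("  reference table:", x$reference_table_source,
        "(not transcribed from the literature)\n")
  }
  invisible(x)
}

#' Evaluate a genome against a cumulative model
#'
#' Per-SNP contributions: a dominant-model SNP contributes one unit of
#' impact if the genotype carries the risk allele in one or both copies;
#' a recessive-model SNP only if homozygous for it (a hemizygous call —
#' one allele on X/Y/MT — is treated as homozygous-equivalent). Positive
#' family health history adds one unit when the model supports it and
#' selects the with-FHH odds-ratio column; negative or unknown FHH uses
#' the without-FHH column (unknown is flagged, never imputed positive).
#'
#' In `"strict"` mode (the default) the whole model abstains — status
#' `"unknown"` — if any model SNP is unassayed or a no-call. In
#' `"bounds"` mode missing SNPs are bracketed as 0/1 impact each and the
#' result carries `[impact_min, impact_max]` and the corresponding OR
#' range instead.
#'
#' @param genome A `personal_genome`.
#' @param model A `cumulative_model`.
#' @param fhh Family health history: `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @param mode `"strict"` or `"bounds"`.
#' @return A `cumulative_result`: list with `model_name`, `total_impact`,
#'   `odds_ratio`, `ci`, `status` (`"evaluated"`/`"unknown"`/`"bounds"`),
#'   `missing_snps`, `nocall_snps`, `fhh_used`, `category` (see
#'   [classify_cumulative()]); bounds mode adds `impact_range` and
#'   `or_range`.
#' @export
evaluate_cumulative <- function(genome, model,
                                fhh = c("unknown", "negative", "positive"),
                                mode = c("strict", "bounds")) {
  stopifnot(inherits(genome, "personal_genome"),
            inherits(model, "cumulative_model"))
  fhh <- match.arg(fhh)
  mode <- match.arg(mode)

  snps <- model$snps
  idx <- match(snps$rsid, genome$records$rsid)
  genotype <- ifelse(is.na(idx), NA_character_,
                     genome$records$genotype[idx])
  zyg <- rep(NA_character_, nrow(snps))
  assayed <- !is.na(genotype)
  if (any(assayed)) {
    zyg[assayed] <- genotype_zygosity(genotype[assayed],
                                      snps$risk_allele[assayed])
  }
  missing_snps <- snps$rsid[!assayed]
  nocall_snps <- snps$rsid[assayed & zyg == "nocall"]
  usable <- assayed & zyg != "nocall"

  contrib <- integer(nrow(snps))
  contrib[usable] <- ifelse(
    snps$genetic_model[usable] == "dominant",
    zyg[usable] %in% c("het_risk", "hom_risk", "hemizygous_risk"),
    zyg[usable] %in% c("hom_risk", "hemizygous_risk")
  )

  use_fhh_column <- model$supports_fhh && fhh == "positive"
  fhh_bonus <- as.integer(use_fhh_column)
  fhh_used <- if (!model$supports_fhh) {
    "not_supported"
  } else if (fhh == "positive") "with_fhh" else "without_fhh"

  n_unknown <- length(missing_snps) + length(nocall_snps)
  result <- list(model_name = model$name, status = "evaluated",
                 missing_snps = missing_snps, nocall_snps = nocall_snps,
                 fhh = fhh, fhh_used = fhh_used)

  if (n_unknown > 0L && mode == "strict") {
    result$status <- "unknown"
    result$total_impact <- NA_integer_
    result$odds_ratio <- NA_real_
    result$ci <- c(NA_real_, NA_real_)
    result$category <- "unknown"
    return(structure(result, class = "cumulative_result"))
  }

  base_impact <- sum(contrib[usable]) + fhh_bonus
  if (n_unknown == 0L) {
    lk <- lookup_reference_or(model, base_impact, use_fhh_column)
    result$total_impact <- base_impact
    result$odds_ratio <- lk$odds_ratio
    result$ci <- lk$ci
    result$category <- if (lk$odds_ratio >= 2.5) "high" else "lower"
  } else {
    lo <- lookup_reference_or(model, base_impact, use_fhh_column)
    hi <- lookup_reference_or(model, base_impact + n_unknown, use_fhh_column)
    result$status <- "bounds"
    result$total_impact <- NA_integer_
    result$impact_range <- c(base_impact, base_impact + n_unknown)
    result$or_range <- c(lo$odds_ratio, hi$odds_ratio)
    result$odds_ratio <- NA_real_
    result$ci <- c(NA_real_, NA_real_)
    result$category <- if (lo$odds_ratio >= 2.5) {
      "high"
    } else if (hi$odds_ratio < 2.5) "lower" else "unknown"
  }
  structure(result, class = "cumulative_result")
}

lookup_reference_or <- function(model, total_impact, with_fhh) {
  rt <- model$reference_table
  row <- match(total_impact, rt$total_impact)
  col <- if (with_fhh) "or_with_fhh" else "or_without_fhh"
  if (is.na(row) || is.na(rt[[col]][row])) {
    stop("total impact ", total_impact, " outside the ", model$name,
         " reference table (", if (with_fhh) "with" else "without",
         " FHH column)", call. = FALSE)
  }
  ci_cols <- if (with_fhh) {
    c("ci_low_with_fhh", "ci_high_with_fhh")
  } else c("ci_low_without_fhh", "ci_high_without_fhh")
  ci <- if (all(ci_cols %in% names(rt))) {
    c(rt[[ci_cols[1]]][row], rt[[ci_cols[2]]][row])
  } else c(NA_real_, NA_real_)
  list(odds_ratio = rt[[col]][row], ci = ci)
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat("<cumulative_result>", x$model_name, "| status", x$status, "\n")
  if (x$status == "evaluated") {
    cat("  total impact", x$total_impact, "-> OR", format(x$odds_ratio),
        "(", x$category, ")\n")
  } else if (x$status == "bounds") {
    cat("  impact in [", x$impact_range[1], ",", x$impact_range[2],
        "] -> OR in [", format(x$or_range[1]), ",", format(x$or_range[2]),
        "] (", x$category, ")\n")
  }
  if (length(x$missing_snps) > 0L) {
    cat("  not assayed:", paste(x$missing_snps, collapse = ", "), "\n")
  }
  if (length(x$nocall_snps) > 0L) {
    cat("  no-calls:", paste(x$nocall_snps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a cumulative result into the reporting categories
#'
#' Results are grouped by the looked-up odds ratio: `"high"` when
#' OR >= 2.5, `"lower"` when OR < 2.5, `"unknown"` when the model
#' abstained for lack of data.
#'
#' @param result A `cumulative_result`.
#' @return `"high"`, `"lower"` or `"unknown"`.
#' @export
classify_cumulative <- function(result) {
  stopifnot(inherits(result, "cumulative_result"))
  result$category
}

#' Construct a probabilistic branch-set model
#'
#' Encodes a trained classifier (e.g. a decision tree distilled from an
#' SVM+ID3 hybrid) as a disjunction of branches, each a conjunction of
#' genotype requirements and, optionally, clinical requirements over BMI
#' class, smoking and alcohol use. Matching any branch implies disease
#' risk. Published performance metrics are carried as display metadata
#' only and never recomputed.
#'
#' @param name Model name.
#' @param branches List of branches; each branch is a list with
#'   `branch_id`, `snp_requirements` (list of `list(rsid=, genotype=)` for
#'   an exact unordered genotype match or `list(rsid=, allele=)` for
#'   risk-allele presence) and optional `clinical_requirements` (list of
#'   `list(field=, value=)` over `bmi_class`, `smoking`, `alcohol`).
#' @param metrics Optional named list, e.g.
#'   `list(accuracy=, precision=, recall=)`.
#' @param source `"published"` or `"synthetic"`.
#' @return A `branch_set_model`.
#' @export
branch_set_model <- function(name, branches, metrics = NULL,
                             source = "published") {
  stopifnot(is.list(branches), length(branches) > 0L)
  ids <- vapply(branches, function(b) as.character(b$branch_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate branch ids", call. = FALSE)
  for (b in branches) {
    n_req <- length(b$snp_requirements) + length(b$clinical_requirements)
    if (n_req == 0L) {
      stop("branch ", b$branch_id, " has no requirements", call. = FALSE)
    }
    for (cr in b$clinical_requirements) {
      if (!cr$field %in% CLINICAL_FIELDS) {
        stop("branch ", b$branch_id, " references unknown clinical field '",
             cr$field, "'", call. = FALSE)
      }
    }
    for (sr in b$snp_requirements) {
      if (is.null(sr$rsid) || (is.null(sr$genotype) && is.null(sr$allele))) {
        stop("branch ", b$branch_id,
             " has a SNP requirement without rsid + genotype/allele",
             call. = FALSE)
      }
    }
  }
  structure(
    list(name = name, type = "branch_set", branches = branches,
         metrics = metrics, source = source),
    class = "branch_set_model"
  )
}

#' @export
print.branch_set_model <- function(x, ...) {
  cat("<branch_set_model>", x$name, "|", length(x$branches), "branches\n")
  if (!is.null(x$metrics)) {
    cat("  reported metrics:",
        paste(names(x$metrics), unlist(x$metrics), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Evaluate one requirement against the available data.
# Returns TRUE (satisfied), FALSE (definitively violated) or NA
# (references missing data: SNP unassayed/no-call, clinical unknown).
eval_snp_requirement <- function(req, genome) {
  idx <- match(req$rsid, genome$records$rsid)
  if (is.na(idx)) return(NA)
  gt <- genome$records$genotype[idx]
  if (gt == NOCALL) return(NA)
  if (!is.null(req$genotype)) {
    sort_chars <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
    sort_chars(gt) == sort_chars(toupper(req$genotype))
  } else {
    genotype_zygosity(gt, req$allele) %in%
      c("het_risk", "hom_risk", "hemizygous_risk")
  }
}

eval_clinical_requirement <- function(req, clinical) {
  if (is.null(clinical)) return(NA)
  val <- clinical[[req$field]]
  if (is.null(val) || identical(val, "unknown")) return(NA)
  identical(val, req$value)
}

#' Match a genome (and clinical profile) against a branch-set model
#'
#' Each branch is classified as matched (every requirement satisfied),
#' contradicted (at least one requirement definitively violated by
#' available data), or indeterminate (some requirement references missing
#' data and none is violated). The verdict is `"at_risk"` if at least one
#' branch matched, `"risk_free"` if every branch is contradicted, and
#' `"indeterminate"` otherwise — the three-valued logic keeps data
#' incompleteness distinct from evidence of absence.
#'
#' @param genome A `personal_genome`.
#' @param model A `branch_set_model`.
#' @param clinical Optional `clinical_profile`; when `NULL`, every
#'   clinical requirement is treated as referencing missing data.
#' @return A `branch_verdict`: list with `verdict`, `matched_branches`,
#'   `contradicted_branches`, `indeterminate_branches`, `model_name` and
#'   the model's reported `metrics`.
#' @export
match_branches <- function(genome, model, clinical = NULL) {
  stopifnot(inherits(genome, "personal_genome"),
            inherits(model, "branch_set_model"))
  if (!is.null(clinical)) stopifnot(inherits(clinical, "clinical_profile"))
  status <- vapply(model$branches, function(b) {
    vals <- c(
      vapply(b$snp_requirements, eval_snp_requirement, logical(1),
             genome = genome),
      vapply(b$clinical_requirements, eval_clinical_requirement, logical(1),
             clinical = clinical)
    )
    if (any(!vals, na.rm = TRUE)) {
      "contradicted"
    } else if (anyNA(vals)) "indeterminate" else "matched"
  }, character(1))
  ids <- vapply(model$branches, function(b) as.character(b$branch_id),
                character(1))
  verdict <- if (any(status == "matched")) {
    "at_risk"
  } else if (all(status == "contradicted")) "risk_free" else "indeterminate"
  structure(
    list(verdict = verdict,
         matched_branches = ids[status == "matched"],
         contradicted_branches = ids[status == "contradicted"],
         indeterminate_branches = ids[status == "indeterminate"],
         model_name = model$name, metrics = model$metrics),
    class = "branch_verdict"
  )
}

#' @export
print.branch_verdict <- function(x, ...) {
  cat("<branch_verdict>", x$model_name, "->", x$verdict,
      "(", length(x$matched_branches), "matched,",
      length(x$contradicted_branches), "contradicted,",
      length(x$indeterminate_branches), "indeterminate )\n")
  invisible(x)
}

#' Polygenic risk scores over independent association hits
#'
#' Three classical aggregation methods over the risk alleles a genome
#' carries. With allele count \eqn{w_i} (1 for heterozygous or hemizygous,
#' 2 for homozygous) and per-allele odds ratio \eqn{OR_i}:
#' the count method is \eqn{\sum_i w_i}; the log-odds method is
#' \eqn{\sum_i w_i \ln OR_i}; the multiplicative model is
#' \eqn{\prod_i OR_i^{w_i}}, optionally scaled by an average population
#' risk to yield a lifetime risk estimate (capped at 1 and flagged when
#' the cap binds). `exp(log_odds_score)` equals `multiplicative_or` by
#' construction. A per-genotype weighting (every hit counted once
#' regardless of zygosity) is available via `weighting = "genotype"`.
#'
#' @param hits Hits from [extract_hits()].
#' @param average_population_risk Optional baseline lifetime risk in
#'   (0, 1); no default is assumed.
#' @param weighting `"allele"` (default) or `"genotype"`.
#' @return A `polygenic_scores` list: `count_score`, `log_odds_score`,
#'   `multiplicative_or`, `lifetime_risk` (NA when no baseline supplied),
#'   `lifetime_risk_capped`.
#' @export
polygenic_scores <- function(hits, average_population_risk = NULL,
                             weighting = c("allele", "genotype")) {
  weighting <- match.arg(weighting)
  check_hits(hits)
  if (nrow(hits) > 0L && any(hits$odds_ratio <= 0)) {
    stop("odds ratios must be > 0", call. = FALSE)
  }
  if (!is.null(average_population_risk)) {
    stopifnot(is.numeric(average_population_risk),
              average_population_risk > 0, average_population_risk < 1)
  }
  w <- if (weighting == "allele") hits$zygosity_weight else
    rep(1L, nrow(hits))
  count <- sum(w)
  log_odds <- sum(w * log(hits$odds_ratio))
  mult <- prod(hits$odds_ratio^w)
  lifetime <- NA_real_
  capped <- FALSE
  if (!is.null(average_population_risk)) {
    lifetime <- mult * average_population_risk
    if (lifetime > 1) {
      lifetime <- 1
      capped <- TRUE
    }
  }
  structure(
    list(count_score = as.integer(count), log_odds_score = log_odds,
         multiplicative_or = mult, lifetime_risk = lifetime,
         lifetime_risk_capped = capped),
    class = "polygenic_scores"
  )
}

#' @export
print.polygenic_scores <- function(x, ...) {
  cat("Polygenic scores: count", x$count_score,
      "| log-odds", format(x$log_odds_score, digits = 4),
      "| multiplicative OR", format(x$multiplicative_or, digits = 4), "\n")
  if (!is.na(x$lifetime_risk)) {
    cat("  lifetime risk", format(x$lifetime_risk, digits = 4),
        if (x$lifetime_risk_capped) "(capped at 1)" else "", "\n")
  }
  invisible(x)
}

#' Serialize / restore risk models
#'
#' Models are stored as JSON: `{name, type, snps|branches,
#' reference_table, supports_fhh, metrics, ...}`. Validation (reference-
#' table completeness, OR monotonicity, unique branch ids) runs on load.
#'
#' @param model A `cumulative_model` or `branch_set_model`.
#' @param path File path.
#' @return `load_model()` returns the model; `save_model()` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "cumulative_model")) {
    payload <- list(name = model$name, type = "cumulative",
                    snps = model$snps,
                    reference_table = model$reference_table,
                    supports_fhh = model$supports_fhh,
                    reference_table_source = model$reference_table_source)
  } else if (inherits(model, "branch_set_model")) {
    payload <- list(name = model$name, type = "branch_set",
                    branches = model$branches, metrics = model$metrics,
                    source = model$source)
  } else stop("not a risk model", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw$type)) stop("model file lacks a 'type' field: ", path,
                              call. = FALSE)
  if (raw$type == "cumulative") {
    snps <- do.call(rbind, lapply(raw$snps, function(s) {
      data.frame(rsid = s$rsid, risk_allele = s$risk_allele,
                 genetic_model = s$genetic_model, stringsAsFactors = FALSE)
    }))
    rt_cols <- unique(unlist(lapply(raw$reference_table, names)))
    rt <- do.call(rbind, lapply(raw$reference_table, function(r) {
      row <- lapply(rt_cols, function(col) {
        v <- r[[col]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      })
      names(row) <- rt_cols
      as.data.frame(row)
    }))
    cumulative_model(raw$name, snps, rt,
                     supports_fhh = isTRUE(raw$supports_fhh),
                     reference_table_source =
                       raw$reference_table_source %||% "published")
  } else if (raw$type == "branch_set") {
    branch_set_model(raw$name, raw$branches, metrics = raw$metrics,
                     source = raw$source %||% "published")
  } else {
    stop("unknown model type '", raw$type, "' in ", path, call. = FALSE)
  }
}

#' Load every model file in a directory
#'
#' @param dir Directory of `.json` model files.
#' @return Named list of models.
#' @export
load_models <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no model files in ", dir, call. = FALSE)
  models <- lapply(files, load_model)
  names(models) <- vapply(models, function(m) m$name, character(1))
  models
}

#' Shipped risk prediction models
#'
#' Loads the cumulative models bundled with the package: six SNP panels
#' (17-SNP_Helfand, 9-SNP_Helfand, 5-SNP_Zheng, 5-SNP_Salinas, 4-SNP_Nam,
#' 3-SNP_Beuten) and a small synthetic branch-set model. Only the
#' 5-SNP_Zheng reference table is transcribed from the literature; the
#' other panels carry synthetic stand-in tables (flagged
#' `reference_table_source = "synthetic"`) because their published tables
#' are not available in the open text.
#'
#' @return Named list of models.
#' @export
shipped_models <- function() {
  load_models(system.file("extdata", "models", package = "snprisk"))
}

#' @rdname shipped_models
#' @export
zheng_model <- function() {
  load_model(system.file("extdata", "models", "cumulative_5snp_zheng.json",
                         package = "snprisk"))
}
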