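# Report assembly: ties KB lookup, genome parsing, independent scoring and
# model evaluation into one personal risk report, plus cohort simulation.

#' Assess a personal genome end to end
#'
#' Runs the full pipeline on one subject: extracts the clinically relevant
#' SNP hits from the knowledge base, computes the four independent
#' association scores and the impact-by-evidence categorical summary,
#' evaluates every supplied cumulative and branch-set model, and computes
#' the polygenic scores. The report is deterministic: identical inputs
#' give identical structured output (the timestamp can be suppressed for
#' byte-identical files).
#'
#' @param genome A `personal_genome` or path to a raw genotype file.
#' @param kb A `snp_kb` or path to a KB JSON file.
#' @param models List of models (see [load_models()]), a directory path,
#'   or `NULL` to skip model-based assessment.
#' @param clinical Optional `clinical_profile` or path to a profile JSON.
#' @param fhh Family health history override; when `NULL`, taken from the
#'   clinical profile (default `"unknown"`).
#' @param average_population_risk Optional baseline lifetime risk in
#'   (0, 1) for the multiplicative model; no default is assumed.
#' @param mode Missing-SNP handling for cumulative models, `"strict"` or
#'   `"bounds"`.
#' @param combine Evidence-impact rank combination, `"product"` or
#'   `"sum"`.
#' @return A `risk_report` list; see the fields printed by its `print`
#'   method and written by [save_report()].
#' @export
assess <- function(genome, kb, models = NULL, clinical = NULL, fhh = NULL,
                   average_population_risk = NULL,
                   mode = c("strict", "bounds"),
                   combine = c("product", "sum")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  if (is.character(genome)) genome <- parse_genome(genome)
  if (is.character(kb)) kb <- load_kb(kb)
  if (is.character(clinical)) clinical <- read_clinical_profile(clinical)
  if (is.character(models)) models <- load_models(models)
  if (inherits(models, "cumulative_model") ||
      inherits(models, "branch_set_model")) {
    models <- list(models)
  }
  if (is.null(fhh)) {
    fhh <- if (is.null(clinical)) "unknown" else clinical$family_health_history
  }

  hits <- extract_hits(genome, kb)
  scores <- independent_scores(hits, combine = combine)
  summary_grid <- categorical_summary(hits)
  polygenic <- polygenic_scores(hits, average_population_risk)

  cumulative_results <- list()
  branch_verdicts <- list()
  for (model in models) {
    if (inherits(model, "cumulative_model")) {
      cumulative_results[[model$name]] <-
        evaluate_cumulative(genome, model, fhh = fhh, mode = mode)
    } else if (inherits(model, "branch_set_model")) {
      branch_verdicts[[model$name]] <-
        match_branches(genome, model, clinical = clinical)
    } else stop("unsupported model object", call. = FALSE)
  }

  structure(
    list(
      subject_id = genome$subject_id,
      independent_scores = scores,
      categorical_summary = summary_grid,
      cumulative_results = cumulative_results,
      branch_verdicts = branch_verdicts,
      polygenic = polygenic,
      clinical_flags = list(
        risk_factor_tags = if (is.null(clinical)) character(0) else
          clinical$risk_factor_tags,
        protective_factor_tags = if (is.null(clinical)) character(0) else
          clinical$protective_factor_tags
      ),
      provenance = list(
        kb_version = kb$version, disease_code = kb$disease_code,
        n_kb_associations = nrow(kb$associations),
        model_names = vapply(models %||% list(), function(m) m$name,
                             character(1)),
        tool_version = as.character(utils::packageVersion("snprisk")),
        fhh = fhh, mode = mode, combine = combine,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "risk_report"
  )
}

#' @export
print.risk_report <- function(x, ...) {
  cat("== Personal risk report:", x$subject_id, "==\n")
  print(x$independent_scores)
  cat("  hits by impact x evidence (total",
      attr(x$categorical_summary, "total"), "):\n")
  print(unclass(x$categorical_summary))
  for (res in x$cumulative_results) print(res)
  for (v in x$branch_verdicts) print(v)
  print(x$polygenic)
  invisible(x)
}

#' Write a risk report to disk
#'
#' @param report A `risk_report`.
#' @param path Destination file.
#' @param format `"json"` (canonical, machine-readable) or `"text"`.
#' @param include_timestamp Set `FALSE` for byte-identical reruns.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path, format = c("json", "text"),
                        include_timestamp = TRUE) {
  stopifnot(inherits(report, "risk_report"))
  format <- match.arg(format)
  if (!include_timestamp) report$provenance$timestamp <- NULL
  if (format == "json") {
    payload <- report
    payload$independent_scores <- unclass(payload$independent_scores)
    payload$categorical_summary <- list(
      counts = as.data.frame(payload$categorical_summary),
      total = attr(payload$categorical_summary, "total")
    )
    payload$cumulative_results <- lapply(payload$cumulative_results, unclass)
    payload$branch_verdicts <- lapply(payload$branch_verdicts, unclass)
    payload$polygenic <- unclass(payload$polygenic)
    jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(path)
}

#' Simulate a cohort of synthetic genomes with a truth manifest
#'
#' Writes `n_cases + n_controls` raw genotype files. Cases are seeded with
#' more planted risk genotypes than controls; every file's planted truth
#' (rsid -> zygosity) is recorded in `manifest.json` so downstream
#' extraction can be checked exactly. Deterministic for a fixed seed. The
#' default cohort shape (4 cases, 15 controls) mirrors a small
#' case-control evaluation design.
#'
#' @param kb A `snp_kb`.
#' @param out_dir Output directory (created if needed).
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed.
#' @param n_background Background (non-KB) records per genome.
#' @param case_fraction,control_fraction Fraction of KB SNPs planted as
#'   risk-carrying in cases and controls respectively.
#' @return Invisibly, the manifest as a named list.
#' @export
simulate_cohort <- function(kb, out_dir, n_cases = 4L, n_controls = 15L,
                            seed = 1L, n_background = 100L,
                            case_fraction = 0.6, control_fraction = 0.2) {
  stopifnot(inherits(kb, "snp_kb"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rsids <- kb$associations$rsid
  manifest <- list(seed = seed, subjects = list())
  labels <- c(sprintf("case%02d", seq_len(n_cases)),
              sprintf("control%02d", seq_len(n_controls)))
  fractions <- c(rep(case_fraction, n_cases),
                 rep(control_fraction, n_controls))
  for (i in seq_along(labels)) {
    sub_seed <- seed + i
    set.seed(sub_seed)
    n_plant <- max(1L, round(fractions[i] * length(rsids)))
    chosen <- sample(rsids, min(n_plant, length(rsids)))
    zyg <- sample(c("het", "hom", "nocall"), length(chosen), replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    planted <- stats::setNames(zyg, chosen)
    g <- generate_synthetic_genome(kb, planted, n_background = n_background,
                                   seed = sub_seed, subject_id = labels[i])
    write_genome(g, file.path(out_dir, paste0(labels[i], ".txt")))
    manifest$subjects[[labels[i]]] <- as.list(planted)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Tabulate cumulative-model categories over a cohort of reports
#'
#' Aggregates per-subject cumulative results into a model-by-category
#' count table (`high` for OR >= 2.5, `lower` for OR < 2.5, `unknown`
#' for abstentions), the shape used to summarize a case/control cohort.
#'
#' @param reports List of `risk_report` objects.
#' @return Data frame with columns `model`, `high`, `lower`, `unknown`.
#' @export
cohort_summary <- function(reports) {
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, logical(1), "risk_report")))
  rows <- list()
  for (rep in reports) {
    for (res in rep$cumulative_results) {
      cat3 <- res$category
      if (!cat3 %in% c("high", "lower")) cat3 <- "unknown"
      rows[[length(rows) + 1L]] <- data.frame(model = res$model_name,
                                              category = cat3)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(model = character(0), high = integer(0),
                      lower = integer(0), unknown = integer(0)))
  }
  long <- do.call(rbind, rows)
  tab <- table(long$model, factor(long$category,
                                  c("high", "lower", "unknown")))
  out <- as.data.frame.matrix(tab)
  data.frame(model = rownames(out), out, row.names = NULL)
}
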