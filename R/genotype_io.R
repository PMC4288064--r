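# Direct-to-consumer raw genotype files: parsing, serialization, synthetic
# generation, and zygosity calls against a risk allele.

NOCALL <- "--"

#' Parse a direct-to-consumer raw genotype file
#'
#' Reads the 23andMe-style raw format: comment lines starting `#`, then
#' tab-separated columns rsid, chromosome, position, genotype. The reader
#' tolerates CRLF line endings and trailing whitespace. Duplicate rsIDs
#' keep the first occurrence (with a warning); malformed lines are skipped
#' with a warning unless `strict = TRUE`.
#'
#' @param path Path to the raw genotype file.
#' @param subject_id Identifier for the genome's owner; defaults to the
#'   file name without extension.
#' @param strict If `TRUE`, malformed data lines are an error rather than
#'   a skip-with-warning.
#' @return A `personal_genome`: list with `subject_id`, `build_label`, and
#'   a `records` data frame (rsid, chromosome, position, genotype) with one
#'   row per rsID. Attribute `n_nocall` counts `"--"` genotypes.
#' @export
parse_genome <- function(path, subject_id = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L) stop("empty genotype file: ", path, call. = FALSE)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  build_label <- NULL
  build_line <- grep("build", lines[is_comment], ignore.case = TRUE,
                     value = TRUE)
  if (length(build_line) > 0L) build_label <- trimws(sub("^#+", "", build_line[1L]))
  data_lines <- lines[!is_comment]
  if (length(data_lines) == 0L) {
    stop("genotype file has no data lines: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(data_lines, which = "right"), "\t", fixed = TRUE)
  ok <- lengths(fields) == 4L
  if (any(!ok)) {
    msg <- paste0(sum(!ok), " malformed line(s) (expected 4 tab-separated ",
                  "columns) in ", path)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    fields <- fields[ok]
  }
  if (length(fields) == 0L) stop("no parseable data lines in ", path,
                                 call. = FALSE)
  mat <- do.call(rbind, fields)
  records <- data.frame(
    rsid = mat[, 1L], chromosome = mat[, 2L],
    position = as.integer(mat[, 3L]), genotype = toupper(mat[, 4L]),
    stringsAsFactors = FALSE
  )
  bad_gt <- !grepl("^([ACGTDI]{1,2}|--)$", records$genotype)
  if (any(bad_gt)) {
    msg <- paste0(sum(bad_gt), " record(s) with unparseable genotype in ",
                  path)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    records <- records[!bad_gt, , drop = FALSE]
  }
  dup <- duplicated(records$rsid)
  if (any(dup)) {
    warning(sum(dup), " duplicate rsID line(s); keeping first occurrence",
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  personal_genome(subject_id, records, build_label)
}

personal_genome <- function(subject_id, records, build_label = NULL) {
  stopifnot(is.data.frame(records),
            all(c("rsid", "chromosome", "position", "genotype") %in%
                  names(records)))
  if (anyDuplicated(records$rsid)) {
    stop("personal genome must have one record per rsID", call. = FALSE)
  }
  g <- structure(
    list(subject_id = subject_id, records = records,
         build_label = build_label),
    class = "personal_genome"
  )
  attr(g, "n_nocall") <- sum(records$genotype == NOCALL)
  g
}

#' @export
print.personal_genome <- function(x, ...) {
  cat("<personal_genome>", x$subject_id, "|", nrow(x$records), "records |",
      attr(x, "n_nocall"), "no-calls\n")
  invisible(x)
}

#' Write a genome in the raw 23andMe-style format
#'
#' @param genome A `personal_genome`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "personal_genome"))
  header <- c(
    paste0("# raw genotype export for subject ", genome$subject_id),
    if (!is.null(genome$build_label)) paste0("# ", genome$build_label),
    "# rsid\tchromosome\tposition\tgenotype"
  )
  body <- with(genome$records,
               paste(rsid, chromosome, position, genotype, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a synthetic personal genome with planted risk genotypes
#'
#' Emulates a direct-to-consumer raw file for testing: knowledge-base SNPs
#' are planted at a requested zygosity and padded with background records
#' whose rsIDs never match the KB. Used to validate the extraction and
#' scoring pipeline against known truth.
#'
#' Zygosity codes: `"hom"` plants the risk allele twice, `"het"` the risk
#' allele plus a drawn non-risk allele, `"nocall"` plants `"--"`,
#' `"absent"` omits the rsID entirely (SNP not on the chip).
#'
#' @param kb A `snp_kb`; planted rsIDs must exist in it.
#' @param planted Named character vector, rsid -> zygosity in
#'   `c("hom", "het", "absent", "nocall")`.
#' @param n_background Number of non-KB background records to add.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param subject_id Subject label for the genome.
#' @return A `personal_genome`; attribute `truth` records the planted map.
#' @export
generate_synthetic_genome <- function(kb, planted = character(0),
                                      n_background = 100L, seed = 1L,
                                      subject_id = "synthetic") {
  stopifnot(inherits(kb, "snp_kb"))
  if (length(planted) > 0L) {
    if (is.null(names(planted)) || any(!nzchar(names(planted)))) {
      stop("planted must be a named vector (rsid -> zygosity)", call. = FALSE)
    }
    bad <- setdiff(names(planted), kb$associations$rsid)
    if (length(bad) > 0L) {
      stop("planted rsID(s) not in the knowledge base: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(planted %in% c("hom", "het", "absent", "nocall"))) {
      stop("zygosity must be hom, het, absent or nocall", call. = FALSE)
    }
  }
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  assoc <- kb$associations
  alleles <- c("A", "C", "G", "T")
  rows <- list()
  for (rsid in names(planted)) {
    zyg <- planted[[rsid]]
    if (zyg == "absent") next
    risk <- assoc$risk_allele[match(rsid, assoc$rsid)]
    gt <- switch(zyg,
      hom = paste0(risk, risk),
      het = {
        other <- sample(setdiff(alleles, risk), 1L)
        # character order randomized so tests cover both orderings
        paste(sample(c(risk, other)), collapse = "")
      },
      nocall = NOCALL
    )
    rows[[rsid]] <- data.frame(
      rsid = rsid, chromosome = as.character(sample(1:22, 1L)),
      position = sample.int(2.4e8, 1L), genotype = gt,
      stringsAsFactors = FALSE
    )
  }
  if (n_background > 0L) {
    # background rsIDs drawn above 9e7, far outside the KB's id space
    bg_ids <- paste0("rs", 90000000L + sample.int(9999999L, n_background))
    bg_ids <- setdiff(bg_ids, assoc$rsid)
    bg_alleles <- vapply(seq_along(bg_ids), function(i) {
      pair <- sample(alleles, 2L, replace = TRUE)
      paste(pair, collapse = "")
    }, character(1))
    rows[["background"]] <- data.frame(
      rsid = bg_ids,
      chromosome = as.character(sample(1:22, length(bg_ids), replace = TRUE)),
      position = sample.int(2.4e8, length(bg_ids)),
      genotype = bg_alleles,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  if (is.null(records)) {
    stop("nothing to generate: no planted SNPs and no background",
         call. = FALSE)
  }
  records <- records[order(records$rsid), , drop = FALSE]
  rownames(records) <- NULL
  g <- personal_genome(subject_id, records, "synthetic build 37")
  attr(g, "truth") <- planted
  g
}

ZYGOSITY_LEVELS <- c("hom_risk", "het_risk", "hemizygous_risk",
                     "no_risk", "nocall")

#' Zygosity of a genotype call with respect to a risk allele
#'
#' Classifies each genotype string: `hom_risk` when both characters equal
#' the risk allele, `het_risk` when exactly one does, `hemizygous_risk`
#' when a single-character call (X/Y/MT in males) equals it, `nocall` for
#' `"--"`, otherwise `no_risk`. Classification is symmetric in character
#' order ("AG" and "GA" agree). Insertion/deletion calls (D/I) are
#' `no_risk` with a warning; indels are out of scope.
#'
#' @param genotype Character vector of genotype strings.
#' @param risk_allele Single risk nucleotide (A/C/G/T), recycled.
#' @return Character vector over
#'   `c("hom_risk", "het_risk", "hemizygous_risk", "no_risk", "nocall")`.
#' @export
#' @examples
#' genotype_zygosity(c("AA", "AG", "GG", "A", "--"), "A")
genotype_zygosity <- function(genotype, risk_allele) {
  if (!all(risk_allele %in% c("A", "C", "G", "T"))) {
    stop("risk_allele must be A, C, G or T", call. = FALSE)
  }
  n <- max(length(genotype), length(risk_allele))
  genotype <- rep_len(toupper(genotype), n)
  risk_allele <- rep_len(risk_allele, n)
  if (any(grepl("[DI]", genotype))) {
    warning("insertion/deletion genotype(s) treated as no_risk",
            call. = FALSE)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    gt <- genotype[i]
    if (gt == NOCALL) {
      out[i] <- "nocall"
    } else if (nchar(gt) == 1L) {
      out[i] <- if (gt == risk_allele[i]) "hemizygous_risk" else "no_risk"
    } else {
      k <- sum(strsplit(gt, "")[[1]] == risk_allele[i])
      out[i] <- c("no_risk", "het_risk", "hom_risk")[k + 1L]
    }
  }
  out
}

#' Construct or read a clinical profile
#'
#' Holds the non-genomic inputs to risk models: family health history and
#' the behavioral/anthropometric parameters used by genotype-plus-clinical
#' branch-set models. Tri-state fields are `"positive"`, `"negative"` or
#' `"unknown"` and never silently default to negative: missing data stays
#' `"unknown"` so models can abstain rather than guess.
#'
#' @param subject_id Subject label.
#' @param family_health_history,smoking,alcohol Tri-state values.
#' @param bmi_class One of `"normal"`, `"overweight"`, `"obese"` or
#'   `"unknown"`.
#' @param risk_factor_tags,protective_factor_tags Free-text factor lists
#'   echoed in reports (comorbidities, drugs, supplements).
#' @return A `clinical_profile` list.
#' @export
clinical_profile <- function(subject_id,
                             family_health_history = "unknown",
                             bmi_class = "unknown",
                             smoking = "unknown",
                             alcohol = "unknown",
                             risk_factor_tags = character(0),
                             protective_factor_tags = character(0)) {
  tri <- c("positive", "negative", "unknown")
  stopifnot(family_health_history %in% tri, smoking %in% tri,
            alcohol %in% tri,
            bmi_class %in% c("normal", "overweight", "obese", "unknown"))
  structure(
    list(subject_id = subject_id,
         family_health_history = family_health_history,
         bmi_class = bmi_class, smoking = smoking, alcohol = alcohol,
         risk_factor_tags = as.character(risk_factor_tags),
         protective_factor_tags = as.character(protective_factor_tags)),
    class = "clinical_profile"
  )
}

#' @rdname clinical_profile
#' @param path JSON file with the clinical profile fields; unknown fields
#'   are preserved in the `extra` attribute.
#' @export
read_clinical_profile <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("subject_id", "family_health_history", "bmi_class", "smoking",
             "alcohol", "risk_factor_tags", "protective_factor_tags")
  args <- raw[intersect(names(raw), known)]
  if (is.null(args$subject_id)) {
    args$subject_id <- tools::file_path_sans_ext(basename(path))
  }
  prof <- do.call(clinical_profile, args)
  attr(prof, "extra") <- raw[setdiff(names(raw), known)]
  prof
}
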