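# Helpers local to model evaluation ------------------------------------

# genome with the requested impact pattern on a model: for each SNP give
# "hom", "het", "none", "absent" or "nocall"
model_genome <- function(model, states) {
  stopifnot(length(states) == nrow(model$snps))
  keep <- states != "absent"
  gt <- mapply(function(risk, st) {
    switch(st,
           hom = paste0(risk, risk),
           het = paste0(risk, non_risk_allele(risk)),
           none = paste0(non_risk_allele(risk), non_risk_allele(risk)),
           nocall = "--",
           absent = NA_character_)
  }, model$snps$risk_allele, states)
  make_genome(setNames(gt[keep], model$snps$rsid[keep]))
}

test_that("the shipped 5-SNP panel encodes 3 dominant and 2 recessive SNPs", {
  m <- zheng_model()
  expect_equal(nrow(m$snps), 5L)
  expect_equal(sum(m$snps$genetic_model == "dominant"), 3L)
  expect_equal(sum(m$snps$genetic_model == "recessive"), 2L)
  expect_true(m$supports_fhh)
  expect_setequal(m$snps$rsid[m$snps$genetic_model == "dominant"],
                  c("rs1447295", "rs16901979", "rs6983267"))
  expect_setequal(m$snps$rsid[m$snps$genetic_model == "recessive"],
                  c("rs1859962", "rs4430796"))
})

test_that("maximal risk genotype with positive FHH reaches impact 6 and OR 9.46", {
  m <- zheng_model()
  g <- full_risk_genome(m)
  res <- evaluate_cumulative(g, m, fhh = "positive")
  expect_equal(res$status, "evaluated")
  expect_equal(res$total_impact, 6L)
  expect_equal(res$odds_ratio, 9.46)
  expect_equal(classify_cumulative(res), "high")
})

test_that("one dominant het risk factor without FHH looks up OR 1.50", {
  m <- zheng_model()
  # het at dominant rs1447295 counts; het at the recessive SNPs does not
  g <- model_genome(m, c("het", "none", "none", "het", "het"))
  res <- evaluate_cumulative(g, m, fhh = "negative")
  expect_equal(res$total_impact, 1L)
  expect_equal(res$odds_ratio, 1.50)
  expect_equal(classify_cumulative(res), "lower")
})

test_that("heterozygous recessive-model SNPs are harmless: impact 0, OR 1.00", {
  m <- zheng_model()
  g <- model_genome(m, c("none", "none", "none", "het", "het"))
  res <- evaluate_cumulative(g, m, fhh = "negative")
  expect_equal(res$total_impact, 0L)
  expect_equal(res$odds_ratio, 1.00)
})

test_that("the full reference table reproduces both OR columns", {
  m <- zheng_model()
  without <- c(1.00, 1.50, 1.96, 2.21, 4.47, 4.47)
  withfhh <- c(1.00, 1.62, 2.07, 2.71, 4.76, 9.46, 9.46)
  for (k in 0:5) {
    expect_equal(snprisk:::lookup_reference_or(m, k, FALSE)$odds_ratio,
                 without[k + 1])
  }
  for (k in 0:6) {
    expect_equal(snprisk:::lookup_reference_or(m, k, TRUE)$odds_ratio,
                 withfhh[k + 1])
  }
  expect_error(snprisk:::lookup_reference_or(m, 6, FALSE), "outside")
})

test_that("unknown FHH falls back to the without-FHH column, flagged", {
  m <- zheng_model()
  g <- full_risk_genome(m)
  res <- evaluate_cumulative(g, m, fhh = "unknown")
  expect_equal(res$total_impact, 5L)
  expect_equal(res$odds_ratio, 4.47)
  expect_equal(res$fhh_used, "without_fhh")
})

test_that("strict mode abstains on any unassayed or uncalled model SNP", {
  m <- zheng_model()
  for (bad in c("absent", "nocall")) {
    g <- model_genome(m, c("hom", "hom", bad, "hom", "hom"))
    res <- evaluate_cumulative(g, m, fhh = "negative")
    expect_equal(res$status, "unknown")
    expect_true(is.na(res$odds_ratio))
    expect_equal(classify_cumulative(res), "unknown")
    if (bad == "absent") expect_equal(res$missing_snps, "rs6983267")
    if (bad == "nocall") expect_equal(res$nocall_snps, "rs6983267")
  }
})

test_that("bounds mode brackets missing SNPs between 0 and 1 impact each", {
  m <- zheng_model()
  g <- model_genome(m, c("hom", "hom", "absent", "hom", "hom"))
  res <- evaluate_cumulative(g, m, fhh = "negative", mode = "bounds")
  expect_equal(res$status, "bounds")
  expect_equal(res$impact_range, c(4L, 5L))
  expect_equal(res$or_range, c(4.47, 4.47))
  expect_equal(res$category, "high")
})

test_that("adding a risk allele never lowers the total impact", {
  m <- zheng_model()
  states <- c("none", "none", "none", "none", "none")
  prev <- evaluate_cumulative(model_genome(m, states), m,
                              fhh = "negative")$total_impact
  upgrades <- list(c(1, "het"), c(2, "hom"), c(3, "het"),
                   c(4, "hom"), c(5, "hom"))
  for (u in upgrades) {
    states[as.integer(u[1])] <- u[2]
    cur <- evaluate_cumulative(model_genome(m, states), m,
                               fhh = "negative")$total_impact
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 5L)
})

test_that("model constructor rejects incomplete or non-monotone reference tables", {
  snps <- data.frame(rsid = c("rs1", "rs2"), risk_allele = c("A", "G"),
                     genetic_model = c("dominant", "recessive"))
  rt_missing <- data.frame(total_impact = c(0, 2),
                           or_without_fhh = c(1, 2))
  expect_error(cumulative_model("m", snps, rt_missing), "incomplete")
  rt_nonmono <- data.frame(total_impact = 0:2,
                           or_without_fhh = c(1, 2, 1.5))
  expect_error(cumulative_model("m", snps, rt_nonmono), "non-decreasing")
  rt_ok <- data.frame(total_impact = 0:2, or_without_fhh = c(1, 1.5, 2))
  expect_s3_class(cumulative_model("m", snps, rt_ok), "cumulative_model")
  expect_error(cumulative_model("m", snps, rt_ok, supports_fhh = TRUE),
               "or_with_fhh")
})

test_that("cumulative and branch-set models survive a save/load round trip", {
  m <- zheng_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$snps, m$snps)
  expect_equal(m2$reference_table, m$reference_table)
  expect_equal(m2$supports_fhh, m$supports_fhh)

  set.seed(8)
  bs <- random_branch_model(4, paste0("rs", 1:6),
                            sample(c("A", "C", "G", "T"), 6, replace = TRUE))
  save_model(bs, path)
  bs2 <- load_model(path)
  expect_equal(length(bs2$branches), length(bs$branches))
  expect_equal(
    vapply(bs2$branches, function(b) b$branch_id, character(1)),
    vapply(bs$branches, function(b) b$branch_id, character(1))
  )
})

test_that("every shipped model loads and validates", {
  models <- shipped_models()
  expect_length(models, 7L)
  cum <- Filter(function(m) inherits(m, "cumulative_model"), models)
  expect_length(cum, 6L)
  sizes <- sort(vapply(cum, function(m) nrow(m$snps), integer(1)))
  expect_equal(unname(sizes), c(3L, 4L, 5L, 5L, 9L, 17L))
  # only the 5-SNP panel's table is transcribed from the literature
  published <- names(Filter(function(m) {
    identical(m$reference_table_source, "published")
  }, cum))
  expect_equal(published, "5-SNP_Zheng")
})

# --- branch matching ---------------------------------------------------

test_that("branch verdicts follow the matched/contradicted/indeterminate rules", {
  branches <- list(
    list(branch_id = "b1",
         snp_requirements = list(list(rsid = "rs1", genotype = "AA"),
                                 list(rsid = "rs2", allele = "G")),
         clinical_requirements = list(list(field = "smoking",
                                           value = "positive")))
  )
  model <- branch_set_model("one-branch", branches)

  g_match <- make_genome(c(rs1 = "AA", rs2 = "GT"))
  clin_pos <- clinical_profile("s", smoking = "positive")
  expect_equal(match_branches(g_match, model, clin_pos)$verdict, "at_risk")

  # genotype contradicts -> the only branch is ruled out
  g_contra <- make_genome(c(rs1 = "AG", rs2 = "GT"))
  expect_equal(match_branches(g_contra, model, clin_pos)$verdict, "risk_free")

  # genotypes match but the smoking datum is missing -> indeterminate
  clin_unk <- clinical_profile("s", smoking = "unknown")
  v <- match_branches(g_match, model, clin_unk)
  expect_equal(v$verdict, "indeterminate")
  expect_equal(v$indeterminate_branches, "b1")
})

test_that("unordered genotype requirements match either character order", {
  model <- branch_set_model("flip", list(
    list(branch_id = "b1",
         snp_requirements = list(list(rsid = "rs1", genotype = "AG")))
  ))
  expect_equal(match_branches(make_genome(c(rs1 = "GA")), model)$verdict,
               "at_risk")
})

test_that("branch matching agrees with an independent oracle on random models", {
  set.seed(77)
  alleles_pool <- c("A", "C", "G", "T")
  for (i in 1:40) {
    n_snp <- sample(4:8, 1)
    rsids <- paste0("rs", sample(100:999, n_snp))
    alleles <- sample(alleles_pool, n_snp, replace = TRUE)
    model <- random_branch_model(sample(1:10, 1), rsids, alleles)
    # genome covering a random subset with random calls
    covered <- sample(c(TRUE, FALSE), n_snp, replace = TRUE)
    gt <- vapply(seq_len(n_snp), function(j) {
      if (stats::runif(1) < 0.15) return("--")
      paste(sample(alleles_pool, 2, replace = TRUE), collapse = "")
    }, character(1))
    g <- if (any(covered)) {
      make_genome(setNames(gt[covered], rsids[covered]))
    } else make_genome(c(rs99999 = "AA"))
    clin <- clinical_profile(
      "s",
      smoking = sample(c("positive", "negative", "unknown"), 1),
      alcohol = sample(c("positive", "negative", "unknown"), 1),
      bmi_class = sample(c("obese", "normal", "unknown"), 1)
    )
    v <- match_branches(g, model, clin)
    expect_equal(v$verdict, oracle_match(g, model, clin))
    # trichotomy: the three branch lists partition the branch ids
    all_ids <- vapply(model$branches, function(b) b$branch_id, character(1))
    expect_setequal(c(v$matched_branches, v$contradicted_branches,
                      v$indeterminate_branches), all_ids)
  }
})

test_that("duplicate branch ids and unknown clinical fields are load errors", {
  b <- list(branch_id = "b1",
            snp_requirements = list(list(rsid = "rs1", allele = "A")))
  expect_error(branch_set_model("dup", list(b, b)), "duplicate")
  bad <- list(branch_id = "b2", snp_requirements = list(),
              clinical_requirements = list(list(field = "age", value = "70")))
  expect_error(branch_set_model("badfield", list(bad)), "clinical field")
  expect_error(branch_set_model("empty", list(list(branch_id = "b3"))),
               "no requirements")
})

# --- polygenic scores --------------------------------------------------

test_that("polygenic scores handle the empty and unit cases", {
  p <- polygenic_scores(empty_hits())
  expect_equal(p$count_score, 0L)
  expect_equal(p$log_odds_score, 0)
  expect_equal(p$multiplicative_or, 1.0)
  expect_true(is.na(p$lifetime_risk))

  h <- random_hits(1)
  h$odds_ratio <- exp(1)
  h$zygosity <- "het_risk"; h$zygosity_weight <- 1L
  p <- polygenic_scores(h)
  expect_equal(p$log_odds_score, 1.0)
  expect_equal(p$multiplicative_or, exp(1))
})

test_that("polygenic hand-worked example: het OR 1.5 + hom OR 1.2, baseline 0.16", {
  h <- random_hits(2)
  h$odds_ratio <- c(1.5, 1.2)
  h$zygosity <- c("het_risk", "hom_risk")
  h$zygosity_weight <- c(1L, 2L)
  p <- polygenic_scores(h, average_population_risk = 0.16)
  expect_equal(p$count_score, 3L)
  expect_equal(p$log_odds_score, log(1.5) + 2 * log(1.2))
  expect_equal(p$multiplicative_or, 1.5 * 1.2^2)
  expect_equal(p$lifetime_risk, 1.5 * 1.44 * 0.16)
  expect_false(p$lifetime_risk_capped)
})

test_that("lifetime risk is capped at 1 and flagged", {
  h <- random_hits(3)
  h$odds_ratio <- c(3, 3, 3)
  h$zygosity <- rep("hom_risk", 3); h$zygosity_weight <- rep(2L, 3)
  p <- polygenic_scores(h, average_population_risk = 0.5)
  expect_equal(p$lifetime_risk, 1)
  expect_true(p$lifetime_risk_capped)
})

test_that("per-genotype weighting counts each hit once", {
  h <- random_hits(2)
  h$odds_ratio <- c(2, 2)
  h$zygosity <- c("hom_risk", "het_risk")
  h$zygosity_weight <- c(2L, 1L)
  p <- polygenic_scores(h, weighting = "genotype")
  expect_equal(p$count_score, 2L)
  expect_equal(p$multiplicative_or, 4)
})
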