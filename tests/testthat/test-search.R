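search_specs <- function(m, effects = numeric(m), mafs = rep(0.3, m),
                         models = rep("dominant", m)) {
  tibble::tibble(snp_id = sprintf("rs%02d", seq_len(m)), maf = mafs,
                 model = models, log_or = effects,
                 interaction_with = NA_character_,
                 interaction_log_or = NA_real_)
}

test_that("model count follows 2^m - 1 and matches brute enumeration", {
  expect_equal(count_models(12), 4095)
  expect_equal(count_models(1), 1)
  expect_equal(count_models(3), 7)
  expect_error(count_models(0), "at least 1")
  for (m in 1:10) {
    n_enum <- sum(choose(m, seq_len(m)))
    expect_equal(count_models(m), n_enum)
  }
})

test_that("complete-case assembly keeps only fully observed subjects", {
  specs <- search_specs(3)
  sim <- sim_fixture(31, n = 800, snp_specs = specs,
                     missingness = tibble::tibble(
                       snp_id = "rs01", random_rate = 0,
                       block = "chip"),
                     block_rates = c(chip = 0.46))
  cc <- complete_cases_cohort(sim$gm, sim$pheno, specs$snp_id,
                              covariates = c("sex", "age"))
  # block missingness on one SNP: ~54% retained
  expect_equal(cc$n / 800, 0.54, tolerance = 0.05)
  expect_equal(cc$n_cases + cc$n_controls, cc$n)
  # a subject missing only an unlisted SNP is retained
  cc2 <- complete_cases_cohort(sim$gm, sim$pheno, c("rs02", "rs03"),
                               covariates = c("sex", "age"))
  expect_equal(cc2$n, 800)
  expect_error(complete_cases_cohort(sim$gm, sim$pheno, character(0)),
               "no SNPs")
})

test_that("aliasing is detected at the encoding level and masked", {
  sim <- sim_fixture(32, n = 300, snp_specs = search_specs(2))
  gm <- sim$gm
  gm$rs_dup <- gm$rs01
  # rs03: different dosages but identical dominant carriers as rs01
  gm$rs03 <- ifelse(gm$rs01 >= 1L, 2L, 0L)
  gm <- genotype_matrix(tibble::as_tibble(as.data.frame(gm)))
  st <- tibble::tibble(snp_id = c("rs01", "rs02", "rs_dup", "rs03"),
                       model = "dominant")
  cc <- complete_cases_cohort(gm, sim$pheno, st$snp_id,
                              covariates = character(0))
  blocks <- cgassoc:::snp_design_blocks(cc$data, st)
  al <- detect_aliased(blocks)
  expect_equal(length(al$groups), 1)
  expect_setequal(al$groups[[1]], c("rs01", "rs_dup", "rs03"))
  expect_setequal(al$masked, c("rs_dup", "rs03"))
  # independent SNPs: no groups
  al2 <- detect_aliased(blocks[c("rs01", "rs02")])
  expect_equal(length(al2$groups), 0)
})

test_that("exhaustive search recovers planted effects on a fixed subject set", {
  m <- 6
  specs <- search_specs(m, effects = c(log(1.8), log(1.8), log(1.7),
                                       0, 0, 0))
  hits <- 0; n_rep <- 15
  for (i in seq_len(n_rep)) {
    sim <- sim_fixture(600 + i, n = 1500, snp_specs = specs)
    res <- exhaustive_search(sim$gm, sim$pheno, specs[c("snp_id", "model")],
                             covariates = c("sex", "age"))
    expect_equal(nrow(res$fits), count_models(m))
    # fixed subject set: one n across all fits
    expect_equal(unique(res$fits$n_used), 1500)
    # chosen AIC is the enumeration minimum
    expect_equal(min(res$fits$aic),
                 res$fits$aic[res$fits$subset ==
                                paste(res$chosen_subset, collapse = "+")],
                 tolerance = 1e-9)
    if (all(c("rs01", "rs02", "rs03") %in% res$chosen_subset)) {
      hits <- hits + 1
    }
  }
  expect_gt(hits / n_rep, 0.5)
})

test_that("aliased effect SNPs produce exact AIC ties, broken toward the first", {
  sim <- sim_fixture(33, n = 1200,
                     snp_specs = search_specs(2, effects = c(log(1.9), 0)))
  gm <- sim$gm
  gm$rs_twin <- gm$rs01   # perfect copy of the causal SNP
  gm <- genotype_matrix(tibble::as_tibble(as.data.frame(gm)))
  st <- tibble::tibble(snp_id = c("rs01", "rs_twin", "rs02"),
                       model = "dominant")
  res <- exhaustive_search(gm, sim$pheno, st, covariates = c("sex", "age"))
  # {rs01}, {rs_twin}, {rs01, rs_twin} fit identically: >= 3 tied subsets
  expect_gte(length(res$best_subsets), 3)
  expect_true("rs01" %in% res$chosen_subset)
  expect_false("rs_twin" %in% res$chosen_subset)
  expect_equal(length(res$aliased$groups), 1)
  # masking preserves the best AIC: refit with the alternate member
  st_alt <- tibble::tibble(snp_id = c("rs_twin", "rs02"),
                           model = "dominant")
  res_alt <- exhaustive_search(gm, sim$pheno, st_alt,
                               covariates = c("sex", "age"))
  expect_equal(min(res_alt$fits$aic), min(res$fits$aic), tolerance = 1e-9)
  # m = 1: a single fit, trivially chosen
  res1 <- exhaustive_search(gm, sim$pheno, st[1, ],
                            covariates = c("sex", "age"))
  expect_equal(nrow(res1$fits), 1)
  expect_equal(res1$chosen_subset, "rs01")
})

test_that("stepwise retains a planted gene-environment interaction", {
  specs <- tibble::tibble(
    snp_id = c("rsA", "rsB", "rsC"), maf = 0.3,
    model = c("dominant", "dominant", "recessive"),
    log_or = c(log(1.5), log(1.5), log(1.4)),
    interaction_with = c(NA, NA, "hypertension"),
    interaction_log_or = c(NA, NA, log(2.68)))
  sim <- sim_fixture(733, n = 3000, snp_specs = specs, case_fraction = 0.6)
  sw <- stepwise_interactions(sim$gm, sim$pheno, specs$snp_id,
                              specs[c("snp_id", "model")])
  expect_true("rsC:hypertension" %in% sw$active)
  # hierarchy: every interaction has both parents in the model
  for (t in sw$terms) {
    if (length(t$parents)) expect_true(all(t$parents %in% sw$active))
  }
  # forced covariates present in the coefficient table
  expect_true(all(c("age", "caucasian") %in% names(sw$coef)))
})

test_that("no specific interaction is favoured when none was simulated", {
  # AIC stepwise admits a weak spurious interaction now and then (each null
  # 1-df term enters with roughly P(chisq > 2)); the discriminating property
  # is per-term: any given interaction is retained in well under half the
  # replicates, unlike a planted one
  specs <- tibble::tibble(
    snp_id = c("rsA", "rsB"), maf = 0.3, model = "dominant",
    log_or = log(1.6), interaction_with = NA_character_,
    interaction_log_or = NA_real_)
  n_rep <- 12
  retained <- integer(0)
  for (i in seq_len(n_rep)) {
    sim <- sim_fixture(810 + i, n = 2000, snp_specs = specs,
                       case_fraction = 0.6)
    sw <- stepwise_interactions(sim$gm, sim$pheno, specs$snp_id,
                                specs[c("snp_id", "model")])
    ints <- grep(":", sw$active, value = TRUE)
    retained <- c(retained, table(ints))
    # main effects never collateral damage of a spurious interaction
    for (t in sw$terms) {
      if (length(t$parents)) expect_true(all(t$parents %in% sw$active))
    }
  }
  per_term <- tapply(retained, names(retained), sum)
  if (length(per_term)) expect_lt(max(per_term) / n_rep, 0.5)
})

test_that("an empty base subset yields a covariates-plus-clinical model", {
  sim <- sim_fixture(35, n = 500)
  sw <- stepwise_interactions(sim$gm, sim$pheno, character(0),
                              tibble::tibble(snp_id = character(0),
                                             model = character(0)))
  expect_true(all(sw$active %in% c("diabetes", "hypertension")))
  expect_true("hypertension" %in% names(sw$coef))
})

test_that("p-value-driven backward elimination respects the hierarchy", {
  specs <- search_specs(3, effects = c(log(1.6), 0, 0))
  sim <- sim_fixture(36, n = 2000, snp_specs = specs, case_fraction = 0.6)
  sw <- stepwise_interactions(sim$gm, sim$pheno, specs$snp_id,
                              specs[c("snp_id", "model")],
                              criterion = "pvalue")
  # null SNPs should tend to be eliminated; the causal one retained
  expect_true("rs01" %in% sw$active)
  for (t in sw$terms) {
    if (length(t$parents)) expect_true(all(t$parents %in% sw$active))
  }
  expect_true(all(sw$eliminated %in% c("rs02", "rs03", "diabetes",
                                       "hypertension")))
})

test_that("profile odds ratios equal hand-computed linear contrasts", {
  specs <- tibble::tibble(
    snp_id = c("rsA", "rsB"), maf = 0.3, model = c("dominant", "recessive"),
    log_or = c(log(1.8), log(1.5)),
    interaction_with = c(NA, "hypertension"),
    interaction_log_or = c(NA, log(2)))
  sim <- sim_fixture(37, n = 2500, snp_specs = specs, case_fraction = 0.6)
  sw <- stepwise_interactions(sim$gm, sim$pheno, specs$snp_id,
                              specs[c("snp_id", "model")])
  ref <- tibble::tibble(sex = "male", age = 60, caucasian = 1,
                        diabetes = 0, hypertension = 0, rsA = 0, rsB = 0)
  # reference vs itself: OR exactly 1 with a degenerate CI
  self <- profile_odds_ratios(sw, ref, ref)
  expect_equal(self$or, 1)
  expect_equal(self$or_low, 1)
  # single-term contrast: OR = exp(beta)
  if ("rsA" %in% sw$active) {
    prof <- ref; prof$rsA <- 1
    r <- profile_odds_ratios(sw, prof, ref)
    expect_equal(r$or, exp(sw$coef[["rsA.dominant"]]), tolerance = 1e-10)
  }
  # multi-term profile: hand-computed eta difference
  prof2 <- tibble::tibble(sex = "male", age = 60, caucasian = 1,
                          diabetes = 1, hypertension = 1, rsA = 2, rsB = 2)
  r2 <- profile_odds_ratios(sw, prof2, ref)
  eta <- 0
  for (nm in names(sw$coef)) {
    val <- switch(nm,
      "diabetes" = 1, "hypertension" = 1,
      "rsA.dominant" = 1, "rsB.recessive" = 1,
      "rsB.recessive:hypertension" = 1,
      "rsA.dominant:hypertension" = 1,
      "rsA.dominant:rsB.recessive" = 1,
      0)
    eta <- eta + val * sw$coef[[nm]]
  }
  expect_equal(r2$or, exp(eta), tolerance = 1e-10)
  expect_error(profile_odds_ratios(sw, dplyr::mutate(ref, sex = "other"),
                                   ref), "unknown level")
})
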