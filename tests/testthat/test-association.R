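test_that("inheritance encodings satisfy their algebraic identities", {
  d <- c(0, 1, 2)
  expect_equal(drop(encode_genotype(d, "dominant")), c(0, 1, 1))
  expect_equal(drop(encode_genotype(d, "recessive")), c(0, 0, 1))
  expect_equal(drop(encode_genotype(d, "overdominant")), c(0, 1, 0))
  expect_equal(drop(encode_genotype(d, "additive")), c(0, 1, 2))
  expect_equal(unname(encode_genotype(d, "codominant")),
               cbind(c(0, 1, 0), c(0, 0, 1)))
  # additive = dominant + recessive; overdominant = dominant - recessive
  expect_equal(encode_genotype(d, "dominant") + encode_genotype(d, "recessive"),
               encode_genotype(d, "additive"), ignore_attr = TRUE)
  expect_equal(encode_genotype(d, "dominant") - encode_genotype(d, "recessive"),
               encode_genotype(d, "overdominant"), ignore_attr = TRUE)
  # missing propagates
  expect_true(all(is.na(encode_genotype(NA, "codominant"))))
})

test_that("single-binary-predictor logistic MLE equals the 2x2 log odds ratio", {
  # hypertension counts: controls 361 no / 198 yes; cases 218 no / 2227 yes
  d <- data.frame(outcome = rep(c(0, 0, 1, 1), c(361, 198, 218, 2227)),
                  x = rep(c(0, 1, 0, 1), c(361, 198, 218, 2227)))
  fit <- fit_logistic(outcome ~ x, d)
  o22 <- odds_ratio_2x2(361, 198, 218, 2227)
  expect_equal(exp(fit$coefficients[["x"]]), o22$or, tolerance = 1e-6)
  expect_equal(round(o22$or, 2), 18.63)
  # Wald CI from the fit equals the 2x2 closed form
  td <- tidy(fit)
  expect_equal(td$or_low[td$term == "x"], o22$or_low, tolerance = 1e-6)
  expect_equal(td$or_high[td$term == "x"], o22$or_high, tolerance = 1e-6)
})

test_that("intercept-only fit at 50% cases has intercept zero", {
  d <- data.frame(outcome = rep(c(0, 1), 25))
  fit <- fit_logistic(outcome ~ 1, d)
  expect_equal(fit$coefficients[["(Intercept)"]], 0, tolerance = 1e-10)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("logistic MLE matches a grid-search maximizer on a toy dataset", {
  d <- data.frame(outcome = c(0, 0, 1, 0, 1, 1, 1, 0),
                  x = c(0, 1, 1, 2, 2, 0, 1, 0))
  fit <- fit_logistic(outcome ~ x, d)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * d$x)
    sum(d$outcome * log(p) + (1 - d$outcome) * log(1 - p))
  }
  # coarse-to-fine grid search over (b0, b1)
  centre <- c(0, 0); width <- 8
  for (pass in 1:6) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    lls <- mapply(ll, grid$b0, grid$b1)
    centre <- unlist(grid[which.max(lls), ])
    width <- width / 8
  }
  expect_equal(fit$coefficients[["(Intercept)"]], centre[["b0"]],
               tolerance = 1e-4)
  expect_equal(fit$coefficients[["x"]], centre[["b1"]], tolerance = 1e-4)
  expect_equal(fit$loglik, ll(centre[["b0"]], centre[["b1"]]),
               tolerance = 1e-6)
})

test_that("degenerate fits are rejected or flagged", {
  d <- data.frame(outcome = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(outcome ~ x, d), "single value")
  d2 <- data.frame(outcome = rep(c(0, 1), 10), x = rnorm(20))
  d2$y <- d2$x
  expect_error(fit_logistic(outcome ~ x + y, d2), "aliased")
  # complete separation flagged, not fatal
  d3 <- data.frame(outcome = rep(c(0, 1), each = 10),
                   x = rep(c(0, 1), each = 10))
  expect_warning(f3 <- fit_logistic(outcome ~ x, d3), "separation")
  expect_true(f3$separation)
})

test_that("AIC model selection identifies a pure heterozygote effect", {
  # dosage-1 carriers at elevated risk: overdominant should win most often
  wins <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    sim <- sim_fixture(4000 + i, n = 3000, snp_specs = tibble::tibble(
      snp_id = "rs1", maf = 0.4, model = "overdominant", log_or = log(1.7),
      interaction_with = NA_character_, interaction_log_or = NA_real_))
    sel <- select_inheritance(sim$gm, sim$pheno, "rs1",
                              covariates = c("sex", "age"))
    expect_equal(sel$aic_table$model[which.min(sel$aic_table$AIC)],
                 sel$model)
    if (sel$model == "overdominant") wins <- wins + 1
  }
  expect_gt(wins / n_rep, 0.5)
})

test_that("codominant log-likelihood dominates every nested encoding", {
  sim <- sim_fixture(99, n = 800, snp_specs = tibble::tibble(
    snp_id = "rs1", maf = 0.3, model = "additive", log_or = log(1.4),
    interaction_with = NA_character_, interaction_log_or = NA_real_))
  sel <- select_inheritance(sim$gm, sim$pheno, "rs1",
                            covariates = c("sex", "age"))
  ll <- setNames(sel$aic_table$logLik, sel$aic_table$model)
  for (m in c("dominant", "recessive", "overdominant", "additive")) {
    expect_gte(ll[["codominant"]], ll[[m]] - 1e-8)
  }
})

test_that("monomorphic SNPs are reported untestable", {
  gm <- toy_gm(rep(1L, 20))
  ph <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                       outcome = rep(c(0L, 1L), 10))
  sel <- select_inheritance(gm, ph, "rs1", covariates = character(0))
  expect_false(sel$testable)
  scan <- assoc_scan(gm, ph, covariates = character(0), n_perm = 0)
  expect_equal(nrow(scan), 0)
  expect_match(attr(scan, "failures")[["rs1"]], "untestable")
})

test_that("likelihood-ratio p-values use the correct chi-square tail", {
  sim <- sim_fixture(55, n = 500)
  df <- sim$pheno
  df$dosage <- sim$gm$rs1
  full <- fit_logistic(outcome ~ dosage + sex + age, df)
  red <- fit_logistic(outcome ~ sex + age, df)
  lrt <- adjusted_lrt_p(full, red)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value,
               pchisq(2 * (full$loglik - red$loglik), 1, lower.tail = FALSE))
  # identical models: LR 0, p 1
  same <- adjusted_lrt_p(red, red)
  expect_equal(same$lr, 0); expect_equal(same$p_value, 1)
  # chi-square quantile check: Delta logLik 1.9207 at 1 df sits at p ~ 0.05
  expect_equal(pchisq(2 * 1.92073, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-4)
  # codominant term contributes 2 df
  df$het <- as.numeric(df$dosage == 1); df$hom <- as.numeric(df$dosage == 2)
  full2 <- fit_logistic(outcome ~ het + hom + sex + age, df)
  expect_equal(adjusted_lrt_p(full2, red)$df, 2)
  expect_error(adjusted_lrt_p(full, fit_logistic(outcome ~ sex, df[1:400, ])),
               "different subject sets")
})

test_that("permutation p is deterministic under a seed and bounded", {
  sim <- sim_fixture(21, n = 300)
  p1 <- permutation_p(sim$gm, sim$pheno, "rs1", "additive",
                      n_perm = 199, seed = 9)
  p2 <- permutation_p(sim$gm, sim$pheno, "rs1", "additive",
                      n_perm = 199, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)
  expect_lte(p1$p_value, 1)
  # constant encoded predictor: LR 0, p = 1
  gm0 <- toy_gm(rep(2L, 40))
  ph0 <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                        outcome = rep(c(0L, 1L), 20))
  p0 <- permutation_p(gm0, ph0, "rs1", "dominant", n_perm = 19, seed = 1)
  expect_equal(p0$p_value, 1)
  expect_error(permutation_p(sim$gm, sim$pheno, "rs1", "additive",
                             n_perm = 0, seed = 1), "n_perm")
})

test_that("permutation matches an explicit label-shuffling replay", {
  # oracle: replay the same hypergeometric stream but recompute each
  # permuted LR with an independent fitter (glm)
  sim <- sim_fixture(77, n = 120)
  d <- sim$gm$rs1; y <- sim$pheno$outcome
  res <- permutation_p(sim$gm, sim$pheno, "rs1", "additive",
                       n_perm = 19, seed = 31)
  lr_glm <- function(yy, xx) {
    f1 <- glm(yy ~ xx, family = binomial())
    f0 <- glm(yy ~ 1, family = binomial())
    max(0, 2 * as.numeric(logLik(f1) - logLik(f0)))
  }
  lr_obs <- lr_glm(y, d)
  expect_equal(res$lr_obs, lr_obs, tolerance = 1e-6)
  # replay: same seed, same class layout, same draws
  set.seed(31)
  cls <- factor(d, levels = sort(unique(d)))
  n_g <- as.vector(table(cls)); K <- sum(y)
  count <- 0
  for (b in 1:19) {
    k_star <- integer(length(n_g)); rem_K <- K; rem_N <- sum(n_g)
    for (g in seq_len(length(n_g) - 1)) {
      k_star[g] <- rhyper(1, rem_K, rem_N - rem_K, n_g[g])
      rem_K <- rem_K - k_star[g]; rem_N <- rem_N - n_g[g]
    }
    k_star[length(n_g)] <- rem_K
    yy <- unlist(lapply(seq_along(n_g), function(g)
      c(rep(1, k_star[g]), rep(0, n_g[g] - k_star[g]))))
    xx <- rep(sort(unique(d)), n_g)
    if (lr_glm(yy, xx) >= lr_obs - 1e-12) count <- count + 1
  }
  expect_equal(res$p_value, (1 + count) / 20, tolerance = 1e-12)
})

test_that("association scan returns one row per testable SNP", {
  sim <- sim_fixture(303, n = 600, snp_specs = tibble::tibble(
    snp_id = paste0("rs", 1:12), maf = seq(0.2, 0.45, length.out = 12),
    model = "dominant", log_or = c(log(2.2), rep(0, 11)),
    interaction_with = NA_character_, interaction_log_or = NA_real_))
  scan <- assoc_scan(sim$gm, sim$pheno, covariates = c("sex", "age"),
                     n_perm = 99, seed = 2)
  expect_s3_class(scan, "cg_assoc")
  expect_equal(nrow(scan), 12)
  expect_named(
    tidy(scan),
    c("snp_id", "gene", "model", "n_used", "or", "or_low", "or_high",
      "adjusted_p", "aic", "permutation_p"))
  expect_true(all(scan$or >= scan$or_low & scan$or <= scan$or_high))
  # permutation p only computed for SNPs passing alpha
  expect_true(all(is.na(scan$permutation_p[scan$adjusted_p >= 0.05])))
  expect_true(all(!is.na(scan$permutation_p[scan$adjusted_p < 0.05])))
  # the planted strong SNP is detected
  expect_lt(scan$adjusted_p[scan$snp_id == "rs1"], 0.05)
  g <- glance(scan)
  expect_equal(g$n_snps, 12)
  # empty panel: empty result, no error
  empty <- assoc_scan(sim$gm[, "subject_id", drop = FALSE], sim$pheno,
                      covariates = c("sex", "age"), n_perm = 0)
  expect_equal(nrow(empty), 0)
})

test_that("crude 2x2 odds ratios reproduce closed-form values", {
  expect_equal(round(odds_ratio_2x2(499, 60, 1824, 621)$or, 2), 2.83)
  r <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_equal(r$or_low * r$or_high, 1, tolerance = 1e-12)  # symmetric about 1
  expect_false(odds_ratio_2x2(0, 5, 5, 5)$estimable)
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "negative")
})

test_that("baseline table reproduces crude ORs and test choices", {
  # sex counts: controls 298 M / 261 F; cases 1508 M / 937 F
  ph <- tibble::tibble(
    subject_id = as.character(1:3004),
    outcome = rep(c(0L, 1L), c(559, 2445)),
    sex = factor(c(rep("male", 298), rep("female", 261),
                   rep("male", 1508), rep("female", 937)),
                 levels = c("male", "female")),
    age = rnorm(3004, 57, 12)
  )
  bt <- baseline_table(ph)
  fem <- bt[bt$variable == "sex" & bt$level == "female", ]
  expect_equal(round(fem$or, 2), 0.71)
  expect_equal(round(fem$or_low, 2), 0.59)
  expect_equal(round(fem$or_high, 2), 0.85)
  expect_equal(bt$p_value[bt$variable == "sex" & bt$level == "male"],
               fisher.test(table(ph$sex, ph$outcome))$p.value)
  # identical distributions: Fisher p = 1
  ph2 <- tibble::tibble(subject_id = as.character(1:40),
                        outcome = rep(c(0L, 1L), each = 20),
                        sex = factor(rep(c("male", "female"), 20),
                                     levels = c("male", "female")))
  bt2 <- baseline_table(ph2, quantitative = character(0))
  expect_equal(bt2$p_value[1], 1)
})

test_that("Mann-Whitney U agrees with exhaustive rank enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  # oracle: all C(6,3) = 20 assignments of ranks to group 1
  ranks <- 1:6
  combos <- combn(6, 3)
  u_stats <- apply(combos, 2, function(ix) sum(ranks[ix]) - 3 * 4 / 2)
  u_obs <- sum(rank(c(x, y))[1:3]) - 3 * 4 / 2
  expect_equal(u_obs, 0)
  p_one_sided <- mean(u_stats <= u_obs)
  expect_equal(p_one_sided, 0.05)
  expect_equal(wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value,
               p_one_sided)
})

test_that("adjusted LRT p-values are uniform under the null", {
  set.seed(88)
  n_rep <- 400
  pvals <- numeric(n_rep)
  base <- sim_fixture(1, n = 400)
  for (i in seq_len(n_rep)) {
    d <- base$pheno
    d$dosage <- rbinom(400, 2, 0.3)   # null SNP, redrawn each replicate
    full <- fit_logistic(outcome ~ dosage + sex + age, d)
    red <- fit_logistic(outcome ~ sex + age, d)
    pvals[i] <- adjusted_lrt_p(full, red)$p_value
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})
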