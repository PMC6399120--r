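# Assemble the per-SNP complete-case analysis frame: outcome, dosage and
# adjusting covariates. Association is complete-case per SNP, so each SNP
# uses every subject with data for that SNP and the covariates.
snp_frame <- function(gm, pheno, snp, covariates) {
  miss_cov <- setdiff(covariates, names(pheno))
  if (length(miss_cov)) {
    abort(paste0("covariate(s) absent from phenotypes: ",
                 paste(miss_cov, collapse = ", ")))
  }
  df <- tibble(outcome = pheno$outcome, dosage = gm[[snp]])
  for (cv in covariates) df[[cv]] <- pheno[[cv]]
  df[complete.cases(df), , drop = FALSE]
}

# Build the model frame for one inheritance model: encoded SNP columns with
# constant columns dropped and perfectly collinear duplicates collapsed
# (needed when only two genotype classes are observed).
encoded_terms <- function(dosage, model) {
  enc <- encode_genotype(dosage, model)
  keep <- apply(enc, 2, function(x) stats::var(x) > 0)
  enc <- enc[, keep, drop = FALSE]
  if (ncol(enc) == 2) {
    if (abs(stats::cor(enc[, 1], enc[, 2])) > 1 - 1e-12) {
      enc <- enc[, 1, drop = FALSE]
    }
  }
  enc
}

#' Select the best-fitting inheritance model for one SNP
#'
#' Fits all five inheritance codings (each adjusted for the same covariates,
#' on the identical complete-case subject set) and returns the model with
#' the lowest AIC. With only two observed genotype classes several codings
#' become indistinguishable; they collapse to the same fit and ties are
#' broken by the fixed order dominant < recessive < overdominant <
#' additive < codominant.
#'
#' @param gm A genotype matrix.
#' @param pheno A phenotype tibble.
#' @param snp SNP id.
#' @param covariates Character vector of adjusting covariate columns
#'   (default sex, age and Caucasian yes/no).
#' @return A list: `model` (chosen name), `aic_table` (per-model df, logLik,
#'   AIC), `fits` (the `cg_logit` fit per testable model), `data` (the
#'   complete-case frame) and `testable`.
#' @export
select_inheritance <- function(gm, pheno, snp,
                               covariates = c("sex", "age", "caucasian")) {
  df <- snp_frame(gm, pheno, snp, covariates)
  classes <- unique(df$dosage)
  if (length(classes) < 2) {
    return(list(model = NA_character_, aic_table = tibble(), fits = list(),
                data = df, testable = FALSE))
  }
  fits <- list()
  rows <- list()
  for (m in inheritance_models) {
    enc <- encoded_terms(df$dosage, m)
    if (ncol(enc) == 0) next
    dat <- bind_cols(df, as_tibble(enc))
    fml <- stats::reformulate(c(colnames(enc), covariates),
                              response = "outcome")
    fit <- fit_logistic(fml, dat)
    fits[[m]] <- fit
    rows[[m]] <- tibble(model = m, df = ncol(enc), logLik = fit$loglik,
                        AIC = fit$aic, converged = fit$converged)
  }
  aic_table <- bind_rows(rows)
  # canonical order already; which.min takes the first minimum on ties
  chosen <- aic_table$model[which.min(aic_table$AIC)]
  list(model = chosen, aic_table = aic_table, fits = fits, data = df,
       testable = TRUE)
}

#' Permutation p-value for a single-SNP likelihood-ratio statistic
#'
#' The observed statistic is `LR = 2 (logLik_SNP - logLik_null)` from the
#' unadjusted (no-covariate) logistic model under the given inheritance
#' coding. Case/control labels are then permuted uniformly; because the
#' encoded genotype takes at most three values, a label permutation is
#' equivalent to a multivariate-hypergeometric draw of the case count in
#' each genotype class, which is what is simulated. The p-value is
#' `(1 + #\{LR* >= LR_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams select_inheritance
#' @param model Inheritance model name.
#' @param n_perm Number of permutations (study-scale default 20,000).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @param method `"label"` (default) permutes outcome labels against the
#'   unadjusted SNP model; `"covariate"` permutes the genotype vector across
#'   subjects and recomputes the covariate-adjusted LR, preserving the
#'   covariate-outcome association.
#' @param covariates Adjusting covariates (used by `method = "covariate"`).
#' @return A list with `p_value`, `lr_obs` and `n_perm`.
#' @export
permutation_p <- function(gm, pheno, snp, model, n_perm = 20000, seed = NULL,
                          method = c("label", "covariate"),
                          covariates = c("sex", "age", "caucasian")) {
  method <- arg_match(method)
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (method == "covariate") {
    return(permutation_p_covariate(gm, pheno, snp, model, n_perm, covariates))
  }
  df <- tibble(outcome = pheno$outcome, dosage = gm[[snp]])
  df <- df[complete.cases(df), , drop = FALSE]
  enc <- encoded_terms(df$dosage, model)
  if (ncol(enc) == 0) {
    return(list(p_value = 1, lr_obs = 0, n_perm = n_perm))
  }
  # aggregate by genotype class
  cls <- interaction(as.data.frame(enc), drop = TRUE)
  n_g <- as.vector(table(cls))
  k_g <- as.vector(tapply(df$outcome, cls, sum))
  Xg <- cbind(1, unique_class_design(enc, cls))
  N <- sum(n_g); K <- sum(k_g)
  ll0 <- null_binom_loglik(K, N)
  lr_obs <- max(0, 2 * (irls_binom_loglik(Xg, k_g, n_g) - ll0))
  G <- length(n_g)
  count_ge <- 0L
  for (b in seq_len(n_perm)) {
    k_star <- rmvhyper(K, n_g)
    lr <- 2 * (irls_binom_loglik(Xg, k_star, n_g) - ll0)
    if (lr >= lr_obs - 1e-12) count_ge <- count_ge + 1L
  }
  list(p_value = (1 + count_ge) / (n_perm + 1), lr_obs = lr_obs,
       n_perm = n_perm)
}

# design matrix rows of the unique encoded classes, in the order of levels(cls)
unique_class_design <- function(enc, cls) {
  idx <- match(levels(cls), as.character(cls))
  enc[idx, , drop = FALSE]
}

# multivariate hypergeometric: allocate K cases among classes of sizes n_g
rmvhyper <- function(K, n_g) {
  G <- length(n_g)
  out <- integer(G)
  rem_K <- K
  rem_N <- sum(n_g)
  for (g in seq_len(G - 1)) {
    out[g] <- stats::rhyper(1, rem_K, rem_N - rem_K, n_g[g])
    rem_K <- rem_K - out[g]
    rem_N <- rem_N - n_g[g]
  }
  out[G] <- rem_K
  out
}

permutation_p_covariate <- function(gm, pheno, snp, model, n_perm,
                                    covariates) {
  df <- snp_frame(gm, pheno, snp, covariates)
  enc <- encoded_terms(df$dosage, model)
  if (ncol(enc) == 0) return(list(p_value = 1, lr_obs = 0, n_perm = n_perm))
  adj_lr <- function(dosage) {
    e <- encode_genotype(dosage, model)
    e <- e[, apply(e, 2, function(x) stats::var(x) > 0), drop = FALSE]
    if (ncol(e) == 0) return(0)
    dat <- bind_cols(df["outcome"], as_tibble(e), df[covariates])
    full <- fit_logistic(
      stats::reformulate(c(colnames(e), covariates), "outcome"), dat)
    red <- fit_logistic(stats::reformulate(covariates, "outcome"), dat)
    max(0, 2 * (full$loglik - red$loglik))
  }
  lr_obs <- adj_lr(df$dosage)
  lr_star <- vapply(seq_len(n_perm),
                    function(b) adj_lr(sample(df$dosage)), numeric(1))
  list(p_value = (1 + sum(lr_star >= lr_obs - 1e-12)) / (n_perm + 1),
       lr_obs = lr_obs, n_perm = n_perm)
}

#' Per-SNP association scan
#'
#' For every SNP: inheritance-model selection by AIC, odds ratio with Wald
#' 95% CI under the chosen coding (for codominant the reported OR is the
#' term with the larger absolute log-OR; both terms are kept in the detail
#' attribute), the covariate-adjusted likelihood-ratio p-value against the
#' covariates-only model on the same subjects, and — for SNPs passing
#' `alpha` — a permutation p-value. Analysis is complete-case per SNP.
#'
#' @inheritParams select_inheritance
#' @param alpha Significance threshold deciding which SNPs receive a
#'   permutation p-value.
#' @param n_perm Permutations per SNP (`0` disables permutation testing).
#' @param seed Base seed; SNP `i` uses `seed + i`.
#' @return A tibble of class `cg_assoc`, one row per testable SNP: `snp_id`,
#'   `gene`, `model`, `n_used`, `or`, `or_low`, `or_high`, `adjusted_p`,
#'   `aic`, `permutation_p`. Untestable SNPs are recorded in the
#'   `failures` attribute; per-model AIC tables in the `detail` attribute.
#' @export
assoc_scan <- function(gm, pheno, covariates = c("sex", "age", "caucasian"),
                       alpha = 0.05, n_perm = 20000, seed = 1) {
  al <- align_cohort(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  vinfo <- variants(gm)
  rows <- list(); detail <- list(); failures <- character(0)
  for (i in seq_along(snp_ids(gm))) {
    s <- snp_ids(gm)[i]
    res <- tryCatch(
      scan_one(gm, pheno, s, covariates, alpha, n_perm,
               seed = seed + i),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      failures <- c(failures, setNames(res, s))
      next
    }
    if (!res$testable) {
      failures <- c(failures, setNames("untestable (monomorphic)", s))
      next
    }
    rows[[s]] <- res$row
    detail[[s]] <- res$detail
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(snp_id = character(0), model = character(0),
           n_used = integer(0), or = double(0), or_low = double(0),
           or_high = double(0), adjusted_p = double(0), aic = double(0),
           permutation_p = double(0))
  out <- left_join(out, vinfo[c("snp_id", "gene")], by = "snp_id") %>%
    select("snp_id", "gene", dplyr::everything())
  structure(out, detail = detail, failures = failures,
            covariates = covariates, alpha = alpha,
            class = c("cg_assoc", class(out)))
}

scan_one <- function(gm, pheno, s, covariates, alpha, n_perm, seed) {
  sel <- select_inheritance(gm, pheno, s, covariates)
  if (!sel$testable) return(list(testable = FALSE))
  fit <- sel$fits[[sel$model]]
  red <- fit_logistic(stats::reformulate(covariates, "outcome"), sel$data)
  lrt <- adjusted_lrt_p(fit, red)
  co <- tidy(fit)
  enc_names <- c(inheritance_models, "codominant_het", "codominant_hom")
  snp_terms <- co %>% filter(term %in% enc_names)
  rep_term <- snp_terms[which.max(abs(log(snp_terms$or))), ]
  perm <- NA_real_
  if (n_perm > 0 && lrt$p_value < alpha) {
    perm <- permutation_p(gm, pheno, s, sel$model, n_perm = n_perm,
                          seed = seed)$p_value
  }
  list(
    testable = TRUE,
    row = tibble(snp_id = s, model = sel$model, n_used = fit$n_used,
                 or = rep_term$or, or_low = rep_term$or_low,
                 or_high = rep_term$or_high,
                 adjusted_p = lrt$p_value, aic = fit$aic,
                 permutation_p = perm),
    detail = list(aic_table = sel$aic_table, snp_terms = snp_terms)
  )
}

#' @export
print.cg_assoc <- function(x, ...) {
  cat("<cg_assoc> single-SNP association scan:", nrow(x), "SNP(s)\n")
  NextMethod()
}

#' @describeIn assoc_scan The scan result is already tidy; returns it as a
#'   plain tibble.
#' @param x A `cg_assoc` object.
#' @param ... Unused.
#' @export
tidy.cg_assoc <- function(x, ...) {
  as_tibble(unclass_cg(x))
}

#' @describeIn assoc_scan One-row summary: SNPs tested, significant at
#'   `alpha`, failures.
#' @export
glance.cg_assoc <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(n_snps = nrow(x),
         n_significant = sum(x$adjusted_p < alpha, na.rm = TRUE),
         n_failed = length(attr(x, "failures")))
}

unclass_cg <- function(x) {
  class(x) <- setdiff(class(x), c("cg_assoc", "cg_ld", "cg_genotypes"))
  attr(x, "detail") <- NULL; attr(x, "failures") <- NULL
  attr(x, "variants") <- NULL
  x
}

#' Baseline case-control heterogeneity table
#'
#' Summarises demographic and clinical covariates by case/control arm.
#' Qualitative variables get counts, percentages, a crude odds ratio per
#' non-reference level and a Fisher exact p-value; quantitative variables
#' get mean (SD) per arm and a two-sided Mann-Whitney U p-value (normal
#' approximation with tie correction).
#'
#' @param pheno A phenotype tibble with `outcome` plus covariates.
#' @param qualitative,quantitative Column names to summarise; defaults pick
#'   the standard covariate set present in `pheno`.
#' @return A tibble with one row per variable level (qualitative) or per
#'   variable (quantitative).
#' @export
baseline_table <- function(pheno,
                           qualitative = intersect(
                             c("sex", "caucasian", "smoking", "diabetes",
                               "hypertension"), names(pheno)),
                           quantitative = intersect("age", names(pheno))) {
  stopifnot("outcome" %in% names(pheno))
  ctrl <- pheno$outcome == 0
  rows <- list()
  for (v in qualitative) {
    x <- pheno[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
    tab <- table(factor(x, levels = lv), pheno$outcome)
    p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
    for (j in seq_along(lv)) {
      orr <- if (j == 1) list(or = 1, or_low = NA_real_, or_high = NA_real_,
                              estimable = TRUE)
      else odds_ratio_2x2(tab[1, "0"], tab[j, "0"], tab[1, "1"], tab[j, "1"])
      rows[[paste(v, lv[j])]] <- tibble(
        variable = v, level = as.character(lv[j]), type = "qualitative",
        n_controls = tab[j, "0"], pct_controls = tab[j, "0"] / sum(ctrl) * 100,
        n_cases = tab[j, "1"], pct_cases = tab[j, "1"] / sum(!ctrl) * 100,
        mean_controls = NA_real_, sd_controls = NA_real_,
        mean_cases = NA_real_, sd_cases = NA_real_,
        or = orr$or, or_low = orr$or_low, or_high = orr$or_high,
        p_value = if (j == 1) p else NA_real_
      )
    }
  }
  for (v in quantitative) {
    x <- as.numeric(pheno[[v]])
    p <- tryCatch(
      wilcox.test(x[!ctrl], x[ctrl], exact = FALSE, correct = FALSE)$p.value,
      error = function(e) NA_real_)
    rows[[v]] <- tibble(
      variable = v, level = NA_character_, type = "quantitative",
      n_controls = sum(ctrl & !is.na(x)),
      pct_controls = NA_real_,
      n_cases = sum(!ctrl & !is.na(x)), pct_cases = NA_real_,
      mean_controls = mean(x[ctrl], na.rm = TRUE),
      sd_controls = sd(x[ctrl], na.rm = TRUE),
      mean_cases = mean(x[!ctrl], na.rm = TRUE),
      sd_cases = sd(x[!ctrl], na.rm = TRUE),
      or = NA_real_, or_low = NA_real_, or_high = NA_real_, p_value = p
    )
  }
  bind_rows(rows)
}
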