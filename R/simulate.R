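#' Simulation configuration for a synthetic case-control cohort
#'
#' Bundles every parameter of the cohort generator. Genotypes are drawn
#' under Hardy-Weinberg proportions (linked pairs from a four-haplotype
#' pool), covariates from stated marginal prevalences, and the binary
#' outcome from a logistic liability: linear predictor = intercept +
#' covariate effects + per-SNP effects under each SNP's inheritance coding
#' + interaction terms, with the intercept solved numerically so the
#' realized case fraction matches the target. Missingness is applied last.
#'
#' @param n_subjects Cohort size.
#' @param case_fraction Target case share of the cohort.
#' @param seed Integer seed (mandatory; all generation is reproducible).
#' @param covariates List of marginal covariate parameters:
#'   `male_fraction`, `age_mean`, `age_sd`, `noncaucasian_fraction`,
#'   `diabetes_prevalence`, `hypertension_prevalence`,
#'   `smoking_prevalences` (named never/former/current).
#' @param covariate_effects Named log-odds-ratio list: `female`, `age` (per
#'   year), `noncaucasian`, `diabetes`, `hypertension`, `smoking_current`,
#'   `smoking_never` (former is reference).
#' @param snp_specs Tibble with columns `snp_id`, `maf`, `model`
#'   (inheritance coding of the true effect), `log_or`,
#'   `interaction_with` (covariate name or `NA`), `interaction_log_or`.
#' @param ld_pair_specs Tibble with columns `snp1`, `snp2`, `h11`, `h10`,
#'   `h01`, `h00` (haplotype frequencies, summing to 1); listed SNPs are
#'   drawn jointly instead of independently.
#' @param missingness Tibble with columns `snp_id`, `random_rate`, `block`
#'   (label or `NA`); SNPs sharing a block label lose the same random
#'   subject subset.
#' @param block_rates Named vector: fraction of subjects missing per block.
#' @param control_missing_snps SNPs set fully missing in controls
#'   (emulating assay panels never run on the control arm).
#' @return A validated list of class `cg_simconfig`.
#' @export
sim_config <- function(n_subjects, case_fraction, seed,
                       covariates = default_covariate_params(),
                       covariate_effects = default_covariate_effects(),
                       snp_specs = tibble(snp_id = character(0),
                                          maf = double(0),
                                          model = character(0),
                                          log_or = double(0),
                                          interaction_with = character(0),
                                          interaction_log_or = double(0)),
                       ld_pair_specs = NULL,
                       missingness = NULL,
                       block_rates = c(),
                       control_missing_snps = character(0)) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  stopifnot(n_subjects >= 1, case_fraction > 0, case_fraction < 1)
  snp_specs <- as_tibble(snp_specs)
  if (nrow(snp_specs)) {
    if (any(snp_specs$maf <= 0 | snp_specs$maf > 0.5)) {
      abort("snp_specs$maf must lie in (0, 0.5]")
    }
    if (!all(snp_specs$model %in% inheritance_models)) {
      abort("unknown inheritance model in snp_specs")
    }
  }
  if (!is.null(ld_pair_specs)) {
    ld_pair_specs <- as_tibble(ld_pair_specs)
    h <- as.matrix(ld_pair_specs[c("h11", "h10", "h01", "h00")])
    if (any(h < 0)) abort("negative haplotype frequency")
    if (any(abs(rowSums(h) - 1) > 1e-8)) {
      abort("haplotype frequencies must sum to 1")
    }
  }
  structure(
    list(n_subjects = n_subjects, case_fraction = case_fraction, seed = seed,
         covariates = covariates, covariate_effects = covariate_effects,
         snp_specs = snp_specs, ld_pair_specs = ld_pair_specs,
         missingness = missingness, block_rates = block_rates,
         control_missing_snps = control_missing_snps),
    class = "cg_simconfig"
  )
}

default_covariate_params <- function() {
  list(male_fraction = 0.601, age_mean = 57.34, age_sd = 12.6,
       noncaucasian_fraction = 0.031, diabetes_prevalence = 0.226,
       hypertension_prevalence = 0.807,
       smoking_prevalences = c(never = 0.431, former = 0.369,
                               current = 0.199))
}

default_covariate_effects <- function() {
  list(female = log(0.71), age = 0.02, noncaucasian = log(1.95),
       diabetes = log(2.83), hypertension = log(18.63),
       smoking_current = log(1.16), smoking_never = log(1.25))
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' @param maf Effect-allele frequency in `(0, 0.5]`.
#' @param n Number of subjects.
#' @return Integer dosage vector drawn with probabilities
#'   `((1-p)^2, 2p(1-p), p^2)` — a binomial draw of two allele copies.
#' @export
simulate_genotypes <- function(maf, n) {
  if (maf <= 0 || maf > 0.5) abort("maf must lie in (0, 0.5]")
  rbinom(n, 2L, maf)
}

#' Simulate a pair of SNPs in linkage disequilibrium
#'
#' Each subject receives two haplotypes drawn independently from a
#' four-haplotype pool; per-locus dosages are the allele counts.
#'
#' @param hap_freqs Frequencies of haplotypes (1,1), (1,0), (0,1), (0,0)
#'   where 1 marks the effect allele; must sum to 1.
#' @param n Number of subjects.
#' @return A list of two integer dosage vectors `d1`, `d2`.
#' @export
simulate_ld_pair <- function(hap_freqs, n) {
  if (any(hap_freqs < 0)) abort("negative haplotype frequency")
  if (abs(sum(hap_freqs) - 1) > 1e-8) abort("frequencies must sum to 1")
  hap <- matrix(sample.int(4L, 2 * n, replace = TRUE, prob = hap_freqs),
                ncol = 2)
  a1 <- c(1L, 1L, 0L, 0L)[hap]  # locus-1 allele per haplotype
  b1 <- c(1L, 0L, 1L, 0L)[hap]
  dim(a1) <- dim(b1) <- dim(hap)
  list(d1 = rowSums(a1), d2 = rowSums(b1))
}

#' Simulate a full case-control cohort
#'
#' @param cfg A [sim_config()].
#' @return A list: `gm` (genotype matrix), `pheno` (phenotype tibble),
#'   `truth` (the generating parameters: SNP effects, haplotype
#'   frequencies, covariate effects and the solved intercept).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cg_simconfig"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  cv <- cfg$covariates
  ce <- cfg$covariate_effects
  pheno <- tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = factor(ifelse(runif(n) < cv$male_fraction, "male", "female"),
                 levels = c("male", "female")),
    age = rnorm(n, cv$age_mean, cv$age_sd),
    caucasian = as.integer(runif(n) >= cv$noncaucasian_fraction),
    diabetes = rbinom(n, 1L, cv$diabetes_prevalence),
    hypertension = rbinom(n, 1L, cv$hypertension_prevalence),
    smoking = factor(sample(names(cv$smoking_prevalences), n, replace = TRUE,
                            prob = cv$smoking_prevalences),
                     levels = c("never", "former", "current"))
  )
  pheno$age <- pmax(pheno$age, 18)

  # genotypes: LD pairs jointly, remaining SNPs independently
  calls <- tibble(subject_id = pheno$subject_id)
  paired <- character(0)
  hap_truth <- NULL
  if (!is.null(cfg$ld_pair_specs) && nrow(cfg$ld_pair_specs)) {
    for (i in seq_len(nrow(cfg$ld_pair_specs))) {
      pr <- cfg$ld_pair_specs[i, ]
      d <- simulate_ld_pair(unlist(pr[c("h11", "h10", "h01", "h00")]), n)
      calls[[pr$snp1]] <- d$d1
      calls[[pr$snp2]] <- d$d2
      paired <- c(paired, pr$snp1, pr$snp2)
    }
    hap_truth <- cfg$ld_pair_specs
  }
  for (i in seq_len(nrow(cfg$snp_specs))) {
    s <- cfg$snp_specs$snp_id[i]
    if (s %in% paired) next
    calls[[s]] <- simulate_genotypes(cfg$snp_specs$maf[i], n)
  }

  # liability
  eta <- numeric(n)
  eta <- eta + (pheno$sex == "female") * ce$female +
    (pheno$age - cv$age_mean) * ce$age +
    (pheno$caucasian == 0) * ce$noncaucasian +
    pheno$diabetes * ce$diabetes +
    pheno$hypertension * ce$hypertension +
    (pheno$smoking == "current") * ce$smoking_current +
    (pheno$smoking == "never") * ce$smoking_never
  for (i in seq_len(nrow(cfg$snp_specs))) {
    sp <- cfg$snp_specs[i, ]
    enc <- encode_genotype(calls[[sp$snp_id]], sp$model)
    term <- if (ncol(enc) == 1) enc[, 1] else enc[, 2]  # codominant: hom
    eta <- eta + term * sp$log_or
    if (!is.na(sp$interaction_with) && nzchar(sp$interaction_with)) {
      partner <- as.numeric(pheno[[sp$interaction_with]])
      eta <- eta + term * partner * sp$interaction_log_or
    }
  }
  f <- function(b0) mean(plogis(b0 + eta)) - cfg$case_fraction
  intercept <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  pheno$outcome <- rbinom(n, 1L, plogis(intercept + eta))
  if (length(unique(pheno$outcome)) < 2) {
    abort(paste0("simulated outcome is single-class (case fraction target ",
                 cfg$case_fraction, "); adjust the configuration"))
  }
  pheno <- pheno[c("subject_id", "outcome", "sex", "age", "caucasian",
                   "diabetes", "hypertension", "smoking")]

  # missingness: per-SNP random, shared blocks, arm-specific total
  if (!is.null(cfg$missingness) && nrow(cfg$missingness)) {
    blocks <- unique(na.omit(cfg$missingness$block))
    block_rows <- list()
    for (b in blocks) {
      rate <- cfg$block_rates[[b]]
      if (is.null(rate)) abort(paste0("no block_rate for block ", b))
      block_rows[[b]] <- runif(n) < rate
    }
    for (i in seq_len(nrow(cfg$missingness))) {
      ms <- cfg$missingness[i, ]
      if (!ms$snp_id %in% names(calls)) next
      drop_mask <- runif(n) < ms$random_rate
      if (!is.na(ms$block)) drop_mask <- drop_mask | block_rows[[ms$block]]
      calls[[ms$snp_id]][drop_mask] <- NA_integer_
    }
  }
  for (s in cfg$control_missing_snps) {
    if (s %in% names(calls)) calls[[s]][pheno$outcome == 0] <- NA_integer_
  }

  gm <- genotype_matrix(calls, tibble(snp_id = setdiff(names(calls),
                                                       "subject_id")))
  truth <- list(intercept = intercept, snp_specs = cfg$snp_specs,
                ld_pair_specs = hap_truth,
                covariate_effects = ce, seed = cfg$seed)
  list(gm = gm, pheno = pheno, truth = truth)
}

#' Template configuration emulating a large renal case-control study
#'
#' A shipped configuration approximating the cohort structure this package
#' is designed around: 3,004 subjects at 81.4% case share, covariate
#' prevalences and crude effect sizes of a typical nephrology case-control
#' baseline table, a 79-SNP candidate panel of which 12 carry effects
#' (odds ratios 1.22-1.74 under mixed inheritance models), three linked
#' pairs at D' = 0.8, one SNP x hypertension interaction (OR 2.68), ~6%
#' random missingness on most effect SNPs, a shared ~46% missing block on
#' two SNPs, and 13 panel SNPs never genotyped in controls. SNP minor
#' allele frequencies are synthetic stand-ins (plausible candidate-gene
#' values), fixed here once.
#'
#' @param seed Integer seed stored in the config.
#' @param n_subjects Cohort size (default 3004).
#' @return A [sim_config()].
#' @export
study_template_config <- function(seed, n_subjects = 3004) {
  effect <- tibble(
    snp_id = c("rs1126616", "rs35068180", "rs2238135", "rs3102735",
               "rs1800247", "rs385564", "rs679620", "rs2248359",
               "rs1564858", "rs4236", "rs9138", "rs731236"),
    maf = c(0.35, 0.40, 0.20, 0.25, 0.40, 0.30, 0.40, 0.30,
            0.25, 0.35, 0.35, 0.35),
    model = c("dominant", "overdominant", "recessive", "overdominant",
              "overdominant", "dominant", "overdominant", "recessive",
              "dominant", "dominant", "dominant", "dominant"),
    log_or = log(c(1.31, 1.29, 1.74, 1.32, 1.28, 1.27, 1.25, 1.4,
                   1.32, 1.23, 1.22, 1.22)),
    interaction_with = c(NA, NA, NA, NA, NA, NA, NA, "hypertension",
                         NA, NA, NA, NA),
    interaction_log_or = c(NA, NA, NA, NA, NA, NA, NA, log(2.68),
                           NA, NA, NA, NA)
  )
  n_null <- 79 - 12 - 13
  null_snps <- tibble(
    snp_id = sprintf("rsnull%02d", seq_len(n_null)),
    maf = round(seq(0.10, 0.50, length.out = n_null), 3),
    model = "additive", log_or = 0,
    interaction_with = NA_character_, interaction_log_or = NA_real_
  )
  ctrl_missing <- tibble(
    snp_id = sprintf("rscm%02d", seq_len(13)),
    maf = round(seq(0.15, 0.45, length.out = 13), 3),
    model = "additive", log_or = 0,
    interaction_with = NA_character_, interaction_log_or = NA_real_
  )
  snp_specs <- bind_rows(effect, null_snps, ctrl_missing)
  ld_pairs <- bind_rows(
    hap_freqs_for("rs679620", "rs35068180", 0.40, 0.40, d_prime = 0.8),
    hap_freqs_for("rs9138", "rs1126616", 0.35, 0.35, d_prime = 0.8),
    hap_freqs_for("rs3102735", "rs1564858", 0.25, 0.25, d_prime = 0.8)
  )
  missingness <- bind_rows(
    tibble(snp_id = c("rs35068180", "rs4236", "rs731236", "rs9138",
                      "rs1126616", "rs2238135", "rs679620", "rs1800247",
                      "rs385564", "rs3102735"),
           random_rate = c(0.062, 0.062, 0.062, 0.062, 0.063, 0.063,
                           0.063, 0.064, 0.064, 0.062),
           block = NA_character_),
    tibble(snp_id = c("rs2248359", "rs1564858"),
           random_rate = 0.005, block = "late_chip"),
    tibble(snp_id = null_snps$snp_id, random_rate = 0.02,
           block = NA_character_)
  )
  sim_config(
    n_subjects = n_subjects, case_fraction = 0.814, seed = seed,
    snp_specs = snp_specs, ld_pair_specs = ld_pairs,
    missingness = missingness, block_rates = c(late_chip = 0.46),
    control_missing_snps = ctrl_missing$snp_id
  )
}

# haplotype frequencies for two loci with effect-allele frequencies pA, pB
# and a target D' (positive association of effect alleles)
hap_freqs_for <- function(snp1, snp2, pA, pB, d_prime) {
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- d_prime * dmax
  tibble(snp1 = snp1, snp2 = snp2,
         h11 = pA * pB + D, h10 = pA * (1 - pB) - D,
         h01 = (1 - pA) * pB - D, h00 = (1 - pA) * (1 - pB) + D)
}
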