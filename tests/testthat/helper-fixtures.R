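# Shared in-code fixtures: tiny genotype/phenotype tables and small
# simulated cohorts used across test files.

toy_gm <- function(dosages, snp = "rs1") {
  genotype_matrix(
    tibble::tibble(subject_id = sprintf("s%02d", seq_along(dosages)),
                   !!snp := as.integer(dosages))
  )
}

# cohort with one SNP and a binary outcome, no covariates
toy_cohort <- function(dosages, outcome) {
  n <- length(dosages)
  list(
    gm = toy_gm(dosages),
    pheno = tibble::tibble(subject_id = sprintf("s%02d", seq_len(n)),
                           outcome = as.integer(outcome))
  )
}

# simulated cohort with standard covariates and configurable SNP effects
sim_fixture <- function(seed, n = 1000, snp_specs = NULL, ...,
                        case_fraction = 0.5) {
  if (is.null(snp_specs)) {
    snp_specs <- tibble::tibble(
      snp_id = "rs1", maf = 0.3, model = "dominant", log_or = 0,
      interaction_with = NA_character_, interaction_log_or = NA_real_
    )
  }
  simulate_cohort(sim_config(n, case_fraction, seed = seed,
                             snp_specs = snp_specs, ...))
}

# full adjusting set matching the generator's covariate model
all_covariates <- c("sex", "age", "caucasian", "diabetes", "hypertension",
                    "smoking")
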