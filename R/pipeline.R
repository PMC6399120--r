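#' Write a genotype matrix as VCF
#'
#' Minimal VCF 4.2 writer (GT field only) for interchange and fixtures.
#' Alleles default to A (ref) / C (alt) when the panel has no allele
#' annotation; positions are the panel index unless a `position` column is
#' present in [variants()].
#'
#' @param gm A genotype matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  v <- variants(gm)
  ref <- ifelse(is.na(v$allele_ref), "A", v$allele_ref)
  alt <- ifelse(is.na(v$allele_alt), "C", v$allele_alt)
  chrom <- ifelse(is.na(v$chromosome), "1", v$chromosome)
  pos <- if ("position" %in% names(v)) v$position else seq_len(nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$subject_id), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(v))) {
    d <- gm[[v$snp_id[i]]]
    if (v$effect_allele[i] == "ref") d <- 2L - d
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(chrom[i], pos[i], v$snp_id[i], ref[i], alt[i], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Run the full association pipeline
#'
#' Orchestrates quality control, the baseline heterogeneity table, the
#' single-SNP association scan, linkage-disequilibrium assessment of the
#' significant SNPs, the exhaustive multivariate subset search, stepwise
#' interaction modelling with the clinical risk factors, and ROC comparison
#' of the SNP, clinical and combined risk models.
#'
#' @param gm A genotype matrix.
#' @param pheno A phenotype tibble.
#' @param covariates Adjusting covariates (never dropped).
#' @param clinical Clinical risk factors for the interaction and ROC
#'   stages.
#' @param alpha Significance threshold.
#' @param n_perm Permutations per significant SNP (study-scale default
#'   20,000).
#' @param n_boot Bootstrap resamples for the ROC stage (default 1,000).
#' @param seed Global seed; each resampling stage derives its own stream
#'   from it so stages are independently reproducible.
#' @param hwe_alpha,max_variant_missing,max_sample_missing QC thresholds
#'   (see [apply_qc_filters()]).
#' @param max_search_snps Cap on the exhaustive enumeration.
#' @return A results bundle (named list) with elements `qc_report`,
#'   `baseline`, `association`, `ld`, `haplotypes`, `search`,
#'   `final_model`, `roc` and `provenance`; pass to [write_results()].
#' @export
run_pipeline <- function(gm, pheno,
                         covariates = c("sex", "age", "caucasian"),
                         clinical = c("diabetes", "hypertension"),
                         alpha = 0.05, n_perm = 20000, n_boot = 1000,
                         seed = 1, hwe_alpha = 0.05,
                         max_variant_missing = 0.5,
                         max_sample_missing = 0.5,
                         max_search_snps = 20) {
  qc <- apply_qc_filters(gm, pheno,
                         max_variant_missing = max_variant_missing,
                         max_sample_missing = max_sample_missing,
                         hwe_alpha = hwe_alpha)
  baseline <- baseline_table(qc$pheno)
  assoc <- assoc_scan(qc$gm, qc$pheno, covariates = covariates,
                      alpha = alpha, n_perm = n_perm, seed = seed)
  sig <- assoc[!is.na(assoc$adjusted_p) & assoc$adjusted_p < alpha, ]
  ld <- NULL; haplo <- NULL; search <- NULL; final <- NULL; roc <- NULL
  if (nrow(sig) >= 2) {
    ld <- ld_scan(qc$gm, sig$snp_id)
    in_ld <- ld[!is.na(ld$in_ld) & ld$in_ld, ]
    if (nrow(in_ld)) haplo <- haplotype_assessment(qc$gm, in_ld)
  }
  if (nrow(sig) >= 1 && nrow(sig) <= max_search_snps) {
    snp_terms <- sig[c("snp_id", "model")]
    search <- exhaustive_search(qc$gm, qc$pheno, snp_terms,
                                covariates = covariates,
                                max_snps = max_search_snps)
    final <- stepwise_interactions(qc$gm, qc$pheno, search$chosen_subset,
                                   snp_terms, covariates = covariates,
                                   clinical = clinical)
    dat <- final$data
    snp_cols <- intersect(snp_terms$snp_id, names(dat))
    specs <- list(
      snps = stats::reformulate(c(make_snp_formula_terms(snp_terms,
                                                         snp_cols, dat),
                                  covariates), "outcome"),
      clinical = stats::reformulate(c(clinical, covariates), "outcome"),
      combined = final
    )
    roc <- compare_models(dat, specs, n_boot = n_boot, seed = seed + 1000)
  }
  list(
    qc_report = qc$report, baseline = baseline, association = assoc,
    ld = ld, haplotypes = haplo, search = search, final_model = final,
    roc = roc,
    provenance = list(seed = seed, alpha = alpha, n_perm = n_perm,
                      n_boot = n_boot, covariates = covariates,
                      clinical = clinical,
                      package_version = as.character(
                        utils::packageVersion("cgassoc")))
  )
}

# formula terms encoding each SNP under its chosen inheritance model, for
# scoring the SNP-only model on a data frame that holds raw dosages
make_snp_formula_terms <- function(snp_terms, snp_cols, dat) {
  map_chr(snp_cols, function(s) {
    m <- snp_terms$model[snp_terms$snp_id == s]
    switch(m,
      dominant = paste0("I(", s, " >= 1)"),
      recessive = paste0("I(", s, " == 2)"),
      overdominant = paste0("I(", s, " == 1)"),
      additive = s,
      codominant = paste0("factor(", s, ")")
    )
  })
}
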