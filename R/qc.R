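#' Genotype counts for one SNP
#'
#' Tabulates effect-allele dosages 0/1/2 for a SNP over an optional subject
#' subset; missing calls are excluded.
#'
#' @param gm A genotype matrix.
#' @param snp A SNP id present in the panel.
#' @param subset Optional character vector of subject ids or logical vector
#'   selecting rows.
#' @return Named integer vector `c(n_aa, n_ab, n_bb)` counting dosages 0, 1
#'   and 2 of the effect allele.
#' @export
genotype_counts <- function(gm, snp, subset = NULL) {
  if (!snp %in% names(gm)) abort(paste0("unknown SNP: ", snp))
  d <- gm[[snp]]
  if (!is.null(subset)) {
    d <- if (is.logical(subset)) d[subset] else d[gm$subject_id %in% subset]
  }
  d <- d[!is.na(d)]
  c(n_aa = sum(d == 0L), n_ab = sum(d == 1L), n_bb = sum(d == 2L))
}

#' Minor allele frequency from genotype counts
#'
#' @param counts Genotype counts as returned by [genotype_counts()]
#'   (dosage-0, dosage-1, dosage-2 counts, in that order).
#' @return The folded allele frequency `min(p, 1 - p)` in `[0, 0.5]`, where
#'   `p` is the effect-allele frequency.
#' @export
minor_allele_frequency <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("no genotyped subjects: allele frequency undefined")
  p <- (2 * counts[[3]] + counts[[2]]) / (2 * n)
  min(p, 1 - p)
}

#' Chi-squared test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against HWE expectations at the sample allele frequency, without
#' continuity correction.
#'
#' @inheritParams minor_allele_frequency
#' @return A list with `statistic`, `p_value` and `testable` (FALSE for a
#'   monomorphic SNP, where both are `NA`).
#' @export
hwe_chisq <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("empty genotype counts")
  p <- (2 * counts[[3]] + counts[[2]]) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(statistic = NA_real_, p_value = NA_real_, testable = FALSE))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       testable = TRUE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each possible heterozygote count (same parity as the minor-allele
#' count) is computed from the exact conditional distribution, and the
#' p-value is the sum of probabilities of configurations no more probable
#' than the one observed.
#'
#' @inheritParams minor_allele_frequency
#' @return A list with `p_value` and `testable`.
#' @export
hwe_exact <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("empty genotype counts")
  n_minor <- min(2 * counts[[3]] + counts[[2]], 2 * counts[[1]] + counts[[2]])
  if (n_minor == 0) {
    # monomorphic: a single attainable configuration, p = 1, flagged untestable
    return(list(p_value = 1, testable = FALSE))
  }
  probs <- hwe_het_distribution(counts)
  p_obs <- probs[names(probs) == as.character(counts[[2]])]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  list(p_value = min(p, 1), testable = TRUE)
}

# Exact conditional distribution of the heterozygote count given allele
# counts: named vector of probabilities over all attainable n_ab.
hwe_het_distribution <- function(counts) {
  n <- sum(counts)
  n_b <- 2 * counts[[3]] + counts[[2]]   # effect-allele copies
  n_a <- 2 * n - n_b
  n_minor <- min(n_a, n_b)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    bb <- (n_b - h) / 2
    aa <- (n_a - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) +
      lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  names(p) <- as.character(hets)
  p
}

#' Apply variant- and sample-level QC filters
#'
#' Filters are applied in a fixed, logged order: (1) samples above the
#' sample-missingness threshold are dropped; (2) variants with 100% missing
#' genotypes in controls (when `require_control_data`); (3) variants above
#' the variant-missingness threshold; (4) variants out of Hardy-Weinberg
#' equilibrium — a variant is considered in HWE unless *either* the
#' chi-squared or the exact test rejects at `hwe_alpha`, i.e. it is removed
#' if any test rejects. HWE is assessed on cases and controls pooled by
#' default.
#'
#' @param gm A genotype matrix.
#' @param pheno A phenotype tibble with `subject_id` and `outcome`.
#' @param max_variant_missing,max_sample_missing Missing-fraction thresholds
#'   in `[0, 1]` (defaults 0.5: candidate panels routinely retain SNPs with
#'   up to ~46% missing calls).
#' @param hwe_alpha Significance level for the HWE tests.
#' @param require_control_data Drop variants with no genotyped control.
#' @param hwe_controls_only Assess HWE in controls only (off by default;
#'   the pooled sample is used otherwise).
#' @return A list with `gm` (the filtered genotype matrix), `pheno` (aligned
#'   phenotypes for retained samples) and `report`, itself a list of two
#'   tibbles `variants` and `samples` with per-item missingness, MAF, HWE
#'   p-values, status and removal reason.
#' @export
apply_qc_filters <- function(gm, pheno,
                             max_variant_missing = 0.5,
                             max_sample_missing = 0.5,
                             hwe_alpha = 0.05,
                             require_control_data = TRUE,
                             hwe_controls_only = FALSE) {
  for (thr in c(max_variant_missing, max_sample_missing, hwe_alpha)) {
    if (thr < 0 || thr > 1) abort("thresholds must lie in [0, 1]")
  }
  al <- align_cohort(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  snps <- snp_ids(gm)
  dose <- as.matrix(gm[snps])

  # 1. sample filter
  sample_miss <- rowMeans(is.na(dose))
  keep_sample <- sample_miss <= max_sample_missing
  samples <- tibble(
    subject_id = gm$subject_id, missing_fraction = sample_miss,
    status = ifelse(keep_sample, "kept", "removed"),
    removal_reason = ifelse(keep_sample, NA_character_, "sample_missingness")
  )
  dose <- dose[keep_sample, , drop = FALSE]
  pheno_kept <- pheno[keep_sample, , drop = FALSE]
  is_control <- pheno_kept$outcome == 0
  is_case <- pheno_kept$outcome == 1

  miss_all <- colMeans(is.na(dose))
  miss_ctrl <- colMeans(is.na(dose[is_control, , drop = FALSE]))
  miss_case <- colMeans(is.na(dose[is_case, , drop = FALSE]))
  hwe_rows <- if (hwe_controls_only) is_control else rep(TRUE, nrow(dose))

  per_variant <- map(snps, function(s) {
    d <- dose[hwe_rows, s]
    d <- d[!is.na(d)]
    cts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    maf <- if (sum(cts) > 0) minor_allele_frequency(cts) else NA_real_
    chs <- if (sum(cts) > 0) hwe_chisq(cts) else
      list(statistic = NA_real_, p_value = NA_real_, testable = FALSE)
    ex <- if (sum(cts) > 0) hwe_exact(cts) else
      list(p_value = NA_real_, testable = FALSE)
    tibble(snp_id = s, maf = maf,
           hwe_chisq_p = chs$p_value, hwe_exact_p = ex$p_value,
           hwe_testable = isTRUE(chs$testable) || isTRUE(ex$testable))
  }) %>% bind_rows()

  vr <- per_variant %>%
    mutate(
      missing_fraction = miss_all[snp_id],
      missing_in_cases = miss_case[snp_id],
      missing_in_controls = miss_ctrl[snp_id],
      removal_reason = dplyr::case_when(
        require_control_data & missing_in_controls >= 1 ~ "missing_in_controls",
        missing_fraction > max_variant_missing ~ "variant_missingness",
        hwe_testable & !is.na(hwe_chisq_p) & hwe_chisq_p < hwe_alpha ~ "HWE",
        hwe_testable & !is.na(hwe_exact_p) & hwe_exact_p < hwe_alpha ~ "HWE",
        TRUE ~ NA_character_
      ),
      status = ifelse(is.na(removal_reason), "kept", "removed")
    ) %>%
    select(snp_id, missing_fraction, missing_in_cases, missing_in_controls,
           maf, hwe_chisq_p, hwe_exact_p, status, removal_reason)

  kept_snps <- vr$snp_id[vr$status == "kept"]
  v <- variants(gm)
  out_gm <- genotype_matrix(
    bind_cols(tibble(subject_id = gm$subject_id[keep_sample]),
              as_tibble(dose[, kept_snps, drop = FALSE])),
    v[v$snp_id %in% kept_snps, , drop = FALSE]
  )
  for (r in vr$snp_id[vr$status == "removed"]) {
    inform(paste0("QC: removed ", r, " (",
                  vr$removal_reason[vr$snp_id == r], ")"))
  }
  list(gm = out_gm, pheno = pheno_kept,
       report = list(variants = vr, samples = samples))
}

#' Genotype concordance between duplicated samples
#'
#' @param gm A genotype matrix.
#' @param pairs A data frame with columns `id1`, `id2` naming duplicated
#'   subject pairs.
#' @return A tibble per pair: `n_compared` (SNPs called in both), fraction
#'   `concordance`, and `defined` (FALSE when no SNP is jointly called).
#' @export
duplicate_concordance <- function(gm, pairs) {
  pmap(pairs[c("id1", "id2")], function(id1, id2) {
    if (!all(c(id1, id2) %in% gm$subject_id)) {
      abort(paste0("unknown subject id in pair ", id1, "/", id2))
    }
    d1 <- unlist(gm[gm$subject_id == id1, snp_ids(gm)])
    d2 <- unlist(gm[gm$subject_id == id2, snp_ids(gm)])
    both <- !is.na(d1) & !is.na(d2)
    tibble(id1 = id1, id2 = id2, n_compared = sum(both),
           concordance = if (any(both)) mean(d1[both] == d2[both]) else NA_real_,
           defined = any(both))
  }) %>% bind_rows()
}

#' Compare minor allele frequencies between two groups
#'
#' Builds the 2x2 minor/major allele-count table and tests equality of
#' frequencies with a two-sided Fisher exact test. The second group may be
#' an external reference given as a frequency plus an effective number of
#' alleles (e.g. a public reference-population frequency).
#'
#' @param counts1 Genotype counts (length 3, as [genotype_counts()]) or
#'   allele counts (length 2: minor, major) for group 1.
#' @param counts2 Same, for group 2; omit when using `ref_freq`.
#' @param ref_freq Reference minor-allele frequency in `[0, 1]`.
#' @param ref_n_alleles Effective allele count for the reference.
#' @return A list with `or` (allele-count odds ratio, conditional MLE from
#'   the Fisher test), `p_value`, and the `table` used.
#' @export
compare_maf <- function(counts1, counts2 = NULL, ref_freq = NULL,
                        ref_n_alleles = NULL) {
  a1 <- as_allele_counts(counts1)
  if (is.null(counts2)) {
    if (is.null(ref_freq) || is.null(ref_n_alleles)) {
      abort("provide counts2 or ref_freq + ref_n_alleles")
    }
    a2 <- c(round(ref_freq * ref_n_alleles),
            round((1 - ref_freq) * ref_n_alleles))
  } else {
    a2 <- as_allele_counts(counts2)
  }
  if (sum(a1) == 0 || sum(a2) == 0) abort("a group has zero alleles")
  tab <- rbind(group1 = a1, group2 = a2)
  colnames(tab) <- c("minor", "major")
  ft <- fisher.test(tab)
  list(or = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

as_allele_counts <- function(x) {
  if (length(x) == 3) c(2 * x[[3]] + x[[2]], 2 * x[[1]] + x[[2]])
  else if (length(x) == 2) c(x[[1]], x[[2]])
  else abort("counts must be genotype (3) or allele (2) counts")
}
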