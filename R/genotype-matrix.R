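#' Construct a genotype matrix
#'
#' The central genotype container is an ordinary tibble — one row per subject,
#' a `subject_id` column, and one integer column per SNP holding the number of
#' copies of that SNP's effect allele (0, 1, 2, or `NA` for a missing call) —
#' carrying a variant annotation table as an attribute. Because it is a plain
#' tibble, it pipes through dplyr verbs; accessors below recover the panel
#' metadata.
#'
#' @param calls A data frame with a `subject_id` column and one column per
#'   SNP containing effect-allele dosages in `{0, 1, 2, NA}`.
#' @param variants A data frame describing the panel, with columns `snp_id`,
#'   and optionally `gene`, `chromosome`, `allele_ref`, `allele_alt`,
#'   `effect_allele` (one of `"ref"`, `"alt"`). Missing annotation columns
#'   are filled with `NA`.
#'
#' @return A tibble of class `cg_genotypes` with a `variants` attribute.
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   data.frame(subject_id = c("s1", "s2"), rs1 = c(0L, 2L)),
#'   data.frame(snp_id = "rs1", allele_ref = "A", allele_alt = "C")
#' )
#' variants(gm)
genotype_matrix <- function(calls, variants = NULL) {
  calls <- as_tibble(calls)
  if (!"subject_id" %in% names(calls)) {
    abort("`calls` must have a `subject_id` column.")
  }
  calls$subject_id <- as.character(calls$subject_id)
  if (anyDuplicated(calls$subject_id)) {
    abort("duplicated subject_id in genotype calls")
  }
  snp_cols <- setdiff(names(calls), "subject_id")
  for (s in snp_cols) {
    v <- calls[[s]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      abort(paste0("non-dosage genotype value in SNP ", s))
    }
    calls[[s]] <- as.integer(v)
  }
  if (is.null(variants)) {
    variants <- tibble(snp_id = snp_cols)
  }
  variants <- as_tibble(variants)
  if (anyDuplicated(variants$snp_id)) {
    abort("duplicated snp_id in variant table")
  }
  for (col in c("gene", "chromosome", "allele_ref", "allele_alt")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  if (!"effect_allele" %in% names(variants)) variants$effect_allele <- "alt"
  bad <- !is.na(variants$allele_ref) & !is.na(variants$allele_alt) &
    variants$allele_ref == variants$allele_alt
  if (any(bad)) {
    abort(paste0("ref and alt allele identical for ",
                 paste(variants$snp_id[bad], collapse = ", ")))
  }
  missing_ann <- setdiff(snp_cols, variants$snp_id)
  if (length(missing_ann)) {
    variants <- bind_rows(variants, tibble(snp_id = missing_ann))
  }
  variants <- variants[match(snp_cols, variants$snp_id), ]
  canon <- c("snp_id", "gene", "chromosome", "allele_ref", "allele_alt",
             "effect_allele")
  variants <- variants[c(canon, setdiff(names(variants), canon))]
  structure(calls,
            variants = variants,
            class = c("cg_genotypes", class(calls)))
}

#' @rdname genotype_matrix
#' @param gm A genotype matrix (or any data frame with a `subject_id` column).
#' @export
variants <- function(gm) {
  v <- attr(gm, "variants")
  if (is.null(v)) v <- tibble(snp_id = snp_ids(gm), gene = NA_character_,
                              chromosome = NA_character_,
                              allele_ref = NA_character_,
                              allele_alt = NA_character_,
                              effect_allele = "alt")
  v
}

#' @rdname genotype_matrix
#' @export
snp_ids <- function(gm) setdiff(names(gm), "subject_id")

#' Flip the coded effect allele of one or more SNPs
#'
#' Re-expresses dosages relative to the opposite allele: every non-missing
#' call `c` becomes `2 - c`, and the `effect_allele` annotation is toggled.
#'
#' @param gm A genotype matrix.
#' @param snps Character vector of SNP ids to flip (default: all).
#' @return The genotype matrix with complemented dosages.
#' @export
flip_effect_allele <- function(gm, snps = snp_ids(gm)) {
  v <- variants(gm)
  stopifnot(all(snps %in% snp_ids(gm)))
  for (s in snps) gm[[s]] <- 2L - gm[[s]]
  i <- match(snps, v$snp_id)
  v$effect_allele[i] <- ifelse(v$effect_allele[i] == "alt", "ref", "alt")
  attr(gm, "variants") <- v
  gm
}

#' Recode dosages so every SNP counts its minor allele
#'
#' Computes the effect-allele frequency of each SNP over all non-missing
#' calls and flips any SNP whose coded allele is the major one, so that
#' downstream odds ratios refer consistently to the minor allele.
#'
#' @param gm A genotype matrix.
#' @return The genotype matrix, minor-allele coded.
#' @export
code_minor_allele <- function(gm) {
  flip <- map_lgl(snp_ids(gm), function(s) {
    d <- gm[[s]]
    d <- d[!is.na(d)]
    length(d) > 0 && mean(d) / 2 > 0.5
  })
  to_flip <- snp_ids(gm)[flip]
  if (length(to_flip)) gm <- flip_effect_allele(gm, to_flip)
  gm
}

# Align genotype and phenotype tables on subject_id; subjects present in only
# one table are dropped with a warning (not an error).
align_cohort <- function(gm, pheno) {
  common <- intersect(gm$subject_id, pheno$subject_id)
  n_drop <- (nrow(gm) - length(common)) + (nrow(pheno) - length(common))
  if (n_drop > 0) {
    warn(paste0(n_drop, " subject record(s) present in only one of the ",
                "genotype/phenotype tables were dropped"))
  }
  v <- variants(gm)
  gm <- gm[match(common, gm$subject_id), , drop = FALSE]
  attr(gm, "variants") <- v
  class(gm) <- unique(c("cg_genotypes", class(gm)))
  pheno <- pheno[match(common, pheno$subject_id), , drop = FALSE]
  list(gm = gm, pheno = pheno)
}
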