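#' Read genotypes from a VCF file
#'
#' Reads biallelic SNP records from a VCF (v4.x) into a genotype matrix of
#' effect-allele dosages. Only the GT field is used; half-missing or fully
#' missing calls (`./.`) become `NA`. Phase separators (`|`) are accepted but
#' phase is ignored.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @param effect_allele_rule How the coded (effect) allele is chosen per SNP:
#'   `"minor"` (default) codes the minor allele in the full sample, `"alt"`
#'   codes the ALT allele, `"ref"` the REF allele.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, effect_allele_rule = c("minor", "alt", "ref")) {
  effect_allele_rule <- arg_match(effect_allele_rule)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix   # always a character matrix, even for a single record
  fix <- tibble(CHROM = unname(fx[, "CHROM"]), ID = unname(fx[, "ID"]),
                REF = unname(fx[, "REF"]), ALT = unname(fx[, "ALT"]))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(paste0("multiallelic record(s) not supported: ",
                 paste(fix$ID[multi], collapse = ", ")))
  }
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!snp)) {
    abort(paste0("non-SNP record(s): ", paste(fix$ID[!snp], collapse = ", ")))
  }
  if (anyDuplicated(fix$ID)) {
    abort(paste0("duplicated variant id: ",
                 paste(unique(fix$ID[duplicated(fix$ID)]), collapse = ", ")))
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    abort("VCF records lack a GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  dose <- matrix(dose, nrow = nrow(fix), ncol = ncol(gt),
                 dimnames = list(fix$ID, colnames(gt)))
  calls <- as_tibble(t(dose), .name_repair = "minimal")
  calls <- bind_cols(tibble(subject_id = colnames(gt)), calls)
  vars <- tibble(
    snp_id = fix$ID, gene = NA_character_, chromosome = fix$CHROM,
    allele_ref = fix$REF, allele_alt = fix$ALT, effect_allele = "alt"
  )
  gm <- genotype_matrix(calls, vars)
  switch(effect_allele_rule,
    minor = code_minor_allele(gm),
    ref = flip_effect_allele(gm),
    alt = gm
  )
}

#' Read genotypes from a delimited table
#'
#' One row per subject, one column per SNP. Two dialects are supported:
#' `"dosage"` columns hold 0/1/2 effect-allele counts directly;
#' `"allele-pair"` columns hold unordered two-letter genotype strings such as
#' `"AC"` (`"CA"` is equivalent).
#'
#' @param path Path to a TSV/CSV file with a header row and a `subject_id`
#'   column.
#' @param dialect `"dosage"` or `"allele-pair"`.
#' @param missing_token String marking a missing call in the allele-pair
#'   dialect (empty strings are always treated as missing).
#' @param sep Field separator (guessed from the file extension by default).
#' @return A [genotype_matrix()]. In the allele-pair dialect the effect
#'   allele is the minor allele of each column.
#' @export
read_genotype_table <- function(path, dialect = c("dosage", "allele-pair"),
                                missing_token = "NN", sep = NULL) {
  dialect <- arg_match(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE)
  if (!"subject_id" %in% names(raw)) abort("no subject_id column")
  snp_cols <- setdiff(names(raw), "subject_id")
  if (dialect == "dosage") {
    calls <- tibble(subject_id = raw$subject_id)
    for (s in snp_cols) {
      v <- raw[[s]]
      v[v %in% c("", "NA", missing_token)] <- NA
      calls[[s]] <- as.integer(v)
    }
    return(genotype_matrix(calls))
  }
  calls <- tibble(subject_id = raw$subject_id)
  vars <- tibble(snp_id = snp_cols, gene = NA_character_,
                 chromosome = NA_character_, allele_ref = NA_character_,
                 allele_alt = NA_character_, effect_allele = "alt")
  for (i in seq_along(snp_cols)) {
    s <- snp_cols[i]
    g <- raw[[s]]
    g[g %in% c("", missing_token)] <- NA
    obs <- g[!is.na(g)]
    if (any(nchar(obs) != 2L)) abort(paste0("malformed genotype in ", s))
    al <- unlist(strsplit(obs, ""))
    if (!all(al %in% c("A", "C", "G", "T"))) {
      abort(paste0("allele outside {A,C,G,T} in ", s))
    }
    alleles <- sort(unique(al))
    if (length(alleles) > 2L) {
      abort(paste0("more than two alleles observed at ", s))
    }
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    # effect allele = minor allele of this column
    n_a2 <- sum(al == alleles[2])
    eff <- if (n_a2 <= length(al) / 2) alleles[2] else alleles[1]
    dose <- rep(NA_integer_, length(g))
    dose[!is.na(g)] <- vapply(strsplit(obs, ""),
                              function(p) sum(p == eff), integer(1))
    calls[[s]] <- dose
    other <- setdiff(alleles, eff)[1]
    vars$allele_ref[i] <- other
    vars$allele_alt[i] <- eff
  }
  genotype_matrix(calls, vars)
}

#' Read a phenotype/covariate table
#'
#' Expects a delimited file with a header and columns `subject_id`,
#' `outcome` (1 = case, 0 = control; `yes`/`no` accepted), `sex`
#' (`male`/`female`), `age` (years), `caucasian`, `diabetes`, `hypertension`
#' (binary), and `smoking` (`never`/`former`/`current`). Extra columns are
#' kept untouched.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator (guessed from the extension by default).
#' @return A tibble, one row per subject.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- as_tibble(read.table(path, header = TRUE, sep = sep,
                              colClasses = "character", check.names = FALSE))
  if (!"subject_id" %in% names(raw)) abort("no subject_id column")
  if (!"outcome" %in% names(raw)) abort("no outcome column")
  if (anyDuplicated(raw$subject_id)) abort("duplicated subject_id")
  out <- tibble(subject_id = raw$subject_id,
                outcome = parse_binary(raw$outcome, "outcome"))
  if (anyNA(out$outcome)) abort("missing outcome value(s)")
  if ("sex" %in% names(raw)) {
    bad <- !is.na(raw$sex) & !raw$sex %in% c("male", "female")
    if (any(bad)) abort(paste0("unknown sex level in row ", which(bad)[1]))
    out$sex <- factor(raw$sex, levels = c("male", "female"))
  }
  if ("age" %in% names(raw)) {
    age <- suppressWarnings(as.numeric(raw$age))
    if (any(!is.na(age) & age < 0)) abort("negative age")
    out$age <- age
  }
  for (col in c("caucasian", "diabetes", "hypertension")) {
    if (col %in% names(raw)) out[[col]] <- parse_binary(raw[[col]], col)
  }
  if ("smoking" %in% names(raw)) {
    lv <- c("never", "former", "current")
    bad <- !is.na(raw$smoking) & !raw$smoking %in% lv
    if (any(bad)) abort(paste0("unknown smoking level in row ", which(bad)[1]))
    out$smoking <- factor(raw$smoking, levels = lv)
  }
  extra <- setdiff(names(raw), c(names(out)))
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

parse_binary <- function(x, what) {
  v <- rep(NA_integer_, length(x))
  v[x %in% c("1", "yes", "TRUE", "true")] <- 1L
  v[x %in% c("0", "no", "FALSE", "false")] <- 0L
  bad <- !is.na(x) & x != "" & is.na(v)
  if (any(bad)) {
    abort(paste0("unparseable ", what, " value in row ", which(bad)[1],
                 ": '", x[which(bad)[1]], "'"))
  }
  v
}

#' Write a results bundle to disk
#'
#' Writes one TSV per populated result table plus a machine-readable JSON
#' summary with provenance (seed, package version, input description).
#' Output is deterministic: rerunning with identical inputs and seed yields
#' byte-identical files.
#'
#' @param bundle A named list as produced by [run_pipeline()]: any of
#'   `qc_report`, `baseline`, `association`, `ld`, `search`, `roc`, plus a
#'   `provenance` list.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  paths <- character(0)
  tables <- list(
    qc_variants = bundle$qc_report$variants,
    qc_samples = bundle$qc_report$samples,
    baseline = bundle$baseline,
    association = if (!is.null(bundle$association)) tidy(bundle$association),
    ld = bundle$ld,
    search_subsets = if (!is.null(bundle$search)) tidy(bundle$search),
    final_model = if (!is.null(bundle$final_model)) tidy(bundle$final_model),
    roc = if (!is.null(bundle$roc)) tidy(bundle$roc)
  )
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb)) next
    tb <- as.data.frame(format_or_columns(tb))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- list(
    provenance = bundle$provenance,
    tables = lapply(tables[!vapply(tables, is.null, logical(1))],
                    function(tb) as.data.frame(tb))
  )
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

# Collapse (or, or_low, or_high) triples into a single "OR (low-high)" column.
format_or_columns <- function(tb) {
  if (all(c("or", "or_low", "or_high") %in% names(tb))) {
    tb$or_ci <- ifelse(
      is.na(tb$or), "inestimable",
      sprintf("%.2f (%.2f-%.2f)", tb$or, tb$or_low, tb$or_high)
    )
  }
  tb
}
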