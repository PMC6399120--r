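#' Number of candidate multivariate models
#'
#' All non-empty subsets of `m` SNP terms: `2^m - 1`.
#'
#' @param m Number of candidate SNPs (at least 1).
#' @return `2^m - 1`.
#' @export
#' @examples
#' count_models(12)  # 4095
count_models <- function(m) {
  if (m < 1) abort("m must be at least 1")
  2^m - 1
}

#' Complete-case analysis subset for a set of SNPs
#'
#' Subjects with a non-missing genotype at every listed SNP and non-missing
#' covariates/outcome. Multivariate model AICs are only comparable on a
#' common likelihood sample, so every subset fit uses this one subject set.
#'
#' @param gm A genotype matrix.
#' @param pheno A phenotype tibble.
#' @param snps SNP ids entering the multivariate stage.
#' @param covariates Adjusting covariates always included.
#' @param extra Additional phenotype columns that must be complete (e.g.
#'   clinical factors for the interaction stage).
#' @return A list: `data` (tibble with `outcome`, covariates, extras and one
#'   dosage column per SNP), `n`, `n_cases`, `n_controls`.
#' @export
complete_cases_cohort <- function(gm, pheno, snps,
                                  covariates = c("sex", "age", "caucasian"),
                                  extra = character(0)) {
  if (!length(snps)) abort("no SNPs supplied")
  al <- align_cohort(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  df <- bind_cols(pheno[c("outcome", covariates, extra)],
                  as_tibble(gm[snps]))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) {
    abort("no subject has complete data for all SNPs; reduce the SNP set")
  }
  list(data = df, n = nrow(df), n_cases = sum(df$outcome == 1),
       n_controls = sum(df$outcome == 0))
}

# Build the encoded SNP design blocks for the fixed analysis subset.
# Returns a list per SNP: matrix of encoded columns named "<snp>.<part>".
snp_design_blocks <- function(data, snp_terms) {
  blocks <- list()
  for (i in seq_len(nrow(snp_terms))) {
    s <- snp_terms$snp_id[i]; m <- snp_terms$model[i]
    enc <- encoded_terms(data[[s]], m)
    if (ncol(enc) == 0) {
      abort(paste0("SNP ", s, " is constant on the complete-case subset"))
    }
    colnames(enc) <- paste0(s, ".", colnames(enc))
    blocks[[s]] <- enc
  }
  blocks
}

#' Detect aliased (perfectly collinear) SNP terms
#'
#' Two encoded SNP terms are aliased when their design columns are perfectly
#' collinear on the analysis subset — e.g. two SNPs whose risk-carrier
#' indicators coincide subject-for-subject. Within each aliased group all
#' but the first SNP (panel order) are masked from joint models.
#'
#' @param blocks Named list of encoded design blocks (one per SNP, panel
#'   order), as used by [exhaustive_search()].
#' @return A list with `groups` (list of character vectors of aliased SNP
#'   ids) and `masked` (SNPs excluded from joint models).
#' @export
detect_aliased <- function(blocks) {
  snps <- names(blocks)
  n <- length(snps)
  groups <- list()
  assigned <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (snps[i] %in% assigned) next
      grp <- snps[i]
      for (j in (i + 1):n) {
        if (snps[j] %in% assigned) next
        if (blocks_collinear(blocks[[i]], blocks[[j]])) {
          grp <- c(grp, snps[j])
        }
      }
      if (length(grp) > 1) {
        groups <- c(groups, list(grp))
        assigned <- c(assigned, grp)
      }
    }
  }
  masked <- unlist(map(groups, function(g) g[-1]))
  list(groups = groups, masked = masked %||% character(0))
}

blocks_collinear <- function(a, b) {
  if (ncol(a) != ncol(b)) return(FALSE)
  # collinear iff adding b's columns to a's does not increase rank
  qr(cbind(1, a, b))$rank == qr(cbind(1, a))$rank
}

# Fast binomial fit on a design matrix; returns loglik, k (rank), aic.
fit_cols <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  k <- fit$rank
  list(loglik = ll, k = k, aic = 2 * k - 2 * ll,
       converged = fit$converged, coef = fit$coefficients)
}

#' Exhaustive AIC search over SNP subsets
#'
#' Fits every non-empty subset of the candidate SNP terms (each under its
#' pre-selected inheritance coding, always including the adjusting
#' covariates) on one fixed complete-case subject set, and returns the
#' minimum-AIC subset(s). Aliased SNP terms are detected first; inside any
#' subset containing several members of an aliased group only the first
#' member's columns enter the design, so subsets that differ only in which
#' aliased member they carry tie exactly — the tie-break picks the smallest
#' subset with the lowest panel indices, mirroring the convention of
#' keeping the first-listed SNP.
#'
#' @inheritParams complete_cases_cohort
#' @param snp_terms A data frame with columns `snp_id` and `model` (the
#'   chosen inheritance model per SNP), e.g. from [assoc_scan()].
#' @param aic_tie_tol AIC difference treated as an exact tie (default 1e-6).
#' @param max_snps Guard on the enumeration size (default 20).
#' @return An object of class `cg_search`: `fits` (tibble: subset, aic,
#'   logLik, k, n_used, converged), `best_subsets`, `chosen_subset`,
#'   `aliased`, `best_fit` (a `cg_logit` refit of the chosen subset),
#'   `data`, `snp_terms`, `covariates`. Supports [tidy()] and [glance()].
#' @export
exhaustive_search <- function(gm, pheno, snp_terms,
                              covariates = c("sex", "age", "caucasian"),
                              aic_tie_tol = 1e-6, max_snps = 20) {
  m <- nrow(snp_terms)
  if (m < 1) abort("snp_terms is empty")
  if (m > max_snps) abort("too many SNPs for exhaustive enumeration")
  cc <- complete_cases_cohort(gm, pheno, snp_terms$snp_id, covariates)
  data <- cc$data
  y <- data$outcome
  blocks <- snp_design_blocks(data, snp_terms)
  aliased <- detect_aliased(blocks)
  cov_X <- covariate_design(data, covariates)
  snps <- snp_terms$snp_id

  subsets <- map(seq_len(2^m - 1), function(code) {
    snps[bitwAnd(code, 2^(seq_len(m) - 1)) > 0]
  })
  rows <- map(subsets, function(sub) {
    eff <- drop_aliased_members(sub, aliased$groups)
    X <- do.call(cbind, c(list(cov_X), blocks[eff]))
    f <- fit_cols(X, y)
    tibble(subset = paste(sub, collapse = "+"), n_snps = length(sub),
           aic = f$aic, logLik = f$loglik, k = f$k, n_used = length(y),
           converged = f$converged)
  }) %>% bind_rows()
  ok <- rows$converged
  if (any(!ok)) {
    warn(paste0(sum(!ok), " subset fit(s) did not converge; excluded"))
  }
  cand <- rows[ok, ]
  best_aic <- min(cand$aic)
  best <- cand[cand$aic <= best_aic + aic_tie_tol, ]
  # tie-break: fewest SNPs, then lowest panel indices lexicographically
  key <- map_chr(strsplit(best$subset, "+", fixed = TRUE), function(s) {
    paste(sprintf("%03d", sort(match(s, snps))), collapse = ",")
  })
  ordv <- order(best$n_snps, key)
  chosen <- best$subset[ordv[1]]
  chosen_snps <- strsplit(chosen, "+", fixed = TRUE)[[1]]
  eff <- drop_aliased_members(chosen_snps, aliased$groups)
  best_fit <- refit_subset(data, blocks, eff, covariates)
  structure(
    list(fits = rows, best_subsets = best$subset, chosen_subset = chosen_snps,
         aliased = aliased, best_fit = best_fit, data = data,
         snp_terms = snp_terms, covariates = covariates,
         n_cases = cc$n_cases, n_controls = cc$n_controls),
    class = "cg_search"
  )
}

drop_aliased_members <- function(sub, groups) {
  for (g in groups) {
    inn <- intersect(g, sub)
    if (length(inn) > 1) sub <- setdiff(sub, inn[-1])
  }
  sub
}

covariate_design <- function(data, covariates) {
  if (!length(covariates)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(stats::reformulate(covariates), data = data)
}

refit_subset <- function(data, blocks, snps_eff, covariates) {
  enc <- do.call(cbind, blocks[snps_eff])
  dat <- bind_cols(data, as_tibble(enc))
  names(dat) <- make.names(names(dat))
  fit_logistic(
    stats::reformulate(c(make.names(colnames(enc)), covariates), "outcome"),
    dat)
}

#' @export
print.cg_search <- function(x, ...) {
  cat("<cg_search> exhaustive AIC search over",
      nrow(x$snp_terms), "SNP terms:", nrow(x$fits), "models\n")
  cat("  chosen subset:", paste(x$chosen_subset, collapse = " + "), "\n")
  if (length(x$best_subsets) > 1) {
    cat("  tied best subsets:", length(x$best_subsets), "\n")
  }
  if (length(x$aliased$groups)) {
    cat("  aliased groups:",
        paste(map_chr(x$aliased$groups, paste, collapse = "="),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' @describeIn exhaustive_search All subset fits, best first.
#' @param x A `cg_search` object.
#' @param ... Unused.
#' @export
tidy.cg_search <- function(x, ...) arrange(x$fits, .data$aic)

#' @describeIn exhaustive_search One-row summary of the enumeration.
#' @export
glance.cg_search <- function(x, ...) {
  tibble(n_models = nrow(x$fits), n_best = length(x$best_subsets),
         best_aic = min(x$fits$aic[x$fits$converged]),
         n_used = x$fits$n_used[1], n_cases = x$n_cases,
         n_controls = x$n_controls,
         n_aliased_groups = length(x$aliased$groups))
}
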