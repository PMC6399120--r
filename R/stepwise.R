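# ---- term machinery for the interaction stage ---------------------------
# A term owns a named block of design columns on the fixed analysis subset.
# SNP x clinical and SNP x SNP interaction blocks are element-wise products
# of the parent blocks (degenerate product columns dropped).

make_terms <- function(data, blocks, clinical) {
  terms <- list()
  for (s in names(blocks)) {
    terms[[s]] <- list(name = s, cols = blocks[[s]], parents = character(0),
                       type = "snp")
  }
  for (cf in clinical) {
    col <- matrix(as.numeric(data[[cf]]), ncol = 1,
                  dimnames = list(NULL, cf))
    terms[[cf]] <- list(name = cf, cols = col, parents = character(0),
                        type = "clinical")
  }
  main_names <- names(terms)
  # SNP x clinical then SNP x SNP interactions
  for (s in names(blocks)) {
    for (cf in clinical) {
      blk <- interaction_block(blocks[[s]], terms[[cf]]$cols)
      if (!is.null(blk)) {
        nm <- paste0(s, ":", cf)
        terms[[nm]] <- list(name = nm, cols = blk, parents = c(s, cf),
                            type = "interaction")
      }
    }
  }
  sn <- names(blocks)
  if (length(sn) >= 2) {
    prs <- combn(sn, 2)
    for (k in seq_len(ncol(prs))) {
      s1 <- prs[1, k]; s2 <- prs[2, k]
      blk <- interaction_block(blocks[[s1]], blocks[[s2]])
      if (!is.null(blk)) {
        nm <- paste0(s1, ":", s2)
        terms[[nm]] <- list(name = nm, cols = blk, parents = c(s1, s2),
                            type = "interaction")
      }
    }
  }
  list(terms = terms, mains = main_names)
}

interaction_block <- function(a, b) {
  cols <- list()
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    v <- a[, i] * b[, j]
    if (stats::var(v) > 0) {
      cols[[paste0(colnames(a)[i], ":", colnames(b)[j])]] <- v
    }
  }
  if (!length(cols)) return(NULL)
  blk <- do.call(cbind, cols)
  colnames(blk) <- names(cols)
  blk
}

assemble_design <- function(cov_X, terms, active) {
  do.call(cbind, c(list(cov_X), lapply(terms[active], `[[`, "cols")))
}

# a term may be dropped only if no active interaction has it as a parent
droppable <- function(name, terms, active) {
  !any(map_lgl(terms[active], function(t) name %in% t$parents))
}

#' Stepwise interaction modelling on a fixed SNP subset
#'
#' Starting from the main-effects model (the chosen SNP subset plus the
#' clinical risk factors, always adjusted for the forced covariates),
#' performs bidirectional stepwise selection by AIC over candidate terms:
#' SNP main effects, clinical factors, all SNP x clinical and SNP x SNP
#' interactions. The marginality hierarchy is enforced: an interaction may
#' enter only while both parents are in the model, and a parent cannot
#' leave while one of its interactions remains. Adjusting covariates are
#' never dropped. A p-value-driven backward mode (`criterion = "pvalue"`)
#' removes, at each step, the eligible term with the largest
#' likelihood-ratio p-value above `alpha`.
#'
#' @inheritParams exhaustive_search
#' @param base_snps SNP ids of the base subset (e.g.
#'   `chosen_subset` of [exhaustive_search()]); may be empty, in which case
#'   the model holds covariates and clinical factors only.
#' @param clinical Clinical risk-factor columns (default diabetes and
#'   hypertension).
#' @param criterion `"aic"` (bidirectional) or `"pvalue"` (backward).
#' @param alpha Retention threshold for `criterion = "pvalue"`.
#' @param max_steps Step cap.
#' @return An object of class `cg_riskmodel`: `coef`, `vcov`, `loglik`,
#'   `k`, `aic`, `n_used`, active `terms`, `steps` (the move log),
#'   `eliminated` (dropped terms in order), plus the design metadata needed
#'   to score new profiles. Supports [tidy()], [glance()], [autoplot()].
#' @export
stepwise_interactions <- function(gm, pheno, base_snps, snp_terms,
                                  covariates = c("sex", "age", "caucasian"),
                                  clinical = c("diabetes", "hypertension"),
                                  criterion = c("aic", "pvalue"),
                                  alpha = 0.05, max_steps = 200) {
  criterion <- arg_match(criterion)
  if (length(base_snps)) {
    cc <- complete_cases_cohort(gm, pheno, base_snps, covariates,
                                extra = clinical)
    data <- cc$data
  } else {
    al <- align_cohort(gm, pheno)
    data <- al$pheno[c("outcome", covariates, clinical)]
    data <- data[complete.cases(data), , drop = FALSE]
  }
  y <- data$outcome
  blocks <- if (length(base_snps)) {
    snp_design_blocks(data, snp_terms[snp_terms$snp_id %in% base_snps, ])
  } else list()
  tm <- make_terms(data, blocks, clinical)
  terms <- tm$terms
  cov_X <- covariate_design(data, covariates)
  active <- tm$mains
  fit_active <- function(act) fit_cols(assemble_design(cov_X, terms, act), y)
  cur <- fit_active(active)
  steps <- list(tibble(step = 0L, move = "start",
                       term = paste(active, collapse = "+"),
                       aic = cur$aic))
  eliminated <- character(0)
  for (it in seq_len(max_steps)) {
    moves <- list()
    if (criterion == "aic") {
      for (t in setdiff(names(terms), active)) {
        tt <- terms[[t]]
        if (length(tt$parents) && !all(tt$parents %in% active)) next
        moves[[paste0("+", t)]] <- list(act = c(active, t), term = t,
                                        move = "add")
      }
    }
    for (t in active) {
      if (!droppable(t, terms, active)) next
      moves[[paste0("-", t)]] <- list(act = setdiff(active, t), term = t,
                                      move = "drop")
    }
    if (!length(moves)) break
    fits <- map(moves, function(mv) tryCatch(fit_active(mv$act),
                                             error = function(e) NULL))
    keep <- !map_lgl(fits, is.null) &
      map_lgl(fits, function(f) isTRUE(f$converged))
    if (!any(keep)) break
    moves <- moves[keep]; fits <- fits[keep]
    if (criterion == "aic") {
      aics <- map_dbl(fits, "aic")
      best <- which.min(aics)
      if (aics[best] >= cur$aic - 1e-8) break
    } else {
      drops <- map_lgl(moves, function(mv) mv$move == "drop")
      if (!any(drops)) break
      # LRT p of each droppable term; drop the weakest if p > alpha
      pvals <- map_dbl(which(drops), function(i) {
        lr <- max(0, 2 * (cur$loglik - fits[[i]]$loglik))
        df <- cur$k - fits[[i]]$k
        if (df <= 0) return(0)
        pchisq(lr, df, lower.tail = FALSE)
      })
      cand <- which(drops)[pvals > alpha]
      if (!length(cand)) break
      best <- cand[which.max(pvals[match(cand, which(drops))])]
    }
    mv <- moves[[best]]
    active <- mv$act
    cur <- fits[[best]]
    if (mv$move == "drop") eliminated <- c(eliminated, mv$term)
    steps[[length(steps) + 1]] <- tibble(step = it, move = mv$move,
                                         term = mv$term, aic = cur$aic)
  }
  X <- assemble_design(cov_X, terms, active)
  final <- fit_cols_full(X, y)
  structure(
    list(coef = final$coef, vcov = final$vcov, loglik = final$loglik,
         k = final$k, aic = final$aic, n_used = length(y),
         active = active, terms = terms[active], steps = bind_rows(steps),
         eliminated = eliminated, covariates = covariates,
         clinical = clinical, data = data,
         snp_terms = if (length(base_snps))
           snp_terms[snp_terms$snp_id %in% base_snps, ] else snp_terms[0, ],
         criterion = criterion),
    class = "cg_riskmodel"
  )
}

# full fit with coefficient covariance (observed information)
fit_cols_full <- function(X, y) {
  f <- fit_cols(X, y)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  vc <- solve(crossprod(X, w * X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  list(coef = beta, vcov = vc, loglik = f$loglik, k = f$k, aic = f$aic)
}

#' @export
print.cg_riskmodel <- function(x, ...) {
  cat("<cg_riskmodel> final risk model, n =", x$n_used, "\n")
  cat("  terms:", paste(x$active, collapse = ", "), "\n")
  if (length(x$eliminated)) {
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  }
  cat("  AIC:", format(x$aic, digits = 7), "\n")
  invisible(x)
}

#' @describeIn stepwise_interactions Coefficient table with odds ratios and
#'   Wald 95% CIs.
#' @param x A `cg_riskmodel` object.
#' @param ... Unused.
#' @export
tidy.cg_riskmodel <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(0.975)
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(se),
         statistic = unname(x$coef / se),
         p.value = 2 * pnorm(-abs(x$coef / se)),
         or = exp(unname(x$coef)),
         or_low = exp(unname(x$coef - z * se)),
         or_high = exp(unname(x$coef + z * se)))
}

#' @describeIn stepwise_interactions One-row model summary.
#' @export
glance.cg_riskmodel <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, df = x$k, nobs = x$n_used,
         n_terms = length(x$active),
         n_interactions = sum(grepl(":", x$active)),
         n_eliminated = length(x$eliminated))
}

# predicted probabilities of the risk model on its analysis data (or new
# design rows built from profiles)
riskmodel_scores <- function(x, X = NULL) {
  if (is.null(X)) {
    cov_X <- covariate_design(x$data, x$covariates)
    X <- do.call(cbind, c(list(cov_X), lapply(x$terms, `[[`, "cols")))
  }
  drop(plogis(X %*% x$coef))
}

#' Predicted odds ratios for covariate/genotype profiles
#'
#' Computes the model-predicted odds ratio of each profile against a
#' reference profile: `OR = exp(eta_profile - eta_reference)`, with a
#' delta-method (linear-contrast) Wald CI. A profile supplies one value per
#' model variable: a dosage for each SNP in the model, values for the
#' clinical factors, and the adjusting covariates; omitted covariates
#' default to the reference profile's values.
#'
#' @param model A `cg_riskmodel`.
#' @param profiles A data frame, one row per profile.
#' @param reference A one-row data frame, the reference profile.
#' @param conf_level Confidence level.
#' @return A tibble: one row per profile with `or`, `or_low`, `or_high`.
#' @export
profile_odds_ratios <- function(model, profiles, reference,
                                conf_level = 0.95) {
  x_ref <- profile_row(model, reference)
  z <- qnorm(1 - (1 - conf_level) / 2)
  map(seq_len(nrow(profiles)), function(i) {
    prof <- merge_profile(reference, profiles[i, , drop = FALSE])
    x_p <- profile_row(model, prof)
    cvec <- x_p - x_ref
    est <- sum(cvec * model$coef)
    v <- drop(t(cvec) %*% model$vcov %*% cvec)
    tibble(profile = i, or = exp(est),
           or_low = exp(est - z * sqrt(v)),
           or_high = exp(est + z * sqrt(v)))
  }) %>% bind_rows()
}

merge_profile <- function(reference, profile) {
  out <- reference
  for (nm in names(profile)) out[[nm]] <- profile[[nm]]
  out
}

# build the design row of one profile: covariate columns via model.matrix
# with the training factor levels, then each active term's columns
profile_row <- function(model, prof) {
  xlev <- lapply(model$data[model$covariates],
                 function(v) if (is.factor(v)) levels(v))
  xlev <- xlev[!vapply(xlev, is.null, logical(1))]
  for (cv in model$covariates) {
    if (!cv %in% names(prof)) abort(paste0("profile lacks covariate ", cv))
    if (cv %in% names(xlev) &&
        !as.character(prof[[cv]]) %in% xlev[[cv]]) {
      abort(paste0("unknown level for ", cv, ": ", prof[[cv]]))
    }
  }
  pdat <- as.data.frame(prof)
  for (cv in names(xlev)) pdat[[cv]] <- factor(pdat[[cv]], levels = xlev[[cv]])
  cov_row <- stats::model.matrix(stats::reformulate(model$covariates),
                                 data = pdat, xlev = xlev)
  pieces <- list(drop(cov_row))
  st <- model$snp_terms
  term_cols <- function(name) {
    if (name %in% st$snp_id) {
      if (!name %in% names(prof)) abort(paste0("profile lacks SNP ", name))
      enc <- encode_genotype(prof[[name]],
                             st$model[st$snp_id == name])
      # keep the columns the fitted block kept
      keep <- sub(paste0("^", name, "\\."), "",
                  colnames(model$terms[[name]]$cols))
      matched <- enc[, match(keep, colnames(enc)), drop = FALSE]
      setNames(as.numeric(matched), colnames(model$terms[[name]]$cols))
    } else if (name %in% model$clinical) {
      if (!name %in% names(prof)) abort(paste0("profile lacks ", name))
      setNames(as.numeric(prof[[name]]), name)
    } else abort(paste0("unknown term ", name))
  }
  for (t in model$terms) {
    if (!length(t$parents)) {
      pieces[[length(pieces) + 1]] <- term_cols(t$name)
    } else {
      a <- term_cols(t$parents[1]); b <- term_cols(t$parents[2])
      prod_all <- as.numeric(outer(a, b))
      names(prod_all) <- as.character(outer(names(a), names(b), paste,
                                            sep = ":"))
      pieces[[length(pieces) + 1]] <-
        prod_all[colnames(t$cols)]
    }
  }
  row <- unlist(pieces)
  if (length(row) != length(model$coef)) {
    abort("profile design row does not match model terms")
  }
  row
}
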