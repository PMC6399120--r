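#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half; identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = case).
#' @return The AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes required to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity at every distinct score threshold (rule:
#' score >= threshold is called positive), with the degenerate endpoints
#' (sens 1 / spec 0 and sens 0 / spec 1) included.
#'
#' @inheritParams auc_mw
#' @return A tibble of class `cg_roc`: `threshold`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`, with attributes `n_cases`,
#'   `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes required for a ROC curve")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  rows <- map(thr, function(t) {
    pos <- scores >= t
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    tibble(threshold = t, sensitivity = tp / n1,
           specificity = (n0 - fp) / n0,
           tp = tp, fp = fp, tn = n0 - fp, fn = n1 - tp)
  })
  out <- bind_rows(rows)
  structure(out, n_cases = n1, n_controls = n0,
            class = c("cg_roc", class(out)))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two risk scores evaluated on the
#' same subjects, using the covariance of case and control placement values
#' (structural components).
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary outcome (1 = case), shared by both scores.
#' @return A list: `auc_a`, `auc_b`, `delta`, `variance`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("scores_a, scores_b and labels must be paired (equal length)")
  }
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  sa <- scores_a[ok]; sb <- scores_b[ok]; y <- labels[ok]
  cases <- y == 1; ctrls <- y == 0
  m <- sum(cases); n <- sum(ctrls)
  if (m == 0 || n == 0) abort("both classes required")
  pv <- function(s) {
    x <- s[cases]; yv <- s[ctrls]
    # placement of each case among controls and vice versa
    v10 <- vapply(x, function(xi) (sum(xi > yv) + 0.5 * sum(xi == yv)) / n,
                  numeric(1))
    v01 <- vapply(yv, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- pv(sa); b <- pv(sb)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  variance <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (variance <= 0) {
    z <- if (abs(delta) < 1e-15) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(variance)
  }
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, variance = variance,
       z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Bootstrap AUC with percentile confidence interval
#'
#' Resamples subjects with replacement (stratified by outcome so both
#' classes survive), refits the model on each resample, evaluates the AUC
#' on the resample, and returns the bootstrap mean and the 2.5/97.5
#' percentile interval.
#'
#' @param score_fn A function `score_fn(idx)` returning the risk scores of
#'   subjects `idx` after refitting the model on those rows (see
#'   [model_score_fn()]); in refit-free mode a plain score vector may be
#'   given instead.
#' @param labels Binary outcome vector.
#' @param n_boot Number of resamples (study-scale default 1000).
#' @param seed Integer seed.
#' @param stratified Resample within cases and controls (default TRUE).
#' @return A list: `mean`, `ci_low`, `ci_high`, `auc_boot` (the resample
#'   AUCs), `n_redrawn` (single-class resamples redrawn, unstratified mode).
#' @export
bootstrap_auc <- function(score_fn, labels, n_boot = 1000, seed = NULL,
                          stratified = TRUE) {
  if (n_boot < 1) abort("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  N <- length(labels)
  idx_cases <- which(labels == 1); idx_ctrls <- which(labels == 0)
  if (is.numeric(score_fn)) {
    scores <- score_fn
    score_fn <- function(idx) scores[idx]
  }
  n_redrawn <- 0L
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- if (stratified) {
        c(sample(idx_cases, length(idx_cases), replace = TRUE),
          sample(idx_ctrls, length(idx_ctrls), replace = TRUE))
      } else {
        sample.int(N, N, replace = TRUE)
      }
      if (length(unique(labels[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    aucs[b] <- auc_mw(score_fn(idx), labels[idx])
  }
  qs <- unname(quantile(aucs, c(0.025, 0.975), type = 7))
  list(mean = mean(aucs), ci_low = qs[1], ci_high = qs[2],
       auc_boot = aucs, n_redrawn = n_redrawn)
}

#' Optimal operating point of a ROC curve
#'
#' The threshold maximizing Youden's index (sensitivity + specificity - 1),
#' equivalently the point of maximal perpendicular distance to the
#' diagonal; ties resolved toward higher specificity. Sensitivity,
#' specificity, PPV and NPV at that point carry Wilson 95% confidence
#' intervals; predictive values are computed at the sample case fraction.
#'
#' @param curve A [roc_curve()] tibble.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` each with `_low`/`_high` Wilson bounds, `youden`, and
#'   `informative` (FALSE when no threshold beats the diagonal).
#' @export
optimal_threshold <- function(curve) {
  finite <- curve[is.finite(curve$threshold), , drop = FALSE]
  if (nrow(finite) == 0) finite <- curve
  youden <- finite$sensitivity + finite$specificity - 1
  best_y <- max(youden)
  if (best_y <= 0) {
    return(tibble(threshold = NA_real_, sensitivity = NA_real_,
                  sensitivity_low = NA_real_, sensitivity_high = NA_real_,
                  specificity = NA_real_, specificity_low = NA_real_,
                  specificity_high = NA_real_, ppv = NA_real_,
                  ppv_low = NA_real_, ppv_high = NA_real_, npv = NA_real_,
                  npv_low = NA_real_, npv_high = NA_real_,
                  youden = best_y, informative = FALSE))
  }
  cand <- which(youden >= best_y - 1e-12)
  best <- cand[which.max(finite$specificity[cand])]
  row <- finite[best, ]
  wi <- function(x, n) wilson_interval(x, n)
  sens_ci <- wi(row$tp, row$tp + row$fn)
  spec_ci <- wi(row$tn, row$tn + row$fp)
  ppv_ci <- wi(row$tp, row$tp + row$fp)
  npv_ci <- wi(row$tn, row$tn + row$fn)
  tibble(threshold = row$threshold,
         sensitivity = row$sensitivity,
         sensitivity_low = sens_ci[1], sensitivity_high = sens_ci[2],
         specificity = row$specificity,
         specificity_low = spec_ci[1], specificity_high = spec_ci[2],
         ppv = row$tp / (row$tp + row$fp),
         ppv_low = ppv_ci[1], ppv_high = ppv_ci[2],
         npv = row$tn / (row$tn + row$fn),
         npv_low = npv_ci[1], npv_high = npv_ci[2],
         youden = youden[best], informative = TRUE)
}

# Wilson score interval for x successes of n
wilson_interval <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Turn a model specification into a refitting score function
#'
#' @param spec Either a formula (a logistic model refit on each subject
#'   subset, scored in-sample), a `cg_riskmodel` (its fixed term design is
#'   refit), or a function `f(idx)` used as is.
#' @param data The analysis data (for formula specs).
#' @return A function `f(idx)` returning scores for subjects `idx`; with
#'   `idx = NULL` the full-sample in-sample scores.
#' @export
model_score_fn <- function(spec, data = NULL) {
  if (is.function(spec)) return(spec)
  if (inherits(spec, "cg_riskmodel")) {
    cov_X <- covariate_design(spec$data, spec$covariates)
    X <- do.call(cbind, c(list(cov_X), lapply(spec$terms, `[[`, "cols")))
    y <- spec$data$outcome
    return(function(idx = NULL) {
      if (is.null(idx)) idx <- seq_along(y)
      f <- fit_cols_refit(X[idx, , drop = FALSE], y[idx])
      drop(plogis(X[idx, , drop = FALSE] %*% f))
    })
  }
  if (inherits(spec, "formula")) {
    if (is.null(data)) abort("formula specs need `data`")
    mf <- stats::model.frame(spec, data, na.action = na.omit)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    return(function(idx = NULL) {
      if (is.null(idx)) idx <- seq_along(y)
      f <- fit_cols_refit(X[idx, , drop = FALSE], y[idx])
      drop(plogis(X[idx, , drop = FALSE] %*% f))
    })
  }
  abort("unsupported model spec")
}

fit_cols_refit <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co
}

#' Compare the discrimination of several risk models
#'
#' Scores every model in-sample on a shared subject set, then computes
#' per-model AUC, bootstrap mean and percentile CI (refitting each model on
#' every resample), the optimal operating point, and all pairwise DeLong
#' tests.
#'
#' @param data The analysis data (rows = the shared subjects).
#' @param specs Named list of model specifications ([model_score_fn()]).
#' @param outcome Name of the binary outcome column.
#' @param n_boot Bootstrap resamples per model.
#' @param seed Integer seed (model `i` uses `seed + i` for its bootstrap).
#' @return An object of class `cg_roccomp`: `models` (per-model tibble with
#'   AUC, bootstrap summary and operating statistics), `pairwise` (DeLong
#'   contrasts), `curves` (named list of [roc_curve()]s), `scores`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
compare_models <- function(data, specs, outcome = "outcome", n_boot = 1000,
                           seed = 1) {
  if (length(specs) < 2) abort("need at least two model specs")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    abort("specs must be a named list")
  }
  labels <- data[[outcome]]
  fns <- map(specs, model_score_fn, data = data)
  scores <- map(fns, function(f) f(NULL))
  lens <- map_int(scores, length)
  if (length(unique(lens)) != 1 || lens[1] != length(labels)) {
    abort("model specs must score the same shared subjects")
  }
  curves <- map(scores, roc_curve, labels = labels)
  models <- imap(scores, function(sc, nm) {
    i <- match(nm, names(specs))
    bt <- bootstrap_auc(fns[[nm]], labels, n_boot = n_boot, seed = seed + i)
    opt <- optimal_threshold(curves[[nm]])
    bind_cols(tibble(model = nm, auc = auc_mw(sc, labels),
                     auc_boot_mean = bt$mean, auc_boot_low = bt$ci_low,
                     auc_boot_high = bt$ci_high),
              opt)
  }) %>% bind_rows()
  prs <- combn(names(specs), 2)
  pairwise <- map(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    dl <- delong_test(scores[[a]], scores[[b]], labels)
    tibble(model_a = a, model_b = b, auc_a = dl$auc_a, auc_b = dl$auc_b,
           delta = dl$delta, variance = dl$variance, z = dl$z,
           p_value = dl$p_value)
  }) %>% bind_rows()
  structure(list(models = models, pairwise = pairwise, curves = curves,
                 scores = scores, labels = labels, n_boot = n_boot,
                 seed = seed),
            class = "cg_roccomp")
}

#' @export
print.cg_roccomp <- function(x, ...) {
  cat("<cg_roccomp> ROC comparison of", nrow(x$models), "models\n")
  print(x$models[c("model", "auc", "auc_boot_low", "auc_boot_high",
                   "threshold", "sensitivity", "specificity")])
  invisible(x)
}

#' @describeIn compare_models Per-model summary table (threshold,
#'   sensitivity, specificity, PPV, NPV, AUC).
#' @param x A `cg_roccomp` object.
#' @param ... Unused.
#' @export
tidy.cg_roccomp <- function(x, ...) x$models

#' @describeIn compare_models One-row summary: best model by AUC and the
#'   smallest pairwise DeLong p-value.
#' @export
glance.cg_roccomp <- function(x, ...) {
  tibble(n_models = nrow(x$models),
         best_model = x$models$model[which.max(x$models$auc)],
         best_auc = max(x$models$auc),
         min_delong_p = min(x$pairwise$p_value))
}
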