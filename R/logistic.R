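#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (via [stats::glm()]), with strict convergence control, explicit
#' complete-case handling, and detection of rank deficiency and complete
#' separation. This is the single fitting routine used by every modelling
#' stage of the package.
#'
#' @param formula A model formula whose response is the binary outcome.
#' @param data A data frame; rows with a missing value in any model term are
#'   dropped (complete-case analysis, reported in `n_used`).
#' @return An object of class `cg_logit`: the underlying `glm` fit plus
#'   `loglik`, `k` (number of estimated parameters), `aic = 2k - 2 loglik`,
#'   `n_used`, `converged` and `separation` flags. Supports [tidy()] (with
#'   odds ratios and Wald 95% CIs) and [glance()].
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = na.omit)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) {
    abort("response takes a single value among complete cases")
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) &&
    max(abs(coef(fit))) > 10
  if (sep) warn("possible complete separation: coefficient estimates diverge")
  ll <- as.numeric(logLik(fit))
  k <- length(coef(fit))
  structure(
    list(fit = fit, coefficients = coef(fit), vcov = vcov(fit),
         loglik = ll, k = k, aic = 2 * k - 2 * ll,
         n_used = stats::nobs(fit), converged = fit$converged,
         separation = sep, formula = formula),
    class = "cg_logit"
  )
}

#' @export
print.cg_logit <- function(x, ...) {
  cat("<cg_logit> logistic fit:", deparse(x$formula), "\n")
  cat("  n =", x$n_used, " k =", x$k,
      " logLik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\n")
  if (x$separation) cat("  WARNING: possible complete separation\n")
  invisible(x)
}

#' @describeIn fit_logistic Coefficient table with odds ratios and Wald 95%
#'   confidence intervals.
#' @param x A `cg_logit` object.
#' @param ... Unused.
#' @export
tidy.cg_logit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(0.975)
  tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(est / se)),
    or = exp(unname(est)),
    or_low = exp(unname(est - z * se)),
    or_high = exp(unname(est + z * se))
  )
}

#' @describeIn fit_logistic One-row model summary.
#' @export
glance.cg_logit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, df = x$k, nobs = x$n_used,
         converged = x$converged, separation = x$separation)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' Covariate-adjusted SNP p-values are obtained by comparing the model with
#' SNP terms plus covariates against the covariates-only model on the same
#' subjects.
#'
#' @param fit_full,fit_reduced `cg_logit` fits; `fit_reduced` must be nested
#'   in `fit_full` and fitted on the same subject set.
#' @return A list with `lr` (the statistic `2 * delta logLik`), `df` and
#'   `p_value`.
#' @export
adjusted_lrt_p <- function(fit_full, fit_reduced) {
  if (fit_full$n_used != fit_reduced$n_used) {
    abort("fits use different subject sets; LRT undefined")
  }
  df <- fit_full$k - fit_reduced$k
  if (df < 0) abort("full model has fewer parameters than reduced model")
  lr <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) 1 else pchisq(lr, df = df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p)
}

#' Crude odds ratio from a 2x2 table
#'
#' @param a Unexposed controls.
#' @param b Exposed controls.
#' @param c Unexposed cases.
#' @param d Exposed cases.
#' @param conf_level Confidence level of the Wald interval on the log-odds
#'   scale.
#' @return A list with `or = (d/c) / (b/a)`, Wald CI bounds `or_low` /
#'   `or_high`, and `estimable` (FALSE when a cell is zero, in which case
#'   the OR is `NA`).
#' @export
#' @examples
#' odds_ratio_2x2(361, 198, 218, 2227)  # crude OR ~ 18.6
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("negative cell count")
  if (any(cells == 0)) {
    return(list(or = NA_real_, or_low = NA_real_, or_high = NA_real_,
                estimable = FALSE))
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or), or_low = exp(log_or - z * se),
       or_high = exp(log_or + z * se), estimable = TRUE)
}

# ---- fast aggregated logistic likelihood --------------------------------
# IRLS on grouped binomial data (k successes of n trials per design row).
# Used by the permutation test, where each permutation only changes the
# per-genotype-class case counts. Log-likelihood omits the binomial
# coefficient (constant across models on the same data).
irls_binom_loglik <- function(X, k, n, tol = 1e-10, maxit = 50) {
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- n * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (k - n * mu) / w
    beta <- solve(crossprod(X, w * X), crossprod(X, w * z))
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(k * log(mu) + (n - k) * log1p(-mu))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ll
}

# Intercept-only grouped binomial log-likelihood (closed form).
null_binom_loglik <- function(k_tot, n_tot) {
  p <- k_tot / n_tot
  if (p == 0 || p == 1) return(0)
  k_tot * log(p) + (n_tot - k_tot) * log1p(-p)
}
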