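#' Two-locus genotype table
#'
#' Cross-tabulates effect-allele dosages at two SNPs over jointly non-missing
#' subjects.
#'
#' @param gm A genotype matrix.
#' @param snp1,snp2 SNP ids.
#' @return A 3x3 integer matrix: rows dosage at `snp1` (0/1/2), columns
#'   dosage at `snp2`.
#' @export
two_locus_table <- function(gm, snp1, snp2) {
  d1 <- gm[[snp1]]; d2 <- gm[[snp2]]
  ok <- !is.na(d1) & !is.na(d2)
  table(factor(d1[ok], levels = 0:2), factor(d2[ok], levels = 0:2))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Estimates the four haplotype frequencies (effect/effect, effect/other,
#' other/effect, other/other) from unphased genotype counts by
#' expectation-maximization. Only the double heterozygote is
#' phase-ambiguous; all other cells contribute known haplotype counts.
#' Initialization is at linkage equilibrium (the product of allele
#' frequencies), and the observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param tab A 3x3 two-locus genotype count table ([two_locus_table()]).
#' @param tol Convergence threshold on the maximum haplotype-frequency
#'   change (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A list: `freq` (named frequencies `h11`, `h10`, `h01`, `h00`
#'   where 1 marks the effect allele), `D`, `d_prime`, `r2`,
#'   `loglik_trace`, `n_iter`, `converged`, `defined` (FALSE for a
#'   monomorphic locus) and `phase_indeterminate` (TRUE when every subject
#'   is doubly heterozygous, where the likelihood is bimodal).
#' @export
em_haplotypes <- function(tab, tol = 1e-8, max_iter = 1000) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3, 3)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) abort("empty two-locus table")
  pA <- sum(tab * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * n)  # locus 1
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)   # locus 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(freq = c(h11 = NA, h10 = NA, h01 = NA, h00 = NA),
                D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                loglik_trace = numeric(0), n_iter = 0L, converged = FALSE,
                defined = FALSE, phase_indeterminate = FALSE))
  }
  # fixed haplotype contributions of unambiguous cells:
  # cell (i, j) = dosages (i, j); haplotypes per subject = 2.
  # counts of h11, h10, h01, h00 from all cells except (1,1) double het.
  fixed <- c(h11 = 0, h10 = 0, h01 = 0, h00 = 0)
  for (i in 0:2) for (j in 0:2) {
    cnt <- tab[i + 1, j + 1]
    if (cnt == 0 || (i == 1 && j == 1)) next
    # each subject carries two haplotypes with known allele assignment
    # split dosage into the two haplotypes (unique for non-double-hets)
    h <- hap_pair(i, j)
    fixed[h[1]] <- fixed[h[1]] + cnt
    fixed[h[2]] <- fixed[h[2]] + cnt
  }
  n_dh <- tab[2, 2]
  f <- c(h11 = pA * pB, h10 = pA * (1 - pB), h01 = (1 - pA) * pB,
         h00 = (1 - pA) * (1 - pB))
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: double heterozygotes resolve as (h11,h00) or (h10,h01)
    p_cis <- f["h11"] * f["h00"]
    p_trans <- f["h10"] * f["h01"]
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    e <- fixed
    e["h11"] <- e["h11"] + n_dh * w
    e["h00"] <- e["h00"] + n_dh * w
    e["h10"] <- e["h10"] + n_dh * (1 - w)
    e["h01"] <- e["h01"] + n_dh * (1 - w)
    f_new <- e / sum(e)
    ll_trace <- c(ll_trace, hap_loglik(tab, f_new))
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
    if (iter >= max_iter) break
  }
  pA_hat <- f[["h11"]] + f[["h10"]]
  pB_hat <- f[["h11"]] + f[["h01"]]
  D <- f[["h11"]] - pA_hat * pB_hat
  denom <- pA_hat * (1 - pA_hat) * pB_hat * (1 - pB_hat)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  dmax <- if (D >= 0) min(pA_hat * (1 - pB_hat), (1 - pA_hat) * pB_hat)
  else min(pA_hat * pB_hat, (1 - pA_hat) * (1 - pB_hat))
  d_prime <- if (dmax > 0) D / dmax else NA_real_
  list(freq = f, D = D, d_prime = d_prime, r2 = r2,
       loglik_trace = ll_trace, n_iter = iter, converged = converged,
       defined = TRUE,
       phase_indeterminate = n_dh == n)
}

# haplotype pair names for an unambiguous dosage combination
hap_pair <- function(i, j) {
  a <- c(rep(1, i), rep(0, 2 - i))   # locus-1 alleles of the two haplotypes
  b <- c(rep(1, j), rep(0, 2 - j))
  # for non-double-hets at least one locus is homozygous, so pairing is unique
  paste0("h", a, b)
}

# observed-data multinomial log-likelihood of a 3x3 genotype table given
# haplotype frequencies (random mating)
hap_loglik <- function(tab, f) {
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    cnt <- tab[i + 1, j + 1]
    if (cnt == 0) next
    ll <- ll + cnt * log(genotype_prob(i, j, f))
  }
  ll
}

genotype_prob <- function(i, j, f) {
  p <- 0
  haps <- expand.grid(a1 = 0:1, b1 = 0:1, a2 = 0:1, b2 = 0:1)
  sel <- haps$a1 + haps$a2 == i & haps$b1 + haps$b2 == j
  for (r in which(sel)) {
    p <- p + f[[paste0("h", haps$a1[r], haps$b1[r])]] *
      f[[paste0("h", haps$a2[r], haps$b2[r])]]
  }
  max(p, 1e-300)
}

#' LD statistics from a haplotype estimate
#'
#' @param est An [em_haplotypes()] estimate.
#' @param n Number of subjects (2n gametes).
#' @return A list with `r2`, `chisq_stat = 2 n r2` and the 1-df chi-square
#'   `p_value`.
#' @export
ld_r2 <- function(est, n) {
  if (!isTRUE(est$defined)) {
    return(list(r2 = NA_real_, chisq_stat = NA_real_, p_value = NA_real_))
  }
  stat <- 2 * n * est$r2
  list(r2 = est$r2, chisq_stat = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' All-pairs linkage disequilibrium scan
#'
#' Computes EM haplotype frequencies, r-squared, D-prime and the chi-square
#' LD test for every unordered SNP pair, on the pooled sample.
#'
#' @param gm A genotype matrix.
#' @param snps SNP ids to scan (default: all; at least 2).
#' @param r2_threshold,p_threshold Thresholds for the `in_ld` flag.
#' @return A tibble of class `cg_ld`: `snp1`, `snp2`, `n`, `r2`, `d_prime`,
#'   `chisq`, `p_value`, `in_ld`.
#' @export
ld_scan <- function(gm, snps = snp_ids(gm), r2_threshold = 0.5,
                    p_threshold = 0.05) {
  if (length(snps) < 2) abort("need at least two SNPs")
  prs <- combn(snps, 2)
  rows <- map(seq_len(ncol(prs)), function(k) {
    s1 <- prs[1, k]; s2 <- prs[2, k]
    tab <- two_locus_table(gm, s1, s2)
    est <- tryCatch(em_haplotypes(tab), error = function(e) NULL)
    if (is.null(est) || !isTRUE(est$defined)) {
      return(tibble(snp1 = s1, snp2 = s2, n = sum(tab), r2 = NA_real_,
                    d_prime = NA_real_, chisq = NA_real_,
                    p_value = NA_real_, in_ld = NA))
    }
    ld <- ld_r2(est, sum(tab))
    tibble(snp1 = s1, snp2 = s2, n = sum(tab), r2 = ld$r2,
           d_prime = est$d_prime, chisq = ld$chisq_stat,
           p_value = ld$p_value,
           in_ld = ld$r2 >= r2_threshold & ld$p_value < p_threshold)
  })
  out <- bind_rows(rows)
  structure(out, class = c("cg_ld", class(out)))
}

#' Pairwise haplotype-structure assessment
#'
#' For given SNP pairs reports EM haplotype frequencies, D-prime, r-squared
#' and the chi-square LD p-value, plus a `supported` flag: haplotype
#' structure is called supported when the LD test rejects at `alpha` and
#' |D'| exceeds `d_prime_threshold`. This flag is an explicit operational
#' criterion of this package (qualitative haplotype calls have no single
#' standard rule).
#'
#' @param gm A genotype matrix.
#' @param pairs A data frame with columns `snp1`, `snp2` (e.g. flagged rows
#'   of [ld_scan()]).
#' @param alpha LD-test significance level.
#' @param d_prime_threshold Minimum |D'| (default 0.7).
#' @return A tibble: pair, `n`, haplotype frequencies, `d_prime`, `r2`,
#'   `p_value`, `supported` (`NA` when LD is undefined).
#' @export
haplotype_assessment <- function(gm, pairs, alpha = 0.05,
                                 d_prime_threshold = 0.7) {
  pmap(pairs[c("snp1", "snp2")], function(snp1, snp2) {
    tab <- two_locus_table(gm, snp1, snp2)
    est <- em_haplotypes(tab)
    if (!isTRUE(est$defined)) {
      return(tibble(snp1 = snp1, snp2 = snp2, n = sum(tab),
                    h11 = NA_real_, h10 = NA_real_, h01 = NA_real_,
                    h00 = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                    p_value = NA_real_, supported = NA))
    }
    ld <- ld_r2(est, sum(tab))
    tibble(snp1 = snp1, snp2 = snp2, n = sum(tab),
           h11 = est$freq[["h11"]], h10 = est$freq[["h10"]],
           h01 = est$freq[["h01"]], h00 = est$freq[["h00"]],
           d_prime = est$d_prime, r2 = est$r2, p_value = ld$p_value,
           supported = ld$p_value < alpha &
             abs(est$d_prime) >= d_prime_threshold)
  }) %>% bind_rows()
}
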