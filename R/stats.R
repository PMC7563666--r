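# Core per-site statistics: two-sided Fisher's exact test on a 2x2 table and
# the Weir-Cockerham (1984) two-group theta from diploid genotype counts.

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Computes the exact two-sided p-value by the "method of small p-values":
#' the sum of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table. This is
#' the convention used by the classic genome-scan tools this package mirrors
#' (and by [stats::fisher.test()]); a relative tie guard of 1e-7 absorbs
#' floating-point ties on the boundary.
#'
#' @param a,b first row of the table (e.g. ref/alt allele counts in females).
#' @param c,d second row (e.g. ref/alt allele counts in males).
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fet_2x2(10, 0, 0, 10)   # 2 / choose(20, 10)
#' @export
fet_2x2 <- function(a, b, c, d) {
  stop_if(any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))),
          "counts must be non-negative integers")
  r1 <- a + b
  c1 <- a + c
  total <- a + b + c + d
  if (total == 0L || r1 == 0L || r1 == total || c1 == 0L || c1 == total)
    return(1)
  support <- max(0, r1 + c1 - total):min(r1, c1)
  probs <- stats::dhyper(support, c1, total - c1, r1)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Weir-Cockerham theta for two groups from diploid genotype counts
#'
#' Per-site FST estimator (theta-hat) of Weir & Cockerham (1984) for r = 2
#' sampled groups (here: phenotypic males vs females), computed from sample
#' sizes, alternate-allele frequencies and observed heterozygote frequencies.
#' The estimate can be slightly negative by sampling; it is returned
#' unclamped. When all variance components vanish (monomorphic site) the
#' estimator is undefined and `NA` is returned; reporting layers display 0.
#'
#' @param n vector of 2 sample sizes (diploid individuals with calls).
#' @param p vector of 2 alternate-allele sample frequencies.
#' @param h vector of 2 observed heterozygote frequencies.
#' @return theta-hat, or `NA_real_` for an undefined (monomorphic) site.
#' @export
wc_theta <- function(n, p, h) {
  stop_if(length(n) != 2L || length(p) != 2L || length(h) != 2L,
          "wc_theta expects exactly two groups")
  if (any(n == 0)) return(NA_real_)
  r <- 2
  nbar <- mean(n)
  if (nbar <= 1) return(NA_real_)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

#' Chi-square test of an observed sex ratio against 1:1
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed male/female
#' counts against equal expectation, without continuity correction -- the
#' standard progeny-sex-ratio test for fish families.
#'
#' @param n_males,n_females observed counts.
#' @return list with `chisq`, `p`, and `prop_males`.
#' @examples
#' sex_ratio_test(55, 45)  # chisq = 1, p ~ 0.317
#' @export
sex_ratio_test <- function(n_males, n_females) {
  n_males <- check_count(n_males, "n_males", min = 0L)
  n_females <- check_count(n_females, "n_females", min = 0L)
  total <- n_males + n_females
  stop_if(total == 0L, "no individuals")
  expected <- total / 2
  chisq <- (n_males - expected)^2 / expected +
    (n_females - expected)^2 / expected
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       prop_males = n_males / total)
}
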