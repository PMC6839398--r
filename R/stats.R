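#' Standard error of a proportion
#'
#' SE of a counted proportion: sqrt(p(1-p)/n) with p = k/n. The error bar
#' attached to every proportional measure in this package.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @return the standard error (vectorized over k, n).
#' @export
se_proportion <- function(k, n) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  p <- k / n
  sqrt(p * (1 - p) / n)
}

#' Two-proportions Z-test (pooled variance)
#'
#' Two-tailed Z-test for the difference of two proportions using the pooled
#' variance estimate, with Yates continuity correction on by default: the
#' absolute difference is reduced by (1/n1 + 1/n2)/2, floored at zero.
#' When the pooled sample is all-success or all-failure the variance is
#' zero; p = 1 is returned by convention with a flag.
#'
#' @param k1,n1,k2,n2 successes and trials of the two samples.
#' @param continuity apply the Yates correction.
#' @return list: z, p, estimate (p1 - p2), degenerate (zero-variance flag).
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2, continuity = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("both sample sizes must be > 0")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts must lie in [0, n]")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1)
    return(list(z = 0, p = 1, estimate = p1 - p2, degenerate = TRUE))
  d <- abs(p1 - p2)
  if (continuity) d <- max(0, d - (1 / n1 + 1 / n2) / 2)
  z <- d / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = sign(p1 - p2) * z, p = 2 * pnorm(-abs(z)), estimate = p1 - p2,
       degenerate = FALSE)
}

#' One-sample Z-test of a proportion
#'
#' Tests p-hat = k/n against a null value p0 with the null-variance
#' standard error: z = (p-hat - p0) / sqrt(p0 (1 - p0) / n), two-tailed.
#'
#' @param k successes; `n` trials; `p0` null proportion in (0, 1).
#' @param n,p0 see above.
#' @return list: z, p, estimate.
#' @export
one_sample_ztest <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be > 0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be inside (0, 1)")
  ph <- k / n
  z <- (ph - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p = 2 * pnorm(-abs(z)), estimate = ph)
}

#' Exact two-tailed binomial test
#'
#' Exact binomial test with the minimum-likelihood two-tailed definition:
#' the p-value sums the probabilities of all outcomes no more likely than
#' the observed count. A doubled-one-tail alternative is available.
#'
#' @param k observed successes; `n` trials; `p0` null probability.
#' @param n,p0 see above.
#' @param method "min_likelihood" (default) or "double_tail".
#' @return the two-tailed p-value.
#' @export
binomial_test_two_tailed <- function(k, n, p0 = 0.5,
                                     method = c("min_likelihood", "double_tail")) {
  method <- match.arg(method)
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (method == "min_likelihood") {
    binom.test(k, n, p0)$p.value
  } else {
    lo <- pbinom(k, n, p0)
    hi <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }
}

#' @importFrom stats pbinom
NULL

#' Holm (step-down Bonferroni) multiple-testing correction
#'
#' Step-down Holm adjustment with monotonicity enforcement, plus rejection
#' flags at `alpha` based on the adjusted values.
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha familywise error rate for the flags.
#' @return list: p_adjusted (same order as input), reject (logical).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "holm")
  list(p_adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-tailed rank-sum test: exact null distribution when the combined
#' sample is small (<= `exact_max`) and tie-free, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max combined-size limit for the exact null distribution.
#' @return list: statistic (W), p, exact (logical).
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 20) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # zero rank variance (e.g. identical constants)
  list(statistic = unname(wt$statistic), p = p, exact = use_exact)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the two empirical CDFs with the asymptotic
#' two-tailed p-value.
#'
#' @param a,b numeric samples (non-empty).
#' @return list: statistic (D), p.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
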