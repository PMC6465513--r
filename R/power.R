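#' Analytic power of the omnibus fixed-effects ANOVA interaction test
#'
#' Power of the level-`alpha` one-way fixed-effects ANOVA with `n_groups`
#' cells (default 6 = 2 sexes x 3 genotype classes) and Cohen's effect size
#' `f`, using the noncentral-F formulation: the test statistic under the
#' alternative is noncentral F with `df1 = n_groups - 1`,
#' `df2 = n_total - n_groups` and noncentrality \eqn{\lambda = f^2 N}; power
#' is the probability it exceeds the central-F critical value. This is the
#' classical sample-size calculator convention for an interaction contrast
#' treated as a cell-means ANOVA without covariates; for the full regression
#' with covariates it is an upper bound on attainable power.
#'
#' @param effect_size_f Cohen's f (>= 0). Vectorized.
#' @param n_total Total sample size.
#' @param n_groups Number of cells (default 6).
#' @param alpha Test level (default 0.05).
#' @return Power in `[alpha, 1]`; exactly `alpha` at `f = 0`.
#' @export
#' @examples
#' anova_power(c(0.1, 0.2), n_total = 334)   # approx. 0.24 and 0.81
anova_power <- function(effect_size_f, n_total, n_groups = 6, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (any(effect_size_f < 0)) stop("`effect_size_f` must be >= 0", call. = FALSE)
  if (n_total <= n_groups)
    stop("`n_total` must exceed `n_groups`", call. = FALSE)
  df1 <- n_groups - 1
  df2 <- n_total - n_groups
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = effect_size_f^2 * n_total,
            lower.tail = FALSE)
}

#' Analytic power to detect a single eQTL
#'
#' Power of the two-sided level-`alpha` t-test of the genotype slope in a
#' simple linear regression of expression on dosage, for `n` samples and a
#' variant at minor allele frequency `maf`. Under Hardy-Weinberg equilibrium
#' the dosage variance is \eqn{2\,maf\,(1 - maf)}, giving noncentrality
#' \deqn{\delta = \frac{slope \sqrt{n \cdot 2\,maf\,(1 - maf)}}{\sigma}}
#' and power from the noncentral t distribution with `n - 2` degrees of
#' freedom (no normal approximation: per-sex eQTL cohorts are moderate).
#'
#' @param maf Minor allele frequency in (0, 0.5]. Vectorized (as are `n`,
#'   `slope`).
#' @param n Sample size of the analysis (e.g. one sex stratum).
#' @param slope Expression change per alternate allele.
#' @param sigma Residual standard deviation (> 0, default 1).
#' @param alpha Test level (default 0.05).
#' @return Power in `[alpha, 1]`; exactly `alpha` at `slope = 0`.
#' @export
#' @examples
#' eqtl_power(maf = c(0.05, 0.15, 0.3), n = 160, slope = 0.5)
eqtl_power <- function(maf, n, slope, sigma = 1, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (any(maf <= 0 | maf > 0.5))
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (any(n <= 2)) stop("`n` must exceed 2", call. = FALSE)
  df <- n - 2
  ncp <- slope * sqrt(n * 2 * maf * (1 - maf)) / sigma
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) +
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
}
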