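## Validation-panel statistics: Hardy-Weinberg expected genotype
## proportions, a squared-deviance statistic on genotype frequencies, and
## its Monte-Carlo randomization test.
##
## Genotype classes are ordered (PP, PC, CC): homozygote for the focal
## ("partial") allele, heterozygote, homozygote for the other ("complete")
## allele. `p` is always the focal-allele frequency.

#' Hardy-Weinberg expected genotype proportions
#'
#' @param p focal-allele frequency in \[0, 1\].
#' @return numeric triple `(p^2, 2p(1-p), (1-p)^2)` named PP, PC, CC;
#'   sums to 1.
#' @export
#' @examples
#' hwe_expected(0.5)
#' hwe_expected(0.583)
hwe_expected <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    validation_error("allele frequency p must be a single value in [0, 1]")
  c(PP = p^2, PC = 2 * p * (1 - p), CC = (1 - p)^2)
}

## coerce observed genotype counts to a validated (PP, PC, CC) triple
as_genotype_counts <- function(obs) {
  if (!is.numeric(obs) || length(obs) != 3L || anyNA(obs))
    validation_error("genotype counts must be a numeric triple (PP, PC, CC)")
  if (any(obs < 0) || any(obs != round(obs)))
    validation_error("genotype counts must be non-negative integers")
  if (!is.null(names(obs)) && all(c("PP", "PC", "CC") %in% names(obs)))
    obs <- obs[c("PP", "PC", "CC")]
  setNames(as.numeric(obs), c("PP", "PC", "CC"))
}

#' Genotype-frequency deviance from an expectation
#'
#' The test statistic: the sum over the three genotype classes of the
#' squared difference between observed and expected genotype FREQUENCIES
#' (proportions, not counts), so the statistic is invariant to scaling all
#' counts.
#'
#' @param obs observed genotype counts `(PP, PC, CC)`, summing to the panel
#'   size `n > 0`.
#' @param expected expected genotype proportions, e.g. [hwe_expected()].
#' @return deviance `D >= 0`.
#' @export
genotype_deviance <- function(obs, expected) {
  obs <- as_genotype_counts(obs)
  n <- sum(obs)
  if (n == 0) validation_error("panel size is zero")
  if (length(expected) != 3L || abs(sum(expected) - 1) > 1e-9)
    validation_error("expected proportions must be a triple summing to 1")
  sum((obs / n - expected)^2)
}

#' Monte-Carlo randomization test of the genotype deviance
#'
#' Evaluates the observed deviance of a diploid panel against a null
#' distribution built by drawing `n_iter` random panels of the same size:
#' each individual receives two independent alleles that are the focal
#' allele with probability `p` (random mating at the population frequency),
#' and each random panel's deviance from the Hardy-Weinberg expectation at
#' `p` is computed. The p-value is the add-one upper-tail exceedance
#' estimate `(1 + #\{D_null >= D_obs\}) / (1 + n_iter)`, never smaller than
#' `1/(n_iter + 1)`; the percentile is `100 * #\{D_null < D_obs\} / n_iter`.
#'
#' The deviance is non-negative, so departure from HWE in any direction
#' inflates it and the upper tail is the only informative one; the tail
#' convention is recorded in the result.
#'
#' @inheritParams genotype_deviance
#' @param p population frequency of the focal allele, in (0, 1).
#' @param n_iter number of random panels.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return an object of class `mc_result`: list with `observed_deviance`,
#'   `p_value`, `percentile`, `n_iter`, `seed`, `tail`, `expected`, `n`.
#' @export
mc_deviance_test <- function(obs, p, n_iter = 9999, seed = NULL) {
  obs <- as_genotype_counts(obs)
  if (n_iter < 1) config_error("n_iter must be >= 1")
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    validation_error("p must lie strictly inside (0, 1)")
  n <- sum(obs)
  if (n == 0) validation_error("panel size is zero")
  expected <- hwe_expected(p)
  d_obs <- genotype_deviance(obs, expected)
  d_null <- with_seed(seed, {
    draws <- rmultinom(n_iter, n, expected)   # HWE trinomial per panel
    colSums((draws / n - expected)^2)
  })
  structure(list(
    observed_deviance = d_obs,
    p_value = (1 + sum(d_null >= d_obs)) / (1 + n_iter),
    percentile = 100 * sum(d_null < d_obs) / n_iter,
    n_iter = as.integer(n_iter),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    tail = "upper",
    expected = expected,
    n = as.integer(n),
    null_deviances = d_null),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Monte-Carlo HWE deviance test (n = %d, %d iterations, %s tail)\n",
    "  observed deviance: %.6g\n  percentile of null: %.1f\n",
    "  p-value: %.4g\n"),
    x$n, x$n_iter, x$tail, x$observed_deviance, x$percentile, x$p_value))
  invisible(x)
}
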