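#' Fixed-effect inverse-variance pooling
#'
#' Pools independent log-odds-ratio estimates (typically one per state) with
#' weights `w_k = 1/se_k^2`:
#' `beta_pooled = sum(w_k beta_k) / sum(w_k)`, `se_pooled = sum(w_k)^(-1/2)`.
#'
#' @param estimates Data frame with columns `beta` and `se` (all `se > 0`),
#'   one row per estimate.
#' @param level Confidence level for the pooled OR; default 0.95.
#' @return One-row tibble: `beta`, `se`, `or`, `lcl`, `ucl`, `k`.
#' @export
ivw_pool <- function(estimates, level = 0.95) {
  estimates <- as_tibble(estimates)
  beta <- estimates$beta
  se <- estimates$se
  if (length(beta) < 1) abort("need at least one estimate")
  if (any(is.na(se)) || any(se <= 0)) abort("all se must be positive")
  k <- length(beta)
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  ci <- wald_ci(bp, sp, level = level)
  tibble(beta = bp, se = sp, or = ci$or, lcl = ci$lcl, ucl = ci$ucl, k = k)
}

#' Two-group heterogeneity Z-test
#'
#' Compares two pooled estimates (e.g. the low- and high-deprivation strata):
#' `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)`, with a two-sided normal
#' p-value.
#'
#' @param beta_a,se_a Estimate and standard error of the first group.
#' @param beta_b,se_b Estimate and standard error of the second group.
#' @return One-row tibble with `z`, `p`.
#' @export
heterogeneity_z <- function(beta_a, se_a, beta_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  z <- (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Wald heterogeneity test across k strata
#'
#' Tests equality of `k >= 2` independent estimates with the inverse-variance
#' Wald statistic `chi2 = sum w_k (beta_k - beta_pooled)^2`, `w_k = 1/se_k^2`,
#' referred to a chi-square distribution with `k - 1` degrees of freedom. At
#' `k = 2` the statistic equals the square of the [heterogeneity_z()] score.
#'
#' @param estimates Data frame with columns `beta` and `se`, `k >= 2` rows.
#' @return One-row tibble with `chi2`, `df`, `p`.
#' @export
heterogeneity_wald <- function(estimates) {
  estimates <- as_tibble(estimates)
  beta <- estimates$beta
  se <- estimates$se
  if (length(beta) < 2) abort("heterogeneity test needs at least 2 estimates")
  if (any(is.na(se)) || any(se <= 0)) abort("all se must be positive")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  chi2 <- sum(w * (beta - bp)^2)
  df <- length(beta) - 1
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
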