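# Conditional simulation of split GWAS summary statistics.
#
# Conditional on the observed full-sample estimates, the estimates that a
# GWAS on a random pi1-fraction of the sample would have produced follow,
# per variant, a bivariate normal centred at the observed estimates with
# covariance ((1 - pi1)/pi1) * Sigma, where Sigma is the full-sample error
# covariance [[se_x^2, lam*se_x*se_y], [lam*se_x*se_y, se_y^2]]. The
# complement fraction's estimates are then recovered algebraically, and a
# second conditional draw subdivides the complement for the 3-split mode.
# Draws are independent across variants (LD-pruned input).

# one correlated bivariate normal draw per variant; exact at |lam| = 1
draw_correlated_noise <- function(n, lam) {
  lam <- clamp(lam, -1, 1)
  e1 <- rnorm(n)
  e2 <- lam * e1 + sqrt(1 - lam^2) * rnorm(n)
  list(e1 = e1, e2 = e2)
}

#' Simulate selection-split association estimates
#'
#' Draws, for each variant, the exposure and outcome association estimates
#' that a GWAS on a hypothetical random `pi1`-fraction of the sample would
#' have produced, conditional on the observed full-sample estimates.
#'
#' @param pair A [summary_pair] (or data frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param lambda Cross-study error correlation.
#' @param pi1 Fraction of the sample allocated to the selection split,
#'   strictly inside (0, 1).
#' @return A tibble with columns `bx1`, `by1` (split estimates) and
#'   `se_x1`, `se_y1` (their unconditional standard errors,
#'   `se/sqrt(pi1)`).
#' @export
draw_first_split <- function(pair, lambda, pi1 = 0.5) {
  stopifnot(pi1 > 0, pi1 < 1, abs(lambda) <= 1)
  k <- sqrt((1 - pi1) / pi1)
  e <- draw_correlated_noise(nrow(pair), lambda)
  tibble::tibble(
    bx1 = pair$beta_x + k * pair$se_x * e$e1,
    by1 = pair$beta_y + k * pair$se_y * e$e2,
    se_x1 = pair$se_x / sqrt(pi1),
    se_y1 = pair$se_y / sqrt(pi1)
  )
}

#' Reconstruct complement-split estimates
#'
#' Given simulated selection-split estimates, the estimates of the
#' complementary `(1 - pi1)`-fraction follow by asymptotic linearity:
#' `bx2 = (beta_x - pi1 * bx1) / (1 - pi1)` (identically for the outcome),
#' with standard errors scaled by `1/sqrt(1 - pi1)`. The weighted identity
#' `pi1 * bx1 + (1 - pi1) * bx2 = beta_x` holds exactly, and `(bx1, by1)`
#' and `(bx2, by2)` are independent, mimicking disjoint subsamples.
#'
#' @inheritParams draw_first_split
#' @param split1 The tibble returned by [draw_first_split()].
#' @return A tibble with columns `bx2`, `by2`, `se_x2`, `se_y2`.
#' @export
complement_estimates <- function(pair, split1, pi1 = 0.5) {
  stopifnot(pi1 > 0, pi1 < 1, nrow(split1) == nrow(pair))
  tibble::tibble(
    bx2 = (pair$beta_x - pi1 * split1$bx1) / (1 - pi1),
    by2 = (pair$beta_y - pi1 * split1$by1) / (1 - pi1),
    se_x2 = pair$se_x / sqrt(1 - pi1),
    se_y2 = pair$se_y / sqrt(1 - pi1)
  )
}

#' Simulate the second split of the complement fraction
#'
#' For the 3-split mode the `(1 - pi1)`-fraction is further subdivided:
#' exposure estimates are drawn for a `pi2` sub-fraction by a second
#' conditional draw (same form as the first, applied to the complement
#' estimates), and outcome estimates for the remaining `(1 - pi2)`
#' sub-fraction are recovered algebraically. The returned exposure and
#' outcome statistics mimic two disjoint samples, which restores the
#' independence assumed by two-sample MR estimators even under full
#' exposure/outcome sample overlap.
#'
#' @param split2 The tibble returned by [complement_estimates()].
#' @param lambda Cross-study error correlation.
#' @param pi1,pi2 Split fractions in (0, 1); `pi2` subdivides the
#'   complement.
#' @return A tibble with columns `bx2a`, `by2b` and their standard errors
#'   `se_x2a = se_x/sqrt(pi2 (1 - pi1))`,
#'   `se_y2b = se_y/sqrt((1 - pi2)(1 - pi1))`.
#' @export
draw_second_split <- function(split2, lambda, pi1 = 0.5, pi2 = 0.5) {
  stopifnot(pi2 > 0, pi2 < 1, abs(lambda) <= 1)
  k <- sqrt((1 - pi2) / pi2)
  e <- draw_correlated_noise(nrow(split2), lambda)
  bx2a <- split2$bx2 + k * split2$se_x2 * e$e1
  by2a <- split2$by2 + k * split2$se_y2 * e$e2
  tibble::tibble(
    bx2a = bx2a,
    by2b = (split2$by2 - pi2 * by2a) / (1 - pi2),
    se_x2a = split2$se_x2 / sqrt(pi2),
    se_y2b = split2$se_y2 / sqrt(1 - pi2)
  )
}

#' Select instruments from selection-split z-statistics
#'
#' @param bx1,se_x1 Selection-split exposure estimates and their standard
#'   errors.
#' @param alpha Two-sided significance threshold (default genome-wide,
#'   5e-8, i.e. |z| > 5.451...).
#' @return Integer indices of the selected variants (possibly empty).
#' @export
select_instruments <- function(bx1, se_x1, alpha = 5e-8) {
  stopifnot(all(se_x1 > 0), alpha > 0, alpha <= 1)
  if (alpha == 1) return(seq_along(bx1))
  which(abs(bx1) / se_x1 > z_threshold(alpha))
}
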