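#' Cross-study error-correlation model
#'
#' When the exposure and outcome GWASs share participants, the estimation
#' errors of `beta_x` and `beta_y` for the same variant are correlated with
#' correlation `lambda = n_overlap * rho / sqrt(n_x * n_y)`, where `rho` is
#' the phenotypic exposure-outcome correlation (possibly non-zero through
#' confounding). `overlap_model()` builds this from the study design;
#' alternatively supply `lambda` directly, or leave everything unset and
#' let [mr_simss()] estimate it from null variants via [estimate_lambda()].
#'
#' @param n_x,n_y Exposure and outcome GWAS sample sizes.
#' @param n_overlap Number of shared participants (defaults to 0).
#' @param rho Exposure-outcome correlation in the overlapping sample.
#' @param lambda Directly supplied error correlation; overrides
#'   `n_overlap`/`rho` when given.
#' @return A list of class `overlap_model` with elements `n_x`, `n_y`,
#'   `n_overlap`, `rho` and `lambda` (NA when it must be estimated).
#' @export
#' @examples
#' overlap_model(200000, 200000, n_overlap = 100000, rho = 0.5)
overlap_model <- function(n_x, n_y, n_overlap = NULL, rho = NULL,
                          lambda = NULL) {
  check_count(n_x, "n_x")
  check_count(n_y, "n_y")
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 1, is.finite(lambda), abs(lambda) <= 1)
    lam <- lambda
  } else if (!is.null(n_overlap) && !is.null(rho)) {
    lam <- lambda_from_design(n_overlap, rho, n_x, n_y)
  } else {
    lam <- NA_real_
  }
  structure(
    list(n_x = as.double(n_x), n_y = as.double(n_y),
         n_overlap = if (is.null(n_overlap)) NA_real_ else as.double(n_overlap),
         rho = if (is.null(rho)) NA_real_ else rho,
         lambda = lam),
    class = "overlap_model"
  )
}

#' @export
print.overlap_model <- function(x, ...) {
  cat(sprintf(
    "<overlap_model> n_x = %s, n_y = %s, n_overlap = %s, rho = %s, lambda = %s\n",
    format(x$n_x), format(x$n_y), format(x$n_overlap), format(x$rho),
    if (is.na(x$lambda)) "to be estimated" else format(x$lambda)
  ))
  invisible(x)
}

#' Error correlation implied by the study design
#'
#' @param n_overlap Shared participant count, at most `min(n_x, n_y)`.
#' @param rho Exposure-outcome correlation, in `[-1, 1]`.
#' @param n_x,n_y GWAS sample sizes.
#' @return `n_overlap * rho / sqrt(n_x * n_y)`.
#' @export
#' @examples
#' lambda_from_design(100000, 0.5, 200000, 200000) # 0.25
lambda_from_design <- function(n_overlap, rho, n_x, n_y) {
  stopifnot(length(n_overlap) == 1, length(rho) == 1, abs(rho) <= 1,
            n_overlap >= 0)
  if (n_overlap > min(n_x, n_y)) {
    abort("n_overlap cannot exceed min(n_x, n_y)",
          class = "mrsimss_design_error")
  }
  n_overlap * rho / sqrt(n_x * n_y)
}

# Correlation of a standard bivariate normal truncated to the central box
# [-c, c]^2, computed by Gauss-Legendre quadrature. Restricting both
# margins to the box attenuates the correlation (by ~0.76 at c = 1.96 for
# small lambda), so the raw null-set z correlation must be mapped back
# through this function to estimate lambda.
truncated_box_cor <- function(lambda, z_cut, n_nodes = 48) {
  gl <- gauss_legendre(n_nodes, -z_cut, z_cut)
  x <- gl$nodes
  w <- gl$weights
  if (abs(lambda) >= 1) return(sign(lambda))
  s <- sqrt(1 - lambda^2)
  # f(x, y) on the grid; integrate mass, E[XY], E[X^2]
  fy <- outer(x, x, function(xi, yi) {
    stats::dnorm(xi) * stats::dnorm((yi - lambda * xi) / s) / s
  })
  ww <- outer(w, w)
  mass <- sum(ww * fy)
  exy <- sum(ww * fy * outer(x, x))
  ex2 <- sum(ww * fy * outer(x^2, rep(1, length(x))))
  ey2 <- sum(ww * fy * outer(rep(1, length(x)), x^2))
  (exy / mass) / sqrt((ex2 / mass) * (ey2 / mass))
}

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * nodes + (a + b) / 2,
       weights = (b - a) / 2 * weights)
}

#' Estimate the cross-study error correlation from null variants
#'
#' For variants with no true effect on either trait, the z-statistics
#' `(beta_x/se_x, beta_y/se_y)` follow a standard bivariate normal with
#' correlation `lambda`. The estimator restricts to the observed null set
#' (both |z| below `z_cut`), computes the sample correlation there, and
#' inverts the known attenuation induced by that box truncation to recover
#' `lambda`. The truncation correction matters: the raw correlation over
#' the central 95% box underestimates `lambda` by roughly a quarter.
#'
#' @param pair A [summary_pair] (or any data frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param z_cut Two-sided z cutoff defining the null set (default 1.96).
#' @return A one-row tibble: `lambda` (clipped to `[-1, 1]`), `se` (delta
#'   method from the Fisher transform, propagated through the truncation
#'   map), `n_null` (variants used) and `z_cut`.
#' @export
estimate_lambda <- function(pair, z_cut = 1.96) {
  zx <- pair$beta_x / pair$se_x
  zy <- pair$beta_y / pair$se_y
  in_box <- abs(zx) < z_cut & abs(zy) < z_cut
  n_null <- sum(in_box)
  if (n_null < 500) {
    if (nrow(pair) < 50) {
      abort(paste(
        "fewer than 50 usable variants for lambda estimation;",
        "supply lambda (or n_overlap and rho) directly"
      ), class = "mrsimss_estimation_error")
    }
    warn("fewer than 500 null variants; estimating lambda from all variants")
    in_box <- rep(TRUE, length(zx))
    n_null <- length(zx)
    r <- clamp(cor(zx, zy), -1, 1)
    lam <- r
    deriv <- 1
  } else {
    r <- clamp(cor(zx[in_box], zy[in_box]), -1, 1)
    lam <- invert_truncation(r, z_cut)
    # local slope of the truncation map, for delta-method SE propagation
    h <- 1e-4
    lo <- clamp(lam - h, -1 + 1e-9, 1 - 1e-9)
    hi <- clamp(lam + h, -1 + 1e-9, 1 - 1e-9)
    dg <- (truncated_box_cor(hi, z_cut) - truncated_box_cor(lo, z_cut)) /
      (hi - lo)
    deriv <- 1 / max(dg, 1e-8)
  }
  se_r <- (1 - r^2) / sqrt(max(n_null - 3, 1))
  tibble::tibble(lambda = clamp(lam, -1, 1), se = deriv * se_r,
                 n_null = n_null, z_cut = z_cut)
}

invert_truncation <- function(r, z_cut) {
  if (abs(r) < 1e-12) return(0)
  f <- function(l) truncated_box_cor(l, z_cut) - r
  eps <- 1e-9
  if (f(sign(r) * (1 - eps)) * sign(r) < 0) return(sign(r))
  uniroot(f, lower = min(0, sign(r)) * (1 - eps),
          upper = max(0, sign(r)) * (1 - eps), tol = 1e-9)$root
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
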