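# Two-sample summary-level MR estimators. Each takes a data frame of
# per-variant instrument statistics (columns bx, se_x, by, se_y) and
# returns a one-row tibble: method, beta, se, n_instruments, converged.
# These are the estimators embedded inside each MR-SimSS iteration and
# also usable stand-alone.

mr_estimate <- function(method, beta, se, n, converged = TRUE, ...) {
  tibble::tibble(method = method, beta = beta, se = se,
                 n_instruments = as.integer(n), converged = converged, ...)
}

check_instruments <- function(dat, min_n, method) {
  need <- c("bx", "se_x", "by", "se_y")
  if (!all(need %in% names(dat))) {
    abort(paste0(method, ": instrument table needs columns ",
                 paste(need, collapse = ", ")),
          class = "mrsimss_format_error")
  }
  if (nrow(dat) < min_n) {
    abort(sprintf("%s needs at least %d instruments (got %d)",
                  method, min_n, nrow(dat)),
          class = "mrsimss_degenerate_error")
  }
  invisible(dat)
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect IVW with first-order weights `1/se_y^2`:
#' `beta = sum(bx*by/se_y^2) / sum(bx^2/se_y^2)`,
#' `se = 1/sqrt(sum(bx^2/se_y^2))`.
#'
#' @param dat Data frame of instruments with columns `bx`, `se_x`, `by`,
#'   `se_y`.
#' @return A one-row tibble: `method`, `beta`, `se`, `n_instruments`,
#'   `converged`.
#' @export
#' @examples
#' mr_ivw(data.frame(bx = c(0.1, 0.2), se_x = 0.01,
#'                   by = c(0.03, 0.05), se_y = 0.01))
mr_ivw <- function(dat) {
  check_instruments(dat, 1, "ivw")
  w <- 1 / dat$se_y^2
  denom <- sum(dat$bx^2 * w)
  if (denom <= 0) {
    abort("ivw: zero aggregate instrument strength",
          class = "mrsimss_degenerate_error")
  }
  mr_estimate("ivw", sum(dat$bx * dat$by * w) / denom, 1 / sqrt(denom),
              nrow(dat))
}

raps_psi <- function(beta, dat, tau2 = 0) {
  # derivative of the per-variant profile log-likelihood: the second term
  # (residual^2 * beta * se_x^2 / v^2) cancels the -beta*se_x^2 mean of the
  # first and is what makes the score unbiased under weak instruments
  v <- dat$se_y^2 + beta^2 * dat$se_x^2 + tau2
  r <- dat$by - beta * dat$bx
  r * dat$bx / v + r^2 * beta * dat$se_x^2 / v^2
}

raps_score <- function(beta, dat, tau2 = 0) sum(raps_psi(beta, dat, tau2))

#' Profile-score (RAPS-type) estimator
#'
#' Maximizes the profile likelihood of the causal effect with the true
#' variant effects profiled out: the estimate solves
#' `sum(r*bx/v + r^2*beta*se_x^2/v^2) = 0` with `r = by - beta*bx` and
#' `v = se_y^2 + beta^2*se_x^2`. The second score term accounts for
#' measurement error in the variant-exposure associations, making the
#' estimator robust to weak instruments when the exposure and outcome
#' statistics are independent. The standard error is the asymptotic
#' variance of the score root, `sqrt(V1 + V2)/V1` with
#' `V1 = sum((bx^2 - se_x^2)/v)` and `V2 = sum(se_x^2 se_y^2/v^2)`. With
#' `overdispersion = TRUE` an additive variance component `tau2 >= 0` is
#' estimated jointly by a method-of-moments iteration.
#'
#' The root is located by bracketed scalar root-finding, widening the
#' bracket geometrically from the IVW estimate until a sign change is
#' found (tolerance 1e-10); if no sign change occurs within |beta| <= 1e3
#' the IVW estimate is returned with `converged = FALSE`.
#'
#' @inheritParams mr_ivw
#' @param overdispersion Estimate an additive overdispersion variance.
#' @return A one-row tibble as in [mr_ivw()], plus `tau2` when
#'   `overdispersion = TRUE`.
#' @export
mr_raps <- function(dat, overdispersion = FALSE) {
  check_instruments(dat, 2, "raps")
  tau2 <- 0
  fallback <- function() {
    ivw <- mr_ivw(dat)
    mr_estimate("raps", ivw$beta, ivw$se, nrow(dat), converged = FALSE)
  }
  for (round in seq_len(if (overdispersion) 25 else 1)) {
    root <- raps_root(dat, tau2)
    if (is.null(root)) return(fallback())
    if (!overdispersion) break
    v <- dat$se_y^2 + root^2 * dat$se_x^2
    # moment equation: mean standardized squared residual = 1
    tau2_new <- max(0, mean((dat$by - root * dat$bx)^2 - v))
    if (abs(tau2_new - tau2) < 1e-12 * (1 + tau2)) {
      tau2 <- tau2_new
      break
    }
    tau2 <- tau2_new
  }
  beta <- root
  # asymptotic variance of the profile-score root: (V1 + V2)/V1^2 with
  # V1 = sum(gamma^2/v) (plug in bx^2 - se_x^2) and V2 = sum(se_x^2 se_y^2/v^2)
  v <- dat$se_y^2 + beta^2 * dat$se_x^2 + tau2
  v1 <- sum((dat$bx^2 - dat$se_x^2) / v)
  v2 <- sum(dat$se_x^2 * (dat$se_y^2 + tau2) / v^2)
  if (v1 <= 0) return(fallback())
  out <- mr_estimate("raps", beta, sqrt(v1 + v2) / v1, nrow(dat))
  if (overdispersion) out$tau2 <- tau2
  out
}

raps_root <- function(dat, tau2 = 0) {
  f <- function(b) raps_score(b, dat, tau2)
  centre <- tryCatch(mr_ivw(dat)$beta, error = function(e) 0)
  width <- max(1e-3, abs(centre))
  repeat {
    lo <- centre - width
    hi <- centre + width
    flo <- f(lo)
    fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
      return(uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root)
    }
    width <- width * 2
    if (max(abs(lo), abs(hi)) > 1e3) return(NULL)
  }
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with an intercept (weights
#' `1/se_y^2`), after orienting all instruments so that `bx >= 0` (joint
#' sign flips of `(bx, by)` pairs, to which the fit is invariant). The
#' slope is the causal estimate; the intercept captures directional
#' pleiotropy. Standard errors use the multiplicative residual dispersion
#' floored at 1.
#'
#' @inheritParams mr_ivw
#' @return A one-row tibble as in [mr_ivw()], plus `intercept` and
#'   `intercept_se`.
#' @export
mr_egger <- function(dat) {
  check_instruments(dat, 3, "egger")
  flip <- sign(dat$bx)
  flip[flip == 0] <- 1
  bx <- dat$bx * flip
  by <- dat$by * flip
  if (stats::var(bx) < .Machine$double.eps) {
    abort("egger: rank-deficient design (all bx equal)",
          class = "mrsimss_degenerate_error")
  }
  fit <- lm(by ~ bx, weights = 1 / dat$se_y^2)
  sm <- summary(fit)
  infl <- max(1, sm$sigma) / sm$sigma
  mr_estimate("egger",
              beta = unname(coef(fit)["bx"]),
              se = sm$coefficients["bx", "Std. Error"] * infl,
              n = nrow(dat),
              intercept = unname(coef(fit)["(Intercept)"]),
              intercept_se = sm$coefficients["(Intercept)", "Std. Error"] * infl)
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cw <- cumsum(w)
  j <- which(cw >= 0.5 - 1e-12)[1]
  if (abs(cw[j] - 0.5) <= 1e-12 && j < length(r)) {
    (r[j] + r[j + 1]) / 2  # exact tie: midpoint of bracketing ratios
  } else {
    r[j]
  }
}

#' Weighted-median estimator
#'
#' Orders the per-variant ratio estimates `by/bx` and returns the ratio at
#' cumulative normalized weight 0.5, with weights proportional to the
#' first-order inverse ratio variance `bx^2/se_y^2`; at an exact 0.5
#' crossing the two bracketing ratios are averaged. Consistent when
#' instruments carrying at least half the weight are valid. The standard
#' error comes from a parametric bootstrap that redraws `(bx, by)` from
#' their stated normal distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Parametric bootstrap resamples for the standard error.
#' @return A one-row tibble as in [mr_ivw()].
#' @export
mr_weighted_median <- function(dat, n_boot = 1000) {
  check_instruments(dat, 3, "weighted_median")
  if (any(dat$bx == 0)) {
    warn("weighted_median: excluding instruments with bx = 0")
    dat <- dat[dat$bx != 0, , drop = FALSE]
    check_instruments(dat, 3, "weighted_median")
  }
  est <- weighted_median_point(dat$by / dat$bx, dat$bx^2 / dat$se_y^2)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(dat), dat$bx, dat$se_x)
    by <- rnorm(nrow(dat), dat$by, dat$se_y)
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / dat$se_y[ok]^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, stats::sd(boot), nrow(dat))
}

#' Debiased IVW estimator
#'
#' IVW with the denominator corrected for measurement error in the
#' variant-exposure associations:
#' `beta = sum(bx*by/se_y^2) / sum((bx^2 - se_x^2)/se_y^2)`. Designed for
#' the full, unselected variant set, avoiding Winner's Curse without
#' screening. The standard error is the first-order delta-method variance
#' with `bx^2 - se_x^2` plugged in for the squared true effects.
#'
#' @inheritParams mr_ivw
#' @return A one-row tibble as in [mr_ivw()].
#' @export
mr_divw <- function(dat) {
  check_instruments(dat, 1, "divw")
  w <- 1 / dat$se_y^2
  denom <- sum((dat$bx^2 - dat$se_x^2) * w)
  if (denom <= 0) {
    abort("divw: non-positive denominator (insufficient aggregate instrument strength)",
          class = "mrsimss_degenerate_error")
  }
  beta <- sum(dat$bx * dat$by * w) / denom
  g2 <- pmax(dat$bx^2 - dat$se_x^2, 0)
  vnum <- sum((g2 * dat$se_y^2 + beta^2 * g2 * dat$se_x^2 +
                 dat$se_x^2 * dat$se_y^2 + 2 * beta^2 * dat$se_x^4) / dat$se_y^4)
  mr_estimate("divw", beta, sqrt(vnum) / denom, nrow(dat))
}

# ---- plug-in registry -------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Register or look up embedded MR estimators
#'
#' [mr_simss()] and the benchmarking harness accept estimators by name.
#' New estimators with the same signature (a data frame of instruments in,
#' a one-row tibble with `beta` and `se` out) can be registered and then
#' used anywhere a built-in name is accepted.
#'
#' @param name Estimator name.
#' @param fn Function of one data-frame argument returning a one-row data
#'   frame with at least `beta` and `se`.
#' @param min_instruments Minimum instrument count the estimator needs;
#'   MR-SimSS iterations with fewer selected instruments are skipped.
#' @return `register_mr_estimator()` returns `fn` invisibly;
#'   `mr_estimator()` returns the registry entry (list with `fn` and
#'   `min_instruments`); `mr_estimators()` returns the registered names.
#' @export
register_mr_estimator <- function(name, fn, min_instruments = 1) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, list(fn = fn, min_instruments = as.integer(min_instruments)),
         envir = the_registry)
  invisible(fn)
}

#' @rdname register_mr_estimator
#' @export
mr_estimator <- function(name) {
  if (is.function(name)) return(list(fn = name, min_instruments = 1L))
  if (!exists(name, envir = the_registry)) {
    abort(sprintf("unknown estimator '%s'; registered: %s", name,
                  paste(mr_estimators(), collapse = ", ")),
          class = "mrsimss_format_error")
  }
  get(name, envir = the_registry)
}

#' @rdname register_mr_estimator
#' @export
mr_estimators <- function() sort(ls(the_registry))

register_builtin_estimators <- function() {
  register_mr_estimator("ivw", mr_ivw, 1)
  register_mr_estimator("raps", mr_raps, 2)
  register_mr_estimator("egger", mr_egger, 3)
  register_mr_estimator("wmedian", mr_weighted_median, 3)
  register_mr_estimator("divw", mr_divw, 1)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_estimators()
}
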