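#' Per-iteration instrument selection probability
#'
#' Probability that a variant passes the selection threshold in one
#' simulated split, given its full-sample statistics. Writing
#' `z = sqrt(pi1) * beta_x / se_x` for the rescaled full-sample
#' z-statistic, the selection-split z-statistic is normal with mean `z`
#' and variance `1 - pi1`, so the probability of exceeding the two-sided
#' threshold `c = qnorm(1 - alpha/2)` is
#' `pnorm((-c + z)/sqrt(1 - pi1)) + pnorm((-c - z)/sqrt(1 - pi1))`.
#'
#' @param z Rescaled full-sample z-statistic(s),
#'   `sqrt(pi1) * beta_x / se_x`.
#' @param pi1 Selection-split fraction in (0, 1).
#' @param alpha Two-sided selection threshold.
#' @return Selection probabilities, same length as `z`.
#' @export
#' @examples
#' selection_probability(0, pi1 = 0.5, alpha = 0.05) # 0.005577
selection_probability <- function(z, pi1 = 0.5, alpha = 5e-8) {
  stopifnot(pi1 > 0, pi1 < 1)
  cc <- z_threshold(alpha)
  s <- sqrt(1 - pi1)
  pnorm((-cc + z) / s) + pnorm((-cc - z) / s)
}

#' Deterministic variant pre-selection
#'
#' Simulating splits for every genome-wide variant is wasteful when almost
#' none can ever be selected. Variants are ranked by their selection
#' probability and the largest possible low-probability tail whose summed
#' probabilities stay within `1 - guarantee` is excluded. By the union
#' bound, the probability that any excluded variant would have been
#' selected on a given iteration is at most `1 - guarantee`, so the
#' reduced and full sets produce identical instrument lists on any
#' iteration with probability at least `guarantee`.
#'
#' @param pair A [summary_pair].
#' @inheritParams selection_probability
#' @param guarantee Lower bound on the per-iteration probability that the
#'   reduced set selects exactly the same instruments as the full set.
#' @return Integer indices of the retained variants.
#' @export
preselect_variants <- function(pair, pi1 = 0.5, alpha = 5e-8,
                               guarantee = 0.95) {
  stopifnot(guarantee > 0, guarantee < 1)
  p <- selection_probability(sqrt(pi1) * pair$beta_x / pair$se_x, pi1, alpha)
  ord <- order(p)  # ascending: candidate exclusions first
  excludable <- cumsum(p[ord]) <= (1 - guarantee)
  sort(ord[!excludable])
}

#' Split-simulation configuration
#'
#' @param pi1 Fraction of the sample allocated to the selection split.
#' @param pi2 Sub-fraction of the complement allocated to exposure
#'   estimation (3-split mode only).
#' @param n_iter Number of simulated splits averaged over.
#' @param alpha Two-sided instrument-selection threshold.
#' @param mode `"two_split"` or `"three_split"`.
#' @param estimator Registered estimator name (see [mr_estimators()]) or a
#'   function.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param guarantee Pre-selection guarantee passed to
#'   [preselect_variants()].
#' @return A list of class `split_config`.
#' @export
split_config <- function(pi1 = 0.5, pi2 = 0.5, n_iter = 1000, alpha = 5e-8,
                         mode = c("three_split", "two_split"),
                         estimator = "raps", seed = NULL, guarantee = 0.95) {
  stopifnot(pi1 > 0, pi1 < 1, pi2 > 0, pi2 < 1, n_iter >= 1,
            alpha > 0, alpha <= 1)
  mode <- match.arg(mode)
  structure(list(pi1 = pi1, pi2 = pi2, n_iter = as.integer(n_iter),
                 alpha = alpha, mode = mode, estimator = estimator,
                 seed = seed, guarantee = guarantee),
            class = "split_config")
}

#' Causal-effect estimation by simulated sample splitting (MR-SimSS)
#'
#' Corrects Winner's Curse and sample-overlap bias in summary-level MR by
#' repeatedly simulating the summary statistics that independent sample
#' splits would have produced, selecting instruments in the simulated
#' selection split, estimating the causal effect from the complementary
#' split(s) with a pluggable two-sample estimator, and averaging over
#' iterations. In `two_split` mode the estimator sees the complement-split
#' exposure and outcome statistics; in `three_split` mode the complement
#' is further subdivided so the exposure and outcome statistics mimic
#' disjoint samples, which keeps estimation unbiased even under full
#' exposure/outcome sample overlap.
#'
#' The final estimate is the iteration mean, and its standard error
#' subtracts the between-iteration (Monte Carlo) variance from the mean
#' squared per-iteration standard error:
#' `se = sqrt(mean(se_k^2) - mean((beta_k - mean(beta_k))^2))`.
#'
#' @param pair A [summary_pair] of LD-pruned, harmonized variants.
#' @param overlap An [overlap_model], or `NULL` to estimate the error
#'   correlation from the data with [estimate_lambda()].
#' @param config A [split_config]; individual `...` arguments override
#'   its fields for convenience.
#' @param ... Passed to [split_config()] when `config` is not supplied.
#' @return An object of class `mr_simss`: a list with elements `beta`,
#'   `se`, `n_iter_used`, `skipped_iterations`, `mean_instruments`,
#'   `lam_used`, `lam_source`, `config` and the per-iteration tibble
#'   `iterations`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' scn <- sim_scenario(n_variants = 5000, p_causal = 0.02, h2 = 0.4,
#'                     n_x = 1e5, n_y = 1e5, overlap_frac = 1, rho = 0.5)
#' pair <- simulate_gwas_pair(scn, seed = 7)
#' fit <- mr_simss(pair, n_iter = 50, seed = 1)
#' tidy(fit)
mr_simss <- function(pair, overlap = NULL, config = NULL, ...) {
  if (is.null(config)) config <- split_config(...)
  stopifnot(inherits(config, "split_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  if (is.null(overlap)) {
    overlap <- overlap_model(attr(pair, "n_x") %||% 1, attr(pair, "n_y") %||% 1)
  }
  if (is.na(overlap$lambda)) {
    est <- estimate_lambda(pair)
    lam <- est$lambda
    lam_source <- sprintf("estimated from %d null variants (se %.4f)",
                          est$n_null, est$se)
  } else {
    lam <- overlap$lambda
    lam_source <- "supplied"
  }

  estr <- mr_estimator(config$estimator)
  keep <- preselect_variants(pair, config$pi1, config$alpha, config$guarantee)
  reduced <- pair[keep, , drop = FALSE]

  iters <- purrr::map_dfr(seq_len(config$n_iter), function(k) {
    s1 <- draw_first_split(reduced, lam, config$pi1)
    sel <- select_instruments(s1$bx1, s1$se_x1, config$alpha)
    if (length(sel) < estr$min_instruments) {
      return(tibble::tibble(iteration = k, beta = NA_real_, se = NA_real_,
                            n_instruments = length(sel), converged = FALSE))
    }
    s2 <- complement_estimates(reduced[sel, , drop = FALSE],
                               s1[sel, , drop = FALSE], config$pi1)
    dat <- if (config$mode == "three_split") {
      s3 <- draw_second_split(s2, lam, config$pi1, config$pi2)
      tibble::tibble(bx = s3$bx2a, se_x = s3$se_x2a,
                     by = s3$by2b, se_y = s3$se_y2b)
    } else {
      tibble::tibble(bx = s2$bx2, se_x = s2$se_x2,
                     by = s2$by2, se_y = s2$se_y2)
    }
    fit <- tryCatch(estr$fn(dat), error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged[1])) {
      return(tibble::tibble(iteration = k, beta = NA_real_, se = NA_real_,
                            n_instruments = length(sel), converged = FALSE))
    }
    tibble::tibble(iteration = k, beta = fit$beta[1], se = fit$se[1],
                   n_instruments = length(sel), converged = TRUE)
  })

  used <- iters[iters$converged, , drop = FALSE]
  n_skipped <- config$n_iter - nrow(used)
  if (nrow(used) == 0 || n_skipped > config$n_iter / 2) {
    abort(paste(
      "more than half of the iterations had too few instruments or a",
      "failed estimator fit; relaxing the selection threshold (alpha)",
      "can improve stability when few variants reach significance"
    ), class = "mrsimss_instability_error")
  }

  beta_hat <- mean(used$beta)
  mean_se2 <- mean(used$se^2)
  between <- mean((used$beta - beta_hat)^2)
  if (nrow(used) == 1) {
    se_hat <- used$se[1]
  } else {
    radicand <- mean_se2 - between
    if (radicand <= 0) {
      warn(paste(
        "non-estimable standard error: between-iteration variance exceeds",
        "the mean estimation variance (n_iter too small); se reported as NA"
      ), class = "mrsimss_se_warning")
      se_hat <- NA_real_
    } else {
      se_hat <- sqrt(radicand)
    }
  }

  structure(
    list(beta = beta_hat, se = se_hat,
         n_iter_used = nrow(used), skipped_iterations = n_skipped,
         mean_instruments = mean(used$n_instruments),
         n_variants_retained = length(keep),
         lam_used = lam, lam_source = lam_source,
         config = config, iterations = iters),
    class = "mr_simss"
  )
}

#' @export
print.mr_simss <- function(x, ...) {
  cfg <- x$config
  label <- sprintf("MR-SimSS (%s, %s)",
                   if (cfg$mode == "three_split") "3-split" else "2-split",
                   if (is.character(cfg$estimator)) cfg$estimator else "custom")
  ci <- x$beta + c(-1, 1) * 1.96 * x$se
  cat(label, "\n", sep = "")
  cat(sprintf("  beta = %.4f  se = %.4f  95%% CI [%.4f, %.4f]\n",
              x$beta, x$se, ci[1], ci[2]))
  cat(sprintf("  iterations used: %d (skipped %d), mean instruments: %.1f\n",
              x$n_iter_used, x$skipped_iterations, x$mean_instruments))
  cat(sprintf("  lambda = %.4f (%s)\n", x$lam_used, x$lam_source))
  invisible(x)
}

#' Run a conventional MR analysis with naive instrument selection
#'
#' The comparator MR-SimSS is designed to improve on: instruments are
#' selected at the given threshold from the *same* full-sample exposure
#' statistics that are then used for estimation, so the estimate inherits
#' Winner's Curse (bias toward the null under no overlap) and
#' overlap-dependent weak-instrument bias.
#'
#' @param pair A [summary_pair].
#' @param estimator Registered estimator name or function.
#' @param alpha Two-sided selection threshold; `divw` conventionally uses
#'   `alpha = 1` (all variants, no selection).
#' @return A one-row tibble: `method`, `beta`, `se`, `n_instruments`,
#'   `converged`.
#' @export
mr_naive <- function(pair, estimator = "ivw", alpha = 5e-8) {
  estr <- mr_estimator(estimator)
  sel <- select_instruments(pair$beta_x, pair$se_x, alpha)
  if (length(sel) < estr$min_instruments) {
    abort("too few instruments at the chosen threshold",
          class = "mrsimss_degenerate_error")
  }
  dat <- tibble::tibble(bx = pair$beta_x[sel], se_x = pair$se_x[sel],
                        by = pair$beta_y[sel], se_y = pair$se_y[sel])
  out <- estr$fn(dat)
  out$method <- paste0("naive_", out$method)
  out
}
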