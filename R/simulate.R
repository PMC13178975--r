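#' Define a summary-level GWAS simulation scenario
#'
#' Describes one cell of the factorial simulation design: a pair of
#' exposure/outcome GWASs on unit-variance traits, with a fraction
#' `p_causal` of variants carrying true exposure effects calibrated to a
#' target heritability, a linear causal effect on the outcome, and
#' optional sample overlap and balanced/directional pleiotropy.
#'
#' Standardized causal effects are drawn as
#' `b_j ~ N(0, h2 / (p_causal * n_variants))`, so the expected sum of
#' squared standardized effects equals `h2`. Per-allele effects are
#' `b_j / sqrt(2 maf_j (1 - maf_j))`, matching the per-allele sampling
#' variance `1 / (2 maf_j (1 - maf_j) n)` used for the estimates.
#'
#' @param n_variants Number of independent variants per dataset.
#' @param p_causal Proportion of variants with non-zero exposure effects.
#' @param h2 Exposure heritability in (0, 1).
#' @param n_x,n_y GWAS sample sizes.
#' @param overlap_frac Overlapping fraction of `min(n_x, n_y)` in [0, 1].
#' @param rho Exposure-outcome correlation in the overlapping sample.
#' @param beta_true True causal effect of the exposure on the outcome.
#' @param maf_range Minor-allele-frequency range (uniform draw).
#' @param pleiotropy Optional list `(q, mu_alpha, sd_alpha)`: a fraction
#'   `q` of variants receives a direct (standardized) outcome effect
#'   `~ N(mu_alpha, sd_alpha^2)`; a generic knob, not a reproduction of
#'   any specific published pleiotropy scenario.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_variants = 1e6, p_causal = 0.01, h2 = 0.7,
                         n_x = 200000, n_y = 200000, overlap_frac = 0,
                         rho = 0.5, beta_true = 0.3,
                         maf_range = c(0.01, 0.5), pleiotropy = NULL) {
  stopifnot(p_causal > 0, p_causal <= 1, h2 >= 0, h2 < 1,
            overlap_frac >= 0, overlap_frac <= 1, abs(rho) <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  if (!is.null(pleiotropy)) {
    stopifnot(is.list(pleiotropy),
              all(c("q", "mu_alpha", "sd_alpha") %in% names(pleiotropy)))
  }
  structure(
    list(n_variants = as.integer(n_variants), p_causal = p_causal, h2 = h2,
         n_x = as.double(n_x), n_y = as.double(n_y),
         overlap_frac = overlap_frac, rho = rho, beta_true = beta_true,
         maf_range = maf_range, pleiotropy = pleiotropy),
    class = "sim_scenario"
  )
}

#' Simulate one matched GWAS summary-statistics pair
#'
#' Draws per-variant minor allele frequencies, true effects and estimated
#' summary statistics from the scenario's bivariate sampling model: the
#' estimate pair is normal around the truth with variances
#' `1/(2 maf (1 - maf) n)` and error correlation
#' `lambda = overlap_frac * min(n_x, n_y) * rho / sqrt(n_x n_y)`.
#' Standard errors are reported at their known true values.
#'
#' @param scenario A [sim_scenario].
#' @param seed Optional integer seed.
#' @return A [summary_pair] with extra columns `beta_x_true`,
#'   `beta_y_true` and attribute `lambda_true`.
#' @export
simulate_gwas_pair <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_variants
  sigma_b2 <- scenario$h2 / (scenario$p_causal * n)
  if (!is.finite(sigma_b2) || sigma_b2 < 0) {
    abort("invalid scenario: h2 / (p_causal * n_variants) must be >= 0",
          class = "mrsimss_format_error")
  }

  maf <- runif(n, scenario$maf_range[1], scenario$maf_range[2])
  scale <- sqrt(2 * maf * (1 - maf))
  causal <- rbinom(n, 1, scenario$p_causal) == 1
  b <- numeric(n)
  b[causal] <- rnorm(sum(causal), 0, sqrt(sigma_b2))
  beta_x_true <- b / scale
  beta_y_true <- scenario$beta_true * beta_x_true
  if (!is.null(scenario$pleiotropy)) {
    pl <- scenario$pleiotropy
    hit <- rbinom(n, 1, pl$q) == 1
    alpha_std <- rnorm(sum(hit), pl$mu_alpha, pl$sd_alpha)
    beta_y_true[hit] <- beta_y_true[hit] + alpha_std / scale[hit]
  }

  se_x <- 1 / (scale * sqrt(scenario$n_x))
  se_y <- 1 / (scale * sqrt(scenario$n_y))
  lam <- lambda_from_design(scenario$overlap_frac * min(scenario$n_x, scenario$n_y),
                            scenario$rho, scenario$n_x, scenario$n_y)
  e <- draw_correlated_noise(n, lam)

  pair <- summary_pair(
    tibble::tibble(
      variant_id = paste0("v", seq_len(n)),
      beta_x = beta_x_true + se_x * e$e1,
      se_x = se_x,
      beta_y = beta_y_true + se_y * e$e2,
      se_y = se_y,
      maf = maf,
      beta_x_true = beta_x_true,
      beta_y_true = beta_y_true
    ),
    n_x = scenario$n_x, n_y = scenario$n_y
  )
  attr(pair, "lambda_true") <- lam
  attr(pair, "scenario") <- scenario
  pair
}

method_label <- function(spec) {
  if (is.function(spec)) return("custom")
  if (is.list(spec)) return(spec$label %||% "custom")
  spec
}

# Resolve a method specification into fn(pair) -> one-row tibble.
# Character shorthands: "ivw"/"raps"/... = naive selection + estimator,
# "divw" = all variants, "simss2_raps"/"simss3_ivw"/... = MR-SimSS.
resolve_method <- function(spec, simss_control = list()) {
  if (is.function(spec)) return(spec)
  if (is.list(spec) && !is.null(spec$fn)) return(spec$fn)
  stopifnot(is.character(spec), length(spec) == 1)
  if (grepl("^simss[23]_", spec)) {
    mode <- if (substr(spec, 6, 6) == "3") "three_split" else "two_split"
    estimator <- sub("^simss[23]_", "", spec)
    args <- modifyList(list(mode = mode, estimator = estimator),
                       simss_control)
    function(pair) {
      fit <- mr_simss(pair, config = do.call(split_config, args))
      tibble::tibble(method = spec, beta = fit$beta, se = fit$se,
                     n_instruments = fit$mean_instruments,
                     converged = TRUE)
    }
  } else if (spec == "divw") {
    function(pair) mr_naive(pair, "divw", alpha = 1)
  } else {
    function(pair) mr_naive(pair, spec, alpha = 5e-8)
  }
}

#' Score MR methods on simulated data
#'
#' Simulates `n_replicates` independent datasets from a scenario, runs
#' each method on each replicate, and reports the evaluation metrics of
#' the factorial study: mean estimate, bias, absolute bias, RMSE, mean
#' standard error, empirical 95% CI coverage of the true effect and mean
#' instrument count. A method failure on a replicate is recorded and that
#' replicate is excluded from the method's metrics.
#'
#' @param scenario A [sim_scenario].
#' @param methods Character vector of method shorthands (`"ivw"`,
#'   `"raps"`, `"divw"`, `"simss2_raps"`, `"simss3_ivw"`, ...), or a
#'   (optionally named) list of functions `pair -> tibble(beta, se, ...)`.
#' @param n_replicates Independent datasets to simulate.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param simss_control Named list of [split_config()] overrides applied
#'   to every `simss*` method (e.g. `list(n_iter = 300)`).
#' @return A tibble with one row per method: `method`, `n_replicates`,
#'   `n_failed`, `mean_beta`, `bias`, `abs_bias`, `rmse`, `mean_se`,
#'   `coverage`, `mean_n_instruments`.
#' @export
evaluate_methods <- function(scenario, methods, n_replicates = 100,
                             seed = NULL, simss_control = list()) {
  if (!is.list(methods)) methods <- as.list(methods)
  labels <- names(methods) %||% rep("", length(methods))
  labels <- ifelse(labels == "", vapply(methods, method_label, character(1)),
                   labels)
  fns <- lapply(methods, resolve_method, simss_control = simss_control)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)

  per_rep <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    pair <- simulate_gwas_pair(scenario, seed = rep_seeds[r])
    purrr::map_dfr(seq_along(fns), function(m) {
      fit <- tryCatch(fns[[m]](pair), error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(replicate = r, method = labels[m], beta = NA_real_,
                       se = NA_real_, n_instruments = NA_real_)
      } else {
        tibble::tibble(replicate = r, method = labels[m],
                       beta = fit$beta[1], se = fit$se[1],
                       n_instruments = as.numeric(fit$n_instruments[1]))
      }
    })
  })

  truth <- scenario$beta_true
  out <- per_rep |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_failed = sum(is.na(.data$beta)),
      mean_beta = mean(.data$beta, na.rm = TRUE),
      bias = mean(.data$beta - truth, na.rm = TRUE),
      rmse = sqrt(mean((.data$beta - truth)^2, na.rm = TRUE)),
      mean_se = mean(.data$se, na.rm = TRUE),
      coverage = mean(abs(.data$beta - truth) <= 1.96 * .data$se,
                      na.rm = TRUE),
      mean_n_instruments = mean(.data$n_instruments, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(abs_bias = abs(.data$bias), .after = "bias") |>
    dplyr::arrange(match(.data$method, labels))
  attr(out, "per_replicate") <- per_rep
  out
}

#' Run a factorial simulation grid
#'
#' Crosses the supplied scenario axes, evaluates every method in every
#' cell with [evaluate_methods()], and returns one long tidy table. Cell
#' seeds are derived deterministically from the master seed, so re-running
#' with the same seed reproduces the table exactly.
#'
#' @param grid A named list of scenario-axis values to cross (any
#'   [sim_scenario()] argument, e.g. `list(h2 = c(0.3, 0.7),
#'   p_causal = c(0.01, 0.001))`); scalar entries are held fixed.
#' @inheritParams evaluate_methods
#' @return A tibble of class `simss_grid`: the crossed scenario columns
#'   plus the [evaluate_methods()] metrics for each method.
#' @export
run_grid <- function(grid, methods, n_replicates = 100, seed = 1,
                     simss_control = list()) {
  cells <- tidyr::expand_grid(!!!grid)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    scn <- do.call(sim_scenario, as.list(cells[i, ]))
    metrics <- evaluate_methods(scn, methods, n_replicates,
                                seed = cell_seeds[i],
                                simss_control = simss_control)
    dplyr::bind_cols(cells[rep(i, nrow(metrics)), ], metrics)
  })
  class(out) <- c("simss_grid", class(out))
  out
}
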