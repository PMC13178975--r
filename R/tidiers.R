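#' Tidy an MR-SimSS fit
#'
#' @param x An `mr_simss` object.
#' @param conf_level Confidence level for the normal-approximation
#'   interval (`beta +/- z * se`).
#' @param ... Unused.
#' @return A one-row tibble: `method`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @exportS3Method generics::tidy
tidy.mr_simss <- function(x, conf_level = 0.95, ...) {
  z <- x$beta / x$se
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    method = sprintf("simss%s_%s",
                     if (x$config$mode == "three_split") "3" else "2",
                     if (is.character(x$config$estimator)) x$config$estimator
                     else "custom"),
    estimate = x$beta,
    std_error = x$se,
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    conf_low = x$beta - q * x$se,
    conf_high = x$beta + q * x$se
  )
}

#' Glance at an MR-SimSS fit
#'
#' @param x An `mr_simss` object.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics: iterations used and
#'   skipped, mean instrument count, variants retained by pre-selection,
#'   the error correlation used and its provenance.
#' @exportS3Method generics::glance
glance.mr_simss <- function(x, ...) {
  tibble::tibble(
    n_iter_used = x$n_iter_used,
    skipped_iterations = x$skipped_iterations,
    mean_instruments = x$mean_instruments,
    n_variants_retained = x$n_variants_retained,
    lambda = x$lam_used,
    lambda_source = x$lam_source
  )
}

#' Plot per-iteration MR-SimSS estimates
#'
#' Histogram of the per-iteration causal-effect estimates with the
#' aggregated estimate and its 95% interval overlaid; a quick visual
#' check that the iteration distribution is unimodal and that enough
#' iterations were run.
#'
#' @param object An `mr_simss` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_simss <- function(object, ...) {
  used <- object$iterations[object$iterations$converged, , drop = FALSE]
  ggplot2::ggplot(used, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$beta, linewidth = 0.8) +
    ggplot2::geom_vline(
      xintercept = object$beta + c(-1.96, 1.96) * object$se,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "per-iteration causal-effect estimate", y = "iterations",
      title = "MR-SimSS iteration estimates",
      subtitle = sprintf("aggregate beta = %.4f (se %.4f), %d iterations",
                         object$beta, object$se, object$n_iter_used)
    )
}

#' Plot factorial-grid benchmarking results
#'
#' Mean estimate with a +/- 1.96 * mean-SE interval per method and grid
#' cell, faceted by the crossed scenario axes, with the true effect as a
#' horizontal reference line.
#'
#' @param object A `simss_grid` tibble from [run_grid()].
#' @param truth True causal effect reference line (taken from the grid's
#'   `beta_true` column when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.simss_grid <- function(object, truth = NULL, ...) {
  truth <- truth %||%
    (if ("beta_true" %in% names(object)) object$beta_true[1] else NA_real_)
  axes <- intersect(c("h2", "p_causal", "overlap_frac", "rho"),
                    names(object))
  axes <- axes[vapply(object[axes],
                      function(x) length(unique(x)) > 1, logical(1))]
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$method, y = .data$mean_beta,
    ymin = .data$mean_beta - 1.96 * .data$mean_se,
    ymax = .data$mean_beta + 1.96 * .data$mean_se
  )) +
    ggplot2::geom_pointrange() +
    ggplot2::labs(x = NULL, y = "mean causal-effect estimate") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.finite(truth)) {
    p <- p + ggplot2::geom_hline(yintercept = truth, linetype = "dashed")
  }
  if (length(axes) > 0) {
    p <- p + ggplot2::facet_wrap(
      stats::as.formula(paste("~", paste(axes, collapse = "+"))),
      labeller = ggplot2::label_both
    )
  }
  p
}
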