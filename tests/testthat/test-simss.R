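test_that("selection probability matches its closed form and Monte Carlo", {
  # closed-form oracle: 2 * pnorm(-qnorm(0.975)/sqrt(0.5))
  expect_equal(selection_probability(0, pi1 = 0.5, alpha = 0.05),
               2 * pnorm(-qnorm(0.975) / sqrt(0.5)))
  expect_lt(abs(selection_probability(0, pi1 = 0.5, alpha = 0.05) - 0.005577),
            1e-5)

  z <- seq(-4, 4, by = 0.8)
  expect_equal(selection_probability(z, 0.5, 1e-4),
               selection_probability(-z, 0.5, 1e-4))
  expect_gt(selection_probability(50, 0.3, 5e-8), 1 - 1e-10)

  # Monte-Carlo frequency of selection under draw_first_split agrees with
  # the closed form (validates the z = sqrt(pi1) beta_x / se_x convention)
  pair <- summary_pair(
    tibble::tibble(variant_id = "v", beta_x = 0.05, se_x = 0.008,
                   beta_y = 0, se_y = 0.008),
    n_x = 1e5, n_y = 1e5
  )
  pi1 <- 0.5
  alpha <- 1e-6
  n_draw <- 2e5
  many <- pair[rep(1, n_draw), ]
  set.seed(51)
  s1 <- draw_first_split(many, lambda = 0, pi1 = pi1)
  freq <- length(select_instruments(s1$bx1, s1$se_x1, alpha)) / n_draw
  p_closed <- selection_probability(sqrt(pi1) * 0.05 / 0.008, pi1, alpha)
  expect_lt(abs(freq - p_closed),
            3 * sqrt(p_closed * (1 - p_closed) / n_draw))
})

test_that("pre-selection keeps every variant the union bound cannot exclude", {
  # one near-certain variant among hopeless ones: only it is retained
  pair <- make_pair(n = 1000, seed = 52)
  pair$beta_x <- rep(0, 1000)
  pair$se_x <- rep(0.01, 1000)
  pair$beta_x[17] <- 0.1 # z = 10
  keep <- preselect_variants(pair, pi1 = 0.5, alpha = 5e-8)
  expect_equal(keep, 17L)

  # equal moderate probabilities: tail budget below any single probability
  pair10 <- make_pair(n = 10, seed = 53)
  pair10$beta_x <- rep(0.0686, 10) # z ~ 6.86, selection prob ~ 0.2
  pair10$se_x <- rep(0.01, 10)
  p <- selection_probability(sqrt(0.5) * 6.86, 0.5, 5e-8)
  expect_gt(p, 0.05)
  expect_equal(preselect_variants(pair10, 0.5, 5e-8), 1:10)
})

test_that("reduced and full variant sets select identical instruments >= 95% of iterations", {
  scn <- sim_scenario(n_variants = 5e4, p_causal = 0.02, h2 = 0.5,
                      n_x = 1e5, n_y = 1e5, overlap_frac = 0, rho = 0)
  pair <- simulate_gwas_pair(scn, seed = 54)
  keep <- preselect_variants(pair)
  expect_lt(length(keep), nrow(pair))
  set.seed(55)
  n_iter <- 400
  mismatch <- 0
  for (k in seq_len(n_iter)) {
    s1 <- draw_first_split(pair, lambda = 0, pi1 = 0.5)
    full_sel <- select_instruments(s1$bx1, s1$se_x1)
    red_sel <- intersect(full_sel, keep)
    if (!identical(full_sel, red_sel)) mismatch <- mismatch + 1
  }
  expect_lte(mismatch / n_iter,
             0.05 + 3 * sqrt(0.05 * 0.95 / n_iter))
})

test_that("aggregation handles the degenerate and forced-identical cases", {
  scn <- sim_scenario(n_variants = 5000, p_causal = 0.02, h2 = 0.4,
                      n_x = 1e5, n_y = 1e5, overlap_frac = 0, rho = 0)
  pair <- simulate_gwas_pair(scn, seed = 61)

  fit1 <- mr_simss(pair, mode = "two_split", estimator = "ivw",
                   n_iter = 1, seed = 62)
  expect_equal(fit1$n_iter_used, 1)
  it <- fit1$iterations
  expect_equal(fit1$beta, it$beta[1])
  expect_equal(fit1$se, it$se[1]) # zero between-iteration variance

  # all iterations identical: aggregate se equals the per-iteration se
  register_mr_estimator("fixed_fit", function(dat) {
    tibble::tibble(method = "fixed_fit", beta = 0.42, se = 0.07,
                   n_instruments = nrow(dat), converged = TRUE)
  })
  fitc <- mr_simss(pair, estimator = "fixed_fit", n_iter = 20, seed = 63)
  expect_equal(fitc$beta, 0.42)
  expect_equal(fitc$se, 0.07)
})

test_that("runs are deterministic given the seed", {
  scn <- sim_scenario(n_variants = 2e4, p_causal = 0.02, h2 = 0.5,
                      n_x = 1e5, n_y = 1e5, overlap_frac = 1, rho = 0.5)
  pair <- simulate_gwas_pair(scn, seed = 64)
  a <- mr_simss(pair, n_iter = 30, seed = 65)
  b <- mr_simss(pair, n_iter = 30, seed = 65)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_identical(a$iterations, b$iterations)
})

test_that("excess skipped iterations fail with actionable advice", {
  pair <- make_pair(n = 100, seed = 66) # null data: nothing reaches 5e-8
  pair$beta_x <- rnorm(100, 0, 1e-4)
  pair$se_x <- rep(0.01, 100)
  expect_error(
    mr_simss(pair, overlap = overlap_model(1e5, 1e5, lambda = 0),
             n_iter = 10, seed = 67),
    class = "mrsimss_instability_error"
  )
})

test_that("aggregate se never exceeds the root mean per-iteration variance", {
  scn <- sim_scenario(n_variants = 2e4, p_causal = 0.02, h2 = 0.5,
                      n_x = 1e5, n_y = 1e5, overlap_frac = 0.5, rho = 0.3)
  pair <- simulate_gwas_pair(scn, seed = 68)
  fit <- mr_simss(pair, mode = "two_split", estimator = "ivw",
                  n_iter = 40, seed = 69)
  used <- fit$iterations[fit$iterations$converged, ]
  expect_lte(fit$se, sqrt(mean(used$se^2)))
})

test_that("tidy, glance and autoplot expose the fit", {
  scn <- sim_scenario(n_variants = 2e4, p_causal = 0.02, h2 = 0.5,
                      n_x = 1e5, n_y = 1e5, overlap_frac = 0, rho = 0)
  pair <- simulate_gwas_pair(scn, seed = 71)
  fit <- mr_simss(pair, mode = "two_split", estimator = "ivw",
                  n_iter = 25, seed = 72)
  td <- tidy(fit)
  expect_named(td, c("method", "estimate", "std_error", "statistic",
                     "p_value", "conf_low", "conf_high"))
  expect_equal(td$method, "simss2_ivw")
  expect_lt(td$conf_low, td$conf_high)
  gl <- glance(fit)
  expect_equal(gl$n_iter_used + gl$skipped_iterations, 25)
  expect_s3_class(autoplot(fit), "ggplot")
})
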