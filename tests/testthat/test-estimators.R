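test_that("ivw matches hand-computed values and scale equivariance", {
  one <- data.frame(bx = 0.1, se_x = 0.01, by = 0.03, se_y = 0.01)
  expect_equal(mr_ivw(one)$beta, 0.3)

  two <- data.frame(bx = c(0.1, 0.2), se_x = 0.01,
                    by = c(0.03, 0.05), se_y = 0.01)
  expect_equal(mr_ivw(two)$beta, (0.1 * 0.03 + 0.2 * 0.05) / (0.1^2 + 0.2^2))
  expect_equal(mr_ivw(two)$beta, 0.26)

  # rescaling the outcome standard errors alone leaves the point estimate
  # unchanged and scales the standard error; rescaling the whole outcome
  # (by and se_y) is equivariant
  wscaled <- two
  wscaled$se_y <- two$se_y * 10
  expect_equal(mr_ivw(wscaled)$beta, mr_ivw(two)$beta)
  expect_equal(mr_ivw(wscaled)$se, mr_ivw(two)$se * 10)
  scaled <- two
  scaled$by <- two$by * 10
  scaled$se_y <- two$se_y * 10
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(two)$beta * 10)
  expect_equal(mr_ivw(scaled)$se, mr_ivw(two)$se * 10)

  degenerate <- data.frame(bx = 0, se_x = 0.01, by = 0.1, se_y = 0.01)
  expect_error(mr_ivw(degenerate), class = "mrsimss_degenerate_error")
})

test_that("raps collapses to ivw without exposure noise and finds exact roots", {
  dat <- data.frame(bx = c(0.1, 0.25, 0.3), se_x = 0,
                    by = c(0.02, 0.08, 0.10), se_y = c(0.01, 0.02, 0.015))
  expect_equal(mr_raps(dat)$beta, mr_ivw(dat)$beta, tolerance = 1e-8)

  prop <- data.frame(bx = c(0.1, 0.2, 0.4), se_x = 0.05,
                     by = 0.3 * c(0.1, 0.2, 0.4), se_y = 0.03)
  expect_equal(mr_raps(prop)$beta, 0.3, tolerance = 1e-8)
  expect_true(mr_raps(prop)$converged)

  # overdispersion variant still recovers the proportional solution
  expect_equal(mr_raps(prop, overdispersion = TRUE)$beta, 0.3,
               tolerance = 1e-6)
})

test_that("raps is unbiased in a three-sample design with weak instruments", {
  # selection in an independent replicate removes Winner's Curse by
  # construction; profile score corrects exposure measurement error
  set.seed(41)
  n_rep <- 60
  n_var <- 2e4
  gamma_sd <- sqrt(0.3 / 200)
  est <- vapply(seq_len(n_rep), function(r) {
    gamma <- ifelse(runif(n_var) < 0.01, rnorm(n_var, 0, gamma_sd), 0)
    se <- rep(0.004, n_var)
    z_thresh <- qnorm(1 - 2.5e-8)
    z_sel <- (gamma + rnorm(n_var, 0, se)) / se
    sel <- abs(z_sel) > z_thresh
    if (sum(sel) < 2) return(NA_real_)
    bx <- gamma[sel] + rnorm(sum(sel), 0, se[sel])
    by <- 0.3 * gamma[sel] + rnorm(sum(sel), 0, se[sel])
    mr_raps(data.frame(bx = bx, se_x = se[sel], by = by, se_y = se[sel]))$beta
  }, numeric(1))
  est <- est[!is.na(est)]
  expect_lt(abs(mean(est) - 0.3), 3 * sd(est) / sqrt(length(est)))
})

test_that("egger recovers slope and intercept and is orientation invariant", {
  exact <- data.frame(bx = c(0.1, 0.2, 0.4), se_x = 0.01,
                      by = 0.05 + 0.3 * c(0.1, 0.2, 0.4), se_y = 0.01)
  fit <- mr_egger(exact)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-10)

  flipped <- exact
  flipped$bx[2] <- -exact$bx[2]
  flipped$by[2] <- -exact$by[2]
  refit <- mr_egger(flipped)
  expect_equal(refit$beta, fit$beta)
  expect_equal(refit$intercept, fit$intercept)

  # equal weights reduce to ordinary least squares (closed form on 5 points)
  set.seed(42)
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  y <- 0.02 + 0.4 * x + rnorm(5, 0, 0.01)
  ols_slope <- cov(x, y) / var(x)
  ols_int <- mean(y) - ols_slope * mean(x)
  fit_eq <- mr_egger(data.frame(bx = x, se_x = 0.01, by = y, se_y = 0.3))
  expect_equal(fit_eq$beta, ols_slope, tolerance = 1e-10)
  expect_equal(fit_eq$intercept, ols_int, tolerance = 1e-10)

  rankdef <- data.frame(bx = c(0.2, 0.2, 0.2), se_x = 0.01,
                        by = c(0.1, 0.2, 0.3), se_y = 0.01)
  expect_error(mr_egger(rankdef), class = "mrsimss_degenerate_error")
})

test_that("weighted median follows the cumulative-weight rule", {
  eq3 <- data.frame(bx = c(1, 1, 1), se_x = 0.01,
                    by = c(0.1, 0.3, 0.5), se_y = 0.01)
  expect_equal(mr_weighted_median(eq3, n_boot = 50)$beta, 0.3)

  # interpolation at an exact cumulative-weight tie of 0.5
  eq4 <- data.frame(bx = c(1, 1, 1, 1), se_x = 0.01,
                    by = c(0.1, 0.2, 0.4, 0.5), se_y = 0.01)
  expect_equal(mr_weighted_median(eq4, n_boot = 50)$beta, 0.3)

  # a ratio carrying more than half the total weight is returned as-is
  dom <- data.frame(bx = c(0.5, 2, 0.3), se_x = 0.01,
                    by = c(0.5 * 0.1, 2 * 0.3, 0.3 * 0.8), se_y = 0.01)
  w <- dom$bx^2 / dom$se_y^2
  expect_gt(max(w) / sum(w), 0.5)
  expect_equal(mr_weighted_median(dom, n_boot = 50)$beta, 0.3)

  withbad <- rbind(eq3, data.frame(bx = 0, se_x = 0.01, by = 1, se_y = 0.01))
  expect_warning(fit <- mr_weighted_median(withbad, n_boot = 50),
                 "bx = 0")
  expect_equal(fit$beta, 0.3)
})

test_that("divw equals ivw without exposure noise and centres its denominator", {
  dat <- make_instruments(n = 20, seed = 43)
  noiseless <- dat
  noiseless$se_x <- 0
  expect_equal(mr_divw(noiseless)$beta, mr_ivw(noiseless)$beta)

  # pure-noise exposure: E[denominator] = 0
  set.seed(44)
  denoms <- vapply(1:200, function(r) {
    bx <- rnorm(500, 0, 0.02)
    sum((bx^2 - 0.02^2) / 0.01^2)
  }, numeric(1))
  expect_lt(abs(mean(denoms)), 3 * sd(denoms) / sqrt(200))

  pure <- data.frame(bx = c(0.001, -0.001), se_x = 0.1,
                     by = c(0, 0), se_y = 0.1)
  expect_error(mr_divw(pure), class = "mrsimss_degenerate_error")
})

test_that("estimators agree for strong instruments and ignore variant order", {
  dat <- make_instruments(n = 40, beta = 0.3, seed = 45)
  expect_gt(min(abs(dat$bx) / dat$se_x), 50)
  fits <- list(ivw = mr_ivw(dat), raps = mr_raps(dat), egger = mr_egger(dat),
               wm = mr_weighted_median(dat, n_boot = 200))
  for (a in seq_along(fits)) {
    for (b in seq_len(a - 1)) {
      expect_lt(abs(fits[[a]]$beta - fits[[b]]$beta),
                2 * sqrt(fits[[a]]$se^2 + fits[[b]]$se^2))
    }
  }

  perm <- dat[sample(nrow(dat)), ]
  expect_equal(mr_ivw(perm)$beta, fits$ivw$beta)
  expect_equal(mr_raps(perm)$beta, fits$raps$beta, tolerance = 1e-9)

  signs <- rep(c(1, -1), length.out = nrow(dat))
  flipped <- dat
  flipped$bx <- dat$bx * signs
  flipped$by <- dat$by * signs
  expect_equal(mr_ivw(flipped)$beta, fits$ivw$beta)
  expect_equal(mr_egger(flipped)$beta, fits$egger$beta)
})

test_that("custom estimators can be registered and resolved by name", {
  register_mr_estimator("const3", function(dat) {
    tibble::tibble(method = "const3", beta = 3, se = 1,
                   n_instruments = nrow(dat), converged = TRUE)
  }, min_instruments = 1)
  expect_true("const3" %in% mr_estimators())
  expect_equal(mr_estimator("const3")$fn(data.frame(x = 1))$beta, 3)
  expect_error(mr_estimator("nope"), class = "mrsimss_format_error")
})
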