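# OLS, backward elimination, cross-validation, LMG importance, screens.

sim_lm_data <- function(n = 200, seed = 1, noise = 1) {
  withr::with_seed(seed, {
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + noise * rnorm(n)
    d
  })
}

test_that("exact linear data is recovered exactly", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  # noiseless data makes summary/drop1 warn about a perfect fit
  fit <- suppressWarnings(ols_fit(d, "y", "x"))
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("OLS matches the normal-equations oracle on random instances", {
  for (seed in 1:5) {
    d <- sim_lm_data(n = 80, seed = seed)
    fit <- ols_fit(d, "y", c("x1", "x2", "x3"))
    X <- cbind(1, as.matrix(d[c("x1", "x2", "x3")]))
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-8)
    # AIC under the Gaussian likelihood with the variance counted
    rss <- sum((d$y - X %*% beta)^2)
    n <- nrow(d)
    loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
    expect_equal(fit$aic, -2 * loglik + 2 * (ncol(X) + 1), tolerance = 1e-8)
  }
})

test_that("a response independent of the predictors has near-zero fit", {
  withr::with_seed(3, {
    d <- tibble::tibble(x1 = rnorm(10000), x2 = rnorm(10000),
                        y = rnorm(10000))
  })
  fit <- ols_fit(d, "y", c("x1", "x2"))
  expect_lt(fit$r_squared, 0.01)
  expect_lt(max(abs(fit$coefficients[-1])), 0.05)
})

test_that("collinear predictors are rejected by name", {
  d <- sim_lm_data(50)
  d$x1_copy <- d$x1
  expect_error(ols_fit(d, "y", c("x1", "x1_copy")), "x1_copy")
})

test_that("backward elimination keeps informative predictors, drops noise", {
  d <- sim_lm_data(n = 1000, seed = 5, noise = 0.5)
  res <- backward_eliminate_aic(d, "y", c("x1", "x2"))
  expect_setequal(res$retained, c("x1", "x2"))
  # AIC never increases along the elimination path
  drops <- 0
  for (seed in 1:10) {
    d <- sim_lm_data(n = 1000, seed = seed, noise = 1)
    d$noisevar <- withr::with_seed(seed + 100, rnorm(nrow(d)))
    res <- backward_eliminate_aic(d, "y", c("x1", "x2", "noisevar"))
    expect_true(all(diff(res$steps$aic) <= 0))
    if (!("noisevar" %in% res$retained)) drops <- drops + 1
    expect_true(all(c("x1", "x2") %in% res$retained))
  }
  expect_gt(drops / 10, 0.8)
  # a single informative predictor is retained
  d1 <- sim_lm_data(100)
  expect_equal(backward_eliminate_aic(d1, "y", "x1")$retained, "x1")
})

test_that("repeated k-fold CV: noiseless, noise-only and determinism", {
  d <- tibble::tibble(x = rnorm(100), y = 3 * rnorm(1) + 1)
  d$y <- 2 * d$x + 1  # noiseless
  expect_equal(repeated_kfold_r2(d, "y", "x", repeats = 3, seed = 4), 1,
               tolerance = 1e-9)
  withr::with_seed(8, {
    dn <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  })
  cv <- repeated_kfold_r2(dn, "y", "x", repeats = 10, seed = 4)
  expect_lt(cv, 0.05)
  # same seed twice gives the identical value
  d2 <- sim_lm_data(120, seed = 2)
  a <- repeated_kfold_r2(d2, "y", c("x1", "x2"), repeats = 5, seed = 99)
  b <- repeated_kfold_r2(d2, "y", c("x1", "x2"), repeats = 5, seed = 99)
  expect_identical(a, b)
})

test_that("LMG shares match brute-force ordering enumeration", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      d <- tibble::tibble(a = rnorm(60), b = rnorm(60), c = rnorm(60))
      d$b <- d$b + 0.6 * d$a           # induce collinearity
      d$y <- d$a + 0.5 * d$b - 0.3 * d$c + rnorm(60)
    })
    pkg <- lmg_relative_importance(d, "y", c("a", "b", "c"))
    oracle <- lmg_oracle(d, "y", c("a", "b", "c"))
    expect_equal(pkg$share_total_variance, oracle, tolerance = 1e-10)
    # shares sum exactly to the full model's R^2
    full <- ols_fit(d, "y", c("a", "b", "c"))
    expect_equal(sum(pkg$share_total_variance), full$r_squared,
                 tolerance = 1e-9)
    expect_true(all(pkg$share_total_variance >= 0))
  }
})

test_that("orthogonal and duplicated predictors give the expected shares", {
  # two near-orthogonal predictors: shares equal their marginal R^2
  withr::with_seed(10, {
    n <- 5000
    d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
    d$y <- sqrt(0.3) * d$a / stats::sd(d$a) + sqrt(0.1) * d$b / stats::sd(d$b) +
      sqrt(0.6) * rnorm(n)
  })
  shares <- lmg_relative_importance(d, "y", c("a", "b"))
  expect_equal(shares$share_total_variance[1], 0.3, tolerance = 0.03)
  expect_equal(shares$share_total_variance[2], 0.1, tolerance = 0.03)
  # duplicated predictors (tiny jitter) split the importance equally
  withr::with_seed(11, {
    d2 <- tibble::tibble(a = rnorm(500))
    d2$b <- d2$a + 1e-6 * rnorm(500)
    d2$y <- d2$a + rnorm(500)
  })
  s2 <- lmg_relative_importance(d2, "y", c("a", "b"))
  expect_equal(s2$share_total_variance[1], s2$share_total_variance[2],
               tolerance = 1e-3)
  # too many predictors for exact enumeration
  d3 <- tibble::as_tibble(as.data.frame(matrix(rnorm(30 * 11), 30)))
  d3$y <- rnorm(30)
  expect_error(lmg_relative_importance(d3, "y", names(d3)[1:11]), "10")
})

test_that("pearson screen matches its sampling distribution", {
  expect_equal(pearson_screen(1:10, 1:10)$r, 1)
  expect_equal(pearson_screen(1:10, -(1:10))$r, -1)
  withr::with_seed(21, {
    n <- 10000
    x <- rnorm(n)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  })
  s <- pearson_screen(x, y)
  expect_gt(s$r, 0.47); expect_lt(s$r, 0.53)
  expect_lt(s$p_value, 1e-10)
  expect_error(pearson_screen(rep(1, 10), 1:10), "variance")
})

test_that("feeding-group trend models recover generative signs", {
  withr::with_seed(14, {
    n <- 800
    samples <- tibble::tibble(
      sample_id = sprintf("s%04d", 1:n),
      landuse_pct = runif(n, 0, 100),
      altitude_m = runif(n, 0, 2000))
    props <- tibble::tibble(
      sample_id = samples$sample_id,
      generalist = 0.3 + 0.003 * samples$landuse_pct + rnorm(n, 0, 0.04),
      specialist = 0.4 - 0.002 * samples$landuse_pct + rnorm(n, 0, 0.04),
      neutral = 0.5 + rnorm(n, 0, 0.04))
  })
  fits <- trend_models(props, samples)
  gen_lu <- fits[fits$category == "generalist" & fits$term == "landuse_pct", ]
  spec_lu <- fits[fits$category == "specialist" & fits$term == "landuse_pct", ]
  neu <- fits[fits$category == "neutral", ]
  expect_gt(gen_lu$estimate, 0); expect_lt(gen_lu$p_value, 1e-4)
  expect_lt(spec_lu$estimate, 0); expect_lt(spec_lu$p_value, 1e-4)
  # a response independent of both covariates stays within 2 SE of zero
  expect_true(all(neu$p_value > 1e-3))
  # constant responses are flagged, not fitted
  props$flat <- 0.25
  fits2 <- trend_models(props, samples)
  expect_true(all(fits2$degenerate[fits2$category == "flat"]))
})

test_that("index model assembles CV, importances and tidies cleanly", {
  withr::with_seed(30, {
    n <- 400
    d <- tibble::tibble(
      n_taxa = rpois(n, 100), connectance = runif(n, 0, 0.2),
      mean_strength = rnorm(n, 6), modularity = runif(n, 0, 0.6),
      degree_heterogeneity = 1 + rexp(n))
    d$mean_csci <- 0.3 + 4.6e-3 * d$n_taxa - 1.2 * d$connectance -
      1.8e-2 * d$mean_strength + 0.3 * d$modularity +
      0.1 * d$degree_heterogeneity + rnorm(n, 0, 0.05)
  })
  fit <- fit_index_model(d, cv_repeats = 5, seed = 3)
  expect_s3_class(fit, "index_model")
  expect_gt(fit$cv_r_squared, 0.5)
  expect_equal(sum(fit$relative_importance$share_total_variance),
               fit$r_squared, tolerance = 1e-9)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "f_statistic",
                    "importance_pct_explained") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_lte(gl$cv_r_squared, gl$r_squared)
  pred <- predict(fit, d[1:5, ])
  expect_length(pred, 5)
})
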