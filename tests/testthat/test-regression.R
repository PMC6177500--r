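test_that("the full model interpolates its own generating coefficients", {
  set.seed(2)
  wss <- runif(500, 0.5, 3); d <- runif(500, 3, 8)
  beta <- c(0.8, -0.3, 0.05, 0.02)
  wt <- beta[1] + beta[2] * wss + beta[3] * d + beta[4] * wss * d
  fit <- fit_wt_regression(wt, wss, d)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("reduced models fit their own structure exactly", {
  x <- seq(0.2, 3, length.out = 50)
  fit <- fit_wt_regression(2 - x, x, rep(5, 50), terms = "wss")
  expect_equal(unname(coef(fit)), c(2, -1), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # constant regressor in the requested terms is rejected by name
  expect_error(fit_wt_regression(2 - x, x, rep(5, 50), terms = c("wss", "d")),
               "collinear.*d")
})

test_that("OLS matches the normal-equations oracle on random problems", {
  # independent oracle: solve(t(X) X) t(X) y
  set.seed(9)
  for (rep in 1:10) {
    wss <- runif(200, 0.5, 3); d <- runif(200, 3, 8)
    wt <- rnorm(200, 1, 0.3)
    fit <- fit_wt_regression(wt, wss, d)
    X <- cbind(1, wss, d, wss * d)
    oracle <- solve(t(X) %*% X, t(X) %*% wt)[, 1]
    expect_equal(unname(coef(fit)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("coefficient estimates fall within OLS sampling bands", {
  # noisy vertices: beta-hat within 3 SE of truth in almost all seeds
  beta <- c(1.2, -0.3, 0.08, 0.02)
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    wss <- runif(5000, 0.5, 3); d <- runif(5000, 3, 8)
    wt <- beta[1] + beta[2] * wss + beta[3] * d + beta[4] * wss * d +
      rnorm(5000, 0, 0.2)
    X <- cbind(1, wss, d, wss * d)
    fit <- fit_wt_regression(wt, wss, d)
    se <- sqrt(diag(solve(t(X) %*% X)) *
                 sum(residuals(fit)^2) / (5000 - 4))
    all(abs(coef(fit) - beta) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.99 - 2/40)  # binomial slack at 40 draws
})

test_that("prediction applies coefficients term-by-term", {
  wss <- runif(100, 0.5, 3); d <- runif(100, 3, 8)
  p <- predict_wt_map(wss, d, c(`(Intercept)` = 1), terms = character(0))
  expect_equal(as.numeric(p), rep(1, 100))
  beta <- c(`(Intercept)` = 0.5, wss = -0.2)
  p2 <- predict_wt_map(wss, d, beta, terms = "wss")
  expect_equal(as.numeric(p2), 0.5 - 0.2 * wss)
  expect_equal(attr(p2, "n_negative"), sum(0.5 - 0.2 * wss < 0))
  expect_error(predict_wt_map(wss, d, c(`(Intercept)` = 1, bogus = 2),
                              terms = "wss"), "names")
  expect_error(predict_wt_map(wss, d, c(`(Intercept)` = NA_real_),
                              terms = character(0)), "finite")
})

test_that("own-fit prediction reproduces WT minus residual exactly", {
  set.seed(13)
  wss <- runif(300, 0.5, 3); d <- runif(300, 3, 8)
  wt <- 1 - 0.2 * wss + 0.05 * d + rnorm(300, 0, 0.1)
  fit <- fit_wt_regression(wt, wss, d)
  pred <- predict(fit)
  expect_equal(pred, wt - residuals(fit), tolerance = 1e-12)
  # nesting: full-model R^2 >= reduced models on the same data
  for (tt in list("wss", "d", "wss_d")) {
    expect_gte(fit$r_squared + 1e-12,
               fit_wt_regression(wt, wss, d, terms = tt)$r_squared)
  }
})

test_that("wt_fit methods behave like a standard model object", {
  set.seed(17)
  wss <- runif(120, 0.5, 3); d <- runif(120, 3, 8)
  wt <- 1 - 0.2 * wss + rnorm(120, 0, 0.05)
  fit <- fit_wt_regression(wt, wss, d, source = "S01")
  expect_output(print(fit), "wt_fit")
  expect_output(print(summary(fit)), "R-squared")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(length(sims[[1]]), 120)
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, sims2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("bootstrap regressions on identical subjects collapse to one beta", {
  wss <- matrix(rep(runif(50, 0.5, 3), each = 4), 4)
  d <- matrix(rep(runif(50, 3, 8), each = 4), 4)
  wt <- 1 + -0.25 * wss + 0.06 * d + 0.01 * wss * d
  set <- as_cohort_map_set(list(wt = wt, wss = wss, d = d))
  be <- fit_bootstrap_regressions(set, B = 25, seed = 3)
  expect_equal(unname(be$ci95[1, ]), unname(be$ci95[2, ]), tolerance = 1e-12)
  expect_equal(unname(be$mean_beta), c(1, -0.25, 0.06, 0.01),
               tolerance = 1e-9)
  # fixed seed -> bit-identical ensembles
  be2 <- fit_bootstrap_regressions(set, B = 25, seed = 3)
  expect_identical(be$beta, be2$beta)
})

test_that("shared multisets make correlation and regression bootstraps coherent", {
  cfg <- small_config(n_subjects = 5L, seed = 88, noise_sd = 0.1)
  tm <- truth_map_set(cfg)
  ms <- bootstrap_multisets(5, 40, seed = 12)
  bc <- bootstrap_correlations(tm$set, pairs = "wt_wss", multisets = ms)
  be <- fit_bootstrap_regressions(tm$set, multisets = ms)
  expect_equal(bc$wt_wss$B, be$B)
  # replicate 1 refit by hand from the same multiset
  cv <- tm$set$complete_vertices
  f1 <- fit_wt_regression(average_maps(tm$set, ms[1, ], "wt")[cv],
                          average_maps(tm$set, ms[1, ], "wss")[cv],
                          average_maps(tm$set, ms[1, ], "d")[cv])
  expect_equal(unname(be$beta[1, ]), unname(coef(f1)), tolerance = 1e-12)
})

test_that("prediction evaluation identities hold", {
  v <- runif(200, 0.5, 2)
  ev <- evaluate_prediction(v, v)
  expect_equal(ev$spearman_rho, 1)
  expect_equal(ev$mean_difference, 0)
  expect_equal(ev$loa, 0)
  expect_equal(ev$max_wt_original, ev$max_wt_predicted)
  ev2 <- evaluate_prediction(v, v + 0.5)
  expect_equal(ev2$spearman_rho, 1)
  expect_equal(ev2$mean_difference, 0.5)
  expect_equal(ev2$loa, 0)
  # top-5% arithmetic: values 1..100 -> mean(96:100) = 98
  ev3 <- evaluate_prediction(1:100, 1:100)
  expect_equal(ev3$max_wt_original, 98)
  # constant maps: rho undefined, reported missing
  ev4 <- evaluate_prediction(rep(1, 10), rep(2, 10))
  expect_true(is.na(ev4$spearman_rho))
})

test_that("cohort-averaged coefficients predict a held-out subject", {
  cfg <- cohort_config(n_subjects = 8L, seed = 202, noise_sd = 0.05,
                       n_circ = 16L, ring_spacing = 1.2,
                       lengths = c(cca = 16, ica = 12, eca = 12))
  subs <- generate_cohort(cfg, velocity = FALSE)
  tm_fit <- truth_map_set(small_config(n_subjects = 6L, seed = 203,
                                       noise_sd = 0.05))
  be <- fit_bootstrap_regressions(tm_fit$set, B = 100, seed = 7)
  held <- subs[[8]]
  pred <- predict_wt_map(held$truth$wss, held$truth$diameter, coef(be),
                         mesh = held$lumen)
  ev <- evaluate_prediction(held$truth$wt, pred)
  expect_gt(ev$spearman_rho, 0.9)
})
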