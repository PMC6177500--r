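test_that("Spearman rho matches the rank-difference formula on tie-free data", {
  # independent oracle: 1 - 6*sum(d^2) / (n (n^2 - 1))
  oracle <- function(a, b) {
    d <- rank(a) - rank(b)
    1 - 6 * sum(d^2) / (length(a) * (length(a)^2 - 1))
  }
  expect_equal(spearman_rho(c(1, 4, 9, 16), c(1, 4, 9, 16)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(as.numeric(spearman_rho(1:5, c(2, 1, 4, 3, 5))), 0.8)
  set.seed(7)
  for (n in c(4, 7, 12)) {
    for (rep in 1:20) {
      a <- sample(seq_len(100), n)  # tie-free
      b <- sample(seq_len(100), n)
      expect_equal(as.numeric(spearman_rho(a, b)), oracle(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate inputs yield missing rho with a reason", {
  r <- spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "variance")
  r2 <- spearman_rho(c(1, NA), c(2, 3))
  expect_match(attr(r2, "reason"), "pairs")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(11)
  a <- rnorm(40); b <- rnorm(40)
  base <- as.numeric(spearman_rho(a, b))
  expect_equal(as.numeric(spearman_rho(exp(a), b)), base)
  expect_equal(as.numeric(spearman_rho(a, b^3 + 2 * b)), base)
  expect_equal(as.numeric(spearman_rho(-a, b)), -base)
})

test_that("Fisher z-test matches atanh closed form and flags strong coupling", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  z0 <- fisher_z_test(rep(0, 10))
  expect_equal(z0$p_value, 1)
  expect_equal(z0$t, 0)
  set.seed(3)
  rhos <- tanh(rnorm(20, atanh(-0.6), 0.15))
  ft <- fisher_z_test(rhos)
  expect_lt(ft$p_value, 0.001)
  expect_equal(ft$mean_rho, mean(rhos))
  expect_equal(ft$sd_rho, sd(rhos))
  expect_warning(fisher_z_test(c(0.5, 1)), "clipped")
  # cross-check p-value against t.test on the z scale
  expect_equal(ft$p_value, t.test(atanh(rhos))$p.value)
})

test_that("synthetic cohorts with negative coupling give p < 0.001", {
  cfg <- small_config(n_subjects = 8L, seed = 77, noise_sd = 0.05)
  subs <- generate_cohort(cfg, velocity = FALSE)
  r <- individual_correlations(lapply(subs, function(s) s$truth$wt),
                               lapply(subs, function(s) s$truth$wss))
  expect_lt(r$mean_rho, 0)
  expect_lt(r$p_value, 0.001)
})

test_that("bootstrap correlations are reproducible and degenerate cases exact", {
  # WT an exact monotone decreasing function of WSS, no noise:
  # every replicate has rho = -1, CI [-1, -1], significant
  set.seed(5)
  wss <- matrix(runif(6 * 40, 0.5, 3), 6)
  wt <- 2 - 0.4 * wss
  set <- as_cohort_map_set(list(wt = wt, wss = wss))
  bc <- bootstrap_correlations(set, pairs = "wt_wss", B = 50, seed = 4)$wt_wss
  expect_equal(bc$rho_per_bootstrap, rep(-1, 50), tolerance = 1e-12)
  expect_equal(bc$ci95, c(-1, -1), tolerance = 1e-12)
  expect_true(bc$significant)
  # fixed seed -> identical replicate rho vectors
  b1 <- bootstrap_correlations(set, pairs = "wt_wss", B = 30, seed = 9)$wt_wss
  b2 <- bootstrap_correlations(set, pairs = "wt_wss", B = 30, seed = 9)$wt_wss
  expect_identical(b1$rho_per_bootstrap, b2$rho_per_bootstrap)
  # B = 1 degenerates to a single rho with zero-width CI
  b3 <- bootstrap_correlations(set, pairs = "wt_wss", B = 1, seed = 2)$wt_wss
  expect_equal(b3$ci95[1], b3$ci95[2])
  expect_equal(b3$ci95[1], b3$rho_per_bootstrap[1])
})

test_that("bootstrap CI width shrinks as vertex noise vanishes", {
  widths <- vapply(c(0.4, 0.2, 0.05), function(ns) {
    cfg <- small_config(n_subjects = 6L, seed = 101, noise_sd = ns)
    tm <- truth_map_set(cfg)
    bc <- bootstrap_correlations(tm$set, pairs = "wt_wss", B = 150,
                                 seed = 33)$wt_wss
    diff(bc$ci95)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("linearity check separates linear, constant and curved trends", {
  set.seed(21)
  x <- runif(400, -1, 1)
  lin <- linearity_check(x, 2 + 3 * x + rnorm(400, 0, 0.05))
  expect_true(lin$adequate)
  quad <- linearity_check(x, x^2)
  expect_false(quad$adequate)
  const <- linearity_check(x, rep(1.5, 400))
  expect_true(const$adequate)
  few <- linearity_check(rep(c(0, 1), 50), rnorm(100))
  expect_true(is.na(few$adequate))
  expect_match(few$reason, "deciles")
})
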