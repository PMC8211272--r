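test_that("noise variance estimator", {
  # identical trials everywhere -> 0
  r <- array(3, c(5, 2, 2))
  expect_equal(noise_variance(r), c(0, 0))
  # two images with trials {0,2} and {1,3}: unbiased variance 2 each
  r2 <- array(NA_real_, c(2, 2, 1))
  r2[1, , 1] <- c(0, 2); r2[2, , 1] <- c(1, 3)
  expect_equal(noise_variance(r2), 2)
  # Poisson responses: noise variance ~ mean rate
  set.seed(30)
  mu <- c(1.5, 4)
  r3 <- array(rpois(2000 * 2 * 2, rep(mu, each = 2000 * 2)), c(2000, 2, 2))
  expect_equal(noise_variance(r3), mu, tolerance = 0.12)
  # single-trial data has no noise estimate
  r4 <- array(NA_real_, c(3, 2, 1)); r4[, 1, 1] <- 1:3
  expect_true(is.na(noise_variance(r4)))
})

test_that("explainable variance and the inclusion filter", {
  # noiseless deterministic neuron: explainable = total
  r <- array(rep(1:10, 2), c(10, 2, 1))
  expect_equal(explainable_variance(r), var(rep(1:10, 2)))
  # constant-mean Poisson neuron: explainable ~ 0
  set.seed(31)
  r2 <- array(rpois(3000 * 2, 3), c(3000, 2, 1))
  expect_lt(abs(explainable_variance(r2)), 0.25)
  # filter removes low-ratio neurons at the 0.15 threshold
  set.seed(32)
  drive <- rep(c(0, 6), each = 500)
  driven <- array(rpois(2000, rep(drive, 2)), c(1000, 2, 1))
  flat <- array(rpois(2000, 3), c(1000, 2, 1))
  rboth <- array(c(driven, flat), c(1000, 2, 2))
  kept <- filter_neurons(rboth, threshold = 0.15)
  expect_equal(as.integer(kept), 1L)
  expect_length(attr(kept, "ratio"), 2)
})

test_that("FEV identities", {
  set.seed(33)
  n_img <- 1000
  mu <- runif(n_img, 0.5, 6)
  r <- array(rpois(n_img * 2, rep(mu, 2)), c(n_img, 2, 1))
  # predicting the true mean scores ~1
  f1 <- fev(r, matrix(mu, n_img, 1))
  expect_equal(f1$mean_fev, 1, tolerance = 0.1)
  # predicting the grand mean scores 0 up to the estimator's algebra
  rbar <- mean(r)
  f0 <- fev(r, matrix(rbar, n_img, 1))
  # residual variance then equals total variance (both noise-corrected):
  # exact zero would need matching 1/N vs 1/(N-1) conventions, so allow a
  # small numerical gap
  expect_lt(abs(f0$mean_fev), 0.02)
  # noiseless case: per-image mean prediction gives exactly 1
  rdet <- array(rep(1:8, 2), c(8, 2, 1))
  fd <- fev(rdet, matrix(1:8, 8, 1))
  expect_equal(fd$fev[1], 1, tolerance = 1e-12)
})

test_that("average correlation handles constant predictions", {
  r_mean <- matrix(c(1, 2, 3, 4, 2, 2, 2, 2), 4, 2)
  # perfect prediction -> 1; constant prediction -> 0
  rhat <- cbind(r_mean[, 1], rep(5, 4))
  ac <- avg_correlation(r_mean, rhat)
  expect_equal(attr(ac, "per_neuron"), c(1, 0))
  expect_equal(as.numeric(ac), 0.5)
  # anti-correlated pair -> -1
  ac2 <- avg_correlation(matrix(1:4, 4, 1), matrix(4:1, 4, 1))
  expect_equal(as.numeric(ac2), -1)
})

test_that("model selection ranks by validation and summarizes test scores", {
  # hand-made scores 1..20 with k = 10 selects 11..20
  sel <- select_top_models(1:20, 1:20, k = 10)
  expect_setequal(sel$selected, 11:20)
  expect_equal(sel$mean, mean(11:20))
  # identical fits: zero-width interval
  sel2 <- select_top_models(rep(1, 12), rep(0.4, 12), k = 10)
  expect_equal(sel2$ci, 0)
  # k = 1 returns the single best fit
  sel3 <- select_top_models(c(0.1, 0.9, 0.5), c(1, 2, 3), k = 1)
  expect_equal(sel3$mean, 2)
  expect_warning(select_top_models(1:3, 1:3, k = 10), "fewer")
})

test_that("log-uniform hyperparameter sampling stays in the stated intervals", {
  set.seed(34)
  draws <- replicate(400, sample_hyperparameters("dn")$lambda_smooth)
  expect_true(all(draws >= 1e-9 & draws <= 10^-3.5))
  lg <- log10(draws)
  ks <- suppressWarnings(ks.test(lg, "punif", -9, -3.5))
  expect_gt(ks$p.value, 1e-4)
  set.seed(35)
  d_dn <- replicate(200, sample_hyperparameters("dn")$lambda_out)
  expect_true(all(d_dn >= 1e-8 & d_dn <= 1e2))
  set.seed(35)
  d_ns <- replicate(200, sample_hyperparameters("dn_nonspecific")$lambda_out)
  expect_true(all(d_ns >= 1e-5 & d_ns <= 1))
  set.seed(36); s1 <- sample_hyperparameters("dn")
  set.seed(36); s2 <- sample_hyperparameters("dn")
  expect_identical(s1, s2)
})
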