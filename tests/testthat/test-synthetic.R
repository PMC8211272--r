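test_that("generated images are standardized, reproducible pink noise", {
  imgs <- generate_images(300, seed = 50, style = "pink_noise")
  expect_lt(abs(mean(imgs)), 0.02)
  expect_lt(abs(sd(as.vector(imgs)) - 1), 0.02)
  imgs2 <- generate_images(300, seed = 50, style = "pink_noise")
  expect_identical(imgs, imgs2)

  # radially averaged log-log power slope ~ -2
  side <- 40
  pow <- matrix(0, side, side)
  for (j in 1:300) pow <- pow + Mod(fft(imgs[, , j]))^2
  fr <- (0:(side - 1)); fr <- ifelse(fr >= side / 2, fr - side, fr)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  sel <- rad >= 2 & rad <= 15
  fitc <- coef(lm(log(pow[sel]) ~ log(rad[sel])))
  expect_lt(abs(fitc[2] - (-2)), 0.3)

  # aperture blanks the corners
  imga <- generate_images(10, seed = 51, aperture = TRUE)
  expect_equal(unname(imga[1, 1, ]), rep(imga[1, 1, 1], 10))
})

test_that("raw-image preprocessing downsamples, crops and standardizes", {
  set.seed(52)
  raw <- array(rnorm(140 * 140 * 4, mean = 111.5, sd = 45), c(140, 140, 4))
  raw[, , 4] <- 128  # one constant image among varied ones
  out <- preprocess_images(raw)
  expect_equal(dim(out), c(40L, 40L, 4L))
  expect_lt(abs(mean(out)), 1e-10)
  # the constant image is flat after population standardization
  expect_equal(sd(out[, , 4]), 0)
  # crop is symmetric: offset 15 on the 70x70 downsampled grid
  raw2 <- array(0, c(140, 140, 1))
  raw2[31, 31, 1] <- 400  # downsampled pixel (16, 16) -> cropped (1, 1)
  out2 <- preprocess_images(raw2)
  expect_equal(which(out2[, , 1] == max(out2[, , 1]), arr.ind = TRUE)[1, ],
               c(row = 1, col = 1))
  expect_error(preprocess_images(array(0, c(60, 60, 1))), "80")
})

test_that("ground-truth construction plants the stated structure", {
  cfg <- synthetic_config(n_neurons = 6, channels = 16, kappa = 1, seed = 3)
  gt <- make_ground_truth(cfg)
  th <- attr(gt, "theta")
  expect_gte(length(unique(round(th, 6))), 8)
  # orientation estimator recovers the construction angles within 5 degrees
  est <- dnv1:::estimate_orientations(gt$core$subunit$w)
  for (c in seq_along(est)) {
    expect_true(est[[c]]$oriented)
    d <- dnv1:::ori_diff(est[[c]]$theta, th[c])
    expect_lt(d * 180 / pi, 5)
  }
  # kappa = 0 gives constant columns (nonspecific ground truth)
  gt0 <- make_ground_truth(synthetic_config(n_neurons = 6, channels = 16,
                                            kappa = 0, seed = 3))
  p0 <- gt0$core$dn$p
  expect_true(all(abs(sweep(p0, 2, colMeans(p0))) < 1e-12))
  # planted similar/dissimilar ratio exceeds 1 for kappa = 1 (unit drives)
  sp <- split_similar_dissimilar(gt$core$dn$p, est)
  expect_gt(sp$ratio, 1)
})

test_that("simulated populations have Poisson statistics and 64/16/20 splits", {
  cfg <- synthetic_config(n_images = 1500, n_neurons = 8, trials = 4,
                          channels = 8, seed = 9)
  imgs <- generate_images(cfg$n_images, seed = 9)
  gt <- make_ground_truth(cfg)
  ds <- simulate_population(gt, imgs, trials = 4, seed = 10)
  expect_s3_class(ds, "dnv1_dataset")
  expect_equal(dim(ds$responses), c(1500L, 4L, 8L))
  expect_true(all(ds$responses >= 0 & ds$responses == round(ds$responses)))
  # split fractions
  expect_equal(as.integer(table(ds$split)), c(960L, 240L, 300L))
  # aggregate Fano factor within [0.9, 1.1]
  vr <- apply(ds$responses, c(1, 3), var)
  mn <- apply(ds$responses, c(1, 3), mean)
  fano <- mean(vr[mn > 0.5] / mn[mn > 0.5])
  expect_gt(fano, 0.9); expect_lt(fano, 1.1)
  # noise variance matches the mean rate per neuron
  expect_equal(noise_variance(ds$responses), colMeans(ds$rates),
               tolerance = 0.12)
  # a unit with zero mean rate yields all-zero counts
  gt0 <- gt
  gt0$readout$b <- gt$readout$b * 0
  gt0$readout$q <- rep(-50, 8)
  ds0 <- simulate_population(gt0, imgs[, , 1:50, drop = FALSE], 2, seed = 1)
  expect_true(all(ds0$responses == 0))
})

test_that("default synthetic populations sit in the emulated variance regime", {
  ds <- synth_dataset(synthetic_config(n_images = 600, n_neurons = 12,
                                       seed = 21))
  ratio <- explainable_variance(ds$responses) /
    dnv1:::total_variance(ds$responses)
  expect_gt(mean(ratio), 0.285 - 0.15)
  expect_lt(mean(ratio), 0.285 + 0.15)
  expect_gt(mean(ds$responses), 0.5)
  expect_lt(mean(ds$responses), 10)
})
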