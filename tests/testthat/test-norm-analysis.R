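test_that("orientation estimator recovers Gabor angles and rejects blobs", {
  # isotropic Gaussian blob: below the orientation threshold
  blob <- outer(dnorm(-6:6, sd = 2.5), dnorm(-6:6, sd = 2.5))
  eb <- estimate_orientation(blob)
  expect_lt(eb$magnitude, 0.125)
  expect_false(eb$oriented)
  # all-zero filter: unoriented with |m| = 0
  e0 <- estimate_orientation(matrix(0, 13, 13))
  expect_equal(e0$magnitude, 0)

  # synthetic Gabors at known angles recovered within 5 degrees
  for (deg in c(0, 30, 75, 120, 160)) {
    th <- deg * pi / 180
    g <- render_gabor(gabor_params(center = c(7, 7), size = 10, freq = 2.5,
                                   phase = 0, ori = th), 13)
    e <- estimate_orientation(g)
    expect_gte(e$magnitude, 0.125)
    d <- min(abs(e$theta - th %% pi), pi - abs(e$theta - th %% pi))
    expect_lt(d * 180 / pi, 5)
  }

  # rotating a filter by 90 degrees rotates the estimate by 90 degrees
  g <- render_gabor(gabor_params(center = c(7, 7), size = 10, freq = 2.5,
                                 phase = 0, ori = pi / 6), 13)
  g90 <- t(g)[, 13:1]  # exact 90-degree rotation of the sampled filter
  e1 <- estimate_orientation(g)
  e2 <- estimate_orientation(g90)
  d <- abs(dnv1:::ori_diff(e1$theta, e2$theta) - pi / 2)
  expect_lt(d * 180 / pi, 5)

  # invariant to sign and positive scaling
  e3 <- estimate_orientation(-3.7 * g)
  expect_equal(e3$theta, e1$theta, tolerance = 1e-10)
  expect_equal(e3$magnitude, e1$magnitude, tolerance = 1e-10)
})

test_that("normalization-input matrix averages the denominator quantity", {
  # constant drive: filter sees nothing, bias gives y = 2 everywhere
  C <- 1
  w <- array(0, c(3, 3, C))
  sub <- subunit_params(w, o = 2, bn = NULL)
  dn <- dn_params(n = 1, sigma = 1, p = matrix(0.5, 1, 1))
  cfg <- core_config(channels = 1, kernel = 3, pool = 3, variant = "dn",
                     image_side = 9)
  ro <- readout_params(array(1, c(7, 7, 1)), matrix(1, 1, 1), q = 0)
  model <- dn_model(cfg, sub, dn, ro)
  imgs <- array(rnorm(81 * 3), c(9, 9, 3))
  # unpooled variant: exactly p * y^n = 0.5 * 2
  M_raw <- normalization_input_matrix(model, imgs, pooled = FALSE)
  expect_equal(as.numeric(M_raw), 1.0, tolerance = 1e-12)
  # pooled variant: border pixels are under-pooled, so slightly below 1
  M <- normalization_input_matrix(model, imgs, pooled = TRUE)
  expect_lt(as.numeric(M), 1.0)
  expect_gt(as.numeric(M), 0.5)
  # zero weights give a zero matrix
  model$core$dn$p <- matrix(0, 1, 1)
  expect_equal(as.numeric(normalization_input_matrix(model, imgs)), 0)
})

test_that("orientation splits and bins of the normalization input", {
  # build estimates at evenly spaced angles
  C <- 8
  th <- pi * (0:(C - 1)) / C
  est <- lapply(th, function(t)
    structure(list(m = exp(2i * t), magnitude = 1, theta = t,
                   oriented = TRUE), class = "dnv1_orientation"))
  # mass only below 45 degrees -> capped infinite ratio
  dth <- dnv1:::ori_diff(outer(th, rep(1, C)), t(outer(th, rep(1, C))))
  Msim <- ifelse(dth < pi / 4, 1, 0)
  sp <- split_similar_dissimilar(Msim, est)
  expect_true(is.infinite(sp$ratio) && sp$capped)
  # uniform M over a uniform orientation distribution: ratio ~ 1
  set.seed(44)
  thr <- runif(300, 0, pi)
  estr <- lapply(thr, function(t)
    structure(list(m = exp(2i * t), magnitude = 1, theta = t,
                   oriented = TRUE), class = "dnv1_orientation"))
  spu <- split_similar_dissimilar(matrix(1, 300, 300), estr)
  expect_equal(spu$ratio, 1, tolerance = 0.1)
  # planted von-Mises-like profile: ratio matches direct computation
  kappa <- 1
  Mk <- exp(kappa * cos(2 * dth))
  spk <- split_similar_dissimilar(Mk, est)
  expect_gt(spk$ratio, 1)
  direct <- sum(Mk[dth < pi / 4]) / sum(Mk[dth >= pi / 4])
  expect_equal(spk$ratio, direct, tolerance = 1e-12)

  # bins partition [0, 90]; all mass at zero difference lands in bin one
  bins <- bin_by_orientation_difference(diag(C), est)
  expect_equal(nrow(bins), 9)
  expect_equal(bins$mean[1] * bins$n_pairs[1], C)
  expect_true(all(is.na(bins$mean) | bins$mean >= 0))
  # conservation: bin means times counts reconstruct the total
  binsk <- bin_by_orientation_difference(Mk, est)
  tot <- sum(binsk$mean * binsk$n_pairs, na.rm = TRUE)
  expect_equal(tot, sum(Mk), tolerance = 1e-9)
  # planted decreasing profile is recovered as decreasing
  ok <- !is.na(binsk$mean)
  expect_lt(cor(seq_len(9)[ok], binsk$mean[ok], method = "spearman"), 0)
})

test_that("cosine-similarity split separates matched and opposed filters", {
  set.seed(40)
  w <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  w[, , 2] <- -w[, , 1]          # exact negation
  M <- matrix(1, 3, 3)
  cs <- cosine_similarity_split(M, w)
  # self pairs are similar, the negated pair dissimilar
  fmat <- matrix(w, 25, 3)
  cosim <- crossprod(fmat) / outer(sqrt(colSums(fmat^2)),
                                   sqrt(colSums(fmat^2)))
  expect_equal(cs$similar, sum(M[cosim > 0]))
  expect_equal(cs$dissimilar, sum(M[cosim < 0]))
  expect_true(cosim[1, 2] < 0)
  expect_equal(diag(cosim), rep(1, 3), tolerance = 1e-12)
})

test_that("exponent summaries pool across models", {
  m1 <- rand_model("dn", C = 3, k = 13, side = 20)
  m2 <- rand_model("dn", C = 3, k = 13, side = 20, seed = 8)
  m1$core$dn$n <- rep(1, 3); m2$core$dn$n <- rep(2, 3)
  es <- exponent_summary(list(m1, m2))
  expect_equal(es$mean, 1.5)
  es1 <- exponent_summary(list(m1))
  expect_equal(es1$mean, 1)
  expect_equal(sum(es$hist$counts), 6)
})

test_that("readout contribution is degeneracy-invariant with a closed-form one-hot CV", {
  # identical weights -> CV 0
  expect_equal(readout_contribution(matrix(1, 4, 6))$cv, 0)
  # one channel carrying everything -> CV = sqrt(C - 1)
  C <- 8
  b <- matrix(0, C, 5); b[3, ] <- 2.2
  expect_equal(readout_contribution(b)$cv, sqrt(C - 1), tolerance = 1e-12)
  # invariant to the spatial/feature scaling degeneracy
  set.seed(41)
  b1 <- matrix(runif(12), 3, 4)
  r1 <- readout_contribution(b1)
  r2 <- readout_contribution(sweep(b1, 2, c(2, 0.5, 7, 1), "*"))
  expect_equal(r1$pooled, r2$pooled, tolerance = 1e-12)
  # all-zero neurons are excluded with a warning
  b3 <- cbind(b1, 0)
  expect_warning(r3 <- readout_contribution(b3), "all-zero")
  expect_equal(r3$pooled, r1$pooled, tolerance = 1e-12)
})
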