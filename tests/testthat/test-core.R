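test_that("subunit stage computes a valid convolution with rectification", {
  set.seed(3)
  # 40 px input with 13 px kernels gives 28 px maps
  sub <- subunit_params(array(rnorm(13 * 13 * 4, sd = 0.1), c(13, 13, 4)),
                        o = rep(0, 4), bn = NULL)
  y <- subunit_forward(array(rnorm(40 * 40 * 2), c(40, 40, 2)), sub)
  expect_equal(dim(y), c(28L, 28L, 2L, 4L))
  expect_true(all(y >= 0))

  # all-zero image, zero biases -> all-zero maps
  y0 <- subunit_forward(array(0, c(40, 40, 1)), sub)
  expect_true(all(y0 == 0))

  # hand-rolled loop oracle on a ramp image, identity standardization
  ramp <- array(seq_len(25) / 25, c(5, 5, 1))
  w <- array(0, c(3, 3, 1)); w[2, 2, 1] <- 1; w[1, 3, 1] <- -0.5
  sub1 <- subunit_params(w, o = 0.1, bn = NULL)
  y1 <- subunit_forward(ramp, sub1)
  for (i in 1:3) for (j in 1:3) {
    v <- sum(ramp[i:(i + 2), j:(j + 2), 1] * w[, , 1]) + 0.1
    expect_equal(y1[i, j, 1, 1], max(v, 0), tolerance = 1e-12)
  }

  expect_error(subunit_forward(array(NaN, c(40, 40, 1)), sub), "finite")
})

test_that("batch normalization standardizes in train mode and tracks running stats", {
  set.seed(4)
  sub <- subunit_params(array(rnorm(5 * 5 * 3, sd = 0.5), c(5, 5, 3)),
                        o = c(0.5, 0, -0.2), bn = bn_state(3))
  stim <- array(rnorm(12 * 12 * 50), c(12, 12, 50))
  expect_error(subunit_forward(stim, sub, mode = "eval"), "initialized")
  y <- subunit_forward(stim, sub, mode = "train")
  bn <- attr(y, "bn_state")
  expect_true(bn$initialized)
  # standardized pre-bias response has mean ~0 and unit variance:
  # the channel with bias 0 should be ReLU of a standard variable
  conv <- dnv1:::conv_valid(stim, sub$w)
  cm <- dnv1:::fm_mat(conv)
  expect_equal(bn$mean, colMeans(cm), tolerance = 1e-10)
  # eval mode now works and uses the stored statistics
  sub$bn <- bn
  y2 <- subunit_forward(stim[, , 1:2, drop = FALSE], sub, mode = "eval")
  expect_equal(dim(y2), c(8L, 8L, 2L, 3L))
})

test_that("divisive normalization matches the brute-force oracle", {
  y <- rand_maps(S = 12, N = 2, C = 8, seed = 42)
  par <- rand_dn_params(C = 8, seed = 43)
  z <- dn_forward(y, par, pool = 5)
  zo <- dn_oracle(y, par$n, par$sigma, par$p, pool = 5)
  expect_lt(max(abs(z - zo)), 1e-6)
  expect_true(all(z >= 0))
})

test_that("divisive normalization hand cases", {
  # p = 0, sigma = 1, n = 1 -> identity
  y <- rand_maps(S = 8, N = 1, C = 3, seed = 5)
  z <- dn_forward(y, dn_params(rep(1, 3), rep(1, 3), matrix(0, 3, 3)))
  expect_equal(z, y, tolerance = 1e-12)

  # uniform y = 2, n = 2, sigma = 1, self weight 1 -> 4 / (1 + 4) interior
  yu <- array(2, c(9, 9, 1, 1))
  zu <- dn_forward(yu, dn_params(2, 1, matrix(1, 1, 1)), pool = 5)
  expect_equal(zu[5, 5, 1, 1], 0.8, tolerance = 1e-12)

  # sigma = 0 with an empty pool is rejected
  expect_error(dn_forward(yu * 0, dn_params(1, 0, matrix(0, 1, 1))),
               "denominator")
})

test_that("scale equivalence: scaling y and sigma together leaves z unchanged (n = 1)", {
  y <- rand_maps(S = 10, N = 2, C = 4, seed = 9)
  C <- 4
  set.seed(10)
  p <- matrix(runif(C * C, 0, 0.3), C, C)
  sigma <- runif(C, 0.5, 1.5)
  beta <- 3.7
  z1 <- dn_forward(y, dn_params(rep(1, C), sigma, p))
  # with n = 1 the whole denominator scales by beta, like the numerator
  z2 <- dn_forward(beta * y, dn_params(rep(1, C), beta * sigma, p))
  expect_lt(max(abs(z1 - z2)), 1e-6)
})

test_that("extended normalization matches its five-loop oracle and degenerates to the center model", {
  set.seed(21)
  C <- 4; S <- 12; kk <- 3; dil <- 2; pool <- 3
  y <- rand_maps(S = S, N = 2, C = C, seed = 21)
  n <- runif(C, 0.5, 2); sig <- runif(C, 0.5, 1.5)
  cp <- array(runif(kk * kk * C * 2, 0, 0.3), c(kk, kk, C, 2))
  df <- array(runif(C * C * 2, 0, 0.3), c(C, C, 2))
  ep <- ext_dn_params(n, sig, cp, df, dilation = dil)
  z <- extended_dn_forward(y, ep, pool = pool)
  margin <- dil * (kk - 1) / 2
  os <- S - 2 * margin
  expect_equal(dim(z)[1:2], c(os, os))
  # explicit loop oracle
  half <- (pool - 1) / 2
  for (b in 1:2) for (l in 1:C) for (i in c(1, 4, os)) for (j in c(2, os)) {
    den <- sig[l]^n[l]
    for (k in 1:C) for (u in 1:kk) for (v in 1:kk) {
      pk <- cp[u, v, l, 1] * df[k, l, 1] + cp[u, v, l, 2] * df[k, l, 2]
      ii <- i + dil * (u - 1); jj <- j + dil * (v - 1)
      ri <- max(1, ii - half):min(S, ii + half)
      ci <- max(1, jj - half):min(S, jj + half)
      den <- den + pk * sum(y[ri, ci, b, k]^n[k]) / pool^2
    }
    zo <- y[i + margin, j + margin, b, l]^n[l] / den
    expect_lt(abs(z[i, j, b, l] - zo), 1e-6)
  }

  # 1x1 kernel equals dn_forward with the collapsed weights
  cp1 <- array(runif(C * 2, 0, 0.5), c(1, 1, C, 2))
  ep1 <- ext_dn_params(n, sig, cp1, df, dilation = 5)
  z1 <- extended_dn_forward(y, ep1, pool = 3)
  peq <- dnv1:::ext_collapse_p(ep1)
  z2 <- dn_forward(y, dn_params(n, sig, peq), pool = 3)
  expect_lt(max(abs(z1 - z2)), 1e-12)

  # maps too small for the dilated kernel are rejected
  tiny <- rand_maps(S = 4, N = 1, C = C, seed = 2)
  expect_error(extended_dn_forward(tiny, ep, pool = 3), "too small")
})

test_that("nonspecific constraint collapses each target's weights to one value", {
  par <- dn_params(rep(1, 4), rep(1, 4), diag(4))
  ns <- make_nonspecific(par)
  expect_true(all(apply(ns$p, 2, function(col) all(col == col[1]))))
  expect_equal(colMeans(ns$p), colMeans(diag(4)))
  # free weights: one per target channel instead of channels^2
  expect_equal(length(unique(as.vector(ns$p))), 1L)  # here all columns equal
  expect_true(ns$nonspecific)
})

test_that("subunit variant is the identity with an identity Jacobian", {
  y <- rand_maps(S = 6, N = 1, C = 2, seed = 3)
  expect_identical(subunit_variant(y), y)
  # gradient wrt z equals gradient wrt y: check via loss_and_grads on the
  # subunit variant (dy flows through unchanged)
  model <- rand_model("subunit", C = 2, k = 3, side = 8, I = 1)
  stim <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  r <- matrix(rpois(2, 2), 2, 1)
  lg <- dnv1:::loss_and_grads(model, stim, r, loss_config(0, 0, 0))
  expect_true(is.matrix(lg$grads$b))
})
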