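test_that("Poisson loss closed forms", {
  expect_equal(as.numeric(poisson_loss(c(1, 2), c(1, 2))),
               (1 - 0) + (2 - 2 * log(2)), tolerance = 1e-12)
  expect_equal(round(as.numeric(poisson_loss(c(1, 2), c(1, 2))), 4), 1.6137)
  # r = 0 -> loss is just the sum of predictions
  expect_equal(as.numeric(poisson_loss(c(0.3, 1.7), c(0, 0))), 2.0)
  # minimized at rhat = r (grid scan)
  r <- c(3, 1)
  grid <- seq(0.2, 6, by = 0.05)
  losses <- sapply(grid, function(x) as.numeric(poisson_loss(c(x, 1), r)))
  expect_equal(grid[which.min(losses)], 3, tolerance = 0.051)
  # non-positive predictions are floored and counted
  expect_equal(attr(poisson_loss(c(-1, 1), c(0, 0)), "n_floored"), 1L)
})

test_that("Laplace smoothness penalty", {
  # spatially constant filter: kernel entries sum to zero
  wconst <- array(0.7, c(13, 13, 2))
  expect_equal(smoothness_penalty(wconst), 0, tolerance = 1e-20)
  # single-pixel delta: penalty is the sum of squared kernel entries
  wdelta <- array(0, c(13, 13, 1)); wdelta[7, 7, 1] <- 1
  expect_equal(smoothness_penalty(wdelta), 4 * 0.25^2 + 4 * 0.5^2 + 9,
               tolerance = 1e-12)
  # smooth Gaussian beats matched-norm white noise
  g <- outer(dnorm(-6:6, sd = 2), dnorm(-6:6, sd = 2))
  g <- g / sqrt(sum(g^2))
  set.seed(16)
  wn <- matrix(rnorm(169), 13, 13); wn <- wn / sqrt(sum(wn^2))
  expect_lt(smoothness_penalty(array(g, c(13, 13, 1))),
            smoothness_penalty(array(wn, c(13, 13, 1))))
})

test_that("readout sparsity penalty is the separable L1 sum", {
  a0 <- array(0, c(4, 4, 2)); b <- matrix(1, 3, 2)
  expect_equal(sparsity_penalty(a0, b), 0)
  # one neuron, sum |a| = 2 and sum |b| = 3 -> 6
  a1 <- array(0, c(4, 4, 1)); a1[1, 1, 1] <- 2
  b1 <- matrix(c(1, 1, 1), 3, 1)
  expect_equal(sparsity_penalty(a1, b1), 6)
  # random instance vs triple loop
  set.seed(17)
  a <- array(runif(4 * 4 * 3), c(4, 4, 3)); b <- matrix(runif(6), 2, 3)
  acc <- 0
  for (i in 1:3) for (u in 1:4) for (v in 1:4) for (l in 1:2)
    acc <- acc + abs(a[u, v, i]) * abs(b[l, i])
  expect_equal(sparsity_penalty(a, b), acc, tolerance = 1e-12)
})

test_that("output nonlinearity penalty on finite differences", {
  expect_equal(output_nl_penalty(matrix(2.5, 10, 3)), 0)
  # linear coefficients: second differences vanish, first do not
  alpha <- matrix(seq(0, 1, length.out = 11), 11, 1)
  p <- output_nl_penalty(alpha)
  expect_gt(p, 0)
  expect_equal(p, sum(diff(alpha[, 1])^2) / 11, tolerance = 1e-12)
  # small instance vs loop oracle
  set.seed(18)
  al <- matrix(rnorm(5 * 2), 5, 2)
  acc <- 0
  for (i in 1:2) {
    for (j in 2:5) acc <- acc + (al[j, i] - al[j - 1, i])^2
    for (j in 2:4) acc <- acc + (2 * al[j, i] - al[j - 1, i] - al[j + 1, i])^2
  }
  expect_equal(output_nl_penalty(al), acc / 5, tolerance = 1e-12)
})

test_that("total loss composes linearly from its parts", {
  model <- rand_model("dn", C = 3, k = 5, side = 12, I = 2)
  set.seed(19)
  stim <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
  r <- matrix(rpois(8, 2), 4, 2)
  l0 <- total_loss(model, stim, r, loss_config(0, 0, 0))
  rhat <- predict(model, stim)
  expect_equal(as.numeric(l0), as.numeric(poisson_loss(rhat, r)),
               tolerance = 1e-10)
  l1 <- total_loss(model, stim, r, loss_config(0, 0.3, 0))
  expect_equal(as.numeric(l1) - as.numeric(l0),
               0.3 * sparsity_penalty(model$readout$a, model$readout$b),
               tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  for (spec in list(list(variant = "dn", bn = FALSE),
                    list(variant = "dn", bn = TRUE),
                    list(variant = "subunit", bn = TRUE),
                    list(variant = "dn_extended", bn = FALSE))) {
    model <- rand_model(spec$variant, C = 3, k = 5, side = 12, I = 2,
                        use_bn = spec$bn,
                        norm_kernel = if (spec$variant == "dn_extended") 3L else 1L)
    set.seed(20)
    stim <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
    r <- matrix(rpois(8, 2), 4, 2)
    lcfg <- loss_config(1e-3, 1e-3, 1e-2)
    lg <- dnv1:::loss_and_grads(model, stim, r, lcfg, mode = "train")
    eps <- 1e-5
    floss <- function(m) dnv1:::loss_and_grads(
      m, stim, r, lcfg, mode = "train",
      freeze = c("filters", "dn", "readout", "outputnl"))$loss
    paths <- list(w = c("core", "subunit", "w"), o = c("core", "subunit", "o"),
                  n = c("core", "dn", "n"), sigma = c("core", "dn", "sigma"),
                  p = c("core", "dn", "p"), cpool = c("core", "dn", "cpool"),
                  dfeat = c("core", "dn", "dfeat"), a = c("readout", "a"),
                  b = c("readout", "b"), q = c("readout", "q"),
                  alpha = c("readout", "alpha"))
    for (nm in names(lg$grads)) {
      if (nm == "p" && isTRUE(model$core$dn$nonspecific)) next
      path <- paths[[nm]]
      x <- model
      for (pp in path) x <- x[[pp]]
      idx <- sample(length(x), min(3, length(x)))
      for (ii in idx) {
        bump <- function(val) {
          m2 <- model
          xx <- x; xx[ii] <- x[ii] + val
          if (length(path) == 3) m2[[path[1]]][[path[2]]][[path[3]]] <- xx
          else m2[[path[1]]][[path[2]]] <- xx
          m2
        }
        num <- (floss(bump(eps)) - floss(bump(-eps))) / (2 * eps)
        an <- lg$grads[[nm]][ii]
        expect_lt(abs(num - an) / max(1e-4, abs(num), abs(an)), 1e-4)
      }
    }
  }
})
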