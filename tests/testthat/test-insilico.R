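test_that("exhaustive search finds a matched-filter Gabor", {
  # a single-unit model whose filter is itself a grid Gabor: the search
  # must return that Gabor's orientation and frequency bin
  grids <- tiny_grids()
  target <- gabor_params(center = c(20, 20), size = 15, freq = 2.5,
                         phase = 0, ori = pi / 4, amplitude = 1)
  k <- 13
  f <- render_gabor(gabor_params(center = c(7, 7), size = 15, freq = 2.5,
                                 phase = 0, ori = pi / 4), k)
  sub <- subunit_params(array(f, c(k, k, 1)), o = 0, bn = NULL)
  cfg <- core_config(channels = 1, kernel = k, variant = "subunit")
  a <- array(0, c(28, 28, 1)); a[14, 14, 1] <- 1
  model <- dn_model(cfg, sub, NULL,
                    readout_params(a, matrix(1, 1, 1), q = 0))
  og <- find_optimal_gabor(model, grids)
  expect_equal(og$params[[1]]$ori, pi / 4)
  expect_equal(og$params[[1]]$freq, 2.5)
  expect_equal(og$params[[1]]$center, c(20, 20))
  # maximal contrast wins for a rectified-linear unit
  expect_equal(og$params[[1]]$amplitude, 2.52)
})

test_that("cross-orientation inhibition distinguishes DN from subunit cores", {
  m_dn <- energy_model("dn")
  m_su <- energy_model("subunit")
  grids <- tiny_grids()
  og <- find_optimal_gabor(m_dn, grids)
  og_su <- find_optimal_gabor(m_su, grids)
  contrasts <- coi_contrasts()[c(1, 4, 7, 10)]
  for (i in 1:2) {
    ci <- coi_index(m_dn, i, og$params[[i]], contrasts, n_phases = 4)
    cs <- coi_index(m_su, i, og_su$params[[i]], contrasts, n_phases = 4)
    expect_true(ci$inhibited)
    expect_gt(ci$max_coi, 0.10)
    expect_lt(cs$max_coi, 0.02)
    # zero mask contrast defines the reference: first row is exactly zero
    expect_equal(unname(ci$coi[1, -1]), rep(0, 3))
  }
})

test_that("COI matches direct evaluation of the normalization equation", {
  # uniform drive lets the prediction be written in closed form
  m <- energy_model("dn")
  og <- find_optimal_gabor(m, tiny_grids())
  contrasts <- c(0, 1.26, 2.52)
  ci <- coi_index(m, 1, og$params[[1]], contrasts, n_phases = 4)
  # oracle: phase-averaged predictions computed directly from rendered
  # plaids through the model equation (independent composition of stages)
  phases <- 2 * pi * (0:3) / 4
  direct <- matrix(0, 3, 3)
  for (ii in 1:3) for (jj in 1:3) {
    resp <- 0
    for (ph in phases) {
      stim <- render_plaid(og$params[[1]], contrasts[jj], contrasts[ii], ph)
      y <- subunit_forward(array(stim, c(40, 40, 1)), m$core$subunit)
      z <- dn_forward(y, m$core$dn, pool = 5)
      g <- readout_forward(z, m$readout)
      resp <- resp + output_nonlinearity(g, m$readout)[1, 1] / 4
    }
    direct[ii, jj] <- resp
  }
  coi_direct <- 1 - sweep(direct, 2, direct[1, ], "/")
  expect_equal(unname(ci$coi[, -1]), coi_direct[, -1], tolerance = 1e-8)
})

test_that("COI is invariant to scaling all predictions", {
  m <- energy_model("dn")
  og <- find_optimal_gabor(m, tiny_grids())
  ci1 <- coi_index(m, 1, og$params[[1]], c(0, 1.26), n_phases = 2)
  # a constant shift of alpha multiplies every prediction by exp(shift)
  m2 <- m; m2$readout$alpha <- m$readout$alpha + log(4)
  ci2 <- coi_index(m2, 1, og$params[[1]], c(0, 1.26), n_phases = 2)
  expect_equal(ci1$coi[2, 2], ci2$coi[2, 2], tolerance = 1e-10)
})

test_that("suppression index summarizes size-tuning curves", {
  # monotone non-decreasing curve: no suppression
  curve <- data.frame(diameter = 1:10, response = cumsum(runif(10)))
  expect_equal(suppression_index(curve), 0)
  # peak 1.0 dropping to 0.5 at full field
  curve2 <- data.frame(diameter = 1:5, response = c(0.2, 1, 0.8, 0.6, 0.5))
  expect_equal(suppression_index(curve2), 0.5)
  # silent unit: undefined
  curve3 <- data.frame(diameter = 1:3, response = c(0, 0, 0))
  expect_true(is.na(suppression_index(curve3)))
  # invariant to positive scaling of the curve
  expect_equal(suppression_index(transform(curve2, response = response * 7)),
               0.5)
})

test_that("size tuning of a center-normalization model saturates to a flat asymptote", {
  m <- energy_model("dn", p_strength = 0.6)
  og <- find_optimal_gabor(m, tiny_grids())
  st <- size_tuning(m, 1, og$params[[1]])
  # beyond the pool's input coverage the response must not change:
  # denominators pool at most 17 px around the readout RF
  tailr <- st$response[st$diameter > 60]
  expect_lt(max(tailr) - min(tailr), 1e-8 * max(1, max(tailr)))
})
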