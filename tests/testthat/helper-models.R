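# Small builders shared across tests.

# Random feature maps [S, S, N, C], non-negative.
rand_maps <- function(S = 12, N = 2, C = 8, max = 2, seed = 1) {
  set.seed(seed)
  array(runif(S * S * N * C, 0, max), c(S, S, N, C))
}

# Random valid DN parameters.
rand_dn_params <- function(C = 8, seed = 1, pmax = 0.3) {
  set.seed(seed)
  dn_params(runif(C, 0.5, 2.5), runif(C, 0.3, 1.5),
            matrix(runif(C * C, 0, pmax), C, C))
}

# A small fully random model for gradient and round-trip tests.
rand_model <- function(variant = "dn", C = 3, k = 5, side = 12, I = 2,
                       use_bn = FALSE, norm_kernel = 1L, dilation = 2L,
                       seed = 7) {
  set.seed(seed)
  cfg <- core_config(channels = C, kernel = k, pool = 3,
                     variant = variant, norm_kernel = norm_kernel,
                     dilation = dilation, image_side = side)
  model <- init_model(cfg, n_neurons = I, use_bn = use_bn)
  model$core$subunit$w <- array(rnorm(k * k * C, sd = 0.3), c(k, k, C))
  model$core$subunit$o <- rnorm(C, 0.2, 0.1)
  if (use_bn)
    model$core$subunit$bn <- list(mean = rnorm(C, 0, 0.1),
                                  var = runif(C, 0.5, 1.5),
                                  initialized = TRUE)
  if (!is.null(model$core$dn)) {
    model$core$dn$n <- runif(C, 0.8, 1.8)
    model$core$dn$sigma <- runif(C, 0.5, 1.2)
    if (variant == "dn_extended") {
      kk <- norm_kernel
      model$core$dn$cpool <- array(runif(kk * kk * C * 2, 0, 0.3),
                                   c(kk, kk, C, 2))
      model$core$dn$dfeat <- array(runif(C * C * 2, 0, 0.3), c(C, C, 2))
    } else {
      model$core$dn$p <- matrix(runif(C * C, 0, 0.4), C, C)
      if (variant == "dn_nonspecific")
        model$core$dn <- make_nonspecific(model$core$dn)
    }
  }
  sd_ <- dim(model$readout$a)
  model$readout$a <- array(runif(prod(sd_), 0, 0.3), sd_)
  model$readout$b <- matrix(runif(C * I, 0, 0.5), C, I)
  model$readout$q <- rnorm(I, 0.2, 0.1)
  model$readout$alpha <- matrix(rnorm(51 * I, 0, 0.1), 51, I)
  model
}

# Hand-built energy model: quadrature Gabor pairs at 0 and 90 degrees with
# uniform strong cross-channel normalization; unit 1 reads the 0-degree
# pair, unit 2 the 90-degree pair, both at the central location.
energy_model <- function(variant = "dn", p_strength = 0.6) {
  k <- 13; C <- 4
  oris <- c(0, 0, pi / 2, pi / 2); phases <- c(0, pi / 2, 0, pi / 2)
  w <- array(0, c(k, k, C))
  for (c in 1:C) {
    f <- render_gabor(gabor_params(center = c(7, 7), size = 10, freq = 2.5,
                                   phase = phases[c], ori = oris[c]), k)
    w[, , c] <- f / sqrt(sum(f^2))
  }
  sub <- subunit_params(w, o = numeric(C), bn = NULL)
  dn <- if (variant == "dn")
    dn_params(rep(2, C), rep(0.3, C), matrix(p_strength, C, C))
  cfg <- core_config(channels = C, kernel = k, pool = 5, variant = variant)
  a <- array(0, c(28, 28, 2)); a[14, 14, 1] <- 1; a[14, 14, 2] <- 1
  b <- matrix(0, C, 2); b[1:2, 1] <- 2; b[3:4, 2] <- 2
  dn_model(cfg, sub, dn, readout_params(a, b, q = c(0.5, 0.5)))
}

# Tiny Gabor search grids centered on the energy model's preferences.
tiny_grids <- function() {
  list(centers = as.matrix(expand.grid(row = c(14, 20, 26),
                                       col = c(14, 20, 26))),
       orientations = pi * (0:3) / 4,
       phases = 2 * pi * (0:1) / 2,
       sizes = c(10, 15),
       freqs = c(2, 2.5),
       amplitudes = c(1.26, 2.52))
}

# Brute-force center-DN oracle (triple loop over pixels/channels).
dn_oracle <- function(y, n, sigma, p, pool) {
  d <- dim(y)
  half <- (pool - 1) / 2
  z <- array(0, d)
  for (b in seq_len(d[3])) for (l in seq_len(d[4])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      den <- sigma[l]^n[l]
      for (k in seq_len(d[4])) {
        ri <- max(1, i - half):min(d[1], i + half)
        ci <- max(1, j - half):min(d[2], j + half)
        den <- den + p[k, l] * sum(y[ri, ci, b, k]^n[k]) / pool^2
      }
      z[i, j, b, l] <- y[i, j, b, l]^n[l] / den
    }
  }
  z
}
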