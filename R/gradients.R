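# Hand-derived gradients of the total training loss.
#
# The whole chain -- subunit convolution, bias-only batch normalization,
# rectification, divisive normalization (center or spatially extended),
# factorized readout, tent-modulated ELU* output nonlinearity, Poisson loss
# plus the three regularizers -- is differentiated analytically here. The
# test suite checks every parameter group against central finite differences.
#
# Numerical guards: the forward pass uses exact powers y^n (y >= 0); the
# gradient terms use log(y + 1e-6) and pmax(y, 1e-6)^(n-1) so derivatives
# stay finite at y = 0.

POW_EPS <- 1e-6

# Derivative of the tent basis wrt x: +-1/dx on the rising/falling flank.
tent_basis_grad <- function(x, grid) {
  up <- outer(x, grid$points, function(xx, xj) xx - (xj - grid$dx))
  dn <- outer(x, grid$points, function(xx, xj) (xj + grid$dx) - xx)
  g <- matrix(0, length(x), grid$n)
  rising <- up > 0 & up < dn
  falling <- dn > 0 & dn <= up
  g[rising] <- 1 / grid$dx
  g[falling] <- -1 / grid$dx
  g
}

# Loss and gradients on one batch. `driving` short-circuits the subunit
# stage with precomputed rectified maps (used when filters are frozen);
# `freeze` names parameter groups whose gradients are skipped:
# "filters" (w, o, bn), "dn" (n, sigma, p / cpool, dfeat), "readout"
# (a, b, q), "outputnl" (alpha).
loss_and_grads <- function(model, stimuli, r, cfg = loss_config(),
                           mode = "train", freeze = character(),
                           driving = NULL, driving_log = NULL) {
  cfgc <- model$config
  variant <- cfgc$variant
  grads <- list()
  bn_state <- NULL

  ## ---- forward: subunit stage ----
  if (is.null(driving)) {
    if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
    k <- cfgc$kernel
    patches <- if ("filters" %in% freeze) NULL else im2col(stimuli, k)
    d_img <- dim(stimuli)
    oh <- d_img[1] - k + 1L; ow <- d_img[2] - k + 1L; N <- d_img[3]
    C <- cfgc$channels
    wmat <- matrix(model$core$subunit$w, k * k, C)
    cmat <- if (is.null(patches)) fm_mat(conv_valid(stimuli, model$core$subunit$w))
            else patches %*% wmat
    bn <- model$core$subunit$bn
    if (!is.null(bn)) {
      if (mode == "train") {
        mu <- colMeans(cmat)
        v <- colMeans(cmat^2) - mu^2
        if (!bn$initialized) {
          bn$mean <- mu; bn$var <- v; bn$initialized <- TRUE
        } else {
          bn$mean <- 0.9 * bn$mean + 0.1 * mu
          bn$var <- 0.9 * bn$var + 0.1 * v
        }
        bn_state <- bn
      } else {
        mu <- bn$mean; v <- bn$var
      }
      s_bn <- sqrt(v + 1e-4)
      xhat <- sweep(sweep(cmat, 2, mu, "-"), 2, s_bn, "/")
    } else {
      xhat <- cmat
    }
    umat <- sweep(xhat, 2, model$core$subunit$o, "+")
    ymat <- pmax(umat, 0)
    y <- fm_arr(ymat, c(oh, ow, N, C))
  } else {
    y <- driving
    d_y <- dim(y)
    oh <- d_y[1]; ow <- d_y[2]; N <- d_y[3]; C <- d_y[4]
    ymat <- fm_mat(y)
  }

  ## ---- forward: normalization stage ----
  dnp <- model$core$dn
  logy <- NULL
  chan_pow <- function() {
    # y^n, reusing precomputed log(y + eps) when the driving maps are fixed
    if (!is.null(driving_log)) {
      logy <<- fm_mat(driving_log)
      exp(logy * rep(dnp$n, each = nrow(logy)))
    } else {
      pow_channels(y, dnp$n)
    }
  }
  if (variant == "subunit") {
    z <- y
    zmat <- fm_mat(z)
  } else if (variant %in% c("dn", "dn_nonspecific")) {
    tpow <- chan_pow()
    dim(tpow) <- dim(y)
    tmat <- fm_mat(tpow)
    pooled <- avg_pool_same(tpow, cfgc$pool)
    A <- fm_mat(pooled)
    den <- sweep(A %*% dnp$p, 2, dnp$sigma^dnp$n, "+")
    zmat <- tmat / den
    z <- fm_arr(zmat, dim(y))
  } else { # dn_extended
    kk <- dnp$kernel_size; dil <- dnp$dilation
    margin <- as.integer(dil * (kk - 1L) / 2L)
    os1 <- oh - 2L * margin; os2 <- ow - 2L * margin
    tpow <- chan_pow()
    dim(tpow) <- dim(y)
    pooled <- avg_pool_same(tpow, cfgc$pool)
    A <- fm_mat(pooled)
    emaps <- vector("list", 2)
    s <- array(0, c(os1, os2, N, C))
    for (m in 1:2) {
      emaps[[m]] <- fm_arr(A %*% dnp$dfeat[, , m], dim(y))
      for (u in seq_len(kk)) for (v in seq_len(kk)) {
        ri <- (1L + dil * (u - 1L)):(os1 + dil * (u - 1L))
        ci <- (1L + dil * (v - 1L)):(os2 + dil * (v - 1L))
        sl <- fm_mat(emaps[[m]][ri, ci, , , drop = FALSE])
        s <- s + fm_arr(sl * rep(dnp$cpool[u, v, , m], each = nrow(sl)),
                        dim(s))
      }
    }
    num <- crop_sym(tpow, margin)
    den <- sweep(fm_mat(s), 2, dnp$sigma^dnp$n, "+")
    zmat <- fm_mat(num) / den
    z <- fm_arr(zmat, dim(num))
  }
  dz_dims <- dim(z)
  zh <- dz_dims[1]; zw <- dz_dims[2]

  ## ---- forward: readout + output nonlinearity ----
  ro <- model$readout
  npix <- zh * zw
  I <- dim(ro$a)[3]
  amat <- matrix(ro$a, npix, I)
  Zv <- matrix(zmat, npix, N * C)  # [pix, (N, C)] view
  U <- crossprod(amat, Zv)         # [I, (N, C)]
  g <- matrix(0, N, I)
  for (i in seq_len(I))
    g[, i] <- matrix(U[i, ], N, C) %*% ro$b[, i]
  g <- sweep(g, 2, ro$q, "+")
  grid <- ro$grid
  lo <- grid$points[1]; hi <- grid$points[grid$n]
  gc <- pmin(pmax(g, lo), hi)
  E <- elu_star(g)
  Ep <- elu_star_grad(g)
  hmat <- matrix(0, N, I)
  hpmat <- matrix(0, N, I)
  tb_list <- vector("list", I)
  for (i in seq_len(I)) {
    tb_list[[i]] <- tent_basis(gc[, i], grid)
    ea <- exp(ro$alpha[, i])
    hmat[, i] <- tb_list[[i]] %*% ea
    hpmat[, i] <- (tent_basis_grad(gc[, i], grid) %*% ea) *
      (g[, i] > lo & g[, i] < hi)
  }
  rhat <- hmat * E

  ## ---- loss ----
  lp <- as.numeric(poisson_loss(rhat, r))
  lsm <- smoothness_penalty(model$core$subunit$w)
  lsp <- sparsity_penalty(ro$a, ro$b)
  lout <- output_nl_penalty(ro$alpha)
  loss <- lp + cfg$lambda_smooth * lsm + cfg$lambda_sparse * lsp +
    cfg$lambda_out * lout

  ## ---- backward: Poisson + output nonlinearity ----
  dR <- 1 - r / pmax(rhat, 1e-8)
  dG <- dR * (hpmat * E + hmat * Ep)
  if (!("outputnl" %in% freeze)) {
    dalpha <- matrix(0, grid$n, I)
    for (i in seq_len(I)) {
      dalpha[, i] <- crossprod(tb_list[[i]], dR[, i] * E[, i]) *
        exp(ro$alpha[, i])
    }
    grads$alpha <- dalpha + cfg$lambda_out * output_nl_penalty_grad(ro$alpha)
  }

  ## ---- backward: readout ----
  # dz[pix, (n, c)] = sum_i a[pix, i] * b[c, i] * dG[n, i]
  V <- matrix(0, I, N * C)
  for (i in seq_len(I)) V[i, ] <- as.vector(outer(dG[, i], ro$b[, i]))
  if (!("readout" %in% freeze)) {
    sa <- colSums(abs(amat)); sb <- colSums(abs(ro$b))
    da <- Zv %*% t(V) + matrix(sb * cfg$lambda_sparse, npix, I, byrow = TRUE)
    db <- matrix(0, C, I)
    for (i in seq_len(I))
      db[, i] <- crossprod(matrix(U[i, ], N, C), dG[, i]) +
        cfg$lambda_sparse * sa[i]
    grads$a <- array(da, dim(ro$a))
    grads$b <- db
    grads$q <- colSums(dG)
  }
  dzmat <- amat %*% V              # [pix, (N, C)] view
  dim(dzmat) <- c(npix * N, C)

  ## ---- backward: normalization stage ----
  need_dn <- !("dn" %in% freeze) && variant != "subunit"
  need_y <- is.null(driving) && !("filters" %in% freeze)
  dy_mat <- NULL
  if (variant == "subunit") {
    dy_mat <- dzmat
  } else if (variant %in% c("dn", "dn_nonspecific")) {
    dnum <- dzmat / den
    dden <- -dzmat * zmat / den
    if (need_dn) {
      grads$sigma <- colSums(dden) * dnp$n * dnp$sigma^(dnp$n - 1)
      dn_sigma_term <- colSums(dden) *
        ifelse(dnp$sigma > 0, dnp$sigma^dnp$n * log(pmax(dnp$sigma, POW_EPS)), 0)
      dp <- crossprod(A, dden)
      if (isTRUE(dnp$nonspecific)) dp <- project_nonspecific(dp)
      grads$p <- dp
    }
    if (need_dn || need_y) {
      dA <- dden %*% t(dnp$p)
      dt <- dnum + fm_mat(avg_pool_same(fm_arr(dA, dim(y)), cfgc$pool))
      if (is.null(logy)) logy <- log(ymat + POW_EPS)
      if (need_dn) grads$n <- colSums(dt * tmat * logy) + dn_sigma_term
      if (need_y)
        dy_mat <- dt * sweep_pow(pmax(ymat, POW_EPS), dnp$n - 1) *
          rep(dnp$n, each = nrow(dt))
    }
  } else { # dn_extended
    dnum <- dzmat / den
    ds <- fm_arr(-dzmat * zmat / den, dim(z))
    if (need_dn) {
      dssum <- colSums(fm_mat(ds))
      grads$sigma <- dssum * dnp$n * dnp$sigma^(dnp$n - 1)
      dn_sigma_term <- dssum *
        ifelse(dnp$sigma > 0, dnp$sigma^dnp$n * log(pmax(dnp$sigma, POW_EPS)), 0)
      grads$cpool <- array(0, dim(dnp$cpool))
      grads$dfeat <- array(0, dim(dnp$dfeat))
    }
    dA <- matrix(0, nrow(A), C)
    dsm <- fm_mat(ds)
    for (m in 1:2) {
      de <- array(0, dim(y))
      em <- emaps[[m]]
      for (u in seq_len(kk)) for (v in seq_len(kk)) {
        ri <- (1L + dil * (u - 1L)):(os1 + dil * (u - 1L))
        ci <- (1L + dil * (v - 1L)):(os2 + dil * (v - 1L))
        if (need_dn) {
          esl <- fm_mat(em[ri, ci, , , drop = FALSE])
          grads$cpool[u, v, , m] <- colSums(esl * dsm)
        }
        de[ri, ci, , ] <- de[ri, ci, , , drop = FALSE] +
          fm_arr(dsm * rep(dnp$cpool[u, v, , m], each = nrow(dsm)),
                 c(os1, os2, N, C))
      }
      dem <- fm_mat(de)
      if (need_dn) grads$dfeat[, , m] <- crossprod(A, dem)
      dA <- dA + dem %*% t(dnp$dfeat[, , m])
    }
    if (need_dn || need_y) {
      dt <- fm_mat(uncrop_sym(fm_arr(dnum, dim(z)), margin, dim(y))) +
        fm_mat(avg_pool_same(fm_arr(dA, dim(y)), cfgc$pool))
      if (is.null(logy)) logy <- log(ymat + POW_EPS)
      tmat_full <- fm_mat(tpow)
      if (need_dn) grads$n <- colSums(dt * tmat_full * logy) + dn_sigma_term
      if (need_y)
        dy_mat <- dt * sweep_pow(pmax(ymat, POW_EPS), dnp$n - 1) *
          rep(dnp$n, each = nrow(dt))
    }
  }

  ## ---- backward: subunit stage ----
  if (need_y && !is.null(dy_mat)) {
    du <- dy_mat * (umat > 0)
    grads$o <- colSums(du)
    if (!is.null(model$core$subunit$bn)) {
      dxhat <- du
      if (mode == "train") {
        # batch statistics depend on c: full batch-norm backward
        mean_dx <- colMeans(dxhat)
        mean_dx_x <- colMeans(dxhat * xhat)
        dc <- sweep(sweep(dxhat, 2, mean_dx, "-") -
                      sweep(xhat, 2, mean_dx_x, "*"),
                    2, s_bn, "/")
      } else {
        dc <- sweep(dxhat, 2, s_bn, "/")
      }
    } else {
      dc <- du
    }
    dwmat <- crossprod(patches, dc)
    dw <- array(dwmat, dim(model$core$subunit$w))
    grads$w <- dw + cfg$lambda_smooth * smoothness_penalty_grad(model$core$subunit$w)
  }

  list(loss = loss,
       parts = c(poisson = lp, smooth = lsm, sparse = lsp, out = lout),
       grads = grads, bn_state = bn_state, rhat = rhat)
}

# Gradient of the Laplace smoothness penalty wrt the filters.
smoothness_penalty_grad <- function(w) {
  L <- laplace_kernel()
  Lr <- L[3:1, 3:1]
  out <- conv_valid(w, array(Lr, c(3, 3, 1)))  # [k-2, k-2, C, 1]
  d <- dim(w)
  g <- array(0, d)
  for (dj in 1:3) for (di in 1:3) {
    g[di:(di + d[1] - 3L), dj:(dj + d[2] - 3L), ] <-
      g[di:(di + d[1] - 3L), dj:(dj + d[2] - 3L), , drop = FALSE] +
      2 * out[, , , 1] * Lr[di, dj]
  }
  g
}
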