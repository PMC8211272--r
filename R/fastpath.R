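# Compiled fast path for frozen-filter training of the center DN model.
# Produces the same loss and gradients as loss_and_grads() (the reference
# implementation); equality is asserted in the test suite.
#
# Precomputed driving maps are carried in matrix form ("drv" container:
# y and logy as [npix * n_images, channels] matrices plus the map geometry)
# so that per-batch extraction is a blockwise memcpy instead of a strided
# 4-d array subset.

fast_step_applicable <- function(model, freeze) {
  model$config$variant %in% c("dn", "dn_nonspecific") &&
    "filters" %in% freeze &&
    is.null(model$core$subunit$bn)
}

# Build the matrix-form container from images.
driving_container <- function(model, images, with_log = TRUE) {
  arr <- compute_driving(model, images)
  d <- dim(arr)
  drv <- list(oh = d[1], ow = d[2], n_images = d[3], C = d[4],
              npix = d[1] * d[2])
  dim(arr) <- c(drv$npix * d[3], d[4])
  drv$y <- arr
  if (with_log) drv$logy <- log(arr + POW_EPS)
  drv
}

# Driving maps of a set of images as an [oh, ow, n, C] array.
driving_slice <- function(drv, idx) {
  y <- .gather_images(drv$y, idx, drv$npix)
  dim(y) <- c(drv$oh, drv$ow, length(idx), drv$C)
  y
}

fast_loss_and_grads <- function(model, r, cfg, drv, idx,
                                freeze = character()) {
  ro <- model$readout
  dnp <- model$core$dn
  grid <- ro$grid
  res <- .dn_step_frozen_blocked(
    drv$y, drv$logy, idx, drv$oh, drv$ow, model$config$pool,
    dnp$n, dnp$sigma, dnp$p,
    matrix(ro$a, drv$npix, dim(ro$a)[3]), ro$b, ro$q, ro$alpha, r,
    grid$points[1], grid$points[grid$n], grid$dx,
    cfg$lambda_sparse, cfg$lambda_out,
    isTRUE(dnp$nonspecific))
  grads <- res$grads
  dim(grads$a) <- dim(ro$a)
  grads$q <- as.numeric(grads$q)
  grads$n <- as.numeric(grads$n)
  grads$sigma <- as.numeric(grads$sigma)
  for (grp in freeze) {
    drop <- switch(grp, dn = c("n", "sigma", "p"), readout = c("a", "b", "q"),
                   outputnl = "alpha", NULL)
    grads[drop] <- NULL
  }
  list(loss = res$loss, parts = c(poisson = res$poisson), grads = grads,
       bn_state = NULL)
}
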