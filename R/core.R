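#' Core architecture configuration
#'
#' The shared ("core") part of every model variant is a bank of `channels`
#' convolutional subunit filters of size `kernel` x `kernel` px applied to the
#' `image_side` x `image_side` px stimulus without padding, bias-only batch
#' normalization, and a rectifying nonlinearity. The `variant` selects what
#' happens next:
#' \describe{
#'   \item{`"subunit"`}{identity — the rectified feature maps are the output.}
#'   \item{`"dn"`}{divisive normalization with a learned, feature-specific
#'     normalization pool (weights `p[k, l]`).}
#'   \item{`"dn_nonspecific"`}{as `"dn"` but each target channel receives the
#'     same weight from every source channel.}
#'   \item{`"dn_extended"`}{normalization pooled over space by a dilated
#'     `norm_kernel` x `norm_kernel` convolution with two factorized pool
#'     components per channel.}
#' }
#'
#' @param channels number of subunit channels (full-scale default 32).
#' @param kernel subunit filter side, px (odd).
#' @param pool denominator average-pooling window, px.
#' @param variant model variant, see Details.
#' @param norm_kernel spatial size of the extended normalization kernel
#'   (odd, one of 1/3/5/7 at full scale).
#' @param dilation dilation of the extended normalization convolution.
#' @param image_side model input side, px.
#' @return list of class `dnv1_core_config`.
#' @export
core_config <- function(channels = 32L, kernel = 13L, pool = 5L,
                        variant = c("dn", "subunit", "dn_nonspecific",
                                    "dn_extended"),
                        norm_kernel = 1L, dilation = 5L, image_side = 40L) {
  variant <- match.arg(variant)
  stopifnot(channels >= 1, kernel %% 2 == 1, pool >= 1,
            norm_kernel %% 2 == 1, dilation >= 1, image_side > kernel)
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = as.integer(pool), variant = variant,
                 norm_kernel = as.integer(norm_kernel),
                 dilation = as.integer(dilation),
                 image_side = as.integer(image_side)),
            class = "dnv1_core_config")
}

#' Subunit stage parameters
#'
#' Filters `w` and biases `o` of the rectified convolutional filter bank,
#' plus the running statistics of the bias-only batch normalization (BN
#' without a learned scale: responses are standardized to zero mean / unit
#' variance, then the bias is added). With `bn = NULL` the standardization is
#' the identity and the stage is plain `relu(w * x + o)` — the form used for
#' synthetic ground-truth models.
#'
#' @param w filter array `[kernel, kernel, channels]`.
#' @param o per-channel bias.
#' @param bn `NULL`, or a list with `mean`, `var` (running statistics) —
#'   use `bn_state()` to create an uninitialized state.
#' @return list of class `dnv1_subunit_params`.
#' @export
subunit_params <- function(w, o, bn = NULL) {
  stopifnot(length(dim(w)) == 3, dim(w)[1] == dim(w)[2],
            dim(w)[1] %% 2 == 1, length(o) == dim(w)[3])
  if (!is.null(bn)) {
    stopifnot(is.list(bn))
    if (bn$initialized) stopifnot(all(bn$var > 0))
  }
  structure(list(w = w, o = as.numeric(o), bn = bn),
            class = "dnv1_subunit_params")
}

#' @rdname subunit_params
#' @param channels number of channels for a fresh (uninitialized) state.
#' @export
bn_state <- function(channels) {
  list(mean = numeric(channels), var = rep(1, channels), initialized = FALSE)
}

#' Divisive normalization parameters
#'
#' Each channel's rectified drive `y_l` is raised to the learned exponent
#' `n[l]` and divided by `sigma[l]^n[l]` plus the weighted sum over channels
#' of the spatially average-pooled exponentiated drives, with non-negative
#' normalization weights `p[k, l]` (source channel k, target channel l).
#'
#' @param n per-channel exponents (>= 0).
#' @param sigma per-channel semi-saturation constants (>= 0).
#' @param p normalization weight matrix `[channels, channels]`, `p[k, l]` the
#'   weight of source `k` in target `l`'s pool; all entries >= 0.
#' @param nonspecific logical; if `TRUE` the weights are constrained to be
#'   identical across sources for each target (enforced here by column
#'   averaging and re-projected after every optimizer step during training).
#' @return list of class `dnv1_dn_params`.
#' @export
dn_params <- function(n, sigma, p, nonspecific = FALSE) {
  p <- as.matrix(p)
  stopifnot(length(n) == length(sigma), nrow(p) == ncol(p),
            nrow(p) == length(n), all(n >= 0), all(sigma >= 0), all(p >= 0),
            all(is.finite(n)), all(is.finite(sigma)), all(is.finite(p)))
  if (nonspecific) p <- project_nonspecific(p)
  structure(list(n = as.numeric(n), sigma = as.numeric(sigma), p = p,
                 nonspecific = isTRUE(nonspecific)),
            class = "dnv1_dn_params")
}

# Constrain each target channel's incoming weights to a single value.
project_nonspecific <- function(p) {
  matrix(rep(colMeans(p), each = nrow(p)), nrow(p), ncol(p))
}

#' Spatially extended divisive normalization parameters
#'
#' The scalar weights `p[k, l]` are replaced by a dilated spatial convolution
#' with kernels `p[k, l, u, v] = sum_m cpool[u, v, l, m] * dfeat[k, l, m]`,
#' factorized into two non-negative normalization pool components per target
#' channel (spatial profiles `cpool`, feature weightings `dfeat`).
#'
#' @param n,sigma as in [dn_params()].
#' @param cpool array `[norm_kernel, norm_kernel, channels, 2]` >= 0.
#' @param dfeat array `[channels, channels, 2]` (source, target, component)
#'   >= 0.
#' @param dilation dilation factor of the normalization convolution.
#' @return list of class `dnv1_ext_dn_params`.
#' @export
ext_dn_params <- function(n, sigma, cpool, dfeat, dilation = 5L) {
  stopifnot(length(dim(cpool)) == 4, dim(cpool)[1] == dim(cpool)[2],
            dim(cpool)[1] %% 2 == 1, dim(cpool)[4] == 2,
            length(dim(dfeat)) == 3, dim(dfeat)[3] == 2,
            dim(cpool)[3] == length(n), dim(dfeat)[1] == length(n),
            dim(dfeat)[2] == length(n),
            all(n >= 0), all(sigma >= 0), all(cpool >= 0), all(dfeat >= 0))
  structure(list(n = as.numeric(n), sigma = as.numeric(sigma), cpool = cpool,
                 dfeat = dfeat, kernel_size = dim(cpool)[1],
                 dilation = as.integer(dilation)),
            class = "dnv1_ext_dn_params")
}

# Collapse the factorized extended weights to scalar p for norm_kernel = 1.
ext_collapse_p <- function(params) {
  stopifnot(params$kernel_size == 1L)
  params$dfeat[, , 1] * rep(params$cpool[1, 1, , 1], each = dim(params$dfeat)[1]) +
    params$dfeat[, , 2] * rep(params$cpool[1, 1, , 2], each = dim(params$dfeat)[1])
}

#' Subunit stage forward pass
#'
#' Valid convolution of the stimuli with the filter bank, bias-only batch
#' normalization (batch statistics in `"train"` mode, running statistics in
#' `"eval"` mode), bias, and rectification. A 40 px input with 13 px kernels
#' yields 28 x 28 px feature maps.
#'
#' @param stimuli array `[H, W, N]` of normalized images.
#' @param params a [subunit_params()].
#' @param mode `"eval"` (running statistics) or `"train"` (batch statistics;
#'   the returned maps carry an updated `bn_state` attribute).
#' @return array `[oh, ow, N, channels]` of non-negative driving maps.
#' @export
subunit_forward <- function(stimuli, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!all(is.finite(stimuli))) stop("non-finite stimulus values")
  if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
  conv <- conv_valid(stimuli, params$w)
  d <- dim(conv)
  cm <- fm_mat(conv)
  bn <- params$bn
  if (!is.null(bn)) {
    if (mode == "train") {
      mu <- colMeans(cm)
      v <- colMeans(cm^2) - mu^2
      if (!bn$initialized) {
        bn$mean <- mu; bn$var <- v; bn$initialized <- TRUE
      } else {
        bn$mean <- 0.9 * bn$mean + 0.1 * mu
        bn$var <- 0.9 * bn$var + 0.1 * v
      }
    } else {
      if (!isTRUE(bn$initialized))
        stop("eval mode requires initialized batch-norm running statistics")
      mu <- bn$mean; v <- bn$var
    }
    cm <- sweep(cm, 2, mu, "-")
    cm <- sweep(cm, 2, sqrt(v + 1e-4), "/")
  }
  cm <- sweep(cm, 2, params$o, "+")
  y <- fm_arr(pmax(cm, 0), d)
  if (!is.null(bn)) attr(y, "bn_state") <- bn
  y
}

#' Divisive normalization forward pass
#'
#' Applies `z_l = y_l^n_l / (sigma_l^n_l + sum_k p[k, l] <y_k^n_k>)`
#' elementwise, where `<.>` is stride-1 `pool` x `pool` spatial average
#' pooling (zero-padded "same" output: interior pixels match the exact pool
#' average, border pixels are under-pooled). Exponentiation precedes pooling.
#'
#' @param driving non-negative array `[oh, ow, N, channels]` from
#'   [subunit_forward()].
#' @param params a [dn_params()].
#' @param pool pooling window, px.
#' @return normalized maps, same shape as `driving`.
#' @export
dn_forward <- function(driving, params, pool = 5L) {
  d <- dim(driving)
  C <- d[4]
  stopifnot(length(params$n) == C, min(driving) >= 0)
  tpow <- pow_channels(driving, params$n)
  pooled <- avg_pool_same(tpow, pool)
  den <- fm_mat(pooled) %*% params$p
  den <- sweep(den, 2, params$sigma^params$n, "+")
  if (any(den <= 0))
    stop("invalid parameters: zero denominator (sigma = 0 with empty pool)")
  fm_arr(fm_mat(tpow) / den, d)
}

#' Spatially extended divisive normalization forward pass
#'
#' The pooled exponentiated drives are convolved (valid, dilation
#' `params$dilation`) with the factorized normalization kernels to produce
#' suppression maps `s_l`; the exponentiated numerator is symmetrically
#' cropped to the same spatial size before the elementwise division. With a
#' 1 x 1 normalization kernel this reduces exactly to [dn_forward()] with
#' `p[k, l] = sum_m cpool[1, 1, l, m] * dfeat[k, l, m]`.
#'
#' @param driving non-negative array `[oh, ow, N, channels]`.
#' @param params an [ext_dn_params()].
#' @param pool pooling window, px.
#' @return normalized maps `[os, os, N, channels]` with
#'   `os = oh - dilation * (norm_kernel - 1)`.
#' @export
extended_dn_forward <- function(driving, params, pool = 5L) {
  d <- dim(driving)
  C <- d[4]
  kk <- params$kernel_size
  dil <- params$dilation
  margin <- dil * (kk - 1L) / 2L
  if (margin != floor(margin)) stop("crop residual is not symmetric")
  margin <- as.integer(margin)
  os1 <- d[1] - 2L * margin; os2 <- d[2] - 2L * margin
  if (os1 < 1 || os2 < 1) stop("driving maps too small for dilated kernel")
  tpow <- pow_channels(driving, params$n)
  pooled <- avg_pool_same(tpow, pool)
  pm <- fm_mat(pooled)
  s <- array(0, c(os1, os2, d[3], C))
  for (m in 1:2) {
    e <- fm_arr(pm %*% params$dfeat[, , m], d)
    for (u in seq_len(kk)) {
      for (v in seq_len(kk)) {
        ri <- (1L + dil * (u - 1L)):(os1 + dil * (u - 1L))
        ci <- (1L + dil * (v - 1L)):(os2 + dil * (v - 1L))
        slice <- fm_mat(e[ri, ci, , , drop = FALSE])
        s <- s + fm_arr(slice * rep(params$cpool[u, v, , m],
                                    each = nrow(slice)),
                        dim(s))
      }
    }
  }
  num <- crop_sym(tpow, margin)
  den <- fm_mat(s)
  den <- sweep(den, 2, params$sigma^params$n, "+")
  if (any(den <= 0))
    stop("invalid parameters: zero denominator (sigma = 0 with empty pool)")
  fm_arr(fm_mat(num) / den, dim(num))
}

#' Constrain normalization weights to be nonspecific
#'
#' Returns parameters in which, for each target channel, the incoming
#' normalization weights are identical across source channels (their mean),
#' tagged so training re-projects the constraint after every step. A
#' nonspecific model with C channels has C free normalization weights instead
#' of C^2.
#'
#' @param params a [dn_params()].
#' @return a [dn_params()] with constant columns and `nonspecific = TRUE`.
#' @export
make_nonspecific <- function(params) {
  dn_params(params$n, params$sigma, project_nonspecific(params$p),
            nonspecific = TRUE)
}

#' Identity (subunit) variant
#'
#' The subunit baseline model replaces normalization by the identity: the
#' shared feature maps are the rectified drives themselves.
#'
#' @param driving array `[oh, ow, N, channels]`.
#' @return `driving`, unchanged.
#' @export
subunit_variant <- function(driving) driving

# Shared-core forward dispatch: stimuli -> normalized feature maps z.
core_forward <- function(model, stimuli, mode = "eval") {
  y <- subunit_forward(stimuli, model$core$subunit, mode = mode)
  bn <- attr(y, "bn_state")
  attr(y, "bn_state") <- NULL
  z <- switch(model$config$variant,
    subunit = subunit_variant(y),
    dn = ,
    dn_nonspecific = dn_forward(y, model$core$dn, pool = model$config$pool),
    dn_extended = extended_dn_forward(y, model$core$dn,
                                      pool = model$config$pool))
  if (!is.null(bn)) attr(z, "bn_state") <- bn
  z
}
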