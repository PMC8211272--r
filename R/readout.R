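#' Tent-function interpolation grid
#'
#' Uniform grid of interpolation points for the learnable output
#' nonlinearity: `x_j = -3, -2.82, ..., 6` with spacing 0.18 (51 points).
#'
#' @param from,to grid endpoints.
#' @param by spacing.
#' @return list of class `dnv1_tent_grid` with `points` and `dx`.
#' @export
tent_grid <- function(from = -3, to = 6, by = 0.18) {
  pts <- seq(from, to, by = by)
  structure(list(points = pts, dx = by, n = length(pts)),
            class = "dnv1_tent_grid")
}

#' Tent basis functions
#'
#' Piecewise-linear bumps `t_j(x) = min(max(0, (x - x_{j-1}) / dx),
#' max(0, (x_{j+1} - x) / dx))`: each peaks at 1 on its grid point, has
#' support width `2 dx`, and strictly inside the grid the basis is a
#' partition of unity.
#'
#' @param x numeric vector of evaluation points.
#' @param grid a [tent_grid()].
#' @return matrix `[length(x), grid$n]` of basis values in `[0, 1]`.
#' @export
tent_basis <- function(x, grid = tent_grid()) {
  up <- outer(x, grid$points, function(xx, xj) (xx - (xj - grid$dx)) / grid$dx)
  dn <- outer(x, grid$points, function(xx, xj) ((xj + grid$dx) - xx) / grid$dx)
  pmin(pmax(up, 0), pmax(dn, 0))
}

#' Shifted exponential linear unit
#'
#' `ELU*(g) = g` for `g >= 1`, `exp(g - 1)` otherwise. Continuous with
#' continuous first derivative at the branch point (both equal 1).
#'
#' @param g numeric.
#' @return elementwise ELU*.
#' @export
elu_star <- function(g) ifelse(g >= 1, g, exp(g - 1))

elu_star_grad <- function(g) ifelse(g >= 1, 1, exp(g - 1))

#' Factorized readout parameters
#'
#' Per-neuron non-negative spatial weights `a[u, v, i]`, non-negative feature
#' weights `b[l, i]`, bias `q[i]`, and output-nonlinearity coefficients
#' `alpha[j, i]` on a [tent_grid()]. The non-negativity ensures the readout
#' is monotone non-decreasing in every feature-map value, so suppressive
#' effects can only come from the core.
#'
#' @param a array `[oh, ow, neurons]` >= 0.
#' @param b matrix `[channels, neurons]` >= 0.
#' @param q numeric bias per neuron.
#' @param alpha matrix `[grid points, neurons]`; 0 initializes the output
#'   nonlinearity at the plain ELU*.
#' @param grid a [tent_grid()].
#' @return list of class `dnv1_readout_params`.
#' @export
readout_params <- function(a, b, q, alpha = NULL, grid = tent_grid()) {
  stopifnot(length(dim(a)) == 3, is.matrix(b),
            dim(a)[3] == ncol(b), length(q) == ncol(b))
  if (any(a < 0) || any(b < 0)) stop("readout weights must be non-negative")
  if (is.null(alpha)) alpha <- matrix(0, grid$n, ncol(b))
  stopifnot(nrow(alpha) == grid$n, ncol(alpha) == ncol(b),
            all(is.finite(alpha)))
  structure(list(a = a, b = b, q = as.numeric(q), alpha = alpha, grid = grid),
            class = "dnv1_readout_params")
}

#' Factorized linear readout
#'
#' `g_i = sum_{u,v,l} a[u, v, i] * b[l, i] * z[u, v, l] + q[i]` for each
#' image in the batch.
#'
#' @param z feature maps `[oh, ow, N, channels]`.
#' @param params a [readout_params()].
#' @return matrix `[N, neurons]` of pre-nonlinearity activations.
#' @export
readout_forward <- function(z, params) {
  d <- dim(z)
  stopifnot(dim(params$a)[1] == d[1], dim(params$a)[2] == d[2],
            nrow(params$b) == d[4])
  npix <- d[1] * d[2]
  N <- d[3]; C <- d[4]
  I <- dim(params$a)[3]
  amat <- matrix(params$a, npix, I)
  # factorized contraction: first over space, then over channels
  U <- crossprod(amat, matrix(z, npix, N * C))   # [I, (N, C)]
  dim(U) <- c(I, N, C)
  g <- matrix(0, N, I)
  for (i in seq_len(I)) g[, i] <- matrix(U[i, , ], N, C) %*% params$b[, i]
  sweep(g, 2, params$q, "+")
}

#' Learnable output nonlinearity
#'
#' `rhat_i = h_i(g) * ELU*(g)` with `h_i(g) = sum_j t_j(g) exp(alpha[j, i])`,
#' a positive piecewise-exponential modulation of the shifted ELU. `g` is
#' clamped to the tent grid's range before evaluating `h` so predictions
#' outside the grid follow the boundary value of `h` instead of collapsing
#' to zero.
#'
#' @param g activations `[N, neurons]` from [readout_forward()].
#' @param params a [readout_params()] (uses `alpha` and `grid`).
#' @return matrix `[N, neurons]` of non-negative predicted mean spike counts.
#' @export
output_nonlinearity <- function(g, params) {
  grid <- params$grid
  gc <- pmin(pmax(g, grid$points[1]), grid$points[grid$n])
  rhat <- g
  for (i in seq_len(ncol(g))) {
    tb <- tent_basis(gc[, i], grid)
    h <- tb %*% exp(params$alpha[, i])
    rhat[, i] <- h * elu_star(g[, i])
  }
  rhat
}

#' Full encoding model
#'
#' Bundles a [core_config()], the core parameters (subunit stage plus the
#' variant's normalization parameters) and a [readout_params()] into one
#' model object with a `predict` method.
#'
#' @param config a [core_config()].
#' @param subunit a [subunit_params()].
#' @param dn a [dn_params()] / [ext_dn_params()] or `NULL` for the subunit
#'   variant.
#' @param readout a [readout_params()].
#' @return list of class `dnv1_model`.
#' @export
dn_model <- function(config, subunit, dn = NULL, readout = NULL) {
  if (config$variant %in% c("dn", "dn_nonspecific") &&
      !inherits(dn, "dnv1_dn_params"))
    stop("variant '", config$variant, "' needs dn_params")
  if (config$variant == "dn_extended" && !inherits(dn, "dnv1_ext_dn_params"))
    stop("variant 'dn_extended' needs ext_dn_params")
  if (config$variant == "subunit" && !is.null(dn))
    stop("variant 'subunit' takes no normalization parameters")
  structure(list(config = config,
                 core = list(subunit = subunit, dn = dn),
                 readout = readout),
            class = "dnv1_model")
}

#' Predict mean spike counts
#'
#' @param object a [dn_model()].
#' @param stimuli array `[H, W, N]` (or a single `[H, W]` image).
#' @param mode batch-normalization mode, see [subunit_forward()].
#' @param ... unused.
#' @return matrix `[N, neurons]` of predicted mean spike counts.
#' @export
predict.dnv1_model <- function(object, stimuli, mode = "eval", ...) {
  z <- core_forward(object, stimuli, mode = mode)
  attr(z, "bn_state") <- NULL
  g <- readout_forward(z, object$readout)
  output_nonlinearity(g, object$readout)
}

#' @export
print.dnv1_model <- function(x, ...) {
  cfg <- x$config
  cat("<dnv1_model> variant:", cfg$variant,
      sprintf("| %d channels, %dpx kernel, %dpx pool", cfg$channels,
              cfg$kernel, cfg$pool))
  if (cfg$variant == "dn_extended")
    cat(sprintf(", %dx%d norm kernel (dilation %d)", cfg$norm_kernel,
                cfg$norm_kernel, cfg$dilation))
  if (!is.null(x$readout))
    cat(" |", dim(x$readout$a)[3], "neurons")
  cat("\n")
  invisible(x)
}
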