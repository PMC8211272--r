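#' Loss configuration
#'
#' Weights of the three regularizers added to the Poisson objective: Laplace
#' smoothness of the subunit filters, L1 sparsity of the factorized readout,
#' and smoothness of the output-nonlinearity coefficients.
#'
#' @param lambda_smooth,lambda_sparse,lambda_out non-negative weights.
#' @return list of class `dnv1_loss_config`.
#' @export
loss_config <- function(lambda_smooth = 1e-6, lambda_sparse = 1e-6,
                        lambda_out = 1e-2) {
  stopifnot(lambda_smooth >= 0, lambda_sparse >= 0, lambda_out >= 0)
  structure(list(lambda_smooth = lambda_smooth, lambda_sparse = lambda_sparse,
                 lambda_out = lambda_out),
            class = "dnv1_loss_config")
}

# Fixed 3x3 Laplace filter; entries sum to zero.
laplace_kernel <- function() {
  matrix(c(0.25, 0.5, 0.25, 0.5, -3, 0.5, 0.25, 0.5, 0.25), 3, 3)
}

#' Poisson loss
#'
#' `sum_{i,j} (rhat - r * ln rhat)`: the negative Poisson log-likelihood of
#' integer spike counts `r` under predicted means `rhat`, dropping the
#' `ln(r!)` term that does not depend on the model. Predictions are floored
#' at 1e-8 before the logarithm; floored entries are counted in the
#' `"n_floored"` attribute.
#'
#' @param rhat predicted means (any shape).
#' @param r observed spike counts, same shape.
#' @return scalar loss with attribute `n_floored`.
#' @export
poisson_loss <- function(rhat, r) {
  stopifnot(length(rhat) == length(r), all(r >= 0))
  nf <- sum(rhat <= 0)
  if (nf > 0) rhat <- pmax(rhat, 1e-8)
  structure(sum(rhat - r * log(pmax(rhat, 1e-8))), n_floored = nf)
}

#' Laplace smoothness penalty on subunit filters
#'
#' `sum_{u,v,k} (L * w_k)^2` with the fixed 3x3 Laplace filter applied as a
#' valid convolution, so spatially constant filters are unpenalized.
#'
#' @param w filter array `[k, k, channels]`.
#' @return scalar penalty.
#' @export
smoothness_penalty <- function(w) {
  L <- laplace_kernel()
  Lr <- L[3:1, 3:1]  # convolution = cross-correlation with flipped kernel
  out <- conv_valid(w, array(Lr, c(3, 3, 1)))
  sum(out^2)
}

#' Readout sparsity penalty
#'
#' L1 norm of the implied full readout tensor: because the readout is
#' factorized, `sum_i sum_{u,v,l} |a[u,v,i]| |b[l,i]|` separates into
#' `sum_i (sum |a_i|) (sum |b_i|)`.
#'
#' @param a spatial readout weights `[oh, ow, neurons]`.
#' @param b feature readout weights `[channels, neurons]`.
#' @return scalar penalty.
#' @export
sparsity_penalty <- function(a, b) {
  sa <- colSums(abs(matrix(a, ncol = dim(a)[3])))
  sb <- colSums(abs(b))
  sum(sa * sb)
}

#' Output-nonlinearity smoothness penalty
#'
#' Mean (over grid points) of the summed squared first and second finite
#' differences of each neuron's tent coefficients; zero exactly when every
#' `alpha` column is constant. Differences with undefined neighbors at the
#' grid boundary are skipped.
#'
#' @param alpha matrix `[grid points, neurons]`.
#' @return scalar penalty.
#' @export
output_nl_penalty <- function(alpha) {
  stopifnot(nrow(alpha) >= 3)
  n <- nrow(alpha)
  d1 <- alpha[2:n, , drop = FALSE] - alpha[1:(n - 1), , drop = FALSE]
  d2 <- 2 * alpha[2:(n - 1), , drop = FALSE] -
    alpha[1:(n - 2), , drop = FALSE] - alpha[3:n, , drop = FALSE]
  (sum(d1^2) + sum(d2^2)) / n
}

# Gradient of output_nl_penalty wrt alpha (same shape).
output_nl_penalty_grad <- function(alpha) {
  n <- nrow(alpha)
  g <- matrix(0, n, ncol(alpha))
  d1 <- alpha[2:n, , drop = FALSE] - alpha[1:(n - 1), , drop = FALSE]
  g[2:n, ] <- g[2:n, ] + 2 * d1
  g[1:(n - 1), ] <- g[1:(n - 1), ] - 2 * d1
  d2 <- 2 * alpha[2:(n - 1), , drop = FALSE] -
    alpha[1:(n - 2), , drop = FALSE] - alpha[3:n, , drop = FALSE]
  g[2:(n - 1), ] <- g[2:(n - 1), ] + 4 * d2
  g[1:(n - 2), ] <- g[1:(n - 2), ] - 2 * d2
  g[3:n, ] <- g[3:n, ] - 2 * d2
  g / n
}

#' Total training loss
#'
#' `L = L_Poisson + lambda_smooth L_smooth + lambda_sparse L_sparse +
#' lambda_out L_out` evaluated on one batch of stimuli and per-trial counts.
#'
#' @param model a [dn_model()].
#' @param stimuli array `[H, W, N]`.
#' @param r counts `[N, neurons]`.
#' @param cfg a [loss_config()].
#' @param mode batch-normalization mode.
#' @return scalar loss; attribute `parts` holds the four components.
#' @export
total_loss <- function(model, stimuli, r, cfg = loss_config(),
                       mode = "eval") {
  rhat <- predict(model, stimuli, mode = mode)
  lp <- as.numeric(poisson_loss(rhat, r))
  ls <- smoothness_penalty(model$core$subunit$w)
  lsp <- sparsity_penalty(model$readout$a, model$readout$b)
  lo <- output_nl_penalty(model$readout$alpha)
  structure(lp + cfg$lambda_smooth * ls + cfg$lambda_sparse * lsp +
              cfg$lambda_out * lo,
            parts = c(poisson = lp, smooth = ls, sparse = lsp, out = lo))
}
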