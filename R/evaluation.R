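#' Observation-noise variance
#'
#' For each neuron, the across-trial (unbiased) variance of the response to
#' each image, averaged over images. Images with fewer than two observed
#' trials are skipped; a neuron with no such image is reported `NA`.
#'
#' @param r spike counts `[images, trials, neurons]`, `NA` for missing
#'   trials.
#' @return numeric vector, per-neuron noise variance.
#' @export
noise_variance <- function(r) {
  stopifnot(length(dim(r)) == 3)
  ntr <- apply(!is.na(r[, , 1, drop = FALSE]), 1, sum)
  usable <- ntr >= 2
  if (!any(usable)) return(rep(NA_real_, dim(r)[3]))
  v <- apply(r[usable, , , drop = FALSE], c(1, 3), stats::var, na.rm = TRUE)
  colMeans(v)
}

#' Explainable variance
#'
#' Total response variance over all image-trial observations minus the
#' observation-noise variance: the part of the variance that a perfect model
#' of the stimulus-driven mean could capture.
#'
#' @inheritParams noise_variance
#' @return numeric vector, per-neuron explainable variance.
#' @export
explainable_variance <- function(r) {
  total_variance(r) - noise_variance(r)
}

total_variance <- function(r) {
  apply(r, 3, function(m) stats::var(as.vector(m), na.rm = TRUE))
}

#' Neuron inclusion filter
#'
#' Indices of neurons whose explainable-to-total variance ratio reaches the
#' threshold (0.15 in the emulated recordings' preprocessing).
#'
#' @inheritParams noise_variance
#' @param threshold minimum explainable/total variance ratio.
#' @return integer vector of retained neuron indices; the ratios are
#'   attached as attribute `"ratio"`.
#' @export
filter_neurons <- function(r, threshold = 0.15) {
  ratio <- explainable_variance(r) / total_variance(r)
  structure(which(!is.na(ratio) & ratio >= threshold), ratio = ratio)
}

#' Fraction of explainable variance explained
#'
#' `FEV = 1 - (Var_res / Var_exp)` per neuron, where the residual variance
#' `Var_res = mean((r - rhat)^2) - sigma2_noise` is computed against the
#' per-trial observations (1/N normalization) and corrected by the
#' observation-noise variance. A perfect model of the stimulus-driven mean
#' scores 1 regardless of trial noise.
#'
#' @inheritParams noise_variance
#' @param rhat predictions `[images, neurons]`.
#' @return list with per-neuron `fev`, `mean_fev` over included neurons, and
#'   the indices of neurons excluded for non-positive explainable variance.
#' @export
fev <- function(r, rhat) {
  stopifnot(dim(r)[1] == nrow(rhat), dim(r)[3] == ncol(rhat))
  s2 <- noise_variance(r)
  vexp <- explainable_variance(r)
  I <- ncol(rhat)
  out <- rep(NA_real_, I)
  for (i in seq_len(I)) {
    resid <- r[, , i] - rhat[, i]
    msr <- mean(resid^2, na.rm = TRUE)
    out[i] <- 1 - (msr - s2[i]) / vexp[i]
  }
  excluded <- which(!is.na(vexp) & vexp <= 0)
  if (length(excluded))
    warning(length(excluded), " neuron(s) excluded (explainable variance <= 0)")
  keep <- setdiff(which(!is.na(out)), excluded)
  list(fev = out, mean_fev = mean(out[keep]), excluded = excluded)
}

#' Average correlation
#'
#' Mean over neurons of the Pearson correlation between per-image mean
#' responses and predictions; neurons with constant prediction (or constant
#' response) contribute a correlation of zero.
#'
#' @param r_mean per-image mean responses `[images, neurons]`.
#' @param rhat predictions `[images, neurons]`.
#' @return scalar mean correlation; per-neuron values as attribute
#'   `"per_neuron"`.
#' @export
avg_correlation <- function(r_mean, rhat) {
  stopifnot(all(dim(r_mean) == dim(rhat)))
  cors <- vapply(seq_len(ncol(rhat)), function(i) {
    if (stats::sd(rhat[, i]) == 0 || stats::sd(r_mean[, i]) == 0) return(0)
    stats::cor(r_mean[, i], rhat[, i])
  }, numeric(1))
  structure(mean(cors), per_neuron = cors)
}
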