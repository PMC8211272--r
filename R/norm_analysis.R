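#' Orientation estimate of a convolutional filter
#'
#' The filter is windowed with a centered Gaussian (sd 3 px), mean-subtracted
#' and scaled to unit L2 norm, zero-padded to 64 x 64 and Fourier
#' transformed. Orientation selectivity is summarized by the mean resultant
#' vector `m = sum_R F_uv exp(2 i phi) / sum_R F_uv` over the annulus
#' `0.3 < sqrt(u^2 + v^2) < 0.7` (frequencies in Nyquist units, strict
#' inequalities), with `F_uv` the power spectral density and
#' `phi = atan2(v, u)`. `|m|` near 1 means all in-band power sits at one
#' orientation; the preferred orientation is `arg(m) / 2 mod pi`. Filters
#' with `|m| >= 0.125` are flagged oriented.
#'
#' @param filter square filter matrix.
#' @param window_sd Gaussian window standard deviation, px.
#' @param fft_size zero-padded transform size.
#' @param band annulus bounds in Nyquist units.
#' @param threshold `|m|` threshold separating oriented from unoriented.
#' @return list of class `dnv1_orientation`: `m` (complex), `magnitude`,
#'   `theta` (radians in `[0, pi)`), `oriented`.
#' @export
estimate_orientation <- function(filter, window_sd = 3, fft_size = 64L,
                                 band = c(0.3, 0.7), threshold = 0.125) {
  stopifnot(is.matrix(filter), nrow(filter) == ncol(filter))
  k <- nrow(filter)
  ctr <- (k + 1) / 2
  g <- outer(seq_len(k) - ctr, seq_len(k) - ctr,
             function(r, c) exp(-(r^2 + c^2) / (2 * window_sd^2)))
  fw <- filter * g
  fw <- fw - mean(fw)
  nrm <- sqrt(sum(fw^2))
  if (nrm == 0)
    return(structure(list(m = 0 + 0i, magnitude = 0, theta = NA_real_,
                          oriented = FALSE), class = "dnv1_orientation"))
  fw <- fw / nrm
  pad <- matrix(0, fft_size, fft_size)
  pad[seq_len(k), seq_len(k)] <- fw
  P <- Mod(stats::fft(pad))^2
  fr <- (seq_len(fft_size) - 1)
  fr <- ifelse(fr >= fft_size / 2, fr - fft_size, fr) / (fft_size / 2)
  fu <- matrix(fr, fft_size, fft_size)           # row frequency
  fv <- matrix(fr, fft_size, fft_size, byrow = TRUE)
  rad <- sqrt(fu^2 + fv^2)
  sel <- rad > band[1] & rad < band[2]
  phi <- atan2(fv, fu)
  m <- sum(P[sel] * exp(2i * phi[sel])) / sum(P[sel])
  theta <- (Arg(m) / 2) %% pi
  structure(list(m = m, magnitude = Mod(m), theta = theta,
                 oriented = Mod(m) >= threshold),
            class = "dnv1_orientation")
}

# Orientation estimates for a whole filter bank [k, k, C].
estimate_orientations <- function(w, ...) {
  lapply(seq_len(dim(w)[3]), function(c) estimate_orientation(w[, , c], ...))
}

#' Image-averaged normalization-input matrix
#'
#' For a fitted center DN model, `M[k, l]` is the average (over images and
#' feature-map locations) of the product `p[k, l] * <y_k^n_k>` — the
#' contribution of source channel `k` to target channel `l`'s denominator.
#' With `pooled = FALSE` the unpooled exponentiated drive `y_k^n_k` is
#' averaged instead.
#'
#' @param model a [dn_model()] with a `"dn"` or `"dn_nonspecific"` variant.
#' @param images evaluation images `[H, W, N]` (typically the validation
#'   set).
#' @param pooled average the pooled denominator quantity (default) or the
#'   raw exponentiated drive.
#' @param chunk images per forward pass.
#' @return matrix `[channels, channels]` (source k rows, target l columns)
#'   of class `dnv1_norm_input`.
#' @export
normalization_input_matrix <- function(model, images, pooled = TRUE,
                                       chunk = 256L) {
  stopifnot(model$config$variant %in% c("dn", "dn_nonspecific"))
  dnp <- model$core$dn
  N <- dim(images)[3]
  acc <- numeric(model$config$channels)
  count <- 0
  for (start in seq(1L, N, by = chunk)) {
    ix <- start:min(start + chunk - 1L, N)
    y <- subunit_forward(images[, , ix, drop = FALSE], model$core$subunit,
                         mode = "eval")
    attr(y, "bn_state") <- NULL
    tpow <- pow_channels(y, dnp$n)
    q <- if (pooled) avg_pool_same(tpow, model$config$pool) else tpow
    acc <- acc + colSums(fm_mat(q))
    count <- count + prod(dim(q)[1:3])
  }
  mean_drive <- acc / count
  M <- dnp$p * mean_drive  # recycles down columns: rows are sources
  structure(M, class = c("dnv1_norm_input", "matrix"))
}

# Circular orientation difference in [0, pi/2].
ori_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Similar- versus dissimilar-orientation normalization input
#'
#' Restricted to oriented filters, splits each target channel's incoming
#' normalization input into sources with similar preferred orientation
#' (difference < 45 degrees) and dissimilar ones (>= 45 degrees), and
#' reports the across-target fold ratio of the two summed groups.
#'
#' @param M a [normalization_input_matrix()].
#' @param estimates list of per-filter orientation estimates
#'   (`estimate_orientation` results, one per channel).
#' @return list: per-target `similar`/`dissimilar` sums, `ratio`
#'   (`Inf`-capped with `capped` flag when the dissimilar total is zero).
#' @export
split_similar_dissimilar <- function(M, estimates) {
  ori <- which(vapply(estimates, `[[`, logical(1), "oriented"))
  if (length(ori) < 2) stop("need at least two oriented filters")
  th <- vapply(estimates, function(e) e$theta %||% NA_real_, numeric(1))
  sim <- dis <- setNames(numeric(length(ori)), ori)
  for (j in seq_along(ori)) {
    l <- ori[j]
    dth <- ori_diff(th[ori], th[l])
    sim[j] <- sum(M[ori[dth < pi / 4], l])
    dis[j] <- sum(M[ori[dth >= pi / 4], l])
  }
  tot_d <- sum(dis)
  capped <- tot_d == 0
  list(similar = sim, dissimilar = dis,
       ratio = if (capped) Inf else sum(sim) / tot_d, capped = capped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalization input binned by orientation difference
#'
#' Mean normalization input between oriented filter pairs, binned by their
#' orientation difference into `width`-degree bins partitioning
#' `[0, 90]` degrees. Profiles of several fitted models can be averaged by
#' `rowMeans(sapply(..., \(m) m$mean))`.
#'
#' @param M a [normalization_input_matrix()].
#' @param estimates per-filter orientation estimates.
#' @param width bin width, degrees.
#' @return data.frame with bin bounds, mean input (`NA` for empty bins) and
#'   pair counts.
#' @export
bin_by_orientation_difference <- function(M, estimates, width = 10) {
  ori <- which(vapply(estimates, `[[`, logical(1), "oriented"))
  if (length(ori) < 2) stop("need at least two oriented filters")
  th <- vapply(estimates, function(e) e$theta %||% NA_real_, numeric(1))
  pairs <- expand.grid(k = ori, l = ori)
  dth <- ori_diff(th[pairs$k], th[pairs$l]) * 180 / pi
  vals <- M[cbind(pairs$k, pairs$l)]
  edges <- seq(0, 90, by = width)
  bin <- findInterval(dth, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  mean_in <- count <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    inb <- bin == b
    count[b] <- sum(inb)
    if (count[b] > 0) mean_in[b] <- mean(vals[inb])
  }
  data.frame(lo = edges[-length(edges)], hi = edges[-1], mean = mean_in,
             n_pairs = count)
}

#' Normalization input split by filter cosine similarity
#'
#' Splits all source-target filter pairs (oriented or not) by the cosine
#' similarity of their flattened filters: similar (`cos > 0`) versus
#' dissimilar (`cos < 0`); exactly-zero pairs are counted separately and
#' belong to neither group.
#'
#' @param M a [normalization_input_matrix()].
#' @param w filter bank `[k, k, channels]`.
#' @return list with `similar`, `dissimilar` (summed inputs), `ratio`,
#'   `n_zero`.
#' @export
cosine_similarity_split <- function(M, w) {
  C <- dim(w)[3]
  fmat <- matrix(w, ncol = C)
  nrm <- sqrt(colSums(fmat^2))
  cosim <- crossprod(fmat) / outer(nrm, nrm)
  sim <- sum(M[cosim > 0])
  dis <- sum(M[cosim < 0])
  list(similar = sim, dissimilar = dis,
       ratio = if (dis == 0) Inf else sim / dis,
       n_zero = sum(cosim == 0))
}

#' Exponent summary across fitted models
#'
#' Pools the learned DN exponents of one or more fitted models, labels each
#' by whether its filter is oriented, and reports the pooled mean, per-group
#' means, and a histogram.
#'
#' @param models list of [dn_model()]s with DN parameters.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `exponents` (data.frame of value, oriented, model),
#'   `mean`, `mean_oriented`, `mean_unoriented`, `hist`.
#' @export
exponent_summary <- function(models, breaks = seq(0, 4, by = 0.25)) {
  rows <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    est <- estimate_orientations(m$core$subunit$w)
    rows[[mi]] <- data.frame(
      value = m$core$dn$n,
      oriented = vapply(est, `[[`, logical(1), "oriented"),
      model = mi)
  }
  df <- do.call(rbind, rows)
  br <- unique(c(breaks, max(breaks, max(df$value))))
  list(exponents = df,
       mean = mean(df$value),
       mean_oriented = mean(df$value[df$oriented]),
       mean_unoriented = mean(df$value[!df$oriented]),
       hist = graphics::hist(df$value, breaks = br, plot = FALSE))
}

#' Per-channel readout contribution
#'
#' Normalizes each neuron's feature readout weights to unit sum across
#' channels (removing the spatial/feature scaling degeneracy), averages
#' across neurons per model, pools the per-model channel averages, and
#' reports the coefficient of variation (population standard deviation over
#' mean) of the pooled distribution. Neurons with an all-zero feature vector
#' are excluded with a warning.
#'
#' @param b_list list of feature-weight matrices `[channels, neurons]`, one
#'   per model (or a single matrix).
#' @return list with `per_model` (channel-average matrix, channels x
#'   models), `pooled` (vector), `cv`.
#' @export
readout_contribution <- function(b_list) {
  if (is.matrix(b_list)) b_list <- list(b_list)
  per_model <- sapply(b_list, function(b) {
    s <- colSums(b)
    if (any(s == 0)) {
      warning(sum(s == 0), " neuron(s) with all-zero feature weights excluded")
      b <- b[, s > 0, drop = FALSE]
      s <- s[s > 0]
    }
    rowMeans(sweep(b, 2, s, "/"))
  })
  pooled <- as.vector(per_model)
  cv <- stats::sd(pooled) * sqrt((length(pooled) - 1) / length(pooled)) /
    mean(pooled)
  list(per_model = per_model, pooled = pooled, cv = cv)
}
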