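#' Training configuration
#'
#' Adaptive-moment gradient descent (Adam) with the early-stopping schedule:
#' the validation Poisson loss is evaluated every `eval_every` steps; after
#' `patience` evaluations without improvement the learning rate is divided by
#' `decay_factor`, and after `num_decays` decays the next exhausted patience
#' stops training. Non-negativity constraints are enforced by projection
#' (clipping at zero) after every step.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size stimuli per gradient step.
#' @param eval_every steps between validation evaluations.
#' @param patience non-improving evaluations tolerated per learning rate.
#' @param decay_factor learning-rate division factor.
#' @param num_decays decays before the final stop.
#' @param max_steps hard cap on gradient steps.
#' @param min_delta relative validation-loss improvement below which an
#'   evaluation counts as "no improvement" for the schedule (0 = any
#'   improvement counts; a small value such as 1e-4 lets the learning-rate
#'   decays trigger once the loss merely creeps, which matters for polishing
#'   slowly-converging parameters like the normalization weights).
#' @param seed RNG seed for initialization and batch sampling.
#' @return list of class `dnv1_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256L,
                         eval_every = 100L, patience = 10L, decay_factor = 3,
                         num_decays = 4L, max_steps = 5000L, min_delta = 0,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, eval_every >= 1,
            patience >= 1, decay_factor > 1, num_decays >= 0, max_steps >= 1,
            min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 decay_factor = decay_factor,
                 num_decays = as.integer(num_decays),
                 max_steps = as.integer(max_steps),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "dnv1_train_config")
}

#' Randomly initialized model
#'
#' Filters from a truncated normal (sd 0.01, truncated at two sd); biases 0;
#' exponents 1; semi-saturation constants 1; normalization weights uniform on
#' `[0, 0.01]` (likewise the extended pool components); readout weights
#' uniform on `[0, 0.01]`; readout bias 0; output-nonlinearity coefficients 0
#' (the regularizer's preferred identity-like start).
#'
#' @param config a [core_config()].
#' @param n_neurons number of readout neurons.
#' @param use_bn attach bias-only batch normalization to the subunit stage.
#' @return a [dn_model()].
#' @export
init_model <- function(config, n_neurons, use_bn = TRUE) {
  C <- config$channels; k <- config$kernel
  w <- array(rtruncnorm(k * k * C, sd = 0.01), c(k, k, C))
  sub <- subunit_params(w, o = numeric(C),
                        bn = if (use_bn) bn_state(C) else NULL)
  dn <- switch(config$variant,
    subunit = NULL,
    dn = dn_params(rep(1, C), rep(1, C),
                   matrix(runif(C * C, 0, 0.01), C, C)),
    dn_nonspecific = dn_params(rep(1, C), rep(1, C),
                               matrix(runif(C * C, 0, 0.01), C, C),
                               nonspecific = TRUE),
    dn_extended = ext_dn_params(rep(1, C), rep(1, C),
                                array(runif(config$norm_kernel^2 * C * 2,
                                            0, 0.01),
                                      c(config$norm_kernel,
                                        config$norm_kernel, C, 2)),
                                array(runif(C * C * 2, 0, 0.01), c(C, C, 2)),
                                dilation = config$dilation))
  side <- config$image_side - k + 1L
  if (config$variant == "dn_extended")
    side <- side - config$dilation * (config$norm_kernel - 1L)
  ro <- readout_params(a = array(runif(side * side * n_neurons, 0, 0.01),
                                 c(side, side, n_neurons)),
                       b = matrix(runif(C * n_neurons, 0, 0.01), C, n_neurons),
                       q = numeric(n_neurons))
  dn_model(config, sub, dn, ro)
}

rtruncnorm <- function(n, sd = 1, trunc = 2) {
  x <- stats::rnorm(n, sd = sd)
  while (any(bad <- abs(x) > trunc * sd)) x[bad] <- stats::rnorm(sum(bad), sd = sd)
  x
}

# Flat parameter access for the optimizer.
get_params <- function(model) {
  out <- list(w = model$core$subunit$w, o = model$core$subunit$o)
  dn <- model$core$dn
  if (!is.null(dn)) {
    out$n <- dn$n; out$sigma <- dn$sigma
    if (inherits(dn, "dnv1_ext_dn_params")) {
      out$cpool <- dn$cpool; out$dfeat <- dn$dfeat
    } else {
      out$p <- dn$p
    }
  }
  out$a <- model$readout$a; out$b <- model$readout$b
  out$q <- model$readout$q; out$alpha <- model$readout$alpha
  out
}

set_params <- function(model, par) {
  if (!is.null(par$w)) model$core$subunit$w <- par$w
  if (!is.null(par$o)) model$core$subunit$o <- par$o
  if (!is.null(model$core$dn)) {
    for (f in c("n", "sigma", "p", "cpool", "dfeat"))
      if (!is.null(par[[f]])) model$core$dn[[f]] <- par[[f]]
  }
  for (f in c("a", "b", "q", "alpha"))
    if (!is.null(par[[f]])) model$readout[[f]] <- par[[f]]
  model
}

# Non-negativity projection (clip at 0), plus the nonspecific constraint.
project_params <- function(model) {
  dn <- model$core$dn
  if (!is.null(dn)) {
    dn$n <- pmax(dn$n, 0); dn$sigma <- pmax(dn$sigma, 0)
    if (inherits(dn, "dnv1_ext_dn_params")) {
      dn$cpool <- pmax(dn$cpool, 0); dn$dfeat <- pmax(dn$dfeat, 0)
    } else {
      dn$p <- pmax(dn$p, 0)
      if (isTRUE(dn$nonspecific)) dn$p <- project_nonspecific(dn$p)
    }
    model$core$dn <- dn
  }
  model$readout$a <- pmax(model$readout$a, 0)
  model$readout$b <- pmax(model$readout$b, 0)
  model
}

#' Fit a model by Poisson regression
#'
#' Minimizes the [total_loss()] over the training split of `dataset` with
#' Adam, mini-batches of `cfg$batch_size` image-trial samples, non-negativity
#' projection after every step, and the early-stopping/learning-rate schedule
#' of [train_config()]. Early stopping monitors the validation-set Poisson
#' loss; the parameters achieving the best validation loss are returned.
#'
#' @param dataset a `dnv1_dataset` (see [simulate_population()]) with train
#'   and validation splits.
#' @param model an initialized [dn_model()] (e.g. from [init_model()]).
#' @param loss_cfg a [loss_config()].
#' @param cfg a [train_config()].
#' @param freeze character vector of parameter groups to keep fixed:
#'   any of `"filters"`, `"dn"`, `"readout"`, `"outputnl"`.
#' @param verbose print evaluation progress.
#' @return list of class `dnv1_fit`: `model` (best on validation), `trace`
#'   (data.frame of step, learning rate, training loss, validation Poisson
#'   loss and validation mean correlation), `val_loss`, `val_corr`, `steps`.
#' @export
train <- function(dataset, model, loss_cfg = loss_config(),
                  cfg = train_config(), freeze = character(),
                  verbose = FALSE) {
  stopifnot(inherits(dataset, "dnv1_dataset"), inherits(model, "dnv1_model"))
  set.seed(cfg$seed)
  idx_train <- which(dataset$split == "train")
  idx_val <- which(dataset$split == "val")
  if (length(idx_train) == 0 || length(idx_val) == 0)
    stop("dataset needs train and validation partitions")

  # With frozen filters and fixed (or absent) batch-norm statistics the
  # driving maps are constant: precompute them once for the whole dataset.
  frozen_filters <- "filters" %in% freeze
  drv <- NULL
  if (frozen_filters && is.null(model$core$subunit$bn)) {
    drv <- driving_container(model, dataset$images,
                             with_log = !is.null(model$core$dn))
  }
  fast <- !is.null(drv) && fast_step_applicable(model, freeze)

  lr <- cfg$learning_rate
  adam_m <- list(); adam_v <- list(); adam_t <- 0
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  best_val <- Inf
  best_model <- model
  n_bad <- 0L; n_decays <- 0L
  trace <- list()
  val_r <- dataset$responses[idx_val, , , drop = FALSE]

  for (step in seq_len(cfg$max_steps)) {
    bi <- sample(idx_train, cfg$batch_size, replace = TRUE)
    rb <- sample_trial_counts(dataset$responses, bi)
    if (fast) {
      lg <- fast_loss_and_grads(model, rb, loss_cfg, drv, bi,
                                freeze = freeze)
    } else if (!is.null(drv)) {
      lg <- loss_and_grads(model, NULL, rb, loss_cfg, mode = "train",
                           freeze = freeze,
                           driving = driving_slice(drv, bi),
                           driving_log = if (!is.null(drv$logy)) {
                             lb <- .gather_images(drv$logy, bi, drv$npix)
                             dim(lb) <- c(drv$oh, drv$ow, length(bi), drv$C)
                             lb
                           })
    } else {
      lg <- loss_and_grads(model, dataset$images[, , bi, drop = FALSE], rb,
                           loss_cfg, mode = "train", freeze = freeze)
    }
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss) at step ", step)
    if (!is.null(lg$bn_state)) model$core$subunit$bn <- lg$bn_state

    adam_t <- adam_t + 1
    par <- get_params(model)
    for (nm in names(lg$grads)) {
      gr <- lg$grads[[nm]]
      if (is.null(adam_m[[nm]])) {
        adam_m[[nm]] <- gr * 0; adam_v[[nm]] <- gr * 0
      }
      adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
      adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
      mhat <- adam_m[[nm]] / (1 - beta1^adam_t)
      vhat <- adam_v[[nm]] / (1 - beta2^adam_t)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    model <- project_params(set_params(model, par))

    if (step %% cfg$eval_every == 0) {
      ev <- evaluate_split(model, dataset, idx_val, drv)
      trace[[length(trace) + 1]] <-
        data.frame(step = step, lr = lr, train_loss = lg$loss,
                   val_loss = ev$poisson, val_corr = ev$corr)
      if (verbose)
        message(sprintf("step %5d lr %.2e train %.2f val %.2f corr %.3f",
                        step, lr, lg$loss, ev$poisson, ev$corr))
      improved <- !is.finite(best_val) || ev$poisson <
        best_val - max(1e-12, cfg$min_delta * abs(best_val))
      if (ev$poisson < best_val) {
        # best-on-validation checkpoint tracks any improvement
        best_val <- ev$poisson
        best_model <- model
      }
      if (improved) {
        n_bad <- 0L
      } else {
        n_bad <- n_bad + 1L
        if (n_bad >= cfg$patience) {
          if (n_decays >= cfg$num_decays) break
          lr <- lr / cfg$decay_factor
          n_decays <- n_decays + 1L
          n_bad <- 0L
        }
      }
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), lr = numeric(), train_loss = numeric(),
               val_loss = numeric(), val_corr = numeric())
  ev <- evaluate_split(best_model, dataset, idx_val, drv)
  structure(list(model = best_model, trace = trace, val_loss = ev$poisson,
                 val_corr = ev$corr, steps = step),
            class = "dnv1_fit")
}

# One observed trial per sampled image (unbiased for the Poisson objective).
sample_trial_counts <- function(responses, idx) {
  n <- length(idx); I <- dim(responses)[3]
  out <- matrix(0, n, I)
  ntr <- dim(responses)[2]
  for (j in seq_len(n)) {
    obs <- which(!is.na(responses[idx[j], , 1]))
    t <- if (length(obs) == 1L) obs else sample(obs, 1L)
    out[j, ] <- responses[idx[j], t, ]
  }
  out
}

# Driving maps for all images, in chunks small enough to bound the im2col
# transient (chunk * positions * kernel^2 doubles).
compute_driving <- function(model, images, chunk = 128L) {
  N <- dim(images)[3]
  out <- NULL
  for (start in seq(1L, N, by = chunk)) {
    ix <- start:min(start + chunk - 1L, N)
    y <- subunit_forward(images[, , ix, drop = FALSE], model$core$subunit,
                         mode = "eval")
    attr(y, "bn_state") <- NULL
    if (is.null(out)) out <- array(0, c(dim(y)[1:2], N, dim(y)[4]))
    out[, , ix, ] <- y
  }
  out
}

# Validation Poisson loss (summed over observed trials) and mean correlation.
evaluate_split <- function(model, dataset, idx, drv = NULL,
                           chunk = 512L) {
  rhat <- predict_in_chunks(model, dataset, idx, drv, chunk)
  r <- dataset$responses[idx, , , drop = FALSE]
  ntr <- dim(r)[2]
  lp <- 0
  for (t in seq_len(ntr)) {
    rt <- r[, t, , drop = TRUE]
    if (length(idx) == 1L) rt <- matrix(rt, 1)
    obs <- !is.na(rt)
    lp <- lp + sum((rhat - rt * log(pmax(rhat, 1e-8)))[obs])
  }
  rbar <- apply(r, c(1, 3), mean, na.rm = TRUE)
  list(poisson = lp, corr = avg_correlation(rbar, rhat))
}

predict_in_chunks <- function(model, dataset, idx, drv = NULL,
                              chunk = 512L) {
  I <- dim(model$readout$a)[3]
  rhat <- matrix(0, length(idx), I)
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(idx))
    ix <- idx[sel]
    if (!is.null(drv)) {
      y <- driving_slice(drv, ix)
      z <- switch(model$config$variant,
        subunit = y,
        dn = ,
        dn_nonspecific = dn_forward(y, model$core$dn,
                                    pool = model$config$pool),
        dn_extended = extended_dn_forward(y, model$core$dn,
                                          pool = model$config$pool))
      g <- readout_forward(z, model$readout)
      rhat[sel, ] <- output_nonlinearity(g, model$readout)
    } else {
      rhat[sel, ] <- predict(model, dataset$images[, , ix, drop = FALSE])
    }
  }
  rhat
}

#' Sample regularization weights
#'
#' Draws each regularizer weight from a log-uniform distribution over the
#' variant's search interval: `lambda_smooth` on `[1e-9, 10^-3.5]` and
#' `lambda_sparse` on `[1e-9, 10^-4.5]` for all variants; `lambda_out` on
#' `[1e-8, 1e2]` for the center DN and subunit models and on `[1e-5, 1]` for
#' the nonspecific and spatially extended models.
#'
#' @param variant model variant name.
#' @return a [loss_config()].
#' @export
sample_hyperparameters <- function(variant = c("dn", "subunit",
                                               "dn_nonspecific",
                                               "dn_extended")) {
  variant <- match.arg(variant)
  lout <- if (variant %in% c("dn", "subunit")) c(-8, 2) else c(-5, 0)
  loss_config(lambda_smooth = 10^stats::runif(1, -9, -3.5),
              lambda_sparse = 10^stats::runif(1, -9, -4.5),
              lambda_out = 10^stats::runif(1, lout[1], lout[2]))
}

#' Summarize the best fits of a model class
#'
#' Ranks fits by validation score and reports the mean and normal-
#' approximation 95% confidence interval of the test scores of the top `k`.
#'
#' @param val_scores validation score per fit (higher is better).
#' @param test_scores matching test scores.
#' @param k number of top fits to keep.
#' @return list with `k`, `mean`, `ci` (half-width), `selected` (indices).
#' @export
select_top_models <- function(val_scores, test_scores, k = 10L) {
  stopifnot(length(val_scores) == length(test_scores))
  if (length(val_scores) < k) {
    warning("fewer than ", k, " fits; using all ", length(val_scores))
    k <- length(val_scores)
  }
  sel <- order(val_scores, decreasing = TRUE)[seq_len(k)]
  ts <- test_scores[sel]
  half <- if (k > 1) 1.96 * stats::sd(ts) / sqrt(k) else 0
  list(k = k, mean = mean(ts), ci = half, selected = sel)
}
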