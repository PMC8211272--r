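#' Run a configured experiment end to end
#'
#' Thin orchestration over the package's stages: simulate a synthetic
#' dataset (unless one is supplied), fit the requested model variant once
#' per seed, evaluate on the test split, and optionally run the in-silico
#' and normalization-structure analyses. All artifacts (checkpoints,
#' training traces, metrics, manifest) are written as JSON/CSV text under
#' `out_dir`, and the manifest records per-stage status so a rerun with the
#' same configuration and seeds reproduces the same files.
#'
#' @param cfg experiment configuration: a list (or path to a YAML file) with
#'   fields `variant`, `seeds` (vector), `synth` (arguments for
#'   [synthetic_config()]), optional `loss` ([loss_config()] arguments),
#'   `train` ([train_config()] arguments), `freeze`, and logical stage
#'   switches `insilico`, `analyze_norm`.
#' @param out_dir output directory (created if missing).
#' @param dataset optional prebuilt `dnv1_dataset` (skips the simulate
#'   stage).
#' @param verbose print stage progress.
#' @return the manifest list, invisibly.
#' @export
run_experiment <- function(cfg, out_dir, dataset = NULL, verbose = TRUE) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(!is.null(cfg$variant))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- cfg$seeds %||% 1L
  manifest <- list(package = "dnv1",
                   version = as.character(utils::packageVersion("dnv1")),
                   variant = cfg$variant, seeds = seeds, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$error)
    if (!res$ok) stop("stage '", name, "' failed: ", res$error)
    if (verbose) message("stage ", name, ": ok")
    res$value
  }

  if (is.null(dataset)) {
    dataset <- stage("simulate", {
      synth <- do.call(synthetic_config, cfg$synth %||% list())
      synth_dataset(synth)
    })
  } else manifest$stages$simulate <- "skipped (dataset supplied)"

  loss_cfg <- do.call(loss_config, cfg$loss %||% list())
  fits <- list()
  for (s in seeds) {
    fits[[as.character(s)]] <- stage(paste0("train_seed", s), {
      tcfg <- do.call(train_config, utils::modifyList(cfg$train %||% list(),
                                                      list(seed = s)))
      n_chan <- cfg$channels %||%
        dim(dataset$ground_truth$core$subunit$w)[3] %||% 16L
      ccfg <- core_config(channels = n_chan,
                          variant = cfg$variant,
                          norm_kernel = cfg$norm_kernel %||% 1L,
                          image_side = dim(dataset$images)[1])
      set.seed(s)
      model <- init_model(ccfg, n_neurons = dim(dataset$responses)[3],
                          use_bn = !isTRUE(cfg$no_bn))
      fit <- train(dataset, model, loss_cfg, tcfg,
                   freeze = cfg$freeze %||% character())
      ck <- file.path(out_dir, sprintf("checkpoint_seed%s.json", s))
      save_checkpoint(fit$model, ck)
      utils::write.csv(fit$trace,
                       file.path(out_dir, sprintf("trace_seed%s.csv", s)),
                       row.names = FALSE)
      fit
    })
  }

  metrics <- stage("evaluate", {
    idx_test <- which(dataset$split == "test")
    out <- lapply(fits, function(fit) {
      rhat <- predict_in_chunks(fit$model, dataset, idx_test)
      fv <- fev(dataset$responses[idx_test, , , drop = FALSE], rhat)
      rbar <- apply(dataset$responses[idx_test, , , drop = FALSE], c(1, 3),
                    mean, na.rm = TRUE)
      list(val_loss = fit$val_loss, val_corr = fit$val_corr,
           mean_fev = fv$mean_fev,
           test_corr = as.numeric(avg_correlation(rbar, rhat)))
    })
    jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  if (isTRUE(cfg$insilico)) {
    stage("insilico", {
      fit <- fits[[1]]
      og <- find_optimal_gabor(fit$model, gabor_grids(reduced = TRUE))
      I <- length(og$params)
      res <- lapply(seq_len(I), function(i) {
        ci <- coi_index(fit$model, i, og$params[[i]])
        st <- size_tuning(fit$model, i, og$params[[i]])
        list(unit = i, max_coi = ci$max_coi, inhibited = ci$inhibited,
             si = suppression_index(st))
      })
      jsonlite::write_json(res, file.path(out_dir, "insilico.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  if (isTRUE(cfg$analyze_norm) &&
      cfg$variant %in% c("dn", "dn_nonspecific")) {
    stage("analyze_norm", {
      fit <- fits[[1]]
      idx_val <- which(dataset$split == "val")
      M <- normalization_input_matrix(fit$model,
                                      dataset$images[, , idx_val, drop = FALSE])
      est <- estimate_orientations(fit$model$core$subunit$w)
      sp <- split_similar_dissimilar(M, est)
      bn <- bin_by_orientation_difference(M, est)
      cs <- cosine_similarity_split(M, fit$model$core$subunit$w)
      utils::write.csv(as.data.frame(unclass(M)),
                       file.path(out_dir, "norm_input_matrix.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(similar_ratio = sp$ratio, cosine_ratio = cs$ratio,
             bins = bn,
             orientations = lapply(est, function(e)
               list(magnitude = e$magnitude, theta = e$theta,
                    oriented = e$oriented))),
        file.path(out_dir, "norm_analysis.json"),
        auto_unbox = TRUE, digits = NA)
      sp$ratio
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
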