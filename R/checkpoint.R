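#' Save a model checkpoint
#'
#' Serializes the architecture configuration and every parameter array to a
#' portable JSON container (full double precision, named arrays with their
#' dimensions), so checkpoints survive round trips exactly.
#'
#' @param model a [dn_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  enc <- function(x) {
    if (is.null(x)) return(NULL)
    list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
  dn <- model$core$dn
  obj <- list(
    format = "dnv1-checkpoint-1",
    config = unclass(model$config),
    subunit = list(w = enc(model$core$subunit$w),
                   o = enc(model$core$subunit$o),
                   bn = if (!is.null(model$core$subunit$bn))
                     list(mean = enc(model$core$subunit$bn$mean),
                          var = enc(model$core$subunit$bn$var),
                          initialized = model$core$subunit$bn$initialized)),
    dn = if (!is.null(dn)) {
      if (inherits(dn, "dnv1_ext_dn_params"))
        list(n = enc(dn$n), sigma = enc(dn$sigma), cpool = enc(dn$cpool),
             dfeat = enc(dn$dfeat), dilation = dn$dilation)
      else
        list(n = enc(dn$n), sigma = enc(dn$sigma), p = enc(dn$p),
             nonspecific = dn$nonspecific)
    },
    readout = if (!is.null(model$readout))
      list(a = enc(model$readout$a), b = enc(model$readout$b),
           q = enc(model$readout$q), alpha = enc(model$readout$alpha),
           grid = list(from = model$readout$grid$points[1],
                       to = model$readout$grid$points[model$readout$grid$n],
                       by = model$readout$grid$dx)))
  # I(17): 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param expect_variant if given, loading a checkpoint of a different model
#'   variant is an error.
#' @return a [dn_model()].
#' @export
load_checkpoint <- function(path, expect_variant = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dnv1-checkpoint-1")
    stop("unrecognized checkpoint format")
  dec <- function(e) {
    if (is.null(e)) return(NULL)
    x <- as.numeric(e$data)
    if (length(e$dim) > 1) dim(x) <- as.integer(e$dim)
    x
  }
  cfgl <- obj$config
  config <- core_config(channels = cfgl$channels, kernel = cfgl$kernel,
                        pool = cfgl$pool, variant = cfgl$variant,
                        norm_kernel = cfgl$norm_kernel,
                        dilation = cfgl$dilation,
                        image_side = cfgl$image_side)
  if (!is.null(expect_variant) && config$variant != expect_variant)
    stop("checkpoint variant '", config$variant, "' does not match expected '",
         expect_variant, "'")
  bn <- NULL
  if (!is.null(obj$subunit$bn))
    bn <- list(mean = dec(obj$subunit$bn$mean), var = dec(obj$subunit$bn$var),
               initialized = isTRUE(obj$subunit$bn$initialized))
  sub <- subunit_params(dec(obj$subunit$w), dec(obj$subunit$o), bn)
  dn <- NULL
  if (!is.null(obj$dn)) {
    if (!is.null(obj$dn$p))
      dn <- dn_params(dec(obj$dn$n), dec(obj$dn$sigma), dec(obj$dn$p),
                      nonspecific = isTRUE(obj$dn$nonspecific))
    else
      dn <- ext_dn_params(dec(obj$dn$n), dec(obj$dn$sigma),
                          dec(obj$dn$cpool), dec(obj$dn$dfeat),
                          dilation = obj$dn$dilation)
  }
  ro <- NULL
  if (!is.null(obj$readout)) {
    gr <- tent_grid(obj$readout$grid$from, obj$readout$grid$to,
                    obj$readout$grid$by)
    ro <- readout_params(dec(obj$readout$a), dec(obj$readout$b),
                         dec(obj$readout$q), dec(obj$readout$alpha),
                         grid = gr)
  }
  dn_model(config, sub, dn, ro)
}
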