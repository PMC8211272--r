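#' Stimulus and model geometry
#'
#' The models operate on 40 x 40 px crops of stimuli sampled at 35 px per
#' degree of visual angle (2 degree / 140 px originals, downsampled by two),
#' so the model input spans 1.14 degrees. `geometry_config()` bundles the
#' fixed geometric constants; [px_to_deg()] and [coverage_extent()] are pure
#' functions of them.
#'
#' @param px_per_deg pixels per degree of visual angle at model resolution.
#' @param image_side side length of the model input, px.
#' @param conv_kernel side length of the first-layer convolutional filters, px.
#' @param pool side length of the denominator average-pooling window, px.
#' @param dilation dilation factor of the spatially extended normalization
#'   convolution (weights are `dilation` px apart in feature space).
#' @return A list of class `dnv1_geometry`.
#' @export
#' @examples
#' g <- geometry_config()
#' px_to_deg(40, g)                      # 1.14 degrees
#' coverage_extent("dn_pool", g, kernel_size = 3)
geometry_config <- function(px_per_deg = 35, image_side = 40, conv_kernel = 13,
                            pool = 5, dilation = 5) {
  stopifnot(px_per_deg > 0, image_side > 0, conv_kernel %% 2 == 1, pool > 0,
            dilation >= 1)
  structure(list(px_per_deg = px_per_deg, image_side = image_side,
                 conv_kernel = conv_kernel, pool = pool, dilation = dilation),
            class = "dnv1_geometry")
}

#' Convert pixel lengths to degrees of visual angle
#'
#' @param px length in pixels (vectorized).
#' @param geometry a [geometry_config()].
#' @param digits decimal places for the reported value; use `NULL` for full
#'   precision.
#' @return length in degrees of visual angle.
#' @export
px_to_deg <- function(px, geometry = geometry_config(), digits = 2) {
  stopifnot(all(px >= 0))
  deg <- px / geometry$px_per_deg
  if (!is.null(digits)) deg <- round(deg, digits) # report convention
  deg
}

#' Spatial coverage of model stages
#'
#' Computes how much of feature space and of the input image a model stage
#' integrates over. `"conv"` is the first-layer filter itself; `"pool"` is
#' the 5 px denominator average pooling applied after the convolution;
#' `"dn_pool"` is the spatially extended normalization pool: a dilated
#' `kernel_size` x `kernel_size` convolution whose taps each see one
#' `pool` x `pool` average so the pool tiles `dilation * kernel_size` px of
#' feature space. Input-space extents add the first-layer kernel
#' (`extent + conv_kernel - 1`).
#'
#' @param kind one of `"conv"`, `"pool"`, `"dn_pool"`.
#' @param geometry a [geometry_config()].
#' @param kernel_size normalization kernel side (odd), used for `"dn_pool"`.
#' @return list with `feature_px`, `input_px`, `feature_deg`, `input_deg`
#'   (degrees rounded to two decimals, matching report conventions).
#' @export
coverage_extent <- function(kind = c("conv", "pool", "dn_pool"),
                            geometry = geometry_config(), kernel_size = NULL) {
  kind <- match.arg(kind)
  ck <- geometry$conv_kernel
  feature_px <- switch(kind,
    conv = 1L,
    pool = geometry$pool,
    dn_pool = {
      if (is.null(kernel_size)) stop("kernel_size is required for dn_pool")
      if (kernel_size %% 2 == 0) stop("normalization kernel size must be odd")
      # dilated taps span dilation*(k-1)+1; each tap averages a pool window
      geometry$dilation * (kernel_size - 1L) + 1L + (geometry$pool - 1L)
    })
  if (kind == "conv") {
    feature_px <- ck
    input_px <- ck
  } else {
    input_px <- feature_px + ck - 1L
  }
  list(kind = kind,
       feature_px = feature_px,
       input_px = input_px,
       feature_deg = px_to_deg(feature_px, geometry),
       input_deg = px_to_deg(input_px, geometry))
}
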