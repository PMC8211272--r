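#' Gabor stimulus parameters
#'
#' A Gabor is specified by its center (row, col, px, 1-based pixel-center
#' coordinates with origin at the top left), size `s` (the +-2 standard
#' deviation extent of the isotropic Gaussian envelope, px), spatial
#' frequency `f` (cycles per four envelope standard deviations, i.e. per
#' `s` px), phase `psi` (radians), orientation `phi` (the carrier wave-vector
#' angle, counterclockwise from the positive row axis, radians in
#' `[0, pi)`), and amplitude `a` (contrast `c = 2 a`).
#'
#' @param center numeric length 2 (row, col).
#' @param size envelope extent, px.
#' @param freq cycles per four envelope standard deviations.
#' @param phase carrier phase, radians.
#' @param ori carrier wave-vector angle, radians.
#' @param amplitude peak amplitude in normalized intensity units.
#' @return list of class `dnv1_gabor`.
#' @export
gabor_params <- function(center = c(20, 20), size = 16, freq = 2,
                         phase = 0, ori = 0, amplitude = 1) {
  stopifnot(size > 0, freq > 0, amplitude >= 0)
  structure(list(center = center, size = size, freq = freq, phase = phase,
                 ori = ori, amplitude = amplitude), class = "dnv1_gabor")
}

#' Render a Gabor patch
#'
#' Isotropic Gaussian envelope with standard deviation `size / 4` and cosine
#' carrier `cos(2 pi (f / size) d + psi)` where `d` is the pixel's signed
#' distance from the center along the wave vector. The background is 0
#' (mean gray in normalized units); pixel values are evaluated at integer
#' pixel centers and never exceed the amplitude in magnitude.
#'
#' @param params a [gabor_params()].
#' @param side canvas side, px.
#' @return matrix `[side, side]`.
#' @export
render_gabor <- function(params, side = 40L) {
  rr <- matrix(seq_len(side), side, side) - params$center[1]
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - params$center[2]
  sd_env <- params$size / 4
  env <- exp(-(rr^2 + cc^2) / (2 * sd_env^2))
  d <- rr * cos(params$ori) + cc * sin(params$ori)
  params$amplitude * env * cos(2 * pi * (params$freq / params$size) * d +
                                 params$phase)
}

#' Render a plaid (optimal Gabor plus orthogonal mask)
#'
#' Linear superposition of the base Gabor at contrast `c_opt` with a version
#' rotated by 90 degrees at contrast `c_mask` and mask phase `mask_phase`.
#' Contrasts are in the same units as `2 * amplitude`.
#'
#' @param optimal a [gabor_params()] (its amplitude field is ignored).
#' @param c_opt,c_mask component contrasts.
#' @param mask_phase phase of the orthogonal component, radians.
#' @param side canvas side, px.
#' @return matrix `[side, side]`.
#' @export
render_plaid <- function(optimal, c_opt, c_mask, mask_phase = 0, side = 40L) {
  base <- optimal; base$amplitude <- c_opt / 2
  mask <- optimal; mask$amplitude <- c_mask / 2
  mask$ori <- optimal$ori + pi / 2
  mask$phase <- mask_phase
  render_gabor(base, side) + render_gabor(mask, side)
}

#' Render a hard-edged circular grating
#'
#' Full-contrast sinusoid with the orientation, spatial frequency, phase and
#' center of the given Gabor, sharply masked to zero (mean gray) outside a
#' circle of the given diameter; the part of the disc outside the canvas is
#' cropped.
#'
#' @param optimal a [gabor_params()] providing carrier and center.
#' @param diameter circle diameter, px.
#' @param amplitude grating amplitude (defaults to the maximum amplitude
#'   2.52 seen during training).
#' @param side canvas side, px.
#' @return matrix `[side, side]`.
#' @export
render_grating <- function(optimal, diameter, amplitude = 2.52, side = 40L) {
  if (diameter <= 0) return(matrix(0, side, side))
  rr <- matrix(seq_len(side), side, side) - optimal$center[1]
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - optimal$center[2]
  d <- rr * cos(optimal$ori) + cc * sin(optimal$ori)
  img <- amplitude * cos(2 * pi * (optimal$freq / optimal$size) * d +
                           optimal$phase)
  img[rr^2 + cc^2 > (diameter / 2)^2] <- 0
  img
}

#' Stimulus parameter grids for the optimal-Gabor search
#'
#' The full-scale grids: every pixel as center, 12 orientations, 8 phases,
#' 8 sizes `4 * 1.3895^i`, 10 frequencies `1.3^(i-1)`, 6 amplitudes
#' `0.01 * a_max * 2.51189^i` (`a_max = 2.52`). `reduced = TRUE` selects the
#' coarse grids used for desk-scale in-silico runs (5 x 5 centers, 6
#' orientations, 4 phases, 3 sizes, 3 frequencies, 2 amplitudes).
#'
#' @param side canvas side, px.
#' @param reduced use the coarse desk-scale grids.
#' @param a_max maximum amplitude.
#' @return list of grid vectors (`centers` is a 2-column matrix).
#' @export
gabor_grids <- function(side = 40L, reduced = FALSE, a_max = 2.52) {
  if (reduced) {
    cent <- seq(8L, 32L, by = 6L)
    list(centers = as.matrix(expand.grid(row = cent, col = cent)),
         orientations = pi * (0:5) / 6,
         phases = 2 * pi * (0:3) / 4,
         sizes = 4 * 1.3895^c(2, 4, 6),
         freqs = 1.3^(-1) * 1.3^c(2, 4, 6),
         amplitudes = 0.01 * a_max * 2.51189^c(3, 5))
  } else {
    cent <- seq_len(side)
    list(centers = as.matrix(expand.grid(row = cent, col = cent)),
         orientations = pi * (0:11) / 12,
         phases = 2 * pi * (0:7) / 8,
         sizes = 4 * 1.3895^(0:7),
         freqs = 1.3^(-1) * 1.3^(0:9),
         amplitudes = 0.01 * a_max * 2.51189^(0:5))
  }
}

#' Contrast grid for the cross-orientation experiment
#'
#' `{0} + 0.01 * c_max * 1.63069^i, i = 0..8`: ten contrasts topping out at
#' half the maximum contrast, so the summed plaid stays within the intensity
#' range seen during training.
#'
#' @param c_max maximum contrast (`2 * a_max`).
#' @return numeric vector of 10 contrasts including 0.
#' @export
coi_contrasts <- function(c_max = 2 * 2.52) {
  c(0, 0.01 * c_max * 1.63069^(0:8))
}

#' Diameter grid for the size-tuning experiment
#'
#' `d_i = 0.05 * d_max * 1.23859^i, i = 0..14` with `d_max = 120` px
#' (3.43 degrees): the largest grating fills the image from any center.
#'
#' @param d_max maximum diameter, px.
#' @return numeric vector of 15 diameters.
#' @export
grating_diameters <- function(d_max = 120) {
  0.05 * d_max * 1.23859^(0:14)
}
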