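#' Exhaustive optimal-Gabor search
#'
#' Renders every combination of the grid parameters, evaluates the model on
#' them in batches, and returns for each model neuron the Gabor eliciting
#' the maximum predicted response. Ties are broken by the first combination
#' in lexicographic grid order (amplitude, frequency, size, phase,
#' orientation, center — fastest first), so the search is deterministic.
#'
#' @param model a [dn_model()].
#' @param grids a [gabor_grids()] list.
#' @param batch_size stimuli per forward pass.
#' @param verbose print progress.
#' @return list with `params` (list of [gabor_params()] per neuron) and
#'   `response` (the maximal predictions).
#' @export
find_optimal_gabor <- function(model, grids = gabor_grids(reduced = TRUE),
                               batch_size = 128L, verbose = FALSE) {
  side <- model$config$image_side
  combos <- expand.grid(ai = seq_along(grids$amplitudes),
                        fi = seq_along(grids$freqs),
                        si = seq_along(grids$sizes),
                        pi = seq_along(grids$phases),
                        oi = seq_along(grids$orientations),
                        ci = seq_len(nrow(grids$centers)))
  n_total <- nrow(combos)
  I <- dim(model$readout$a)[3]
  best_resp <- rep(-Inf, I)
  best_idx <- rep(NA_integer_, I)
  for (start in seq(1L, n_total, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n_total)
    stim <- array(0, c(side, side, length(ix)))
    for (j in seq_along(ix)) {
      cb <- combos[ix[j], ]
      stim[, , j] <- render_gabor(gabor_params(
        center = as.numeric(grids$centers[cb$ci, ]),
        size = grids$sizes[cb$si], freq = grids$freqs[cb$fi],
        phase = grids$phases[cb$pi], ori = grids$orientations[cb$oi],
        amplitude = grids$amplitudes[cb$ai]), side)
    }
    rhat <- predict(model, stim)
    if (any(!is.finite(rhat))) stop("model returned non-finite predictions")
    for (i in seq_len(I)) {
      m <- which.max(rhat[, i])  # first maximum: lexicographic tie-break
      if (rhat[m, i] > best_resp[i]) {
        best_resp[i] <- rhat[m, i]
        best_idx[i] <- ix[m]
      }
    }
    if (verbose) message("searched ", max(ix), " / ", n_total)
  }
  params <- lapply(seq_len(I), function(i) {
    cb <- combos[best_idx[i], ]
    gabor_params(center = as.numeric(grids$centers[cb$ci, ]),
                 size = grids$sizes[cb$si], freq = grids$freqs[cb$fi],
                 phase = grids$phases[cb$pi], ori = grids$orientations[cb$oi],
                 amplitude = grids$amplitudes[cb$ai])
  })
  list(params = params, response = best_resp)
}

#' Cross-orientation inhibition index
#'
#' Presents plaids combining the neuron's optimal Gabor (contrast `c_j`)
#' with a 90-degree rotated mask (contrast `c_i`, phase-averaged over
#' `n_phases` mask phases) and computes
#' `COI(c_i, c_j) = 1 - rhat(c_i, c_j) / rhat(0, c_j)` for every contrast
#' combination. Entries with a zero reference response are `NA`. A unit is
#' flagged cross-orientation inhibited when its maximal COI reaches 10%.
#'
#' @param model a [dn_model()].
#' @param unit neuron index.
#' @param optimal the unit's optimal [gabor_params()].
#' @param contrasts contrast grid (shared by mask and driving component).
#' @param n_phases number of mask phases averaged over.
#' @return list of class `dnv1_coi`: `coi` matrix (mask contrast x driving
#'   contrast), `max_coi`, `inhibited`, `tuning` (phase-averaged responses).
#' @export
coi_index <- function(model, unit, optimal, contrasts = coi_contrasts(),
                      n_phases = 8L) {
  side <- model$config$image_side
  phases <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  nc <- length(contrasts)
  stim <- array(0, c(side, side, nc * nc * n_phases))
  j <- 1L
  for (ph in phases) for (cj in contrasts) for (ci in contrasts) {
    stim[, , j] <- render_plaid(optimal, c_opt = cj, c_mask = ci,
                                mask_phase = ph, side = side)
    j <- j + 1L
  }
  rhat <- predict(model, stim)[, unit]
  resp <- array(rhat, c(nc, nc, n_phases))  # [mask, driving, phase]
  tuning <- apply(resp, c(1, 2), mean)
  ref <- tuning[1, ]  # mask contrast 0 (contrasts[1] == 0)
  coi <- 1 - sweep(tuning, 2, ref, "/")
  coi[, ref == 0] <- NA
  dimnames(coi) <- list(mask = signif(contrasts, 4),
                        driving = signif(contrasts, 4))
  mc <- suppressWarnings(max(coi, na.rm = TRUE))
  structure(list(coi = coi, max_coi = if (is.finite(mc)) mc else NA_real_,
                 inhibited = is.finite(mc) && mc >= 0.10, tuning = tuning),
            class = "dnv1_coi")
}

#' Size-tuning curve
#'
#' Predicted response of one neuron to hard-edged circular gratings of
#' increasing diameter, rendered from the neuron's optimal Gabor parameters
#' at maximum contrast (single optimal phase).
#'
#' @param model a [dn_model()].
#' @param unit neuron index.
#' @param optimal the unit's optimal [gabor_params()].
#' @param diameters diameter grid, px.
#' @param amplitude grating amplitude.
#' @return data.frame with `diameter` and `response`.
#' @export
size_tuning <- function(model, unit, optimal,
                        diameters = grating_diameters(),
                        amplitude = 2.52) {
  side <- model$config$image_side
  stim <- array(0, c(side, side, length(diameters)))
  for (j in seq_along(diameters))
    stim[, , j] <- render_grating(optimal, diameters[j], amplitude, side)
  data.frame(diameter = diameters, response = predict(model, stim)[, unit])
}

#' Surround-suppression index
#'
#' `SI = 1 - r_supp / r_max`: the drop from the size-tuning curve's maximum
#' to its response at the largest (full-field) grating. Zero means no
#' suppression; `NA` if the curve never responds.
#'
#' @param curve a data.frame from [size_tuning()] (columns `diameter`,
#'   `response`).
#' @return scalar SI.
#' @export
suppression_index <- function(curve) {
  stopifnot(all(c("diameter", "response") %in% names(curve)))
  r_max <- max(curve$response)
  if (r_max <= 0) return(NA_real_)
  r_supp <- curve$response[which.max(curve$diameter)]
  1 - r_supp / r_max
}
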