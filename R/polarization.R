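#' Jones vector of an elliptical polarization state
#'
#' Builds the unit-norm Jones vector
#' \deqn{|a\rangle = (\cos\alpha\cos\epsilon - i\sin\alpha\sin\epsilon,\;
#'                   \sin\alpha\cos\epsilon + i\cos\alpha\sin\epsilon)^T}
#' from the ellipse orientation and ellipticity angles.
#'
#' @param state a [pol_state].
#' @return complex vector of length 2 with unit norm.
#' @export
make_state <- function(state) {
  stopifnot(inherits(state, "tfbg_polstate"))
  a <- state$alpha_rad; e <- state$eps_rad
  c(complex(real = cos(a) * cos(e), imaginary = -sin(a) * sin(e)),
    complex(real = sin(a) * cos(e), imaginary = cos(a) * sin(e)))
}

#' Insertion loss of a device for a given input polarization state
#'
#' Propagates the state through the wavelength-resolved Jones matrix and
#' takes the power ratio \eqn{I(\lambda) = \langle a|J^\dagger J|a\rangle /
#' \langle a|a\rangle}, returned as positive loss
#' \eqn{IL = -10\log_{10} I} in dB. The intensity is clipped below at 1e-12
#' before the logarithm.
#'
#' @param jones a [jones_spectrum].
#' @param state a [pol_state].
#' @return A [tfbg_spectrum] of insertion loss.
#' @export
insertion_loss <- function(jones, state) {
  stopifnot(inherits(jones, "tfbg_jones"))
  a <- make_state(state)
  H <- gram_components(jones$matrices)
  I <- quad_form(H, a)
  I <- pmax(I, 1e-12)
  tfbg_spectrum(jones$wavelengths_nm, -10 * log10(I),
                meta = list(alpha_deg = state$alpha_rad * 180 / pi,
                            eps_deg = state$eps_rad * 180 / pi))
}

# Per-wavelength components of the Hermitian Gram matrix H = J^dagger J:
# H11, H22 real vectors and H12 complex vector.
gram_components <- function(J) {
  list(h11 = Re(Conj(J[, 1, 1]) * J[, 1, 1] + Conj(J[, 2, 1]) * J[, 2, 1]),
       h22 = Re(Conj(J[, 1, 2]) * J[, 1, 2] + Conj(J[, 2, 2]) * J[, 2, 2]),
       h12 = Conj(J[, 1, 1]) * J[, 1, 2] + Conj(J[, 2, 1]) * J[, 2, 2])
}

# <a|H|a> for unit-ish a, vectorized over wavelength
quad_form <- function(H, a) {
  nrm <- Re(Conj(a[1]) * a[1] + Conj(a[2]) * a[2])
  (H$h11 * Mod(a[1])^2 + H$h22 * Mod(a[2])^2 +
     2 * Re(H$h12 * Conj(a[1]) * a[2])) / nrm
}

#' Find the TE input polarization state
#'
#' The TE mode of a gold-coated tilted grating does not excite the surface
#' plasmon, so among all input states it minimizes the wavelength-averaged
#' insertion loss. The search is a deterministic coarse grid over
#' (orientation, ellipticity) followed by Nelder-Mead refinement. Ties on the
#' grid (e.g. an isotropic device) are broken toward the smallest
#' orientation, then the smallest |ellipticity|, giving the canonical linear
#' horizontal state for a fully degenerate device.
#'
#' @param jones a [jones_spectrum] covering the plasmon-resonance region.
#' @param grid_deg coarse grid step in degrees (default 2).
#' @param refine_tol_deg convergence tolerance of the refinement in degrees.
#' @return A [pol_state] with attribute `mean_il_db`, the achieved objective.
#' @export
find_te_state <- function(jones, grid_deg = 2, refine_tol_deg = 1e-4) {
  stopifnot(inherits(jones, "tfbg_jones"))
  H <- gram_components(jones$matrices)
  objective <- function(par) {
    st <- pol_state(par[1], min(max(par[2], -pi / 4), pi / 4))
    I <- pmax(quad_form(H, make_state(st)), 1e-12)
    val <- mean(-10 * log10(I))
    if (!is.finite(val)) stop("non-finite insertion loss during TE search")
    val
  }
  alphas <- seq(0, pi, by = grid_deg * pi / 180)
  alphas <- alphas[alphas < pi - 1e-12]
  # ellipticity grid built outward from 0 so the linear states are sampled
  eps_half <- seq(0, pi / 4, by = grid_deg * pi / 180)
  epss <- sort(unique(c(-eps_half, eps_half)))
  grid <- expand.grid(alpha = alphas, eps = epss)
  vals <- apply(grid, 1, objective)
  if (max(vals) - min(vals) < 1e-9) {
    # degenerate (isotropic) objective: canonical tie-break, no refinement
    o <- order(grid$alpha, abs(grid$eps), grid$eps)
    best <- grid[o[1], ]
    st <- pol_state(best$alpha, best$eps)
    attr(st, "mean_il_db") <- min(vals)
    return(st)
  }
  ties <- which(vals <= min(vals) + 1e-12)
  tie <- grid[ties, , drop = FALSE]
  o <- order(tie$alpha, abs(tie$eps), tie$eps)
  best <- tie[o[1], ]
  opt <- stats::optim(c(best$alpha, best$eps), objective,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 1000))
  if (opt$value <= min(vals)) {
    par <- opt$par; val <- opt$value
  } else {
    par <- c(best$alpha, best$eps); val <- min(vals)
  }
  st <- pol_state(par[1], min(max(par[2], -pi / 4), pi / 4))
  attr(st, "mean_il_db") <- val
  st
}

#' Derive the TM state from the TE state
#'
#' Applies the orthogonality transformations alpha -> alpha + pi/2 (mod pi)
#' and eps -> -eps. The resulting Jones vector is exactly orthogonal to the
#' TE one, so the TM state maximally excites the surface plasmon.
#'
#' @param te a [pol_state].
#' @return The orthogonal [pol_state]. Applying the map twice restores the
#'   original state.
#' @export
tm_from_te <- function(te) {
  stopifnot(inherits(te, "tfbg_polstate"))
  pol_state((te$alpha_rad + pi / 2) %% pi, -te$eps_rad)
}

#' Polarization augmentation grid around a center state
#'
#' Cartesian product of orientation and ellipticity offsets around a center
#' state, used to augment a dataset with near-TM input states that still
#' show the plasmon notch. With `signed = TRUE` the magnitude set
#' `offsets_deg` is expanded to its signed version, so the default
#' \{0, 3, 6\} degrees gives the 5x5 = 25-state grid; any 7-value signed set
#' (e.g. magnitudes \{0, 2, 4, 6\}) gives 49 states.
#'
#' @param center a [pol_state] (typically the TM state).
#' @param offsets_deg numeric vector of offset magnitudes in degrees.
#' @param signed if TRUE (default), use the union of +/- offsets.
#' @return List of [pol_state]; ellipticities are clipped to \[-45, 45\] deg.
#' @export
augmentation_grid <- function(center, offsets_deg = c(0, 3, 6), signed = TRUE) {
  stopifnot(inherits(center, "tfbg_polstate"))
  if (!length(offsets_deg)) stop("offsets_deg must not be empty")
  if (any(!is.finite(offsets_deg))) stop("offsets must be finite")
  set <- if (signed) sort(unique(c(-offsets_deg, offsets_deg))) else
    sort(unique(offsets_deg))
  set_rad <- set * pi / 180
  states <- list()
  for (da in set_rad) for (de in set_rad) {
    states[[length(states) + 1]] <-
      pol_state(center$alpha_rad + da,
                min(max(center$eps_rad + de, -pi / 4), pi / 4))
  }
  states
}
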