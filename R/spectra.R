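#' Insertion-loss spectrum
#'
#' Container for a wavelength-resolved insertion-loss measurement of a fiber
#' grating device. Loss is stored in the positive-loss convention
#' (IL = -10 log10 I, so larger values mean more attenuation) on a strictly
#' increasing wavelength grid in nanometres.
#'
#' @param wavelengths_nm numeric vector, strictly increasing, in nm.
#' @param il_db numeric vector of insertion loss in dB, same length.
#' @param meta named list of free-form metadata (instrument, resolution_pm,
#'   timestamp, ...).
#' @return An object of class `tfbg_spectrum`: a list with elements
#'   `wavelengths_nm`, `il_db`, `meta`.
#' @export
tfbg_spectrum <- function(wavelengths_nm, il_db, meta = list()) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  il_db <- as.numeric(il_db)
  if (length(wavelengths_nm) != length(il_db))
    stop("wavelengths_nm and il_db must have the same length")
  if (anyNA(wavelengths_nm) || anyNA(il_db))
    stop("spectrum contains NA values")
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelengths_nm = wavelengths_nm, il_db = il_db,
                 meta = as.list(meta)),
            class = "tfbg_spectrum")
}

#' @export
print.tfbg_spectrum <- function(x, ...) {
  n <- length(x$wavelengths_nm)
  cat(sprintf("<tfbg_spectrum> %d points, %.4f-%.4f nm, IL %.2f-%.2f dB\n",
              n, min(x$wavelengths_nm), max(x$wavelengths_nm),
              min(x$il_db), max(x$il_db)))
  invisible(x)
}

#' @export
plot.tfbg_spectrum <- function(x, ...) {
  plot(x$wavelengths_nm, x$il_db, type = "l",
       xlab = "wavelength [nm]", ylab = "insertion loss [dB]", ...)
  invisible(x)
}

#' Wavelength-resolved Jones matrix spectrum
#'
#' Stores the 2x2 complex transfer matrix of the device under test at each
#' wavelength, as measured by an optical vector analyzer.
#'
#' @param wavelengths_nm strictly increasing numeric vector in nm.
#' @param matrices complex array of dimension `c(n, 2, 2)` with `n` the number
#'   of wavelengths; `matrices[k, , ]` is the Jones matrix at wavelength k.
#' @return An object of class `tfbg_jones`.
#' @export
jones_spectrum <- function(wavelengths_nm, matrices) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  matrices <- as.array(matrices)
  d <- dim(matrices)
  if (length(d) != 3 || d[2] != 2 || d[3] != 2)
    stop("matrices must have dimension c(n, 2, 2)")
  if (d[1] != length(wavelengths_nm))
    stop("one Jones matrix required per wavelength")
  storage.mode(matrices) <- "complex"
  if (any(!is.finite(Re(matrices))) || any(!is.finite(Im(matrices))))
    stop("Jones matrix entries must be finite")
  structure(list(wavelengths_nm = wavelengths_nm, matrices = matrices),
            class = "tfbg_jones")
}

#' @export
print.tfbg_jones <- function(x, ...) {
  cat(sprintf("<tfbg_jones> %d wavelengths, %.4f-%.4f nm\n",
              length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Elliptical polarization state
#'
#' A fully polarized input state described by the orientation of the major
#' axis of the polarization ellipse and its ellipticity angle.
#'
#' @param alpha_rad orientation of the major axis relative to the x-axis;
#'   reduced modulo pi (states alpha and alpha + pi are the same ellipse).
#' @param eps_rad ellipticity angle in \[-pi/4, pi/4\]; 0 is linear,
#'   +/- pi/4 circular.
#' @return An object of class `tfbg_polstate`.
#' @export
pol_state <- function(alpha_rad, eps_rad = 0) {
  alpha_rad <- as.numeric(alpha_rad)
  eps_rad <- as.numeric(eps_rad)
  if (length(alpha_rad) != 1 || length(eps_rad) != 1 ||
      !is.finite(alpha_rad) || !is.finite(eps_rad))
    stop("alpha_rad and eps_rad must be finite scalars")
  alpha_rad <- alpha_rad %% pi
  if (eps_rad < -pi / 4 - 1e-12 || eps_rad > pi / 4 + 1e-12)
    stop("eps_rad must lie in [-pi/4, pi/4]")
  eps_rad <- min(max(eps_rad, -pi / 4), pi / 4)
  structure(list(alpha_rad = alpha_rad, eps_rad = eps_rad),
            class = "tfbg_polstate")
}

#' @export
print.tfbg_polstate <- function(x, ...) {
  cat(sprintf("<tfbg_polstate> alpha = %.3f deg, eps = %.3f deg\n",
              x$alpha_rad * 180 / pi, x$eps_rad * 180 / pi))
  invisible(x)
}

#' Labeled spectrum record
#'
#' One refractometry measurement: a spectrum together with the fiber it came
#' from, the refractive index of the surrounding solution (measured at
#' 589 nm, refractometer convention) and the input polarization state index.
#'
#' @param spectrum a [tfbg_spectrum].
#' @param fiber_id integer fiber identifier.
#' @param ri_riu refractive index label in RIU, within \[1.30, 1.40\].
#' @param pol_index integer index of the input polarization state.
#' @param is_water_reference logical; TRUE for the pure-water reference
#'   record of this (fiber, polarization) pair.
#' @param pol optional [pol_state] describing the input state.
#' @return An object of class `tfbg_record`.
#' @export
labeled_spectrum <- function(spectrum, fiber_id, ri_riu, pol_index = 1L,
                             is_water_reference = FALSE, pol = NULL) {
  stopifnot(inherits(spectrum, "tfbg_spectrum"))
  if (ri_riu < 1.30 || ri_riu > 1.40)
    stop("ri_riu outside the supported range [1.30, 1.40]")
  structure(list(spectrum = spectrum, fiber_id = as.integer(fiber_id),
                 ri_riu = as.numeric(ri_riu), pol_index = as.integer(pol_index),
                 is_water_reference = isTRUE(is_water_reference), pol = pol),
            class = "tfbg_record")
}

#' Refractometry dataset
#'
#' A labeled collection of spectra spanning several fibers, refractive-index
#' solutions and input polarization states, plus a manifest recording how it
#' was produced.
#'
#' Invariants enforced: every (fiber, polarization) pair has exactly one
#' water-reference record, and RI labels within a fiber differ by at least
#' 2e-4 RIU (the discernibility limit of the index solutions).
#'
#' @param records list of [labeled_spectrum] records.
#' @param manifest named list of provenance (seed, generator configuration).
#' @return An object of class `tfbg_dataset`.
#' @export
refractometry_dataset <- function(records, manifest = list()) {
  if (!length(records)) stop("dataset has no records")
  lapply(records, function(r) stopifnot(inherits(r, "tfbg_record")))
  key <- vapply(records, function(r) paste(r$fiber_id, r$pol_index), "")
  nref <- tapply(vapply(records, function(r) r$is_water_reference, TRUE),
                 key, sum)
  if (any(nref != 1))
    stop("each (fiber, polarization) pair needs exactly one water reference; ",
         "offenders: ", paste(names(nref)[nref != 1], collapse = ", "))
  fib <- vapply(records, function(r) r$fiber_id, 1L)
  ri <- vapply(records, function(r) r$ri_riu, 1)
  for (f in unique(fib)) {
    u <- sort(unique(ri[fib == f]))
    if (length(u) > 1 && min(diff(u)) < 2e-4 - 1e-12)
      stop("RI labels within fiber ", f, " closer than 2e-4 RIU")
  }
  structure(list(records = records, manifest = manifest),
            class = "tfbg_dataset")
}

#' @export
print.tfbg_dataset <- function(x, ...) {
  fib <- vapply(x$records, function(r) r$fiber_id, 1L)
  cat(sprintf("<tfbg_dataset> %d records, %d fibers, %d RI labels\n",
              length(x$records), length(unique(fib)),
              length(unique(vapply(x$records, function(r) r$ri_riu, 1)))))
  invisible(x)
}

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation onto an equally spaced grid spanning the original
#' wavelength range. A uniform grid is required by the discrete Fourier
#' transform used in demodulation. Affine functions of wavelength are
#' preserved exactly.
#'
#' @param spectrum a [tfbg_spectrum] with at least 4 points.
#' @param n_points number of points of the output grid; defaults to the
#'   input length.
#' @return A [tfbg_spectrum] on a uniform grid (spacing constant to within
#'   one part in 1e9).
#' @export
resample_uniform <- function(spectrum, n_points = NULL) {
  stopifnot(inherits(spectrum, "tfbg_spectrum"))
  wl <- spectrum$wavelengths_nm
  if (length(wl) < 4) stop("resample_uniform needs at least 4 points")
  if (is.null(n_points)) n_points <- length(wl)
  n_points <- as.integer(n_points)
  if (n_points < 4) stop("n_points must be at least 4")
  grid <- seq(wl[1], wl[length(wl)], length.out = n_points)
  il <- stats::approx(wl, spectrum$il_db, xout = grid)$y
  out <- tfbg_spectrum(grid, il, spectrum$meta)
  out$meta$resampled <- TRUE
  out
}

# TRUE when grid spacing is constant to within 1 part in 1e9
is_uniform_grid <- function(wl) {
  if (length(wl) < 2) return(TRUE)
  d <- diff(wl)
  (max(d) - min(d)) <= 1e-9 * max(abs(d))
}
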