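#' Physical constants of the plasmonic grating sensor
#'
#' Parameters of the surface-plasmon resonance condition
#' \deqn{\lambda_{sp} = \mathrm{Re}\!\left(n_{eff}^{co} +
#'   \sqrt{\epsilon_m \epsilon_d / (\epsilon_m + \epsilon_d)}\right)
#'   \Lambda_g / \cos\theta}
#' for a gold-coated tilted fiber Bragg grating. The defaults (grating
#' period 550 nm, tilt 8 degrees, core effective index 1.4468, gold
#' permittivity -132 + 12.6i) place the resonance near 1549 nm for water
#' and give a sensitivity of about 567 nm/RIU over the calibration range.
#'
#' @param n_eff_co effective refractive index of the core mode.
#' @param eps_metal complex relative permittivity of the gold film.
#' @param grating_period_nm grating period in nm (half the phase-mask
#'   period used for inscription).
#' @param tilt_rad grating tilt angle in radians.
#' @return An object of class `tfbg_physics`.
#' @export
spr_physics <- function(n_eff_co = 1.4468,
                        eps_metal = complex(real = -132.0, imaginary = 12.6),
                        grating_period_nm = 550.0,
                        tilt_rad = 8 * pi / 180) {
  if (Re(eps_metal) >= 0)
    stop("metal permittivity must have negative real part for a plasmon")
  if (tilt_rad <= 0 || tilt_rad >= pi / 2)
    stop("tilt angle must lie in (0, pi/2)")
  structure(list(n_eff_co = n_eff_co, eps_metal = eps_metal,
                 grating_period_nm = grating_period_nm, tilt_rad = tilt_rad),
            class = "tfbg_physics")
}

#' Surface-plasmon resonance wavelength
#'
#' Evaluates the resonance condition for a dielectric of refractive index
#' `n_d` (so \eqn{\epsilon_d = n_d^2}).
#'
#' @param phys a [spr_physics].
#' @param n_d surrounding refractive index in RIU (vectorized).
#' @return Resonance wavelength(s) in nm.
#' @export
spr_wavelength <- function(phys, n_d) {
  stopifnot(inherits(phys, "tfbg_physics"))
  eps_d <- as.complex(n_d^2)
  denom <- phys$eps_metal + eps_d
  if (any(Mod(denom) < 1e-6))
    stop("pole in the plasmon dispersion: eps_metal + eps_d ~ 0")
  if (Re(phys$eps_metal) > -max(Mod(eps_d)))
    stop("no bound plasmon: need Re(eps_metal) < -eps_dielectric")
  n_spp <- sqrt(phys$eps_metal * eps_d / denom)
  Re(phys$n_eff_co + n_spp) * phys$grating_period_nm / cos(phys$tilt_rad)
}

#' Refractometric sensitivity of the resonance wavelength
#'
#' Central-difference derivative of [spr_wavelength] with respect to the
#' surrounding refractive index (step 1e-5 RIU).
#'
#' @param phys a [spr_physics].
#' @param n_d surrounding refractive index in RIU.
#' @return Sensitivity in nm/RIU.
#' @export
spr_sensitivity <- function(phys, n_d) {
  h <- 1e-5
  (spr_wavelength(phys, n_d + h) - spr_wavelength(phys, n_d - h)) / (2 * h)
}

#' Fiber-specific simulator configuration
#'
#' Describes one simulated sensor: the cladding-mode comb (a cosine in
#' loss-dB whose period sets the dominant generalized frequency, default
#' 1.2516 nm i.e. 0.799 cycles/nm), the plasmon notch geometry, the
#' birefringence axis rotation, a per-fiber jitter on the core effective
#' index, instrument noise, and the sampling grid (2.4 pm emulates a vector
#' analyzer, 50 pm a spectrum analyzer).
#'
#' @param fiber_id integer identifier.
#' @param comb_period_nm comb period in nm.
#' @param comb_depth_db peak-to-peak comb modulation in dB.
#' @param comb_phase_rad comb phase offset.
#' @param notch_span_nm full width at half maximum of the plasmon
#'   attenuation zone in nm.
#' @param notch_depth_db added loss at the notch center in dB.
#' @param notch_shape notch lineshape: `"gaussian"` (default, a peaked
#'   resonance line) or `"supergaussian"` (flat-topped degree-2 variant).
#' @param birefringence_rotation_rad rotation of the fiber eigenaxes
#'   relative to the lab frame.
#' @param n_eff_jitter additive offset applied to the core effective index
#'   for this fiber (fabrication variability).
#' @param noise_sd_db standard deviation of Gaussian measurement noise,
#'   applied in the dB domain.
#' @param resolution_pm wavelength sampling step in pm.
#' @param span_nm length-2 vector, recorded wavelength span in nm.
#' @param il_offset_db broadband background loss in dB.
#' @return An object of class `tfbg_fiber`.
#' @export
fiber_config <- function(fiber_id = 1L,
                         comb_period_nm = 1.2516,
                         comb_depth_db = 10,
                         comb_phase_rad = 0,
                         notch_span_nm = 3.0,
                         notch_depth_db = 6,
                         notch_shape = c("gaussian", "supergaussian"),
                         birefringence_rotation_rad = 0,
                         n_eff_jitter = 0,
                         noise_sd_db = 0,
                         resolution_pm = 50,
                         span_nm = c(1538, 1562),
                         il_offset_db = 8) {
  if (notch_span_nm <= 0) stop("notch_span_nm must be positive")
  n_pts <- floor(diff(span_nm) * 1000 / resolution_pm) + 1
  if (n_pts < 256)
    stop("resolution must divide the span into at least 256 points")
  structure(list(fiber_id = as.integer(fiber_id),
                 comb_period_nm = comb_period_nm,
                 comb_depth_db = comb_depth_db,
                 comb_phase_rad = comb_phase_rad,
                 notch_span_nm = notch_span_nm,
                 notch_depth_db = notch_depth_db,
                 notch_shape = match.arg(notch_shape),
                 birefringence_rotation_rad = birefringence_rotation_rad,
                 n_eff_jitter = n_eff_jitter,
                 noise_sd_db = noise_sd_db,
                 resolution_pm = resolution_pm,
                 span_nm = span_nm,
                 il_offset_db = il_offset_db),
            class = "tfbg_fiber")
}

#' Scenario configuration for a synthetic refractometry campaign
#'
#' @param n_fibers number of fibers.
#' @param ri_values RI labels in RIU; must start at 1.3332 (pure water, the
#'   reference), stay within \[1.3332, 1.3430\] and be spaced by at least
#'   2e-4 RIU. The default sweeps the full range in 40 steps, so a 12-fiber
#'   campaign yields 480 base measurements.
#' @param offsets_deg polarization augmentation offset magnitudes
#'   (see [augmentation_grid]); use `c(0)` for a single TM state.
#' @param signed_offsets expand offsets to their signed set.
#' @param seed integer master seed; all randomness derives from it.
#' @return An object of class `tfbg_scenario`.
#' @export
scenario_config <- function(n_fibers = 12,
                            ri_values = seq(1.3332, 1.3430, length.out = 40),
                            offsets_deg = c(0, 3, 6),
                            signed_offsets = TRUE,
                            seed = 1L) {
  ri_values <- as.numeric(ri_values)
  if (abs(ri_values[1] - 1.3332) > 1e-12)
    stop("the first RI value must be pure water, 1.3332 RIU")
  if (min(ri_values) < 1.3332 - 1e-12 || max(ri_values) > 1.3430 + 1e-12)
    stop("RI values must lie within [1.3332, 1.3430]")
  if (length(ri_values) > 1 && min(diff(sort(ri_values))) < 2e-4 - 1e-12)
    stop("consecutive RI values must differ by at least 2e-4 RIU")
  structure(list(n_fibers = as.integer(n_fibers), ri_values = ri_values,
                 offsets_deg = offsets_deg,
                 signed_offsets = isTRUE(signed_offsets),
                 seed = as.integer(seed)),
            class = "tfbg_scenario")
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# smooth notch profile with given FWHM, peak 1 at center. The Gaussian
# default mimics a resonance line: its single peak keeps the envelope
# minimum well localized. The flat-topped degree-2 super-Gaussian variant
# is retained for sensitivity studies; its ~1.5 nm plateau leaves the
# minimum position ill-conditioned.
notch_profile <- function(wl, center_nm, fwhm_nm,
                          shape = c("gaussian", "supergaussian")) {
  shape <- match.arg(shape)
  if (shape == "gaussian") {
    s <- fwhm_nm / (2 * sqrt(2 * log(2)))
    exp(-((wl - center_nm) / s)^2 / 2)
  } else {
    w <- (fwhm_nm / 2) / log(2)^0.25
    exp(-((wl - center_nm) / w)^4)
  }
}

#' Simulate the Jones-matrix spectrum of a gold-coated tilted grating
#'
#' Builds a diagonal transfer matrix in the fiber eigenframe. Both
#' eigenchannels carry the cladding-mode comb (a cosine in loss-dB); the TM
#' channel additionally carries the plasmon notch: extra broadband loss of
#' `notch_depth_db` and a suppression of the comb modulation amplitude, both
#' shaped by a smooth degree-2 super-Gaussian envelope of the configured
#' span centered at the resonance wavelength for the given surrounding
#' index. The matrix is rotated into the lab frame by the fiber's
#' birefringence-axis angle, and Gaussian noise of the configured standard
#' deviation is added in the dB domain of each channel.
#'
#' @param fiber a [fiber_config].
#' @param phys a [spr_physics].
#' @param n_d surrounding refractive index in RIU.
#' @param seed integer seed for the measurement noise.
#' @return A [jones_spectrum]; deterministic for fixed arguments.
#' @export
synth_jones <- function(fiber, phys = spr_physics(), n_d = 1.3332, seed = 1L) {
  stopifnot(inherits(fiber, "tfbg_fiber"), inherits(phys, "tfbg_physics"))
  phys_f <- phys
  phys_f$n_eff_co <- phys$n_eff_co + fiber$n_eff_jitter
  center <- spr_wavelength(phys_f, n_d)
  dx <- fiber$resolution_pm / 1000
  wl <- seq(fiber$span_nm[1], fiber$span_nm[2], by = dx)
  comb <- cos(2 * pi * wl / fiber$comb_period_nm + fiber$comb_phase_rad)
  g <- notch_profile(wl, center, fiber$notch_span_nm,
                     shape = fiber$notch_shape %||% "gaussian")
  il_te <- fiber$il_offset_db + (fiber$comb_depth_db / 2) * comb
  il_tm <- fiber$il_offset_db +
    (fiber$comb_depth_db / 2) * comb * (1 - 0.5 * g) +
    fiber$notch_depth_db * g
  if (fiber$noise_sd_db > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * length(wl),
                                                 sd = fiber$noise_sd_db),
                                    ncol = 2))
    il_tm <- il_tm + noise[, 1]
    il_te <- il_te + noise[, 2]
  }
  t_tm <- 10^(-il_tm / 20)
  t_te <- 10^(-il_te / 20)
  th <- fiber$birefringence_rotation_rad
  ct <- cos(th); st <- sin(th)
  # R(th) diag(t_tm, t_te) R(-th); TM along x in the eigenframe
  n <- length(wl)
  J <- array(complex(real = 0), dim = c(n, 2, 2))
  J[, 1, 1] <- ct^2 * t_tm + st^2 * t_te
  J[, 1, 2] <- ct * st * (t_tm - t_te)
  J[, 2, 1] <- ct * st * (t_tm - t_te)
  J[, 2, 2] <- st^2 * t_tm + ct^2 * t_te
  jones_spectrum(wl, J)
}

#' Generate a labeled synthetic refractometry dataset
#'
#' For each fiber, a Jones spectrum is simulated per RI solution; insertion
#' losses are then extracted for every polarization state of the
#' augmentation grid centered on that fiber's TM state (the same physical
#' measurement analyzed under many input states, as a vector analyzer
#' permits). The first RI value of each fiber is pure water and its records
#' are flagged as references. Per-fiber comb phases, effective-index
#' jitter and noise streams all derive deterministically from the scenario
#' seed.
#'
#' @param scenario a [scenario_config].
#' @param phys a [spr_physics].
#' @param fiber_template a [fiber_config] supplying per-fiber defaults
#'   (fiber_id, comb phase and index jitter are set per fiber).
#' @return A [refractometry_dataset] whose manifest records the seed and
#'   configurations.
#' @export
generate_dataset <- function(scenario, phys = spr_physics(),
                             fiber_template = fiber_config()) {
  stopifnot(inherits(scenario, "tfbg_scenario"))
  records <- list()
  for (f in seq_len(scenario$n_fibers)) {
    fib <- fiber_template
    fib$fiber_id <- as.integer(f)
    draws <- with_seed(as.numeric(scenario$seed) * 1000 + f, stats::rnorm(2))
    fib$comb_phase_rad <- (fiber_template$comb_phase_rad + draws[1] * pi) %% (2 * pi)
    fib$n_eff_jitter <- fiber_template$n_eff_jitter * draws[2]
    tm <- pol_state(fib$birefringence_rotation_rad, 0)
    states <- augmentation_grid(tm, scenario$offsets_deg,
                                signed = scenario$signed_offsets)
    for (i in seq_along(scenario$ri_values)) {
      n_d <- scenario$ri_values[i]
      jseed <- as.numeric(scenario$seed) * 100000 + f * 1000 + i
      jones <- synth_jones(fib, phys, n_d, seed = jseed)
      for (p in seq_along(states)) {
        records[[length(records) + 1]] <- labeled_spectrum(
          insertion_loss(jones, states[[p]]),
          fiber_id = f, ri_riu = n_d, pol_index = p,
          is_water_reference = (i == 1L), pol = states[[p]])
      }
    }
  }
  manifest <- list(seed = scenario$seed,
                   n_fibers = scenario$n_fibers,
                   ri_values = scenario$ri_values,
                   offsets_deg = scenario$offsets_deg,
                   signed_offsets = scenario$signed_offsets,
                   n_states = length(augmentation_grid(
                     pol_state(0, 0), scenario$offsets_deg,
                     signed = scenario$signed_offsets)),
                   physics = unclass(spr_physics_serializable(phys)),
                   fiber_template = unclass(fiber_template))
  refractometry_dataset(records, manifest)
}

spr_physics_serializable <- function(phys) {
  list(n_eff_co = phys$n_eff_co,
       eps_metal_re = Re(phys$eps_metal),
       eps_metal_im = Im(phys$eps_metal),
       grating_period_nm = phys$grating_period_nm,
       tilt_deg = phys$tilt_rad * 180 / pi)
}

#' Generate a time-ordered stack of spectra for sensorgram analysis
#'
#' Emulates a flow experiment: the surrounding RI follows a piecewise
#' constant program (one level per step) with Gaussian RI noise, an
#' optional instantaneous baseline offset applied from the first flow
#' transition onward, and an optional slow drift of the comb phase that
#' mimics cladding-mode transition artifacts. Each time point is rendered
#' through [synth_jones] and read out at the fixed TM polarization.
#'
#' @param fiber a [fiber_config] (its `noise_sd_db` sets spectral noise).
#' @param phys a [spr_physics].
#' @param steps data.frame with columns `duration_s`, `ri_riu`,
#'   `flow_noise_sd_riu` — one row per flow segment.
#' @param baseline_shift_riu RI offset added from the second segment onward
#'   (default 0).
#' @param sample_period_s time between spectra in seconds.
#' @param comb_drift_rad_per_s comb phase drift rate (default 0).
#' @param seed integer seed.
#' @return A list with elements `times_s`, `ri_true_riu`, and `spectra`
#'   (list of [tfbg_spectrum]), of class `tfbg_series`.
#' @export
generate_timeseries <- function(fiber, phys = spr_physics(), steps,
                                baseline_shift_riu = 0,
                                sample_period_s = 1,
                                comb_drift_rad_per_s = 0,
                                seed = 1L) {
  stopifnot(inherits(fiber, "tfbg_fiber"))
  steps <- as.data.frame(steps)
  if (any(steps$duration_s <= 0)) stop("step durations must be positive")
  times <- numeric(0); ri_level <- numeric(0); ri_noise_sd <- numeric(0)
  t0 <- 0
  for (s in seq_len(nrow(steps))) {
    n_s <- max(1L, floor(steps$duration_s[s] / sample_period_s))
    ts <- t0 + sample_period_s * seq_len(n_s)
    shift <- if (s > 1) baseline_shift_riu else 0
    times <- c(times, ts)
    ri_level <- c(ri_level, rep(steps$ri_riu[s] + shift, n_s))
    ri_noise_sd <- c(ri_noise_sd, rep(steps$flow_noise_sd_riu[s], n_s))
    t0 <- t0 + steps$duration_s[s]
  }
  ri_true <- ri_level + with_seed(seed, stats::rnorm(length(times))) * ri_noise_sd
  tm <- pol_state(fiber$birefringence_rotation_rad, 0)
  spectra <- vector("list", length(times))
  for (i in seq_along(times)) {
    fib_i <- fiber
    fib_i$comb_phase_rad <- fiber$comb_phase_rad +
      comb_drift_rad_per_s * times[i]
    jones <- synth_jones(fib_i, phys, ri_true[i],
                         seed = as.numeric(seed) * 10000 + i)
    spectra[[i]] <- insertion_loss(jones, tm)
  }
  structure(list(times_s = times, ri_true_riu = ri_true, spectra = spectra,
                 seed = seed),
            class = "tfbg_series")
}
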