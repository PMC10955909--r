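# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# instrument-scale noise: calibrated so the filtered-envelope wavelength
# dispersion matches the ~6 pm observed on a stabilized flow baseline
noisy_fiber <- function() fiber_config(n_eff_jitter = 2e-4, noise_sd_db = 0.035)

quiet_fiber <- function() fiber_config(n_eff_jitter = 2e-4)

# paper-scale campaigns: 12 fibers x 40 RI values (480 base measurements),
# single TM polarization state
train_scenario <- function(seed) scenario_config(offsets_deg = 0, seed = seed)

get_noiseless_model <- function() fixture("noiseless_model", function() {
  ds <- generate_dataset(train_scenario(42), fiber_template = quiet_fiber())
  tfbg_train(ds, grid_cfg = list(mu_range = c(0.4, 1.2), n_mu = 8,
                                 sigma_range = c(0.05, 0.25), n_sigma = 5),
             seed = 42)
})

get_noisy_model <- function() fixture("noisy_model", function() {
  ds <- generate_dataset(train_scenario(42), fiber_template = noisy_fiber())
  tfbg_train(ds, seed = 42)
})

# effective refractometric sensitivity of a simulated scenario (nm/RIU),
# from the resonance-condition oracle over the scenario's RI labels
scenario_sensitivity <- function(ri_values, phys = spr_physics()) {
  unname(stats::coef(stats::lm(spr_wavelength(phys, ri_values) ~ ri_values))[2])
}

# brute-force O(n^2) discrete Fourier transform, the oracle kept
# independent of stats::fft
dft_brute <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  sapply(k, function(kk) sum(x * exp(-2i * pi * kk * k / n)))
}

idft_brute <- function(X) {
  n <- length(X)
  k <- 0:(n - 1)
  sapply(k, function(kk) sum(X * exp(2i * pi * kk * k / n)) / n)
}

# analytic-signal envelope by brute-force DFT: zero negative frequencies,
# double positive ones, inverse transform, modulus
hilbert_envelope_brute <- function(x) {
  n <- length(x)
  X <- dft_brute(x - mean(x))
  k <- 0:(n - 1)
  w <- ifelse(k >= 1 & k < n / 2, 2, ifelse(k == n / 2 & n %% 2 == 0, 1, 0))
  w[1] <- 0
  Mod(idft_brute(X * w))
}

random_spectrum <- function(n = 50, seed = 1) {
  set.seed(seed)
  wl <- sort(runif(n, 1530, 1560))
  while (any(diff(wl) < 1e-6)) wl <- sort(runif(n, 1530, 1560))
  tfbg_spectrum(wl, rnorm(n, 5, 2), meta = list(instrument = "synthetic"))
}
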