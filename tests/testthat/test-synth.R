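test_that("resonance wavelength follows the plasmon dispersion", {
  phys <- spr_physics()
  # frozen value from an independent arithmetic evaluation of the
  # resonance condition with the default constants
  expect_equal(spr_wavelength(phys, 1.3334), 1549.13, tolerance = 1e-5)

  flat <- spr_physics(tilt_rad = 1e-9)
  tilted <- spr_physics(tilt_rad = 8 * pi / 180)
  expect_equal(spr_wavelength(tilted, 1.3334) / spr_wavelength(flat, 1.3334),
               1 / cos(8 * pi / 180), tolerance = 1e-9)

  # lossless-metal limit: the plasmon index tends to the dielectric index
  lossless <- spr_physics(eps_metal = complex(real = -1e8))
  lam <- spr_wavelength(lossless, 1.3334)
  expect_equal(lam, (1.4468 + 1.3334) * 550 / cos(8 * pi / 180),
               tolerance = 1e-4)

  expect_error(spr_physics(eps_metal = complex(real = 2)), "negative real")
  near_pole <- spr_physics(eps_metal = complex(real = -1.78))
  expect_error(spr_wavelength(near_pole, sqrt(1.78)), "pole")
})

test_that("sensitivity matches the analytic derivative and printed scale", {
  phys <- spr_physics()
  s <- spr_sensitivity(phys, 1.3334)
  expect_equal(s, 567, tolerance = 0.01)

  double <- spr_physics(grating_period_nm = 1100)
  expect_equal(spr_sensitivity(double, 1.3334) / s, 2, tolerance = 1e-6)

  nd <- 1.3334
  em <- phys$eps_metal; ed <- complex(real = nd^2)
  nspp <- sqrt(em * ed / (em + ed))
  analytic <- Re(nd * em^2 / (nspp * (em + ed)^2)) *
    phys$grating_period_nm / cos(phys$tilt_rad)
  expect_equal(s, analytic, tolerance = 1e-3)
})

test_that("resonance is monotone and near-linear across the RI range", {
  phys <- spr_physics()
  nds <- seq(1.3332, 1.3430, length.out = 30)
  lams <- spr_wavelength(phys, nds)
  expect_true(all(diff(lams) > 0))
  sens <- spr_sensitivity(phys, nds)
  expect_lt((max(sens) - min(sens)) / mean(sens), 0.05)
})

test_that("simulated spectra carry the comb, the notch, and the seed", {
  phys <- spr_physics()
  fib <- fiber_config()
  j1 <- synth_jones(fib, phys, 1.3381, seed = 10)
  j2 <- synth_jones(fib, phys, 1.3381, seed = 10)
  expect_identical(j1$matrices, j2$matrices)
  noisy <- fiber_config(noise_sd_db = 0.05)
  expect_false(identical(synth_jones(noisy, phys, 1.3381, seed = 1)$matrices,
                         synth_jones(noisy, phys, 1.3381, seed = 2)$matrices))

  # notch centers of two RI values differ by sensitivity * delta-n
  p <- filter_params(0.799, 0.097)
  lam_of <- function(nd) filter_envelope(
    insertion_loss(synth_jones(fib, phys, nd, seed = 1), pol_state(0, 0)),
    p)$lambda_min_nm
  dn <- 0.004
  shift <- lam_of(1.3356 + dn) - lam_of(1.3356)
  expected <- spr_sensitivity(phys, 1.3356 + dn / 2) * dn
  expect_lt(abs(shift - expected), fib$resolution_pm / 1000 / 2)
})

test_that("dominant generalized frequency equals the comb frequency", {
  fib <- fiber_config()
  il <- insertion_loss(synth_jones(fib, spr_physics(), 1.3381, seed = 1),
                       pol_state(0, 0))
  ft <- forward_transform(il)
  pos <- ft$frequencies_inv_nm > 0.05
  peak <- ft$frequencies_inv_nm[pos][which.max(Mod(ft$coefficients[pos]))]
  bin <- 1 / diff(range(il$wavelengths_nm))
  expect_lt(abs(peak - 1 / fib$comb_period_nm), bin)
})

test_that("dataset generation books references and respects the seed", {
  sc <- scenario_config(n_fibers = 1, ri_values = c(1.3332, 1.3356),
                        offsets_deg = 0, seed = 3)
  ds <- generate_dataset(sc, fiber_template = fiber_config())
  expect_length(ds$records, 2)
  expect_equal(sum(vapply(ds$records, function(r) r$is_water_reference, TRUE)),
               1L)

  sc2 <- scenario_config(n_fibers = 2, ri_values = c(1.3332, 1.3356, 1.3381),
                         offsets_deg = c(0, 3), seed = 3)
  ds2 <- generate_dataset(sc2, fiber_template = fiber_config())
  expect_length(ds2$records, 2 * 3 * 9)  # fibers x RI x 3^2 signed states

  ds2b <- generate_dataset(sc2, fiber_template = fiber_config())
  expect_identical(ds2$manifest, ds2b$manifest)
  expect_identical(ds2$records[[5]]$spectrum$il_db,
                   ds2b$records[[5]]$spectrum$il_db)

  expect_error(scenario_config(ri_values = c(1.3332, 1.33321)), "2e-4")
  expect_error(scenario_config(ri_values = c(1.3340, 1.3360)), "water")
})

test_that("manifest files are byte-identical under a fixed seed", {
  sc <- scenario_config(n_fibers = 1, ri_values = c(1.3332, 1.3356),
                        offsets_deg = 0, seed = 8)
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  write_dataset(generate_dataset(sc, fiber_template = fiber_config(noise_sd_db = 0.02)), d1)
  write_dataset(generate_dataset(sc, fiber_template = fiber_config(noise_sd_db = 0.02)), d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  rt <- read_dataset(file.path(d1, "manifest.json"))
  expect_length(rt$records, 2)
  expect_identical(rt$records[[1]]$spectrum$il_db,
                   generate_dataset(sc, fiber_template = fiber_config(noise_sd_db = 0.02))$records[[1]]$spectrum$il_db)
})

test_that("time series follow the programmed RI steps", {
  fib <- fiber_config()
  steps <- data.frame(duration_s = 10, ri_riu = 1.3381, flow_noise_sd_riu = 0)
  ser <- generate_timeseries(fib, spr_physics(), steps, seed = 2)
  expect_equal(ser$ri_true_riu, rep(1.3381, 10))
  expect_length(ser$spectra, 10)

  steps2 <- data.frame(duration_s = c(5, 5), ri_riu = c(1.3381, 1.3391),
                       flow_noise_sd_riu = 0)
  ser2 <- generate_timeseries(fib, spr_physics(), steps2,
                              baseline_shift_riu = 1.3e-5, seed = 2)
  expect_equal(unique(ser2$ri_true_riu), c(1.3381, 1.3391 + 1.3e-5))
  expect_error(generate_timeseries(fib, spr_physics(),
                                   data.frame(duration_s = -1, ri_riu = 1.34,
                                              flow_noise_sd_riu = 0)),
               "positive")
})
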