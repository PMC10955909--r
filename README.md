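# tfbgdemod

Signal processing and machine-learning calibration for **gold-coated tilted
fiber Bragg grating (Au-TFBG) surface-plasmon-resonance refractometers**.

An Au-TFBG transmits a dense comb of cladding-mode resonances; when the
input light is TM-polarized, surface-plasmon excitation carves a broad
(~3 nm) attenuation notch into that comb whose position tracks the
refractive index (RI) of the surrounding liquid at roughly
567 nm per refractive-index unit (RIU). Reading that position precisely is
hard: the notch spans many comb teeth and individual teeth appear, vanish
and hand over as the index changes. This package implements a demodulation
and calibration pipeline for such sensors, aimed at biosensing labs that
want RI sensorgrams rather than raw spectra:

* **Jones-calculus polarimetry** — build elliptical input states
  `|a> = (cos a cos e - i sin a sin e, sin a cos e + i cos a sin e)`,
  extract insertion-loss spectra `IL = -10 log10 <a|J'J|a>/<a|a>` from
  measured Jones matrices, discover the TE state (minimum mean loss),
  derive the TM state (`a -> a + pi/2`, `e -> -e`), and span augmentation
  grids of near-TM states.
* **Band-pass envelope demodulation** — Fourier transform of the loss
  spectrum in generalized frequency nu (cycles/nm), super-Gaussian
  band-pass `f(nu; mu, sigma) = exp{-((nu - mu)/(2 sigma))^4}` applied to
  the positive frequencies, inverse transform, modulus: the comb collapses
  to its local amplitude, which dips at the plasmon resonance; the minimum
  `lambda_min` is located to sub-grid precision.
* **Calibration** — pairs `(delta lambda_min, delta n)` referenced to each
  fiber's water measurement; grouped five-fold cross-validation (a fiber
  exposed to one RI is never split across train and test); `(mu, sigma)`
  chosen by grid search minimizing the mean absolute error; final
  least-squares line `N(delta lambda)` with an honest out-of-sample
  prediction interval.
* **Sensorgrams** — real-time RI traces, baseline dispersion, limit of
  detection (3x the maximum dispersion), per-segment step reports, and a
  side-by-side comparison with the classical *cross-demodulation* baseline
  (intersection of cubic fits to the notch flanks), which the band-pass
  method out-stabilizes by an order of magnitude.
* **Physics-based simulator** — spectra generated from the plasmon
  resonance condition
  `lambda_sp = Re(n_eff + sqrt(em ed / (em + ed))) * Lg / cos(theta)`,
  with a configurable comb, notch, birefringence, polarization response,
  instrument resolution (2.4 pm / 50 pm) and noise, used as the test bed
  for every claim above.

## Worked example

Simulate a small refractometry campaign, train the calibration model, and
predict an unknown sample against a water reference:

```r
library(tfbgdemod)

phys <- spr_physics()                      # resonance-condition constants
fib  <- fiber_config(n_eff_jitter = 2e-4,  # fabrication spread
                     noise_sd_db  = 0.035) # instrument amplitude noise
sc   <- scenario_config(n_fibers = 6,
                        ri_values = seq(1.3332, 1.3430, length.out = 12),
                        offsets_deg = 0, seed = 7)
ds   <- generate_dataset(sc, fiber_template = fib)
ds
#> <tfbg_dataset> 72 records, 6 fibers, 12 RI labels

model <- tfbg_train(ds, grid_cfg = list(mu_range = c(0.4, 1.2), n_mu = 9,
                                        sigma_range = c(0.05, 0.25),
                                        n_sigma = 5), seed = 7)
model
#> Refractometric calibration model for plasmonic grating spectra
#>   band-pass: mu = 0.8000 1/nm, sigma = 0.1100 1/nm
#>   N(dl) = 2.2029e-06 + 0.0017649377 * dl  [RIU, dl in nm]
#>   cv MAE = 8.56e-06 RIU, residual sd = 1.07e-05 RIU, 95% CI = +/- 2.97e-05 RIU
#>   trained on 72 pairs (hash 73ec9168, seed 7)

ref  <- insertion_loss(synth_jones(fib, phys, 1.3332, seed = 101), pol_state(0, 0))
spec <- insertion_loss(synth_jones(fib, phys, 1.3390, seed = 102), pol_state(0, 0))
pred <- predict(model, spec, ref, n_ref = 1.3332)
sprintf("n_hat = %.5f +/- %.5f RIU", pred$n_hat_riu, pred$ci95_riu)
#> "n_hat = 1.33900 +/- 0.00003 RIU"
```

The band-pass center lands on the comb's dominant generalized frequency
(1/1.2516 nm ~ 0.8 1/nm), the line's slope is the inverse of the simulated
~567 nm/RIU sensitivity, and the unknown sample is recovered within the
model's 95% interval. `plot(model)` shows the calibration line;
`plot(model, "surface")` the MAE landscape.

A thin command-line wrapper (`inst/scripts/tfbg`) exposes the same
pipeline as `tfbg simulate-dataset | find-te | demod | train | predict |
track | report`.

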