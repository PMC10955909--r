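test_that("training pairs are water-referenced and order invariant", {
  phys <- spr_physics()
  sc <- scenario_config(n_fibers = 1, ri_values = c(1.3332, 1.3381),
                        offsets_deg = 0, seed = 5)
  ds <- generate_dataset(sc, fiber_template = fiber_config())
  p <- filter_params(0.799, 0.097)
  pr <- build_pairs(ds, p)
  expect_equal(nrow(pr), 2)
  ref <- pr[pr$ri_riu == 1.3332, ]
  expect_equal(ref$delta_lambda_nm, 0)
  expect_equal(ref$delta_n_riu, 0)
  other <- pr[pr$ri_riu != 1.3332, ]
  S <- scenario_sensitivity(c(1.3332, 1.3381), phys)
  expect_equal(other$delta_lambda_nm / other$delta_n_riu, S,
               tolerance = 0.03)

  ds_rev <- ds
  ds_rev$records <- rev(ds_rev$records)
  pr2 <- build_pairs(ds_rev, p)
  o1 <- order(pr$ri_riu); o2 <- order(pr2$ri_riu)
  expect_equal(pr$delta_lambda_nm[o1], pr2$delta_lambda_nm[o2])

  # reference-only dataset maps to the anchor pair
  sc0 <- scenario_config(n_fibers = 2, ri_values = 1.3332,
                         offsets_deg = 0, seed = 5)
  pr0 <- build_pairs(generate_dataset(sc0, fiber_template = fiber_config()), p)
  expect_true(all(pr0$delta_lambda_nm == 0 & pr0$delta_n_riu == 0))
})

test_that("grouped folds never straddle a (fiber, RI) condition", {
  pairs <- data.frame(delta_lambda_nm = rnorm(40), delta_n_riu = rnorm(40),
                      fiber_id = rep(1:2, each = 20),
                      ri_riu = rep(seq(1.3332, 1.3368, by = 4e-4), 2),
                      pol_index = 1L)
  pairs$group <- paste(pairs$fiber_id, pairs$ri_riu)
  # 20 groups, 2 pairs each is the augmented layout; collapse to 10 groups
  pairs$group <- rep(paste0("g", 1:10), each = 4)
  splits <- grouped_kfold(pairs, k = 5, seed = 2)
  expect_length(splits, 5)
  tested <- integer(0)
  for (s in splits) {
    expect_length(intersect(s$train, s$test), 0)
    gr_tr <- unique(pairs$group[s$train])
    gr_te <- unique(pairs$group[s$test])
    expect_length(intersect(gr_tr, gr_te), 0)
    expect_length(gr_te, 2)  # 10 groups over 5 folds
    tested <- c(tested, s$test)
  }
  expect_setequal(tested, seq_len(nrow(pairs)))

  expect_error(grouped_kfold(pairs, k = 1), "at least 2")
  expect_error(grouped_kfold(pairs, k = 11), "at least k")
  expect_identical(grouped_kfold(pairs, k = 5, seed = 9),
                   grouped_kfold(pairs, k = 5, seed = 9))
  expect_false(identical(grouped_kfold(pairs, k = 5, seed = 9),
                         grouped_kfold(pairs, k = 5, seed = 10)))
})

test_that("least squares line matches the closed form", {
  ex <- data.frame(delta_lambda_nm = c(0, 1, 2), delta_n_riu = c(1, 3, 5))
  f <- fit_linear(ex)
  expect_equal(f$slope_riu_per_nm, 2)
  expect_equal(f$intercept_riu, 1)
  expect_equal(f$residual_sd_riu, 0, tolerance = 1e-12)

  set.seed(21)
  x <- runif(100)
  y <- 2 * x + rnorm(100, sd = 1e-6)
  f2 <- fit_linear(data.frame(delta_lambda_nm = x, delta_n_riu = y))
  expect_equal(f2$slope_riu_per_nm, 2, tolerance = 1e-5)
  # closed-form OLS oracle
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f2$slope_riu_per_nm, b_hat, tolerance = 1e-12)
  expect_lt(abs(f2$intercept_riu - (mean(y) - b_hat * mean(x))), 1e-12)

  two <- data.frame(delta_lambda_nm = c(1, 4), delta_n_riu = c(2, 11))
  f3 <- fit_linear(two)
  expect_equal(f3$slope_riu_per_nm, 3)
  expect_equal(f3$intercept_riu, -1)

  expect_error(fit_linear(data.frame(delta_lambda_nm = c(1, 1),
                                     delta_n_riu = c(1, 2))), "distinct")
})

test_that("cross-validated MAE behaves like a Gaussian error metric", {
  mk_pairs <- function(noise_sd, n_groups = 50, per_group = 4, seed = 1) {
    set.seed(seed)
    g <- rep(seq_len(n_groups), each = per_group)
    x <- rep(runif(n_groups, 0, 5), each = per_group)
    data.frame(delta_lambda_nm = x,
               delta_n_riu = 0.0017 * x + rnorm(length(x), sd = noise_sd),
               fiber_id = 1L, ri_riu = 1.34, pol_index = 1L,
               group = paste0("g", g))
  }
  exact <- mk_pairs(0)
  expect_lt(tfbgdemod:::cv_mae_pairs(exact, k = 5, seed = 3), 1e-14)

  sd_n <- 1e-5
  noisy <- mk_pairs(sd_n, n_groups = 200, per_group = 5, seed = 2)
  mae <- tfbgdemod:::cv_mae_pairs(noisy, k = 5, seed = 3)
  expect_equal(mae, sd_n * sqrt(2 / pi), tolerance = 0.1)

  shuffled <- noisy[sample(nrow(noisy)), ]
  expect_equal(tfbgdemod:::cv_mae_pairs(shuffled, k = 5, seed = 3), mae,
               tolerance = 1e-12)
  expect_gte(mae, 0)
})

test_that("hyperparameter search returns consistent optima", {
  sc <- scenario_config(n_fibers = 2, ri_values = seq(1.3332, 1.3420, length.out = 5),
                        offsets_deg = 0, seed = 6)
  ds <- generate_dataset(sc, fiber_template = fiber_config(noise_sd_db = 0.035))
  one <- optimize_hyperparams(ds, grid_cfg = list(
    mu_range = c(0.8, 0.8), sigma_range = c(0.1, 0.1), n_mu = 1, n_sigma = 1,
    refine = FALSE), k = 5, seed = 6)
  expect_equal(one$params$mu_inv_nm, 0.8)
  expect_equal(one$params$sigma_inv_nm, 0.1)
  expect_equal(one$mae_riu, cv_mae(ds, one$params, k = 5, seed = 6))

  small <- optimize_hyperparams(ds, grid_cfg = list(
    mu_range = c(0.5, 1.1), sigma_range = c(0.06, 0.16), n_mu = 5,
    n_sigma = 3, refine = FALSE), k = 5, seed = 6)
  expect_equal(min(small$mae_surface$mae, na.rm = TRUE), small$mae_riu)

  expect_error(optimize_hyperparams(ds, grid_cfg = list(
    mu_range = c(30, 40), sigma_range = c(0.01, 0.02), n_mu = 2,
    n_sigma = 2)), "feasible")
})

test_that("training is deterministic and its model round trips as JSON", {
  sc <- scenario_config(n_fibers = 3, ri_values = seq(1.3332, 1.3420, length.out = 4),
                        offsets_deg = 0, seed = 9)
  fib <- fiber_config(noise_sd_db = 0.035, n_eff_jitter = 2e-4)
  grid <- list(mu_range = c(0.6, 1.0), sigma_range = c(0.07, 0.15),
               n_mu = 4, n_sigma = 3, refine = FALSE)
  m1 <- tfbg_train(generate_dataset(sc, fiber_template = fib),
                   grid_cfg = grid, seed = 9)
  m2 <- tfbg_train(generate_dataset(sc, fiber_template = fib),
                   grid_cfg = grid, seed = 9)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model(m1, f1); write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_model(f1)
  expect_equal(back$slope_riu_per_nm, m1$slope_riu_per_nm)
  expect_equal(back$mu_hat_inv_nm, m1$mu_hat_inv_nm)
  expect_equal(back$ci95_riu, m1$ci95_riu)

  expect_equal(unname(coef(m1)["slope_riu_per_nm"]), m1$slope_riu_per_nm)
  expect_length(residuals(m1), nrow(m1$pairs))
  expect_output(print(m1), "band-pass")
  expect_output(print(summary(m1)), "sensitivity")
})

test_that("predictions invert the forward model and flag extrapolation", {
  m <- get_noiseless_model()
  phys <- spr_physics()
  fib <- quiet_fiber(); fib$n_eff_jitter <- 0
  ref <- insertion_loss(synth_jones(fib, phys, 1.3332, seed = 50),
                        pol_state(0, 0))
  pr0 <- predict(m, ref, ref, n_ref = 1.3332)
  expect_equal(pr0$delta_lambda_nm, 0)
  expect_equal(pr0$n_hat_riu, 1.3332, tolerance = 1e-5)
  expect_false(pr0$extrapolation)

  sp <- insertion_loss(synth_jones(fib, phys, 1.3406, seed = 51),
                       pol_state(0, 0))
  pr <- predict(m, sp, ref, n_ref = 1.3332)
  expect_lt(abs(pr$n_hat_riu - 1.3406), 3e-5)

  # shift beyond the training range carries the extrapolation flag
  far <- insertion_loss(synth_jones(fib, phys, 1.3470, seed = 52),
                        pol_state(0, 0))
  prf <- predict(m, far, ref, n_ref = 1.3332)
  expect_true(prf$extrapolation)

  # notch outside the search window -> edge flag and warning
  expect_warning(pre <- predict(m, sp, ref, n_ref = 1.3332,
                                window = c(1540, 1546)),
                 "edge")
  expect_true(pre$at_edge)
})

test_that("noiseless training inverts the simulated sensitivity", {
  m <- get_noiseless_model()
  S <- scenario_sensitivity(train_scenario(42)$ri_values)
  expect_lt(abs(m$slope_riu_per_nm * S - 1), 0.01)
  expect_lt(abs(m$intercept_riu), 1e-5)
})
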