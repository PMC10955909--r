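# Internal: precompute per-record FFTs once so that the hyperparameter grid
# search only pays a weighted inverse transform per (mu, sigma) evaluation.
dataset_cache <- function(dataset, window = NULL) {
  stopifnot(inherits(dataset, "tfbg_dataset"))
  recs <- dataset$records
  cache <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    sp <- recs[[i]]$spectrum
    if (!is_uniform_grid(sp$wavelengths_nm)) sp <- resample_uniform(sp)
    ft <- forward_transform(sp)
    wl <- sp$wavelengths_nm
    win <- window
    if (is.null(win)) {
      span <- wl[length(wl)] - wl[1]
      win <- c(wl[1] + 0.1 * span, wl[length(wl)] - 0.1 * span)
    }
    cache[[i]] <- list(wl = wl, freq = ft$frequencies_inv_nm,
                       coef = ft$coefficients, window = win,
                       fiber_id = recs[[i]]$fiber_id,
                       ri_riu = recs[[i]]$ri_riu,
                       pol_index = recs[[i]]$pol_index,
                       is_ref = recs[[i]]$is_water_reference)
  }
  cache
}

lambda_min_from_cache <- function(entry, params) {
  n <- length(entry$freq)
  w <- numeric(n)
  pos <- entry$freq > 0
  w[pos] <- 2 * super_gaussian(entry$freq[pos], params)
  env <- Mod(stats::fft(entry$coef * w, inverse = TRUE)) / n
  m <- find_local_min(tfbg_spectrum(entry$wl, env), entry$window)
  m$lambda_min_nm
}

#' Build (wavelength shift, RI shift) training pairs
#'
#' For every record, the envelope minimum is extracted at the given filter
#' parameters and referenced against the water measurement of the same
#' (fiber, polarization) pair: delta_lambda = lambda_min(record) -
#' lambda_min(water), delta_n = RI - RI(water). Water references themselves
#' contribute the anchor pair (0, 0).
#'
#' @param dataset a [refractometry_dataset].
#' @param params a [filter_params].
#' @param window optional minimum-search window passed to the demodulation.
#' @return A data.frame of class `tfbg_pairs` with columns
#'   `delta_lambda_nm`, `delta_n_riu`, `fiber_id`, `ri_riu`, `pol_index`,
#'   `group` (the fiber-by-RI cross-validation group).
#' @export
build_pairs <- function(dataset, params, window = NULL) {
  cache <- dataset_cache(dataset, window)
  pairs_from_cache(cache, params)
}

pairs_from_cache <- function(cache, params) {
  lam <- vapply(cache, lambda_min_from_cache, 1, params = params)
  fib <- vapply(cache, `[[`, 1L, "fiber_id")
  ri <- vapply(cache, `[[`, 1, "ri_riu")
  pol <- vapply(cache, `[[`, 1L, "pol_index")
  isref <- vapply(cache, `[[`, TRUE, "is_ref")
  key <- paste(fib, pol, sep = ":")
  ref_lam <- ref_ri <- setNames(rep(NA_real_, length(unique(key))), unique(key))
  ref_lam[key[isref]] <- lam[isref]
  ref_ri[key[isref]] <- ri[isref]
  if (anyNA(ref_lam))
    stop("missing water reference for: ",
         paste(names(ref_lam)[is.na(ref_lam)], collapse = ", "))
  out <- data.frame(delta_lambda_nm = lam - ref_lam[key],
                    delta_n_riu = ri - ref_ri[key],
                    fiber_id = fib, ri_riu = ri, pol_index = pol,
                    group = paste(fib, format(ri, digits = 10), sep = "@"),
                    stringsAsFactors = FALSE)
  class(out) <- c("tfbg_pairs", "data.frame")
  out
}

#' Grouped k-fold splits for calibration pairs
#'
#' Pairs sharing a (fiber, RI) condition — in particular all polarization
#' augmentations of one measurement — form one group. Groups are shuffled
#' and partitioned into k near-equal folds; each split tests the pairs of
#' its fold's groups and trains on all remaining pairs, so no fiber is ever
#' trained and tested under the same RI condition.
#'
#' @param pairs a `tfbg_pairs` data.frame from [build_pairs].
#' @param k number of folds (default 5; must be at least 2).
#' @param seed integer seed controlling the shuffle.
#' @return List of k splits, each a list with integer index vectors
#'   `train` and `test`.
#' @export
grouped_kfold <- function(pairs, k = 5, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  groups <- sort(unique(pairs$group))  # row-order invariant
  if (length(groups) < k)
    stop("need at least k distinct (fiber, RI) groups; have ",
         length(groups))
  perm <- with_seed(seed, sample(groups))
  fold_of <- rep(seq_len(k), length.out = length(perm))
  splits <- vector("list", k)
  for (f in seq_len(k)) {
    test_groups <- perm[fold_of == f]
    test <- which(pairs$group %in% test_groups)
    splits[[f]] <- list(train = setdiff(seq_len(nrow(pairs)), test),
                        test = test)
  }
  splits
}

#' Ordinary least-squares line through the calibration pairs
#'
#' Regresses the RI shift on the wavelength shift. The intercept is
#' retained as a diagnostic; with water-referenced pairs it is expected to
#' be ~0.
#'
#' @param pairs a `tfbg_pairs` data.frame (or any data.frame with columns
#'   `delta_lambda_nm`, `delta_n_riu`).
#' @return List with `slope_riu_per_nm`, `intercept_riu`,
#'   `residual_sd_riu` and the `lm` fit.
#' @export
fit_linear <- function(pairs) {
  if (nrow(pairs) < 2 || length(unique(pairs$delta_lambda_nm)) < 2)
    stop("need at least 2 distinct wavelength shifts to fit a line")
  fit <- stats::lm(delta_n_riu ~ delta_lambda_nm, data = pairs)
  res <- stats::residuals(fit)
  rsd <- if (length(res) > 2) sqrt(sum(res^2) / (length(res) - 2)) else 0
  list(slope_riu_per_nm = unname(stats::coef(fit)[2]),
       intercept_riu = unname(stats::coef(fit)[1]),
       residual_sd_riu = rsd, fit = fit)
}

mae_of_split <- function(pairs, split) {
  fit <- fit_linear(pairs[split$train, , drop = FALSE])
  test <- pairs[split$test, , drop = FALSE]
  pred <- fit$intercept_riu + fit$slope_riu_per_nm * test$delta_lambda_nm
  mean(abs(pred - test$delta_n_riu))
}

cv_mae_pairs <- function(pairs, k = 5, seed = 1L) {
  splits <- grouped_kfold(pairs, k = k, seed = seed)
  mean(vapply(splits, mae_of_split, 1, pairs = pairs))
}

#' Cross-validated mean absolute error at given filter parameters
#'
#' Builds pairs at the given (mu, sigma), runs grouped k-fold
#' cross-validation, fits the linear model on each training split and
#' averages the mean absolute prediction error (in RIU) over the k test
#' folds.
#'
#' @param dataset a [refractometry_dataset].
#' @param params a [filter_params].
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @param window optional demodulation search window.
#' @return Mean MAE in RIU.
#' @export
cv_mae <- function(dataset, params, k = 5, seed = 1L, window = NULL) {
  cv_mae_pairs(build_pairs(dataset, params, window), k = k, seed = seed)
}

#' Optimize the band-pass filter hyperparameters
#'
#' Coarse grid search over (mu, sigma) minimizing the cross-validated MAE,
#' followed by one refinement pass at five-fold density spanning one coarse
#' step around the incumbent. Grid points violating the band constraints
#' (DC leakage, beyond Nyquist) are skipped; the search fails only if no
#' point is feasible. The full MAE surface is returned for inspection.
#'
#' @param dataset a [refractometry_dataset].
#' @param grid_cfg list with `mu_range`, `sigma_range`, `n_mu`, `n_sigma`,
#'   `refine` (logical); defaults mu in \\[0.2, 1.5\\] x sigma in \\[0.02, 0.3\\]
#'   1/nm on a 20 x 20 grid with refinement.
#' @param k folds for the inner cross-validation.
#' @param seed integer seed (same folds reused at every grid point).
#' @param window optional demodulation search window.
#' @return List with `params` (the arg-min [filter_params]) and
#'   `mae_surface` (data.frame `mu`, `sigma`, `mae`, `stage`).
#' @export
optimize_hyperparams <- function(dataset, grid_cfg = list(), k = 5, seed = 1L,
                                 window = NULL) {
  cfg <- utils::modifyList(list(mu_range = c(0.2, 1.5),
                                sigma_range = c(0.02, 0.3),
                                n_mu = 20, n_sigma = 20, refine = TRUE),
                           grid_cfg)
  cache <- dataset_cache(dataset, window)
  nyq <- max(cache[[1]]$freq)
  eval_grid <- function(mus, sigmas, stage) {
    g <- expand.grid(mu = mus, sigma = sigmas)
    g$mae <- NA_real_
    for (i in seq_len(nrow(g))) {
      if (g$mu[i] <= 0 || g$sigma[i] <= 0 ||
          g$mu[i] - 2 * g$sigma[i] <= 0 ||
          g$mu[i] - 2 * g$sigma[i] >= nyq) next
      p <- filter_params(g$mu[i], g$sigma[i])
      g$mae[i] <- tryCatch(
        cv_mae_pairs(pairs_from_cache(cache, p), k = k, seed = seed),
        error = function(e) NA_real_)
    }
    g$stage <- stage
    g
  }
  mus <- seq(cfg$mu_range[1], cfg$mu_range[2], length.out = cfg$n_mu)
  sigmas <- seq(cfg$sigma_range[1], cfg$sigma_range[2],
                length.out = cfg$n_sigma)
  surf <- eval_grid(mus, sigmas, "coarse")
  if (all(is.na(surf$mae)))
    stop("no feasible (mu, sigma) grid point within (0, Nyquist)")
  best <- surf[which.min(surf$mae), ]
  if (isTRUE(cfg$refine) && (cfg$n_mu > 1 || cfg$n_sigma > 1)) {
    h_mu <- if (cfg$n_mu > 1) diff(cfg$mu_range) / (cfg$n_mu - 1) else 0
    h_sg <- if (cfg$n_sigma > 1) diff(cfg$sigma_range) / (cfg$n_sigma - 1) else 0
    mus_f <- if (h_mu > 0) seq(best$mu - h_mu, best$mu + h_mu,
                               by = h_mu / 5) else best$mu
    sig_f <- if (h_sg > 0) seq(best$sigma - h_sg, best$sigma + h_sg,
                               by = h_sg / 5) else best$sigma
    surf_f <- eval_grid(mus_f, sig_f, "refine")
    surf <- rbind(surf, surf_f)
    if (!all(is.na(surf_f$mae))) {
      best_f <- surf_f[which.min(surf_f$mae), ]
      if (!is.na(best_f$mae) && best_f$mae <= best$mae) best <- best_f
    }
  }
  list(params = filter_params(best$mu, best$sigma),
       mae_surface = surf, mae_riu = best$mae)
}

# polynomial rolling hash of a serialized R object (provenance fingerprint)
fingerprint_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Train the refractometric calibration model
#'
#' The package's central fitting function. Runs the hyperparameter
#' optimization ([optimize_hyperparams]) on the labeled dataset, then fits
#' the final least-squares line delta_n = N(delta_lambda) on all pairs at
#' the optimal (mu, sigma). The returned model carries the filter, the
#' line, a prediction standard deviation (root-mean-square of the held-out
#' grouped-CV errors at the selected filter, which unlike the in-sample
#' residual sd also reflects line-fit sampling error) with a 95%
#' prediction interval half-width of that sd times a t quantile whose
#' degrees of freedom equal the fiber count minus two (each fiber's shared
#' water reference makes it a single effective replicate), the
#' cross-validated MAE, and
#' provenance (manifest hash, seed), and supports `print`, `summary`,
#' `coef`, `predict`, `residuals` and `plot`.
#'
#' @param dataset a [refractometry_dataset].
#' @param grid_cfg hyperparameter grid configuration, see
#'   [optimize_hyperparams].
#' @param k cross-validation folds.
#' @param seed integer seed.
#' @param window optional demodulation search window.
#' @return An object of class `tfbg_model`.
#' @export
tfbg_train <- function(dataset, grid_cfg = list(), k = 5, seed = 1L,
                       window = NULL) {
  opt <- optimize_hyperparams(dataset, grid_cfg, k = k, seed = seed,
                              window = window)
  pairs <- build_pairs(dataset, opt$params, window)
  line <- fit_linear(pairs)
  # prediction spread from held-out grouped-CV errors at the selected
  # filter: unlike the in-sample residual sd, this includes the line-fit
  # sampling error and the per-fiber reference-noise clustering a future
  # single-spectrum prediction actually faces.
  splits <- grouped_kfold(pairs, k = k, seed = seed)
  cv_err <- unlist(lapply(splits, function(s) {
    f <- fit_linear(pairs[s$train, , drop = FALSE])
    te <- pairs[s$test, , drop = FALSE]
    f$intercept_riu + f$slope_riu_per_nm * te$delta_lambda_nm - te$delta_n_riu
  }))
  pred_sd <- sqrt(mean(cv_err^2))
  # reference-noise clustering makes one fiber one effective replicate, so
  # the interval quantile uses t with (n_fibers - 2) df, not the normal 1.96
  df_eff <- max(length(unique(pairs$fiber_id)) - 2, 1)
  q95 <- stats::qt(0.975, df_eff)
  structure(list(
    mu_hat_inv_nm = opt$params$mu_inv_nm,
    sigma_hat_inv_nm = opt$params$sigma_inv_nm,
    slope_riu_per_nm = line$slope_riu_per_nm,
    intercept_riu = line$intercept_riu,
    residual_sd_riu = pred_sd,
    insample_sd_riu = line$residual_sd_riu,
    ci95_riu = q95 * pred_sd,
    mae_riu = opt$mae_riu,
    pairs = pairs,
    mae_surface = opt$mae_surface,
    delta_lambda_range_nm = range(pairs$delta_lambda_nm),
    window = window,
    dataset_hash = fingerprint_hash(dataset$manifest),
    seed = as.integer(seed),
    k = as.integer(k),
    version = as.character(utils::packageVersion("tfbgdemod"))),
    class = "tfbg_model")
}

#' @export
print.tfbg_model <- function(x, ...) {
  cat("Refractometric calibration model for plasmonic grating spectra\n")
  cat(sprintf("  band-pass: mu = %.4f 1/nm, sigma = %.4f 1/nm\n",
              x$mu_hat_inv_nm, x$sigma_hat_inv_nm))
  cat(sprintf("  N(dl) = %.6g + %.8g * dl  [RIU, dl in nm]\n",
              x$intercept_riu, x$slope_riu_per_nm))
  cat(sprintf("  cv MAE = %.3g RIU, residual sd = %.3g RIU, 95%% CI = +/- %.3g RIU\n",
              x$mae_riu, x$residual_sd_riu, x$ci95_riu))
  if (!is.null(x$pairs))
    cat(sprintf("  trained on %d pairs (hash %s, seed %d)\n",
                nrow(x$pairs), x$dataset_hash, x$seed))
  invisible(x)
}

#' @export
summary.tfbg_model <- function(object, ...) {
  res <- residuals(object)
  structure(list(model = object,
                 n_pairs = nrow(object$pairs),
                 n_fibers = length(unique(object$pairs$fiber_id)),
                 resid_quartiles = stats::quantile(res),
                 sensitivity_nm_per_riu = 1 / object$slope_riu_per_nm),
            class = "summary.tfbg_model")
}

#' @export
print.summary.tfbg_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d pairs from %d fibers; implied sensitivity %.1f nm/RIU\n",
              x$n_pairs, x$n_fibers, x$sensitivity_nm_per_riu))
  cat("  residual quartiles (RIU):\n")
  print(signif(x$resid_quartiles, 3))
  invisible(x)
}

#' @export
coef.tfbg_model <- function(object, ...) {
  c(intercept_riu = object$intercept_riu,
    slope_riu_per_nm = object$slope_riu_per_nm)
}

#' @export
residuals.tfbg_model <- function(object, ...) {
  p <- object$pairs
  p$delta_n_riu - (object$intercept_riu +
                     object$slope_riu_per_nm * p$delta_lambda_nm)
}

#' @export
plot.tfbg_model <- function(x, which = c("calibration", "surface"), ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    plot(x$pairs$delta_lambda_nm, x$pairs$delta_n_riu,
         xlab = expression(delta * lambda[min] ~ "[nm]"),
         ylab = expression(delta * n ~ "[RIU]"), ...)
    graphics::abline(x$intercept_riu, x$slope_riu_per_nm, col = 2)
  } else {
    s <- x$mae_surface[x$mae_surface$stage == "coarse", ]
    mus <- sort(unique(s$mu)); sigmas <- sort(unique(s$sigma))
    z <- matrix(s$mae[order(s$sigma, s$mu)], nrow = length(mus))
    graphics::image(mus, sigmas, z, xlab = "mu [1/nm]",
                    ylab = "sigma [1/nm]", ...)
    graphics::points(x$mu_hat_inv_nm, x$sigma_hat_inv_nm, pch = 4)
  }
  invisible(x)
}

#' Predict the surrounding refractive index from a spectrum
#'
#' Demodulates the spectrum and a reference spectrum at the model's
#' optimized filter, forms the wavelength shift, and maps it through the
#' calibration line: n_hat = n_ref + N(delta_lambda).
#'
#' @param object a model from [tfbg_train].
#' @param spectrum a [tfbg_spectrum] to predict from.
#' @param reference_spectrum the water/buffer reference [tfbg_spectrum].
#' @param n_ref refractive index of the reference medium (RIU).
#' @param window optional minimum-search window.
#' @param ... unused.
#' @return List with `n_hat_riu`, `ci95_riu`, `delta_lambda_nm`, and flags
#'   `extrapolation` (shift beyond the training range) and `at_edge`
#'   (either minimum hit the search window boundary; a warning is also
#'   raised).
#' @export
predict.tfbg_model <- function(object, spectrum, reference_spectrum,
                               n_ref = 1.3332, window = NULL, ...) {
  params <- filter_params(object$mu_hat_inv_nm, object$sigma_hat_inv_nm)
  if (is.null(window)) window <- object$window
  e1 <- filter_envelope(spectrum, params, window)
  e0 <- filter_envelope(reference_spectrum, params, window)
  at_edge <- e1$at_edge || e0$at_edge
  if (at_edge)
    warning("envelope minimum at the search-window edge; prediction unreliable")
  dl <- e1$lambda_min_nm - e0$lambda_min_nm
  rng <- object$delta_lambda_range_nm
  extrap <- dl < rng[1] || dl > rng[2]
  list(n_hat_riu = n_ref + object$intercept_riu +
         object$slope_riu_per_nm * dl,
       ci95_riu = object$ci95_riu,
       delta_lambda_nm = dl,
       extrapolation = extrap,
       at_edge = at_edge)
}

#' Persist a calibration model as JSON
#'
#' @param model a model from [tfbg_train].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tfbg_model"))
  keep <- c("mu_hat_inv_nm", "sigma_hat_inv_nm", "slope_riu_per_nm",
            "intercept_riu", "residual_sd_riu", "insample_sd_riu",
            "ci95_riu", "mae_riu",
            "delta_lambda_range_nm", "dataset_hash", "seed", "k", "version")
  jsonlite::write_json(unclass(model)[keep], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a calibration model written by [write_model]
#'
#' @param path JSON path.
#' @return A model object (without the training pairs and MAE surface).
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$delta_lambda_range_nm <- as.numeric(m$delta_lambda_range_nm)
  m$window <- NULL
  m$pairs <- NULL
  structure(m, class = "tfbg_model")
}
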