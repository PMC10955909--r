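#' Band-pass filter parameters in generalized frequency
#'
#' Center and width of the super-Gaussian band-pass used by the envelope
#' demodulation, in cycles per nm (the Fourier conjugate of wavelength).
#' The band must exclude DC: mu - 2 sigma > 0.
#'
#' @param mu_inv_nm filter center in 1/nm.
#' @param sigma_inv_nm filter width in 1/nm.
#' @return An object of class `tfbg_filter`.
#' @export
filter_params <- function(mu_inv_nm, sigma_inv_nm) {
  if (mu_inv_nm <= 0 || sigma_inv_nm <= 0)
    stop("mu and sigma must be positive")
  if (mu_inv_nm - 2 * sigma_inv_nm <= 0)
    stop("band must exclude DC: require mu - 2*sigma > 0")
  structure(list(mu_inv_nm = mu_inv_nm, sigma_inv_nm = sigma_inv_nm),
            class = "tfbg_filter")
}

#' Super-Gaussian band-pass weight
#'
#' The degree-4 exponent super-Gaussian
#' \deqn{f(\nu; \mu, \sigma) = \exp\{-((\nu - \mu)/(2\sigma))^4\},}
#' flatter-topped than a Gaussian; equals 1 at the center and 1/e at
#' \eqn{\nu = \mu \pm 2\sigma}.
#'
#' @param nu generalized frequency in 1/nm (vectorized).
#' @param params a [filter_params].
#' @return Weights in (0, 1].
#' @export
super_gaussian <- function(nu, params) {
  stopifnot(inherits(params, "tfbg_filter"))
  exp(-((nu - params$mu_inv_nm) / (2 * params$sigma_inv_nm))^4)
}

#' Discrete Fourier transform of a spectrum
#'
#' Transforms the mean-subtracted insertion loss to the generalized
#' frequency domain. The frequency axis is in cycles per nm; coefficients
#' follow the standard DFT layout (non-negative frequencies first, then
#' negative).
#'
#' @param spectrum a [tfbg_spectrum] on a uniform grid (non-uniform input
#'   is resampled via [resample_uniform]).
#' @return List with `frequencies_inv_nm` and complex `coefficients`.
#' @export
forward_transform <- function(spectrum) {
  stopifnot(inherits(spectrum, "tfbg_spectrum"))
  if (!is_uniform_grid(spectrum$wavelengths_nm))
    spectrum <- resample_uniform(spectrum)
  if (!is_uniform_grid(spectrum$wavelengths_nm))
    stop("grid not uniform after resampling")
  x <- spectrum$il_db - mean(spectrum$il_db)
  n <- length(x)
  dx <- (spectrum$wavelengths_nm[n] - spectrum$wavelengths_nm[1]) / (n - 1)
  k <- seq_len(n) - 1
  freq <- ifelse(k <= n %/% 2, k, k - n) / (n * dx)
  list(frequencies_inv_nm = freq, coefficients = stats::fft(x))
}

#' Band-pass envelope of an insertion-loss spectrum
#'
#' The core demodulation step: Fourier transform of the mean-subtracted
#' loss, super-Gaussian weighting of the positive frequencies only
#' (negative frequencies and DC are zeroed, amplitudes doubled, so the
#' result is the analytic-signal envelope of the band), inverse transform,
#' and complex modulus. The plasmon notch suppresses the cladding-mode comb
#' locally, so the envelope exhibits a local minimum at the resonance
#' wavelength, which is located to sub-grid precision.
#'
#' @param spectrum a [tfbg_spectrum].
#' @param params a [filter_params].
#' @param window length-2 wavelength window searched for the minimum;
#'   default the central 80% of the span.
#' @return An object of class `tfbg_envelope`: list with `envelope` (a
#'   [tfbg_spectrum] in linear amplitude units), `lambda_min_nm`,
#'   `window_used`, and logical `at_edge` flagging an unreliable minimum on
#'   the window boundary.
#' @export
filter_envelope <- function(spectrum, params, window = NULL) {
  stopifnot(inherits(spectrum, "tfbg_spectrum"), inherits(params, "tfbg_filter"))
  ft <- forward_transform(spectrum)
  freq <- ft$frequencies_inv_nm
  n <- length(freq)
  nyq <- max(freq)
  if (params$mu_inv_nm - 2 * params$sigma_inv_nm >= nyq)
    stop("filter band lies entirely beyond the Nyquist frequency (",
         signif(nyq, 4), " 1/nm)")
  w <- numeric(n)
  pos <- freq > 0
  w[pos] <- 2 * super_gaussian(freq[pos], params)
  env <- Mod(stats::fft(ft$coefficients * w, inverse = TRUE)) / n
  if (!is_uniform_grid(spectrum$wavelengths_nm))
    spectrum <- resample_uniform(spectrum)
  wl <- spectrum$wavelengths_nm
  if (is.null(window)) {
    span <- wl[length(wl)] - wl[1]
    window <- c(wl[1] + 0.1 * span, wl[length(wl)] - 0.1 * span)
  }
  env_spec <- tfbg_spectrum(wl, env,
                            meta = list(mu_inv_nm = params$mu_inv_nm,
                                        sigma_inv_nm = params$sigma_inv_nm))
  m <- find_local_min(env_spec, window)
  structure(list(envelope = env_spec, lambda_min_nm = m$lambda_min_nm,
                 window_used = window, at_edge = m$at_edge),
            class = "tfbg_envelope")
}

#' @export
print.tfbg_envelope <- function(x, ...) {
  cat(sprintf("<tfbg_envelope> lambda_min = %.4f nm (window %.2f-%.2f%s)\n",
              x$lambda_min_nm, x$window_used[1], x$window_used[2],
              if (x$at_edge) ", AT EDGE" else ""))
  invisible(x)
}

#' Locate the minimum of an envelope within a window
#'
#' Finds the global minimum of the sampled envelope inside the window and
#' refines it by quadratic interpolation through the three points around
#' the discrete minimum, giving sub-grid precision. Ties break toward the
#' lower wavelength. A minimum on the window boundary cannot be refined and
#' is flagged as unreliable.
#'
#' @param envelope a [tfbg_spectrum] (envelope values in `il_db` slot).
#' @param window length-2 numeric wavelength window, inside the span.
#' @return List with `lambda_min_nm` and logical `at_edge`.
#' @export
find_local_min <- function(envelope, window) {
  stopifnot(inherits(envelope, "tfbg_spectrum"))
  wl <- envelope$wavelengths_nm
  y <- envelope$il_db
  if (window[1] < wl[1] - 1e-9 || window[2] > wl[length(wl)] + 1e-9)
    stop("window must lie inside the spectrum span")
  idx <- which(wl >= window[1] & wl <= window[2])
  if (length(idx) < 3) stop("window must contain at least 3 points")
  j <- idx[which.min(y[idx])]
  at_edge <- (j == idx[1] || j == idx[length(idx)])
  if (at_edge) return(list(lambda_min_nm = wl[j], at_edge = TRUE))
  y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
  denom <- y0 - 2 * y1 + y2
  offset <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y0 - y2) / denom
  offset <- min(max(offset, -0.5), 0.5)
  dx_l <- wl[j] - wl[j - 1]; dx_r <- wl[j + 1] - wl[j]
  lam <- wl[j] + offset * (if (offset >= 0) dx_r else dx_l)
  list(lambda_min_nm = lam, at_edge = FALSE)
}

#' Cross-demodulation baseline: intersection of flank interpolations
#'
#' The conventional demodulation of the plasmon notch. The lower envelope
#' of the spectral comb — the loss local minima, each refined to sub-grid
#' precision by a parabola through its three surrounding samples — bulges
#' upward across the attenuation zone. Its center is estimated as the
#' centroid of the envelope's excess over its lower quartile; the envelope
#' points within `flank_span_nm` on each side of that center form the two
#' flanks, a cubic polynomial is least-squares fitted to each, and the
#' resonance position is the intersection of the two cubics (the real root
#' of their difference nearest the centroid).
#'
#' @param spectrum a [tfbg_spectrum] (raw insertion loss in dB).
#' @param notch_window length-2 wavelength window containing the
#'   attenuation zone (make it several comb periods wider than the zone so
#'   each flank holds at least 4 comb extrema).
#' @param flank_span_nm how far from the estimated center each flank
#'   extends (default 7 nm).
#' @return Intersection wavelength in nm. Fails with an error of class
#'   `tfbg_cross_error` when the notch is too ambiguous to intersect.
#' @export
cross_demodulation <- function(spectrum, notch_window, flank_span_nm = 7) {
  stopifnot(inherits(spectrum, "tfbg_spectrum"))
  wl <- spectrum$wavelengths_nm; y <- spectrum$il_db
  sel <- which(wl >= notch_window[1] & wl <= notch_window[2])
  if (length(sel) < 9) cross_fail("window too small for cross-demodulation")
  wl <- wl[sel]; y <- y[sel]
  n <- length(y)
  i <- 2:(n - 1)
  mins <- i[y[i] <= y[i - 1] & y[i] <= y[i + 1] &
              (y[i] < y[i - 1] | y[i] < y[i + 1])]
  if (length(mins) < 8)
    cross_fail("too few comb minima in window (flat or featureless spectrum)")
  lam_m <- val_m <- numeric(length(mins))
  for (k in seq_along(mins)) {
    j <- mins[k]
    y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
    off <- min(max(off, -0.5), 0.5)
    lam_m[k] <- wl[j] + off * (wl[min(j + 1, n)] - wl[j])
    val_m[k] <- y1 - 0.25 * (y0 - y2) * off
  }
  if (max(val_m) - min(val_m) < 0.05)
    cross_fail("no discernible notch in the comb lower envelope")
  excess <- pmax(val_m - stats::quantile(val_m, 0.25), 0)
  if (sum(excess) <= 0) cross_fail("degenerate lower envelope")
  c0 <- sum(lam_m * excess) / sum(excess)
  left <- which(lam_m >= c0 - flank_span_nm & lam_m < c0)
  right <- which(lam_m > c0 & lam_m <= c0 + flank_span_nm)
  if (length(left) < 4 || length(right) < 4)
    cross_fail("not enough flank points on both sides of the notch")
  cl <- cubic_fit(lam_m[left] - c0, val_m[left])
  cr <- cubic_fit(lam_m[right] - c0, val_m[right])
  roots <- polyroot(cl - cr)
  real <- Re(roots[abs(Im(roots)) < 1e-6 * (1 + abs(Re(roots)))]) + c0
  real <- real[real >= notch_window[1] & real <= notch_window[2]]
  if (!length(real))
    cross_fail("flank interpolations do not intersect inside the window")
  real[which.min(abs(real - c0))]
}

# least-squares cubic; returns coefficients c0..c3 (ascending powers)
cubic_fit <- function(x, y) {
  X <- cbind(1, x, x^2, x^3)
  as.numeric(qr.solve(X, y, tol = 1e-12))
}

cross_fail <- function(msg) {
  stop(structure(class = c("tfbg_cross_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
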