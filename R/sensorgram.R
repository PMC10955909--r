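#' Track refractive index through a time-ordered series of spectra
#'
#' Applies the calibration model frame by frame. After the first frame the
#' minimum-search window is re-centered on the previous envelope minimum
#' (+/- `track_halfwidth_nm`), so the tracker follows the notch as it
#' drifts. A run of edge-flagged frames longer than `max_flag_streak`
#' aborts with a tracking-lost error.
#'
#' @param model a model from [tfbg_train].
#' @param series a `tfbg_series` from [generate_timeseries], or a list with
#'   `times_s` and `spectra`.
#' @param reference the reference [tfbg_spectrum] (fiber in water/buffer).
#' @param n_ref refractive index of the reference medium in RIU.
#' @param track_halfwidth_nm half-width of the tracking window (default 2).
#' @param max_flag_streak consecutive edge-flagged frames tolerated.
#' @return A data.frame of class `tfbg_trace` with columns `time_s`,
#'   `n_hat_riu`, `lambda_min_nm`, `flag` and attribute `method`
#'   (`"filtered"`).
#' @export
track <- function(model, series, reference, n_ref = 1.3332,
                  track_halfwidth_nm = 2, max_flag_streak = 5) {
  stopifnot(inherits(model, "tfbg_model"))
  params <- filter_params(model$mu_hat_inv_nm, model$sigma_hat_inv_nm)
  ref_env <- filter_envelope(reference, params, model$window)
  if (ref_env$at_edge) stop("reference envelope minimum is at the window edge")
  times <- series$times_s
  spectra <- series$spectra
  n <- length(spectra)
  n_hat <- lam <- numeric(n)
  flag <- logical(n)
  prev <- NULL
  streak <- 0
  for (i in seq_len(n)) {
    win <- if (is.null(prev)) model$window else
      c(prev - track_halfwidth_nm, prev + track_halfwidth_nm)
    if (!is.null(win)) {
      wl <- spectra[[i]]$wavelengths_nm
      win <- c(max(win[1], wl[1]), min(win[2], wl[length(wl)]))
    }
    e <- filter_envelope(spectra[[i]], params, win)
    lam[i] <- e$lambda_min_nm
    flag[i] <- e$at_edge
    streak <- if (e$at_edge) streak + 1 else 0
    if (streak > max_flag_streak)
      stop("tracking lost: ", streak, " consecutive edge-flagged frames")
    dl <- e$lambda_min_nm - ref_env$lambda_min_nm
    n_hat[i] <- n_ref + model$intercept_riu + model$slope_riu_per_nm * dl
    if (!e$at_edge) prev <- e$lambda_min_nm
  }
  out <- data.frame(time_s = times, n_hat_riu = n_hat, lambda_min_nm = lam,
                    flag = flag)
  class(out) <- c("tfbg_trace", "data.frame")
  attr(out, "method") <- "filtered"
  out
}

#' @export
plot.tfbg_trace <- function(x, ...) {
  plot(x$time_s, x$n_hat_riu, type = "l", xlab = "time [s]",
       ylab = expression(hat(n) ~ "[RIU]"), ...)
  invisible(x)
}

#' Baseline dispersion of a refractive-index trace
#'
#' Sample standard deviation of the predicted RI within a time window —
#' the noise floor of the sensorgram.
#'
#' @param trace a `tfbg_trace` (or data.frame with `time_s`, `n_hat_riu`).
#' @param window length-2 time window in seconds; default the whole trace.
#' @return Standard deviation in RIU.
#' @export
dispersion <- function(trace, window = NULL) {
  t <- trace$time_s
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3) stop("window must contain at least 3 samples")
  stats::sd(trace$n_hat_riu[sel])
}

#' Limit of detection from the baseline dispersion
#'
#' A change is deemed measurable when it exceeds three times the maximum
#' baseline dispersion.
#'
#' @param max_dispersion_riu largest baseline standard deviation in RIU;
#'   must be positive.
#' @return Detection limit in RIU (3 x the dispersion).
#' @export
limit_of_detection <- function(max_dispersion_riu) {
  if (!is.numeric(max_dispersion_riu) || any(max_dispersion_riu <= 0))
    stop("dispersion must be positive")
  3 * max_dispersion_riu
}

#' Per-segment summary of a sensorgram
#'
#' Splits the trace at the given time boundaries and reports, per segment,
#' the 5%-trimmed mean and standard deviation of the predicted RI and the
#' shift relative to a designated reference (buffer) segment, in mRIU.
#' The trimmed mean makes the levels robust to injection transients.
#'
#' @param trace a `tfbg_trace`.
#' @param segment_boundaries increasing vector of interior boundary times.
#' @param reference_segment index of the reference segment (default 1).
#' @param labels optional segment names.
#' @return data.frame with `segment`, `label`, `n_samples`, `mean_riu`,
#'   `sd_riu`, `shift_mriu`.
#' @export
step_report <- function(trace, segment_boundaries, reference_segment = 1,
                        labels = NULL) {
  t <- trace$time_s
  if (any(segment_boundaries <= min(t)) || any(segment_boundaries >= max(t)))
    stop("segment boundaries must fall strictly inside the trace")
  edges <- c(min(t) - 1e-9, sort(segment_boundaries), max(t) + 1e-9)
  n_seg <- length(edges) - 1
  if (reference_segment < 1 || reference_segment > n_seg)
    stop("reference segment index out of range")
  if (is.null(labels)) labels <- paste0("segment_", seq_len(n_seg))
  means <- sds <- counts <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    sel <- t > edges[s] & t <= edges[s + 1]
    if (!sum(sel)) stop("segment ", s, " is empty")
    means[s] <- mean(trace$n_hat_riu[sel], trim = 0.05)
    sds[s] <- stats::sd(trace$n_hat_riu[sel])
    counts[s] <- sum(sel)
  }
  data.frame(segment = seq_len(n_seg), label = labels, n_samples = counts,
             mean_riu = means, sd_riu = sds,
             shift_mriu = (means - means[reference_segment]) * 1000)
}

#' Compare envelope and cross-demodulation on one series
#'
#' Demodulates every frame with both the model's band-pass envelope method
#' and the cross-demodulation baseline, and reports each wavelength trace
#' with its standard deviation (in nm). Frames where cross-demodulation
#' fails are recorded as NA rather than aborting. On series bearing comb
#' transition artifacts the filtered trace is expected to be the less
#' dispersed of the two.
#'
#' @param series a `tfbg_series`.
#' @param model a model from [tfbg_train].
#' @param reference reference [tfbg_spectrum].
#' @param n_ref reference RI in RIU.
#' @param cross_window wavelength window for cross-demodulation; default
#'   the model's search window (or central 80% of the span).
#' @return List with elements `filtered` and `cross`, each a list holding
#'   `trace` (wavelength positions per frame) and `sd_nm`; `filtered` also
#'   carries the RI trace.
#' @export
compare_methods <- function(series, model, reference, n_ref = 1.3332,
                            cross_window = NULL) {
  tr <- track(model, series, reference, n_ref = n_ref)
  if (is.null(cross_window)) {
    wl <- reference$wavelengths_nm
    span <- wl[length(wl)] - wl[1]
    cross_window <- if (!is.null(model$window)) model$window else
      c(wl[1] + 0.1 * span, wl[length(wl)] - 0.1 * span)
  }
  cross <- vapply(series$spectra, function(sp) {
    tryCatch(cross_demodulation(sp, cross_window),
             tfbg_cross_error = function(e) NA_real_)
  }, 1)
  list(filtered = list(trace = tr$lambda_min_nm, ri_trace = tr$n_hat_riu,
                       sd_nm = stats::sd(tr$lambda_min_nm)),
       cross = list(trace = cross,
                    sd_nm = stats::sd(cross, na.rm = TRUE),
                    n_failed = sum(is.na(cross))))
}
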