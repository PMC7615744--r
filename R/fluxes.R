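insufficient_data_error <- function(msg) {
  structure(class = c("caflux_insufficient_data", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Buffering-scaled removal-flux curve of a transient recovery
#'
#' Converts the post-peak recovery of a calibrated transient into paired
#' (free \[Ca2+\], removal flux) points. The time derivative is obtained by
#' Savitzky-Golay local-polynomial smoothing (simultaneously estimating the
#' smoothed value and its derivative with the same window, whose noise
#' contributions are uncorrelated at the window centre), and scaled by the
#' buffering capacity: `flux = -beta * dc/dt`, in µM total Ca per second.
#' Points are restricted to the part of the decay lying between
#' `window[1]` and `window[2]` of the amplitude above baseline, which
#' avoids both peak rounding and baseline noise. Half a smoothing window is
#' trimmed from each end of the series before selection.
#'
#' @param time,ca Recovery timecourse (post-peak), s and µM.
#' @param beta Buffering capacity (dimensionless scaling of free-Ca
#'   derivatives into total fluxes).
#' @param window Fraction pair (high, low) of amplitude above baseline
#'   delimiting the fitted decay, default `c(0.9, 0.1)`.
#' @param baseline Level the recovery decays toward; default `min(ca)`.
#' @param peak Starting level; default `max(ca)`.
#' @param sg_n Savitzky-Golay window length in samples (odd; reduced
#'   automatically when the series is short).
#' @param sg_p Local polynomial order.
#' @return A data.frame with columns `ca` (µM) and `flux` (µM/s) and
#'   attributes `beta`, `sg_n`, `sg_p`, `window`.
#' @export
recovery_flux_curve <- function(time, ca, beta = 100, window = c(0.9, 0.1),
                                baseline = NULL, peak = NULL,
                                sg_n = 11, sg_p = 2) {
  stopifnot(length(time) == length(ca), beta >= 1)
  if (length(ca) < 5)
    stop(insufficient_data_error("recovery_flux_curve: fewer than 5 samples"))
  if (is.null(baseline)) baseline <- min(ca)
  if (is.null(peak)) peak <- max(ca)
  start <- which.max(ca)
  tt <- time[seq(start, length(time))]
  cc <- ca[seq(start, length(ca))]

  dt <- stats::median(diff(tt))
  n <- min(sg_n, 2 * floor((length(cc) - 1) / 2) - 1)
  if (n < sg_p + 2)
    stop(insufficient_data_error("recovery_flux_curve: series too short for smoothing"))
  if (n %% 2 == 0) n <- n - 1
  ca_hat <- signal::sgolayfilt(cc, p = sg_p, n = n, m = 0)
  dca <- signal::sgolayfilt(cc, p = sg_p, n = n, m = 1, ts = dt)
  half <- (n - 1) / 2
  keep <- seq(half + 1, length(cc) - half)
  ca_hat <- ca_hat[keep]; dca <- dca[keep]

  amp <- peak - baseline
  hi <- baseline + max(window) * amp
  lo <- baseline + min(window) * amp
  sel <- ca_hat <= hi & ca_hat >= lo
  if (sum(sel) < 3)
    stop(insufficient_data_error(sprintf(
      "recovery_flux_curve: only %d usable points in the [%.2g, %.2g] amplitude window",
      sum(sel), max(window), min(window))))
  out <- data.frame(ca = ca_hat[sel], flux = -beta * dca[sel])
  attr(out, "beta") <- beta
  attr(out, "sg_n") <- n
  attr(out, "sg_p") <- sg_p
  attr(out, "window") <- window
  out
}

#' Fit a removal rate constant from a flux-calcium relationship
#'
#' Ordinary least squares of flux on free \[Ca2+\] with a free intercept
#' (the constant backflux/leak terms imply a nonzero intercept); the rate
#' constant is the slope, in s^-1.
#'
#' @param points A data.frame with columns `ca` and `flux`, e.g. from
#'   [recovery_flux_curve()].
#' @return An object of class `flux_fit` with `rate_constant` (s^-1),
#'   `intercept` (µM/s), `r_squared`, `n_points`, `ca_window` (µM range
#'   used).
#' @export
fit_rate_constant <- function(points) {
  stopifnot(is.data.frame(points), all(c("ca", "flux") %in% names(points)))
  if (nrow(points) < 3)
    stop(insufficient_data_error("fit_rate_constant: need at least 3 points"))
  if (stats::sd(points$ca) == 0 || !is.finite(stats::sd(points$ca)))
    stop("fit_rate_constant: degenerate fit, no variance in ca")
  fit <- stats::lm(flux ~ ca, data = points)
  cf <- stats::coef(fit)
  ss_tot <- sum((points$flux - mean(points$flux))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(rate_constant = unname(cf["ca"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = r2, n_points = nrow(points),
                 ca_window = range(points$ca)),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf(
    "<flux_fit> rate constant %.4g s^-1; intercept %.4g uM/s; r2=%.4f; n=%d; ca in [%.3g, %.3g] uM\n",
    x$rate_constant, x$intercept, x$r_squared, x$n_points,
    x$ca_window[1], x$ca_window[2]))
  invisible(x)
}

#' NCX rate constant and sarcolemmal leak from the caffeine recovery
#'
#' With caffeine holding the SR release channels open, SERCA cannot
#' accumulate Ca2+ and net cytosolic removal is via NCX alone, so the slope
#' of the caffeine-recovery flux-\[Ca2+\] relationship is the NCX rate
#' constant. The sarcolemmal leak is the rate required to balance NCX at
#' resting \[Ca2+\]: `leak = k_ncx * resting`.
#'
#' @param cafft A [detect_caffeine_transient()] result.
#' @param beta Buffering capacity.
#' @param window Amplitude-fraction fit window, see [recovery_flux_curve()].
#' @param sg_n,sg_p Smoothing window / order; the caffeine recovery is an
#'   order of magnitude slower than the CaT, hence the wider default.
#' @return A list with `k_ncx` (s^-1), `leak` (µM/s), and `fit`
#'   (a [fit_rate_constant()] result).
#' @export
ncx_analysis <- function(cafft, beta = 100, window = c(0.9, 0.1),
                         sg_n = 41, sg_p = 2) {
  stopifnot(inherits(cafft, "caffeine_transient"))
  pts <- recovery_flux_curve(cafft$recovery$time, cafft$recovery$ca,
                             beta = beta, window = window,
                             baseline = cafft$resting, peak = cafft$peak,
                             sg_n = sg_n, sg_p = sg_p)
  fit <- fit_rate_constant(pts)
  list(k_ncx = fit$rate_constant, leak = fit$rate_constant * cafft$resting,
       fit = fit)
}

#' SERCA rate constant and SR backflux from the averaged CaT recovery
#'
#' The CaT recovery reflects SERCA and NCX acting together, so the slope of
#' its flux-\[Ca2+\] relationship is `k_serca + k_ncx`. In the default
#' `"ncx-subtracted"` mode the caffeine-derived NCX rate constant is
#' subtracted to isolate SERCA; `"lumped"` reports the raw slope. The SR
#' backflux is the rate required to balance SERCA at diastolic \[Ca2+\]:
#' `backflux = k_serca * diastolic`.
#'
#' @param cat_avg A [average_transients()] result.
#' @param ncx_fit A [fit_rate_constant()] result for the caffeine recovery
#'   (required in `"ncx-subtracted"` mode).
#' @param beta Buffering capacity.
#' @param window Amplitude-fraction fit window.
#' @param sg_n,sg_p Smoothing window / order.
#' @param mode `"ncx-subtracted"` or `"lumped"`.
#' @return A list with `k_serca` (s^-1; attribute `flagged_negative` if the
#'   subtraction went below zero), `backflux` (µM/s), `slope` (the raw CaT
#'   recovery slope), and `fit`.
#' @export
serca_analysis <- function(cat_avg, ncx_fit = NULL, beta = 100,
                           window = c(0.9, 0.1), sg_n = 11, sg_p = 2,
                           mode = c("ncx-subtracted", "lumped")) {
  stopifnot(inherits(cat_avg, "ca_transient"))
  mode <- match.arg(mode)
  rec <- seq(cat_avg$peak_index, length(cat_avg$time))
  pts <- recovery_flux_curve(cat_avg$time[rec], cat_avg$ca[rec],
                             beta = beta, window = window,
                             baseline = cat_avg$diastolic,
                             peak = cat_avg$systolic,
                             sg_n = sg_n, sg_p = sg_p)
  fit <- fit_rate_constant(pts)
  slope <- fit$rate_constant
  if (mode == "ncx-subtracted") {
    if (is.null(ncx_fit))
      stop("serca_analysis: ncx_fit is required in 'ncx-subtracted' mode")
    stopifnot(inherits(ncx_fit, "flux_fit"))
    k_serca <- slope - ncx_fit$rate_constant
  } else {
    k_serca <- slope
  }
  attr(k_serca, "flagged_negative") <- k_serca < 0
  list(k_serca = k_serca, backflux = as.numeric(k_serca) * cat_avg$diastolic,
       slope = slope, fit = fit, mode = mode)
}

wrap_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    structure(list(stage = stage, message = conditionMessage(e)),
              class = "caflux_stage_error")
  })
}
is_stage_error <- function(x) inherits(x, "caflux_stage_error")

#' Full per-cell calcium-handling report
#'
#' Orchestrates the whole pipeline on one recording: calibrate, segment the
#' paced train, average, quantify the caffeine transient, and decompose the
#' removal fluxes. Any stage failure is recorded with the stage name and
#' the remaining fields are reported as missing, so a partial report is
#' still produced. The resolved configuration (calibration curve, buffering
#' capacity, windows, smoothing, mode, package version) is embedded as
#' provenance, and the balancing identities `backflux = k_serca *
#' diastolic` and `leak = k_ncx * resting` hold exactly in every report.
#'
#' @param trace A [fluorescence_trace()] (or an already calibrated trace).
#' @param config An [analysis_config()].
#' @return An object of class `ca_handling_report`; use
#'   [as.data.frame.ca_handling_report()] for a flat one-row summary.
#' @examples
#' sim <- simulate_myocyte(myocyte_params(), pacing_protocol(n_beats = 8))
#' trace <- render_fluorescence(sim)
#' rep <- full_report(trace)
#' rep$k_serca
#' @export
full_report <- function(trace, config = analysis_config()) {
  config <- validate_config(config)
  curve <- do.call(calibration_curve, config$calibration)
  errors <- list()
  note_error <- function(x) {
    if (is_stage_error(x)) errors[[length(errors) + 1L]] <<- x
    is_stage_error(x)
  }

  ctrace <- if (inherits(trace, "calibrated_trace")) trace else
    wrap_stage("calibrate", calibrate_trace(trace, curve))
  if (note_error(ctrace))
    stop("full_report: calibration failed: ", ctrace$message)

  segs <- wrap_stage("segment",
    detect_transients(ctrace, pre_window = config$diastolic_window,
                      prominence_k = config$prominence_k))
  segs_ok <- !note_error(segs)
  cat_avg <- if (segs_ok) wrap_stage("average",
    average_transients(segs, discard_first_n = config$discard_first_n,
                       pre_window = config$diastolic_window)) else segs
  if (segs_ok) note_error(cat_avg)

  has_caff <- !is.na(ctrace$caffeine_onset)
  cafft <- if (has_caff) wrap_stage("caffeine",
    detect_caffeine_transient(ctrace,
                              resting_window = config$resting_window,
                              resting_gap = config$resting_gap,
                              peak_method = config$peak_method)) else NULL
  if (!is.null(cafft)) note_error(cafft)
  cafft_ok <- has_caff && !is_stage_error(cafft)

  ncx <- if (cafft_ok) wrap_stage("ncx",
    ncx_analysis(cafft, beta = config$beta, window = config$fit_window,
                 sg_n = config$ncx_sg_n, sg_p = config$sg_p)) else NULL
  if (!is.null(ncx)) note_error(ncx)
  ncx_ok <- !is.null(ncx) && !is_stage_error(ncx)

  mode <- config$mode
  if (mode == "ncx-subtracted" && !ncx_ok) mode <- "lumped"
  serca <- if (!is_stage_error(cat_avg)) wrap_stage("serca",
    serca_analysis(cat_avg, ncx_fit = if (ncx_ok) ncx$fit else NULL,
                   beta = config$beta, window = config$fit_window,
                   sg_n = config$serca_sg_n, sg_p = config$sg_p,
                   mode = mode)) else cat_avg
  if (!is_stage_error(cat_avg)) note_error(serca)
  serca_ok <- !is_stage_error(serca)

  cat_ok <- !is_stage_error(cat_avg)
  fr <- if (cat_ok && cafft_ok && cafft$amplitude > 0)
    wrap_stage("fractional_release", fractional_release(cat_avg, cafft)) else NULL
  if (!is.null(fr)) note_error(fr)
  fr_ok <- !is.null(fr) && !is_stage_error(fr)

  sat_frac <- max(if (cat_ok) cat_avg$saturated_fraction else 0,
                  if (cafft_ok) cafft$saturated_fraction else 0)

  structure(list(
    diastolic = if (cat_ok) cat_avg$diastolic else NA_real_,
    systolic = if (cat_ok) cat_avg$systolic else NA_real_,
    amplitude = if (cat_ok) cat_avg$amplitude else NA_real_,
    t_recovery_90 = if (cat_ok) cat_avg$t_recovery_90 else NA_real_,
    resting = if (cafft_ok) cafft$resting else NA_real_,
    sr_load = if (cafft_ok) cafft$amplitude else NA_real_,
    fractional_release = if (fr_ok) as.numeric(fr) else NA_real_,
    k_serca = if (serca_ok) as.numeric(serca$k_serca) else NA_real_,
    backflux = if (serca_ok) serca$backflux else NA_real_,
    cat_recovery_slope = if (serca_ok) serca$slope else NA_real_,
    k_ncx = if (ncx_ok) ncx$k_ncx else NA_real_,
    leak = if (ncx_ok) ncx$leak else NA_real_,
    mode = mode,
    n_beats_averaged = if (cat_ok) cat_avg$n_averaged else NA_integer_,
    saturated_fraction = sat_frac,
    flags = list(
      peak_unreliable = sat_frac > 0,
      fractional_release_gt1 = fr_ok && isTRUE(attr(fr, "flagged_gt1")),
      k_serca_negative = serca_ok && isTRUE(attr(serca$k_serca, "flagged_negative"))),
    fits = list(serca = if (serca_ok) serca$fit else NULL,
                ncx = if (ncx_ok) ncx$fit else NULL),
    errors = errors,
    provenance = list(
      calibration = config$calibration,
      beta = config$beta,
      diastolic_window = config$diastolic_window,
      resting_window = config$resting_window,
      resting_gap = config$resting_gap,
      fit_window = config$fit_window,
      serca_sg_n = config$serca_sg_n, ncx_sg_n = config$ncx_sg_n,
      sg_p = config$sg_p, discard_first_n = config$discard_first_n,
      peak_method = config$peak_method, mode = config$mode,
      package_version = as.character(utils::packageVersion("caflux")))),
    class = "ca_handling_report")
}

#' @export
print.ca_handling_report <- function(x, ...) {
  cat("<ca_handling_report>\n")
  cat(sprintf("  diastolic %.4g uM | systolic %.4g uM | amplitude %.4g uM | CaT90 %s s\n",
              x$diastolic, x$systolic, x$amplitude,
              if (is.na(x$t_recovery_90)) "-" else sprintf("%.3g", x$t_recovery_90)))
  cat(sprintf("  resting %.4g uM | SR load %.4g uM | fractional release %s\n",
              x$resting, x$sr_load,
              if (is.na(x$fractional_release)) "-" else sprintf("%.3g", x$fractional_release)))
  cat(sprintf("  k_serca %.4g s^-1 (backflux %.4g uM/s) | k_ncx %.4g s^-1 (leak %.4g uM/s) [%s]\n",
              x$k_serca, x$backflux, x$k_ncx, x$leak, x$mode))
  if (x$flags$peak_unreliable)
    cat(sprintf("  flag: %.1f%% of samples saturated; peak metrics unreliable\n",
                100 * x$saturated_fraction))
  if (length(x$errors))
    for (e in x$errors)
      cat(sprintf("  stage '%s' failed: %s\n", e$stage, e$message))
  invisible(x)
}

#' Flatten a calcium-handling report to a one-row data frame
#'
#' @param x A [full_report()] result.
#' @param ... Unused.
#' @return A one-row data.frame of the per-cell metric panel, suitable for
#'   binding across cells into a batch CSV.
#' @export
as.data.frame.ca_handling_report <- function(x, ...) {
  data.frame(diastolic = x$diastolic, systolic = x$systolic,
             amplitude = x$amplitude, t_recovery_90 = x$t_recovery_90,
             resting = x$resting, sr_load = x$sr_load,
             fractional_release = x$fractional_release,
             k_serca = x$k_serca, backflux = x$backflux,
             k_ncx = x$k_ncx, leak = x$leak,
             cat_recovery_slope = x$cat_recovery_slope,
             mode = x$mode, n_beats_averaged = x$n_beats_averaged,
             saturated_fraction = x$saturated_fraction,
             peak_unreliable = x$flags$peak_unreliable,
             stringsAsFactors = FALSE)
}
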