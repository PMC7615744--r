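#' @keywords internal
empty_result_error <- function(msg) {
  structure(class = c("caflux_empty_result", "error", "condition"),
            list(message = msg, call = NULL))
}

robust_noise_sd <- function(x) {
  d <- diff(x)
  stats::mad(d[is.finite(d)]) / sqrt(2)
}

#' Segment a calibrated trace into per-beat calcium transients
#'
#' When stimulus times are available the segmentation anchors to them: each
#' segment spans from `pre_window` s before its stimulus to just before the
#' next stimulus (the last beat extends one median period). Without
#' metadata, beats are found by prominence-based peak detection: local
#' maxima of the lightly smoothed trace whose topographic prominence
#' exceeds `prominence_k` times a robust noise s.d. (median absolute
#' deviation of the first-difference residual), with segment anchors placed
#' at the estimated upstroke onset. Beats whose segment would overlap the
#' caffeine window are excluded.
#'
#' @param ctrace A [calibrate_trace()] result.
#' @param stimulus_times Stimulus times in s, or `NULL` to use the trace
#'   metadata, or `NA` to force prominence-based detection.
#' @param pre_window Pre-stimulus window included in each segment, s; its
#'   mean defines the diastolic level downstream.
#' @param prominence_k Detection threshold in robust noise s.d. units.
#' @return A list of segments, each a data.frame with `time` (aligned so the
#'   stimulus/upstroke is at 0), `ca`, `saturated`, and attributes
#'   `stim_time` and `peak_time`.
#' @export
detect_transients <- function(ctrace, stimulus_times = NULL,
                              pre_window = 0.05, prominence_k = 4) {
  stopifnot(inherits(ctrace, "calibrated_trace"))
  if (is.null(stimulus_times)) stimulus_times <- ctrace$stimulus_times
  anchored <- length(stimulus_times) > 0 && !anyNA(stimulus_times)

  tt <- ctrace$time; ca <- ctrace$ca
  caff <- ctrace$caffeine_onset

  if (anchored) {
    stim <- sort(stimulus_times)
    period <- if (length(stim) > 1) stats::median(diff(stim)) else
      (max(tt) - stim)
    ends <- c(stim[-1], stim[length(stim)] + period)
  } else {
    peaks <- find_peaks(tt, ca, prominence_k)
    if (length(peaks$idx) == 0)
      stop(empty_result_error(sprintf(
        "detect_transients: no beats detected (threshold %.4g uM, max prominence seen %.4g uM)",
        peaks$threshold, peaks$max_prominence)))
    stim <- peaks$onset_time
    period <- if (length(stim) > 1) stats::median(diff(stim)) else
      (max(tt) - stim)
    ends <- c(stim[-1], stim[length(stim)] + period)
  }

  segs <- list()
  for (i in seq_along(stim)) {
    if (!is.na(caff) && ends[i] > caff + 1e-9) next  # overlaps caffeine window
    sel <- tt >= stim[i] - pre_window & tt < ends[i] - 1e-12
    if (!any(sel)) next
    seg <- data.frame(time = tt[sel] - stim[i], ca = ca[sel],
                      saturated = ctrace$saturated[sel])
    attr(seg, "stim_time") <- stim[i]
    attr(seg, "peak_time") <- tt[sel][which.max(ca[sel])]
    segs[[length(segs) + 1L]] <- seg
  }
  if (length(segs) == 0)
    stop(empty_result_error("detect_transients: no usable beat segments"))
  segs
}

# Local-maximum peak finder with topographic prominence.
find_peaks <- function(tt, ca, prominence_k, smooth_n = 5L) {
  x <- if (length(ca) > smooth_n) stats::runmed(ca, smooth_n) else ca
  n <- length(x)
  sigma <- robust_noise_sd(ca)
  threshold <- max(prominence_k * sigma, 1e-3 * diff(range(x)))
  cand <- which(x[-c(1, n)] > x[-c(n - 1, n)] & x[-c(1, n)] >= x[-c(1, 2)]) + 1L
  prom <- numeric(length(cand))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    hi_l <- which(left > x[i]); hi_r <- which(right > x[i])
    base_l <- if (length(hi_l)) min(x[seq(max(hi_l) + 1, i - 1)]) else min(left)
    base_r <- if (length(hi_r)) min(x[seq(i + 1, i + min(hi_r) - 1)]) else min(right)
    prom[j] <- x[i] - max(base_l, base_r)
    keep[j] <- prom[j] > threshold
  }
  idx <- cand[keep]
  # merge plateau/near-duplicate maxima closer than 5 samples
  if (length(idx) > 1) {
    grp <- cumsum(c(TRUE, diff(idx) > 5))
    idx <- vapply(split(idx, grp), function(ii) ii[which.max(x[ii])], integer(1))
  }
  onset <- vapply(idx, function(i) {
    base <- x[i] - prom[cand == i][1]
    j <- i
    lvl <- base + 0.1 * (x[i] - base)
    while (j > 1 && x[j - 1] > lvl && x[j - 1] <= x[j]) j <- j - 1L
    tt[j]
  }, numeric(1))
  list(idx = idx, peak_time = tt[idx], onset_time = onset,
       threshold = threshold,
       max_prominence = if (length(prom)) max(prom) else 0)
}

#' Average a train of calcium-transient segments
#'
#' Discards the first `discard_first_n` beats (approach to SR steady
#' state), resamples the remaining segments onto a common post-stimulus
#' time base by linear interpolation, and averages pointwise. Metrics are
#' computed on the average: diastolic = mean over the pre-stimulus window,
#' systolic = maximum after the stimulus, amplitude = systolic - diastolic,
#' and `t_recovery_90` = first time the post-peak decay falls below
#' diastolic + 0.1 * amplitude (linear interpolation between samples).
#'
#' @param segments Output of [detect_transients()].
#' @param discard_first_n Beats discarded from the head of the train.
#' @param pre_window Pre-stimulus window used for the diastolic level, s.
#' @return An object of class `ca_transient` with the averaged `time`/`ca`
#'   series and fields `diastolic`, `systolic`, `amplitude`,
#'   `t_recovery_90`, `n_averaged`, `saturated_fraction`.
#' @export
average_transients <- function(segments, discard_first_n = 2,
                               pre_window = 0.05) {
  if (length(segments) <= discard_first_n)
    stop("average_transients: no segments left after discarding ",
         discard_first_n, " beats")
  use <- segments[seq(discard_first_n + 1L, length(segments))]
  dt <- stats::median(vapply(use, function(s) stats::median(diff(s$time)),
                             numeric(1)))
  t_lo <- max(vapply(use, function(s) min(s$time), numeric(1)))
  t_hi <- min(vapply(use, function(s) max(s$time), numeric(1)))
  grid <- seq(max(t_lo, -pre_window), t_hi, by = dt)
  mat <- vapply(use, function(s) {
    stats::approx(s$time, s$ca, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  avg <- rowMeans(mat)
  sat_frac <- mean(vapply(use, function(s) mean(s$saturated), numeric(1)))

  dia_sel <- grid < 0 & grid >= -pre_window
  diastolic <- if (any(dia_sel)) mean(avg[dia_sel]) else avg[1]
  post <- grid >= 0
  systolic <- max(avg[post])
  amplitude <- systolic - diastolic
  pk <- which(post)[which.max(avg[post])]
  t90 <- recovery_fraction_time(grid[seq(pk, length(grid))] - grid[pk],
                                avg[seq(pk, length(grid))], fraction = 0.9,
                                baseline = diastolic, peak = systolic)
  structure(list(time = grid, ca = avg, diastolic = diastolic,
                 systolic = systolic, amplitude = amplitude,
                 t_recovery_90 = t90, n_averaged = length(use),
                 saturated_fraction = sat_frac,
                 peak_index = pk),
            class = "ca_transient")
}

#' @export
print.ca_transient <- function(x, ...) {
  cat(sprintf(paste0(
    "<ca_transient> n_averaged=%d; diastolic=%.4g uM; systolic=%.4g uM; ",
    "amplitude=%.4g uM; t90=%s s; saturated_fraction=%.3g\n"),
    x$n_averaged, x$diastolic, x$systolic, x$amplitude,
    if (is.na(x$t_recovery_90)) "-" else sprintf("%.4g", x$t_recovery_90),
    x$saturated_fraction))
  invisible(x)
}

#' Identify and quantify the caffeine-evoked transient
#'
#' The resting level is the mean over a window immediately preceding the
#' caffeine onset; the peak is located after onset and, by default,
#' estimated by back-extrapolating a mono-exponential fit of the recovery
#' to the onset time (noise-robust; the raw post-onset maximum is available
#' via `peak_method = "max"`). The caffeine-transient amplitude (peak minus
#' resting) is the SR Ca2+-load proxy. If no post-onset rise exceeds
#' `rise_k` robust noise s.d. above resting, a no-release warning is issued
#' and the amplitude is 0.
#'
#' @param ctrace A [calibrate_trace()] result.
#' @param caffeine_onset Onset time, s; `NULL` to use trace metadata.
#' @param resting_window Length of the pre-onset window, s.
#' @param resting_gap Gap between the window's end and the onset, s.
#' @param peak_method `"fit"` (exponential back-extrapolation, default) or
#'   `"max"` (raw maximum after onset).
#' @param rise_k Release-detection threshold in noise s.d. units.
#' @return An object of class `caffeine_transient` with fields `resting`,
#'   `peak`, `amplitude`, `recovery` (a data.frame of the post-peak `time`,
#'   `ca`), `decay_rate` (fitted s^-1, free-Ca scale; `NA` for
#'   `peak_method = "max"`), and `saturated_fraction`.
#' @export
detect_caffeine_transient <- function(ctrace, caffeine_onset = NULL,
                                      resting_window = 0.05,
                                      resting_gap = 0,
                                      peak_method = c("fit", "max"),
                                      rise_k = 4) {
  stopifnot(inherits(ctrace, "calibrated_trace"))
  peak_method <- match.arg(peak_method)
  if (is.null(caffeine_onset)) caffeine_onset <- ctrace$caffeine_onset
  if (is.na(caffeine_onset))
    stop("detect_caffeine_transient: no caffeine onset available")
  tt <- ctrace$time; ca <- ctrace$ca
  if (caffeine_onset <= min(tt) || caffeine_onset >= max(tt))
    stop("detect_caffeine_transient: caffeine_onset outside the trace")

  rest_sel <- tt >= caffeine_onset - resting_gap - resting_window &
    tt < caffeine_onset - resting_gap
  if (!any(rest_sel))
    stop("detect_caffeine_transient: no samples in the resting window")
  resting <- mean(ca[rest_sel])

  post <- which(tt >= caffeine_onset)
  sigma <- robust_noise_sd(ca)
  raw_pk <- post[which.max(ca[post])]
  if (ca[raw_pk] <= resting + rise_k * sigma + 1e-12) {
    warning("detect_caffeine_transient: no caffeine-evoked release detected; amplitude set to 0")
    return(structure(list(resting = resting, peak = resting, amplitude = 0,
                          recovery = data.frame(time = tt[post], ca = ca[post]),
                          decay_rate = NA_real_,
                          saturated_fraction = mean(ctrace$saturated[post])),
                     class = "caffeine_transient"))
  }

  recovery <- data.frame(time = tt[seq(raw_pk, length(tt))],
                         ca = ca[seq(raw_pk, length(tt))])
  decay_rate <- NA_real_
  peak <- ca[raw_pk]
  if (peak_method == "fit") {
    fit <- caff_peak_fit(recovery$time, recovery$ca, caffeine_onset)
    if (!is.null(fit)) {
      peak <- max(fit$peak, resting)
      decay_rate <- fit$rate
    }
  }
  structure(list(resting = resting, peak = peak, amplitude = peak - resting,
                 recovery = recovery, decay_rate = decay_rate,
                 saturated_fraction = mean(ctrace$saturated[post])),
            class = "caffeine_transient")
}

# Mono-exponential fit of the caffeine recovery, back-extrapolated to the
# onset time. Returns NULL if the fit cannot be obtained.
caff_peak_fit <- function(tt, ca, onset) {
  if (length(tt) < 10) return(NULL)
  t0 <- tt - onset
  c_inf0 <- min(ca)
  a0 <- max(ca) - c_inf0
  pos <- ca - c_inf0 > 0.05 * a0
  k0 <- tryCatch({
    f <- stats::lm(log(ca[pos] - c_inf0 + 0.05 * a0) ~ t0[pos])
    max(0.05, -stats::coef(f)[2])
  }, error = function(e) 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(ca ~ cinf + A * exp(-k * t0),
                      start = list(cinf = c_inf0, A = a0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["A"]]) || cf[["A"]] <= 0 || cf[["k"]] <= 0) return(NULL)
  list(peak = cf[["cinf"]] + cf[["A"]], rate = cf[["k"]])
}

#' @export
print.caffeine_transient <- function(x, ...) {
  cat(sprintf(
    "<caffeine_transient> resting=%.4g uM; peak=%.4g uM; amplitude=%.4g uM; saturated_fraction=%.3g\n",
    x$resting, x$peak, x$amplitude, x$saturated_fraction))
  invisible(x)
}

#' Fractional SR release
#'
#' Ratio of the averaged CaT amplitude to the caffeine-transient amplitude,
#' i.e. the fraction of the SR Ca2+ load released per beat. Values above 1
#' are physically possible under measurement error and are flagged rather
#' than rejected.
#'
#' @param cat_avg A [average_transients()] result.
#' @param cafft A [detect_caffeine_transient()] result.
#' @return Scalar fraction with attribute `flagged_gt1`.
#' @export
fractional_release <- function(cat_avg, cafft) {
  stopifnot(inherits(cat_avg, "ca_transient"),
            inherits(cafft, "caffeine_transient"))
  if (cafft$amplitude <= 0)
    stop("fractional_release: undefined for zero caffeine-transient amplitude")
  fr <- cat_avg$amplitude / cafft$amplitude
  attr(fr, "flagged_gt1") <- fr > 1
  fr
}

#' Time to a given recovery fraction of a decaying timecourse
#'
#' Returns the first time at which the decay crosses
#' `baseline + (1 - fraction) * (peak - baseline)`, linearly interpolated
#' between the bracketing samples (first-crossing rule, ties broken by
#' earliest time). Works on Ca2+ transients and on normalised voltage
#' traces alike (e.g. CaT90, APD90 with `fraction = 0.9`).
#'
#' @param time Time since the peak, s.
#' @param value Decaying series, same length as `time`.
#' @param fraction Recovery fraction in (0, 1), e.g. 0.9 for t90.
#' @param baseline Baseline toward which the series decays; default the
#'   series minimum.
#' @param peak Starting level; default the series maximum.
#' @return First-crossing time in s, or `NA` (not-recovered sentinel) when
#'   the threshold is never crossed.
#' @export
recovery_fraction_time <- function(time, value, fraction = 0.9,
                                   baseline = NULL, peak = NULL) {
  stopifnot(length(time) == length(value), fraction > 0, fraction < 1)
  if (is.null(baseline)) baseline <- min(value)
  if (is.null(peak)) peak <- max(value)
  thr <- baseline + (1 - fraction) * (peak - baseline)
  below <- which(value <= thr)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(time[1])
  # linear interpolation between the bracketing samples
  t0 <- time[i - 1]; t1 <- time[i]
  v0 <- value[i - 1]; v1 <- value[i]
  if (v0 == v1) return(t1)
  t0 + (v0 - thr) / (v0 - v1) * (t1 - t0)
}
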