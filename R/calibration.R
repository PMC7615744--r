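#' Ratiometric calibration curve for a dual-excitation Ca2+ dye
#'
#' Describes the hyperbolic map between the background-subtracted
#' fluorescence ratio R and free cytosolic \[Ca2+\],
#' \deqn{[\mathrm{Ca}^{2+}] = K_d \frac{R - R_{min}}{R_{max} - R},}
#' together with a saturation threshold above which calibrated values lose
#' resolving power and are flagged. The default threshold of 2.4 is the
#' published FuraRed saturation bound; `r_min`, `r_max` and `kd` default to
#' plausible stand-ins and should be overridden with the constants of the
#' actual calibration. The curve used is embedded in every analysis report.
#'
#' @param r_min Ratio at zero Ca2+.
#' @param r_max Ratio at saturating Ca2+.
#' @param kd Dye dissociation constant, in µM.
#' @param sat_ratio Ratio above which samples are flagged as saturated.
#' @param id Free-text identifier recorded in provenance.
#' @return An object of class `calibration_curve`.
#' @examples
#' curve <- calibration_curve()
#' ratio_to_ca(2.0, curve)
#' @export
calibration_curve <- function(r_min = 1.0, r_max = 3.0, kd = 0.4,
                              sat_ratio = 2.4, id = "default-stand-in") {
  stopifnot(is.numeric(r_min), is.numeric(r_max), is.numeric(kd),
            is.numeric(sat_ratio), length(r_min) == 1L, length(r_max) == 1L,
            length(kd) == 1L, length(sat_ratio) == 1L)
  if (!(r_min < sat_ratio && sat_ratio <= r_max))
    stop("calibration_curve: need r_min < sat_ratio <= r_max")
  if (kd <= 0) stop("calibration_curve: kd must be > 0")
  structure(list(r_min = r_min, r_max = r_max, kd = kd,
                 sat_ratio = sat_ratio, id = as.character(id)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve '%s'> Rmin=%g Rmax=%g Kd=%g uM, saturated above R=%g\n",
    x$id, x$r_min, x$r_max, x$kd, x$sat_ratio))
  invisible(x)
}

#' Background-subtracted fluorescence ratio of two emission channels
#'
#' Computes `(ch_num - bg_num) / (ch_den - bg_den)` per sample. Samples whose
#' denominator is non-positive after background subtraction are masked (`NA`)
#' rather than raising an error; an error is raised only if every sample is
#' masked.
#'
#' @param ch_num,ch_den Numerator / denominator channel intensity series
#'   (equal length).
#' @param bg_num,bg_den Scalar background levels for each channel.
#' @return Numeric ratio series with masked samples as `NA`.
#' @export
compute_ratio <- function(ch_num, ch_den, bg_num = 0, bg_den = 0) {
  if (length(ch_num) != length(ch_den))
    stop("compute_ratio: channel series must have equal length")
  if (bg_num < 0 || bg_den < 0)
    stop("compute_ratio: background levels must be >= 0")
  den <- ch_den - bg_den
  num <- ch_num - bg_num
  r <- ifelse(is.finite(den) & den > 0, num / den, NA_real_)
  if (all(is.na(r)))
    stop(empty_signal_error(
      "compute_ratio: all samples masked (denominator <= 0 after background subtraction)"))
  r
}

#' Convert fluorescence ratios to free calcium with saturation flags
#'
#' Applies the hyperbolic calibration, clipping negative results (ratios
#' below `r_min`) to zero. Ratios above the saturation threshold are flagged;
#' ratios at or above `r_max` additionally have their Ca2+ value capped at
#' the value of the curve at `sat_ratio` so that no infinity can propagate.
#'
#' @param r Ratio value(s); `NA` propagates.
#' @param curve A [calibration_curve()].
#' @return A list with numeric `ca` (µM) and logical `saturated`, each the
#'   length of `r`.
#' @export
ratio_to_ca <- function(r, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  ca <- curve$kd * (r - curve$r_min) / (curve$r_max - r)
  ca <- pmax(ca, 0)
  ca_cap <- curve$kd * (curve$sat_ratio - curve$r_min) /
    (curve$r_max - curve$sat_ratio)
  over <- !is.na(r) & r >= curve$r_max
  ca[over] <- ca_cap
  saturated <- !is.na(r) & r > curve$sat_ratio
  list(ca = ca, saturated = saturated)
}

#' Convert free calcium to the noiseless fluorescence ratio
#'
#' Exact inverse of [ratio_to_ca()] below saturation:
#' `r = (r_min * kd + r_max * ca) / (kd + ca)`; approaches `r_max`
#' asymptotically as Ca2+ grows.
#'
#' @param ca Free \[Ca2+\] in µM, `>= 0`.
#' @param curve A [calibration_curve()].
#' @return Numeric ratio series.
#' @export
ca_to_ratio <- function(ca, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(ca < 0, na.rm = TRUE)) stop("ca_to_ratio: ca must be >= 0")
  (curve$r_min * curve$kd + curve$r_max * ca) / (curve$kd + ca)
}

empty_signal_error <- function(msg) {
  structure(class = c("caflux_empty_signal", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
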