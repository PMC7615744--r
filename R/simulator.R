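#' Ground-truth parameters of the simulated ventricular myocyte
#'
#' A two-pool (cytosol + sarcoplasmic reticulum) description of beat-to-beat
#' Ca2+ handling. Removal fluxes are linear in free \[Ca2+\]
#' (`J_SERCA = k_serca * c`, `J_NCX = k_ncx * c`, both in µM total Ca per
#' second after scaling by the buffering capacity `beta`). Two constant
#' balancing fluxes keep the cell self-consistently at rest: SR backflux
#' `B = k_serca * c_rest` and sarcolemmal leak `L = k_ncx * c_rest`. Each
#' electrical stimulus releases the fraction `fr` of the current SR content
#' into the cytosol as an instantaneous jump, and deposits `stim_influx` µM
#' of trigger Ca2+ entering across the sarcolemma into the SR pool
#' (trigger Ca2+ that is rapidly resequestered). Without that per-beat entry
#' the SR would lose `fr * k_ncx / (k_serca + k_ncx)` of its content on
#' every beat and pacing could never reach a periodic steady state; the
#' default influx is sized so that `sr_init` is (approximately) the paced
#' steady-state SR content. From caffeine onset onwards the SR empties at
#' `k_caff * s`, which must be much faster than cytosolic removal for the
#' caffeine transient to probe SR load; the default 500 s^-1 empties the SR
#' within ~10 ms.
#'
#' @param k_serca SERCA rate constant, s^-1 (slope of removal flux vs free
#'   \[Ca2+\]).
#' @param k_ncx NCX rate constant, s^-1.
#' @param c_rest Resting free \[Ca2+\], µM.
#' @param beta Cytoplasmic buffering capacity (d\[Ca\]total / d\[Ca\]free),
#'   dimensionless, >= 1.
#' @param fr Fractional SR release per stimulus, in (0, 1).
#' @param k_caff Caffeine-open SR emptying rate constant, s^-1.
#' @param sr_init Initial SR content, µM of total Ca in cytosol-volume
#'   equivalents.
#' @param stim_influx Trigger Ca2+ entry per stimulus, µM total; `NULL` for
#'   the steady-state-preserving default
#'   `fr * sr_init * k_ncx / (k_serca + k_ncx)`.
#' @return An object of class `myocyte_params`.
#' @export
myocyte_params <- function(k_serca = 430, k_ncx = 70, c_rest = 0.1,
                           beta = 100, fr = 0.6, k_caff = 500,
                           sr_init = 80, stim_influx = NULL) {
  if (k_serca <= 0 || k_ncx <= 0 || k_caff <= 0)
    stop("myocyte_params: all rate constants must be > 0")
  if (beta < 1) stop("myocyte_params: beta must be >= 1")
  if (!(fr > 0 && fr < 1)) stop("myocyte_params: fr must be in (0, 1)")
  if (c_rest <= 0) stop("myocyte_params: c_rest must be > 0")
  if (sr_init < 0) stop("myocyte_params: sr_init must be >= 0")
  if (is.null(stim_influx))
    stim_influx <- fr * sr_init * k_ncx / (k_serca + k_ncx)
  if (stim_influx < 0) stop("myocyte_params: stim_influx must be >= 0")
  structure(list(k_serca = k_serca, k_ncx = k_ncx, c_rest = c_rest,
                 beta = beta, fr = fr, k_caff = k_caff, sr_init = sr_init,
                 stim_influx = stim_influx),
            class = "myocyte_params")
}

#' @export
print.myocyte_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<myocyte_params> k_serca=%g k_ncx=%g k_caff=%g s^-1; c_rest=%g uM; ",
    "beta=%g; fr=%g; sr_init=%g uM; stim_influx=%g uM/beat\n"),
    x$k_serca, x$k_ncx, x$k_caff, x$c_rest, x$beta, x$fr, x$sr_init,
    x$stim_influx))
  invisible(x)
}

#' Pacing and caffeine-application protocol
#'
#' A train of `n_beats` field stimuli at `pacing_hz`, followed by rapid
#' caffeine application. By default caffeine is applied exactly one pacing
#' period after the last stimulus — in place of the next expected beat — so
#' that the SR content interrogated by caffeine equals its per-beat periodic
#' steady state.
#'
#' @param pacing_hz Stimulation frequency, Hz.
#' @param n_beats Number of stimuli (0 for an unpaced recording).
#' @param caffeine_onset Time of caffeine application, s; `NULL` for one
#'   period after the last stimulus, `NA` for no caffeine.
#' @param duration Total recorded duration, s; `NULL` extends 6 s past
#'   caffeine onset (or past the last stimulus when there is no caffeine).
#' @param dt Integration step, s.
#' @param t_first Time of the first stimulus, s.
#' @return An object of class `pacing_protocol` with the resolved
#'   `stimulus_times`.
#' @export
pacing_protocol <- function(pacing_hz = 2, n_beats = 20,
                            caffeine_onset = NULL, duration = NULL,
                            dt = 0.001, t_first = 0.25) {
  if (dt <= 0) stop("pacing_protocol: dt must be > 0")
  if (n_beats < 0) stop("pacing_protocol: n_beats must be >= 0")
  stim <- if (n_beats > 0) t_first + (seq_len(n_beats) - 1) / pacing_hz
          else numeric(0)
  if (is.null(caffeine_onset)) {
    caffeine_onset <- if (n_beats > 0) stim[n_beats] + 1 / pacing_hz else NA_real_
  }
  if (!is.na(caffeine_onset)) {
    if (n_beats > 0 && caffeine_onset <= n_beats / pacing_hz)
      stop("pacing_protocol: caffeine_onset must follow the pacing train")
    if (n_beats > 0 && caffeine_onset <= stim[n_beats])
      stop("pacing_protocol: caffeine_onset must follow the last stimulus")
  }
  if (is.null(duration)) {
    duration <- if (!is.na(caffeine_onset)) caffeine_onset + 6
                else if (n_beats > 0) stim[n_beats] + 6 else 6
  }
  if (!is.na(caffeine_onset) && duration <= caffeine_onset)
    stop("pacing_protocol: duration must exceed caffeine_onset")
  structure(list(pacing_hz = pacing_hz, n_beats = n_beats,
                 stimulus_times = stim, caffeine_onset = caffeine_onset,
                 duration = duration, dt = dt),
            class = "pacing_protocol")
}

#' Additive channel-noise specification for rendered fluorescence
#'
#' Gaussian noise is added independently to each emission channel (not to
#' the ratio), so the ratio's noise is realistically heteroscedastic.
#'
#' @param channel_sd Additive Gaussian s.d. per channel, in the arbitrary
#'   units of the rendered intensities.
#' @param seed Integer RNG seed; the rendered trace is bit-reproducible for
#'   a fixed seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(channel_sd = 0, seed = 1L) {
  if (channel_sd < 0) stop("noise_spec: channel_sd must be >= 0")
  structure(list(channel_sd = channel_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

sim_integration_error <- function(t) {
  structure(class = c("caflux_integration_failure", "error", "condition"),
            list(message = sprintf(
              "simulate_myocyte: non-finite or negative state at t = %.6g s", t),
              call = NULL))
}

#' Simulate a paced myocyte with an SR compartment
#'
#' Integrates the two-pool Ca2+-handling model with fixed-step RK4.
#' Between events the free cytosolic concentration `c` (µM) and total SR
#' content `s` (µM) obey
#' \deqn{\beta\,dc/dt = J_{rel} + B + L - k_{serca} c - k_{ncx} c, \quad
#'       ds/dt = k_{serca} c - B - J_{rel},}
#' with `B = k_serca * c_rest`, `L = k_ncx * c_rest`, and
#' `J_rel = k_caff * s` after caffeine onset (zero before). Each stimulus is
#' an instantaneous event: `fr * s` moves from SR to cytosol (free `c` jumps
#' by `fr * s / beta`) and `stim_influx` µM of trigger Ca2+ enters the SR
#' pool from outside the cell. Cumulative net sarcolemmal extrusion is
#' co-integrated so that the conservation identity
#' `beta*c + s + extruded` = constant holds to integration tolerance.
#'
#' @param params A [myocyte_params()].
#' @param protocol A [pacing_protocol()].
#' @return An object of class `simulation_result`: a list with `time`, `c`
#'   (free µM), `s` (SR total µM), `extruded` (cumulative net µM), per-term
#'   flux timecourses (`flux_serca`, `flux_ncx`, `flux_backflux`,
#'   `flux_leak`, `flux_release`, µM total/s; the instantaneous stimulus
#'   release is an event, not part of `flux_release`), and the inputs.
#' @examples
#' sim <- simulate_myocyte(myocyte_params(), pacing_protocol(n_beats = 4))
#' range(sim$c)
#' @export
simulate_myocyte <- function(params, protocol) {
  stopifnot(inherits(params, "myocyte_params"),
            inherits(protocol, "pacing_protocol"))
  dt <- protocol$dt
  n <- floor(protocol$duration / dt) + 1L
  time <- (seq_len(n) - 1L) * dt
  ks <- params$k_serca; kn <- params$k_ncx; beta <- params$beta
  B <- ks * params$c_rest; L <- kn * params$c_rest
  kc <- params$k_caff; fr <- params$fr; q <- params$stim_influx

  stim_idx <- if (protocol$n_beats > 0)
    round(protocol$stimulus_times / dt) + 1L else integer(0)
  stim_idx <- stim_idx[stim_idx >= 1L & stim_idx <= n]
  caff_idx <- if (is.na(protocol$caffeine_onset)) n + 1L
              else round(protocol$caffeine_onset / dt) + 1L

  c_out <- numeric(n); s_out <- numeric(n); x_out <- numeric(n)
  cc <- params$c_rest; ss <- params$sr_init; xx <- 0
  is_stim <- logical(n); is_stim[stim_idx] <- TRUE

  deriv <- function(cc, ss, caff_on) {
    jr <- if (caff_on) kc * ss else 0
    dc <- (jr + B + L - (ks + kn) * cc) / beta
    ds <- ks * cc - B - jr
    dx <- kn * cc - L
    c(dc, ds, dx)
  }

  for (i in seq_len(n)) {
    if (is_stim[i]) {
      rel <- fr * ss
      ss <- ss - rel + q
      cc <- cc + rel / beta
      xx <- xx - q  # trigger entry counts as negative net extrusion
    }
    c_out[i] <- cc; s_out[i] <- ss; x_out[i] <- xx
    if (!is.finite(cc) || !is.finite(ss) || cc <= 0 || ss < -1e-9)
      stop(sim_integration_error(time[i]))
    if (i < n) {
      caff_on <- i >= caff_idx
      k1 <- deriv(cc, ss, caff_on)
      k2 <- deriv(cc + dt / 2 * k1[1], ss + dt / 2 * k1[2], caff_on)
      k3 <- deriv(cc + dt / 2 * k2[1], ss + dt / 2 * k2[2], caff_on)
      k4 <- deriv(cc + dt * k3[1], ss + dt * k3[2], caff_on)
      cc <- cc + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      ss <- ss + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      xx <- xx + dt / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
    }
  }

  caff_on_vec <- time >= (caff_idx - 1L) * dt
  structure(list(
    time = time, c = c_out, s = s_out, extruded = x_out,
    flux_serca = ks * c_out,
    flux_ncx = kn * c_out,
    flux_backflux = rep(B, n),
    flux_leak = rep(L, n),
    flux_release = ifelse(caff_on_vec, kc * s_out, 0),
    params = params, protocol = protocol),
    class = "simulation_result")
}

#' Mass-conservation residual of a simulation
#'
#' Maximum absolute deviation of `beta*c + s + extruded` from its initial
#' value, i.e. the integration error on total Ca accounting.
#'
#' @param sim A [simulate_myocyte()] result.
#' @return Scalar residual in µM (total Ca scale).
#' @export
conservation_residual <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  tot <- sim$params$beta * sim$c + sim$s + sim$extruded
  max(abs(tot - tot[1]))
}

#' Render a simulation into a noisy two-channel fluorescence trace
#'
#' Downsamples the simulated free-Ca2+ trajectory to the camera rate,
#' converts it to the noiseless ratio via [ca_to_ratio()], and synthesises
#' two emission channels whose noiseless background-subtracted ratio equals
#' that value: the denominator channel sits at `den_level` and the numerator
#' at `den_level * ratio`, each plus its background and independent Gaussian
#' channel noise. Stimulus times and caffeine onset travel in the trace
#' metadata.
#'
#' @param sim A [simulate_myocyte()] result.
#' @param curve A [calibration_curve()].
#' @param noise A [noise_spec()].
#' @param sample_hz Camera sampling rate, Hz (must divide the simulation
#'   rate).
#' @param den_level Mean denominator-channel intensity, arbitrary units.
#' @param bg_num,bg_den Background levels added to each channel and recorded
#'   in the metadata.
#' @return A [fluorescence_trace()].
#' @export
render_fluorescence <- function(sim, curve = calibration_curve(),
                                noise = noise_spec(), sample_hz = 100,
                                den_level = 100, bg_num = 10, bg_den = 10) {
  stopifnot(inherits(sim, "simulation_result"),
            inherits(curve, "calibration_curve"),
            inherits(noise, "noise_spec"))
  step <- 1 / (sample_hz * sim$protocol$dt)
  if (abs(step - round(step)) > 1e-8)
    stop("render_fluorescence: sample_hz must divide the simulation rate")
  idx <- seq(1L, length(sim$time), by = as.integer(round(step)))
  tt <- sim$time[idx]
  ratio <- ca_to_ratio(sim$c[idx], curve)
  ch_den <- rep(den_level, length(idx)) + bg_den
  ch_num <- den_level * ratio + bg_num
  if (noise$channel_sd > 0) {
    withr::with_seed(noise$seed, {
      ch_num <- ch_num + stats::rnorm(length(idx), 0, noise$channel_sd)
      ch_den <- ch_den + stats::rnorm(length(idx), 0, noise$channel_sd)
    })
  }
  fluorescence_trace(time = tt, ch_num = ch_num, ch_den = ch_den,
                     bg_num = bg_num, bg_den = bg_den,
                     stimulus_times = sim$protocol$stimulus_times,
                     caffeine_onset = sim$protocol$caffeine_onset,
                     dye = "FuraRed", calibration_id = curve$id)
}

#' A sampled fluorescence recording with protocol metadata
#'
#' Container for a two-channel (or precomputed-ratio) recording together
#' with the stimulus times and caffeine onset needed by the segmentation
#' stage. Either both channels or `ratio` must be supplied; background
#' subtraction is only available in the two-channel form.
#'
#' @param time Sample times, s (strictly increasing).
#' @param ch_num,ch_den Channel intensity series, or `NULL` when `ratio` is
#'   given directly.
#' @param ratio Precomputed ratio series, or `NULL`.
#' @param bg_num,bg_den Background levels for the two channels.
#' @param stimulus_times Stimulus times, s.
#' @param caffeine_onset Caffeine application time, s (`NA` if none).
#' @param dye Dye label.
#' @param calibration_id Identifier of the calibration the recording is
#'   intended to be interpreted with.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time, ch_num = NULL, ch_den = NULL,
                               ratio = NULL, bg_num = 0, bg_den = 0,
                               stimulus_times = numeric(0),
                               caffeine_onset = NA_real_,
                               dye = "FuraRed", calibration_id = NA_character_) {
  if (any(diff(time) <= 0)) stop("fluorescence_trace: time must be strictly increasing")
  has_ch <- !is.null(ch_num) && !is.null(ch_den)
  if (!has_ch && is.null(ratio))
    stop("fluorescence_trace: need either both channels or a ratio series")
  if (has_ch && (length(ch_num) != length(time) || length(ch_den) != length(time)))
    stop("fluorescence_trace: channel series must match time length")
  if (!is.null(ratio) && length(ratio) != length(time))
    stop("fluorescence_trace: ratio series must match time length")
  structure(list(time = time, ch_num = ch_num, ch_den = ch_den,
                 ratio = ratio, bg_num = bg_num, bg_den = bg_den,
                 stimulus_times = as.numeric(stimulus_times),
                 caffeine_onset = caffeine_onset, dye = dye,
                 calibration_id = calibration_id),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> %d samples over %.3g s (%s), %d stimuli, caffeine at %s s\n",
    length(x$time), diff(range(x$time)),
    if (!is.null(x$ch_num)) "two channels" else "ratio only",
    length(x$stimulus_times),
    if (is.na(x$caffeine_onset)) "-" else format(x$caffeine_onset)))
  invisible(x)
}

#' Ratio series of a trace
#'
#' Returns the stored ratio, or computes the background-subtracted ratio of
#' the two channels via [compute_ratio()].
#'
#' @param trace A [fluorescence_trace()].
#' @return Numeric ratio series.
#' @export
trace_ratio <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!is.null(trace$ratio)) return(trace$ratio)
  compute_ratio(trace$ch_num, trace$ch_den, trace$bg_num, trace$bg_den)
}

#' Calibrate a fluorescence trace to free calcium
#'
#' @param trace A [fluorescence_trace()].
#' @param curve A [calibration_curve()].
#' @return An object of class `calibrated_trace`: `time`, `ca` (µM),
#'   logical `saturated`, plus the protocol metadata and the curve used.
#' @export
calibrate_trace <- function(trace, curve = calibration_curve()) {
  r <- trace_ratio(trace)
  conv <- ratio_to_ca(r, curve)
  structure(list(time = trace$time, ca = conv$ca, saturated = conv$saturated,
                 stimulus_times = trace$stimulus_times,
                 caffeine_onset = trace$caffeine_onset,
                 dye = trace$dye, curve = curve),
            class = "calibrated_trace")
}
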