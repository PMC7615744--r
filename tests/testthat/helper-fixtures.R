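# Shared fixtures, built once per test run and memoised.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

default_sim <- function() {
  memo("default_sim",
       simulate_myocyte(myocyte_params(), pacing_protocol()))
}

clean_trace <- function() {
  memo("clean_trace",
       render_fluorescence(default_sim(), noise = noise_spec(0)))
}

clean_report <- function() {
  memo("clean_report", full_report(clean_trace()))
}

# Paced train without caffeine (for segmentation cross-checks).
train_only_ctrace <- function(n_beats = 8) {
  memo(paste0("train", n_beats), {
    pr <- pacing_protocol(n_beats = n_beats, caffeine_onset = NA,
                          duration = 0.25 + n_beats / 2 + 1)
    sim <- simulate_myocyte(myocyte_params(), pr)
    calibrate_trace(render_fluorescence(sim, noise = noise_spec(0)))
  })
}

# Calibrated trace built directly from a known free-Ca timecourse.
ca_as_ctrace <- function(time, ca, stimulus_times = numeric(0),
                         caffeine_onset = NA_real_,
                         curve = calibration_curve()) {
  trace <- fluorescence_trace(time = time, ratio = ca_to_ratio(ca, curve),
                              stimulus_times = stimulus_times,
                              caffeine_onset = caffeine_onset)
  calibrate_trace(trace, curve)
}

# Mono-exponential CaT train: baseline + amp * exp(-(t - stim)/tau).
exp_train_ca <- function(stims, tau = 0.2, baseline = 0.1, amp = 0.9,
                         dt = 0.001, duration = max(stims) + 1) {
  tt <- seq(0, duration, by = dt)
  ca <- rep(baseline, length(tt))
  for (s in stims) {
    on <- tt >= s
    ca[on] <- baseline + amp * exp(-(tt[on] - s) / tau)
  }
  list(time = tt, ca = ca)
}
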