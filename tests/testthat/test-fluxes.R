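test_that("flux curve of an analytic exponential recovery matches the closed form", {
  tt <- seq(0, 1.2, by = 0.001)
  ca <- 0.1 + 0.9 * exp(-5 * tt)
  pts <- recovery_flux_curve(tt, ca, beta = 100, baseline = 0.1, peak = 1.0)
  # flux = -beta * dc/dt = 500 * (ca - 0.1) at every point
  expect_lt(max(abs(pts$flux - 500 * (pts$ca - 0.1))), 0.5)
  fit <- fit_rate_constant(pts)
  expect_lt(abs(fit$rate_constant - 500) / 500, 1e-3)
  expect_lt(abs(fit$intercept + 50) / 50, 1e-3)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("flux scales linearly in the buffering capacity", {
  tt <- seq(0, 1.2, by = 0.001)
  ca <- 0.1 + 0.9 * exp(-5 * tt)
  p100 <- recovery_flux_curve(tt, ca, beta = 100, baseline = 0.1, peak = 1.0)
  p1 <- recovery_flux_curve(tt, ca, beta = 1, baseline = 0.1, peak = 1.0)
  expect_equal(p1$flux * 100, p100$flux, tolerance = 1e-12)
  expect_equal(p1$ca, p100$ca, tolerance = 1e-12)
})

test_that("degenerate flux inputs are handled as contracted", {
  tt <- seq(0, 1, by = 0.01)
  # constant concentration: all-zero flux
  pts <- recovery_flux_curve(tt, rep(0.5, length(tt)), beta = 100,
                             baseline = 0.4, peak = 0.6)
  expect_lt(max(abs(pts$flux)), 1e-9)
  # no variance in ca -> degenerate fit
  expect_error(fit_rate_constant(pts), "degenerate")
  # all-zero flux over a real ca range -> slope 0
  f0 <- fit_rate_constant(data.frame(ca = seq(0.1, 1, 0.1), flux = 0))
  expect_equal(f0$rate_constant, 0)
  expect_error(fit_rate_constant(data.frame(ca = 1:2, flux = 1:2)),
               class = "caflux_insufficient_data")
  expect_error(recovery_flux_curve(1:4 / 100, c(1, 0.9, 0.8, 0.7)),
               class = "caflux_insufficient_data")
})

test_that("caffeine-recovery analysis recovers NCX and its balancing leak", {
  ct <- calibrate_trace(clean_trace())
  caff <- detect_caffeine_transient(ct)
  res <- ncx_analysis(caff, beta = 100)
  expect_lt(abs(res$k_ncx - 70) / 70, 0.03)
  expect_equal(res$leak, res$k_ncx * caff$resting)
  # independent oracle: log-linear decay rate times beta
  rec <- caff$recovery
  sel <- rec$ca - 0.1 > 0.05 * (max(rec$ca) - 0.1)
  rate <- -unname(coef(lm(log(rec$ca[sel] - 0.1) ~ rec$time[sel]))[2])
  expect_lt(abs(res$k_ncx - 100 * rate) / (100 * rate), 0.02)
  # buffering capacity is a pure scaling of the recovered rate constant
  res2 <- ncx_analysis(caff, beta = 200)
  expect_equal(res2$k_ncx / res$k_ncx, 2, tolerance = 1e-9)
})

test_that("CaT-recovery analysis separates SERCA from NCX by mode", {
  ct <- calibrate_trace(clean_trace())
  avg <- average_transients(detect_transients(ct))
  caff <- detect_caffeine_transient(ct)
  ncx <- ncx_analysis(caff, beta = 100)
  sub <- serca_analysis(avg, ncx_fit = ncx$fit, beta = 100,
                        mode = "ncx-subtracted")
  expect_lt(abs(as.numeric(sub$k_serca) - 430) / 430, 0.03)
  expect_equal(sub$backflux, as.numeric(sub$k_serca) * avg$diastolic)
  lump <- serca_analysis(avg, beta = 100, mode = "lumped")
  expect_lt(abs(as.numeric(lump$k_serca) - 500) / 500, 0.03)
  expect_equal(lump$slope, sub$slope)
  expect_error(serca_analysis(avg, mode = "ncx-subtracted"), "ncx_fit")
})

test_that("the full report recovers ground truth with exact balancing identities", {
  rep <- clean_report()
  expect_length(rep$errors, 0)
  expect_lt(abs(rep$k_serca - 430) / 430, 0.03)
  expect_lt(abs(rep$k_ncx - 70) / 70, 0.03)
  expect_lt(abs(rep$fractional_release - 0.6) / 0.6, 0.05)
  expect_equal(rep$backflux, rep$k_serca * rep$diastolic, tolerance = 1e-9)
  expect_equal(rep$leak, rep$k_ncx * rep$resting, tolerance = 1e-9)
  expect_identical(rep$mode, "ncx-subtracted")
  expect_equal(rep$n_beats_averaged, 18)
})

test_that("a report survives a CSV round trip of its input unchanged", {
  tr <- clean_trace()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "trace.csv")
  write_trace(tr, path)
  rep1 <- clean_report()
  rep2 <- full_report(read_trace(path))
  for (f in c("diastolic", "systolic", "amplitude", "resting", "sr_load",
              "fractional_release", "k_serca", "k_ncx", "backflux", "leak"))
    expect_equal(rep2[[f]], rep1[[f]], tolerance = 1e-9, label = f)
})

test_that("a trace without caffeine yields a partial, lumped-mode report", {
  pr <- pacing_protocol(n_beats = 8, caffeine_onset = NA, duration = 5)
  sim <- simulate_myocyte(myocyte_params(), pr)
  tr <- render_fluorescence(sim, noise = noise_spec(0))
  rep <- full_report(tr)
  expect_true(is.na(rep$k_ncx))
  expect_true(is.na(rep$leak))
  expect_true(is.na(rep$sr_load))
  expect_true(is.na(rep$fractional_release))
  expect_identical(rep$mode, "lumped")
  expect_lt(abs(rep$k_serca - 500) / 500, 0.03)  # SERCA+NCX lumped slope
  expect_false(is.na(rep$diastolic))
})

test_that("saturated samples force the peak-unreliable flag through the report", {
  # SR load large enough that the caffeine peak exceeds the saturation ratio
  p <- myocyte_params(sr_init = 110)
  sim <- simulate_myocyte(p, pacing_protocol())
  rep <- full_report(render_fluorescence(sim, noise = noise_spec(0)))
  expect_gt(rep$saturated_fraction, 0)
  expect_true(rep$flags$peak_unreliable)
})

test_that("metric concentrations are invariant to the configured buffering capacity", {
  tr <- clean_trace()
  r100 <- clean_report()
  r50 <- full_report(tr, analysis_config(beta = 50))
  expect_equal(r50$diastolic, r100$diastolic)
  expect_equal(r50$sr_load, r100$sr_load)
  expect_equal(r50$k_serca / r100$k_serca, 0.5, tolerance = 1e-6)
  expect_equal(r50$k_ncx / r100$k_ncx, 0.5, tolerance = 1e-6)
})
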