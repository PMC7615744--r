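# caflux

Calcium-handling analysis of cardiomyocyte fluorescence transients.

Isolated ventricular myocytes loaded with a ratiometric Ca²⁺ dye
(FuraRed) and recorded under a concatenated protocol — a 2 Hz train of
electrically evoked Ca²⁺ transients (CaTs) followed by a caffeine-evoked
SR Ca²⁺ release (CaffT) — carry a complete readout of cellular Ca²⁺
handling. caflux turns such recordings into a per-cell physiology panel:

* **Calibration** — background-subtracted channel ratio `R`, mapped to
  free calcium by `[Ca²⁺] = Kd·(R − Rmin)/(Rmax − R)` with explicit
  flagging of ratios above the FuraRed saturation bound of 2.4.
* **Transients** — segmentation and averaging of the paced train;
  diastolic/systolic \[Ca²⁺\], CaT amplitude, CaT₉₀; resting \[Ca²⁺\],
  SR load (CaffT amplitude) and fractional release.
* **Flux decomposition** — removal flux `J = −β·dc/dt` (β = buffering
  capacity) regressed on \[Ca²⁺\] over the recovery phase. The CaT
  recovery slope gives SERCA(+NCX), the caffeine recovery slope gives
  NCX; SR backflux `B = k_SERCA·c_dia` and sarcolemmal leak
  `L = k_NCX·c_rest` are the rates required to balance each pathway at
  baseline. Units: rate constants s⁻¹, fluxes µM/s.
* **Cell shortening** — thresholded-area timecourse of an image stack,
  normalised to diastolic area.
* **Hierarchical statistics** — animal-nested comparisons (animal-mean
  Welch test and two-level bootstrap) that avoid pseudo-replication,
  with a simulation harness demonstrating the error calibration.
* **Forward simulator** — a paced two-pool myocyte model rendered into
  noisy two-channel fluorescence, so every stage above is verifiable by
  parameter recovery against known ground truth.

Intended users: cardiac physiology labs analysing dye-based Ca²⁺
imaging, and anyone needing a tested, scriptable reference
implementation of the flux-slope method.

## Worked example

Simulate a cell with known Ca²⁺ handling, render it to fluorescence, and
analyse it back:

```r
library(caflux)

params <- myocyte_params(k_serca = 430, k_ncx = 70, beta = 100, fr = 0.6)
sim    <- simulate_myocyte(params, pacing_protocol(pacing_hz = 2, n_beats = 20))
trace  <- render_fluorescence(sim, noise = noise_spec(0))
report <- full_report(trace)
report
#> <ca_handling_report>
#>   diastolic 0.1488 uM | systolic 0.6114 uM | amplitude 0.4626 uM | CaT90 0.337 s
#>   resting 0.1495 uM | SR load 0.7795 uM | fractional release 0.593
#>   k_serca 434.2 s^-1 (backflux 64.61 uM/s) | k_ncx 69.53 s^-1 (leak 10.4 uM/s) [ncx-subtracted]
```

The analysis recovers the simulated SERCA rate constant (434.2 vs 430
s⁻¹), NCX rate constant (69.5 vs 70 s⁻¹) and fractional release (0.593
vs 0.6). `diastolic`/`systolic` are the pre-stimulus and peak free
\[Ca²⁺\] of the averaged CaT; `SR load` is the caffeine-transient
amplitude; `backflux` and `leak` satisfy their balancing identities
exactly. Reports embed the calibration curve, buffering capacity,
windows and mode used (`report$provenance`), and serialise with
`write_report()` to JSON or a flat CSV row.

Nested group comparisons:

```r
cohort <- make_cohort(cohort_spec(group_effects = list(k_serca = 0.8)),
                      traces = FALSE)$cells
animal_mean_test(data.frame(value = cohort$k_serca,
                            cell_id = cohort$cell_id,
                            animal_id = cohort$animal_id,
                            group = cohort$group))
#> <comparison_result> animal-mean Welch t-test
#>   effect (group2 - group1) = -85.46 [-131.8, -39.15], p = 0.002179
#>   cells: 210 vs 210; animals: 7 vs 7
```

A thin command-line wrapper (`inst/cli/caflux`) exposes `simulate`,
`analyze`, `cohort`, `compare` and `demo-pseudoreplication`; all
artifacts are byte-reproducible from flags and `--seed`.

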