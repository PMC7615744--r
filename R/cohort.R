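#' Specification of a synthetic two-group, animal-nested cohort
#'
#' Emulates the nested study design of myocyte experiments: cells are
#' isolated from animals, animals belong to groups, and both levels carry
#' biological variability. Per-animal parameter multipliers are drawn
#' lognormally around 1 with fractional s.d. `animal_sd`, per-cell
#' multipliers around each animal with `cell_sd` (each lognormal has
#' `meanlog = -sdlog^2/2` so its mean is exactly 1). `group_effects` applies
#' named multiplicative shifts to the second group's base parameters, e.g.
#' `list(k_serca = 0.8)` for a 20% SERCA deficit.
#'
#' @param n_animals_per_group Animals (isolations) per group.
#' @param cells_per_animal Myocytes recorded per animal.
#' @param animal_sd Between-animal fractional s.d. of each varied parameter.
#' @param cell_sd Between-cell fractional s.d.
#' @param group_effects Named list of multiplicative shifts applied to the
#'   second group.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals_per_group = 7, cells_per_animal = 30,
                        animal_sd = 0.1, cell_sd = 0.2,
                        group_effects = list(), seed = 1L) {
  if (n_animals_per_group < 1 || cells_per_animal < 1)
    stop("cohort_spec: counts must be >= 1")
  if (animal_sd < 0 || cell_sd < 0)
    stop("cohort_spec: s.d. values must be >= 0")
  if (length(group_effects) && is.null(names(group_effects)))
    stop("cohort_spec: group_effects must be a named list")
  structure(list(n_animals_per_group = as.integer(n_animals_per_group),
                 cells_per_animal = as.integer(cells_per_animal),
                 animal_sd = animal_sd, cell_sd = cell_sd,
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of myocytes nested in animals
#'
#' Draws ground-truth per-cell parameters for a two-group, animal-nested
#' cohort and (optionally) simulates and renders a fluorescence trace per
#' cell. The varied parameters are multiplied by lognormal animal- and
#' cell-level factors; all other parameters are held at `base`. The whole
#' draw is reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param base A [myocyte_params()] describing the first group.
#' @param protocol A [pacing_protocol()] (used only when `traces = TRUE`).
#' @param vary Character vector of `myocyte_params` fields receiving the
#'   lognormal animal/cell variability.
#' @param traces If `TRUE`, also simulate and render one noisy trace per
#'   cell (slow); if `FALSE`, return the ground-truth table only.
#' @param curve,noise Calibration curve and channel-noise specification for
#'   rendering (only with `traces = TRUE`; each cell gets a distinct
#'   sub-seed derived from `spec$seed`).
#' @param sample_hz Camera rate for rendered traces.
#' @return A list with `cells` (a data.frame of ground-truth per-cell
#'   parameters with `cell_id`, `animal_id`, `group` labels) and `traces`
#'   (a list of [fluorescence_trace()] or `NULL`).
#' @export
make_cohort <- function(spec, base = myocyte_params(),
                        protocol = pacing_protocol(),
                        vary = c("k_serca", "k_ncx", "sr_init"),
                        traces = FALSE, curve = calibration_curve(),
                        noise = noise_spec(channel_sd = 1), sample_hz = 100) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base, "myocyte_params"))
  bad <- setdiff(names(spec$group_effects), names(unclass(base)))
  if (length(bad))
    stop("make_cohort: unknown group_effects fields: ", paste(bad, collapse = ", "))
  bad <- setdiff(vary, names(unclass(base)))
  if (length(bad))
    stop("make_cohort: unknown vary fields: ", paste(bad, collapse = ", "))

  n_a <- spec$n_animals_per_group; n_c <- spec$cells_per_animal
  groups <- c("group1", "group2")
  fields <- c("k_serca", "k_ncx", "c_rest", "beta", "fr", "k_caff",
              "sr_init", "stim_influx")
  draw <- function() {
    n_animals <- 2L * n_a
    n_cells <- n_animals * n_c
    grp <- rep(groups, each = n_a * n_c)
    animal_no <- rep(rep(seq_len(n_a), each = n_c), times = 2L)
    cell_no <- rep(seq_len(n_c), times = n_animals)
    animal_row <- rep(seq_len(n_animals), each = n_c)
    # lognormal multipliers, mean exactly 1 at each level
    a_fac <- matrix(exp(stats::rnorm(n_animals * length(vary),
                                     -spec$animal_sd^2 / 2, spec$animal_sd)),
                    n_animals, length(vary), dimnames = list(NULL, vary))
    c_fac <- matrix(exp(stats::rnorm(n_cells * length(vary),
                                     -spec$cell_sd^2 / 2, spec$cell_sd)),
                    n_cells, length(vary), dimnames = list(NULL, vary))
    cells <- data.frame(
      cell_id = sprintf("%s_a%02d_c%03d", grp, animal_no, cell_no),
      animal_id = sprintf("%s_a%02d", grp, animal_no),
      group = grp, stringsAsFactors = FALSE)
    for (nm in fields) {
      v <- rep(unclass(base)[[nm]], n_cells)
      if (!is.null(spec$group_effects[[nm]]))
        v[grp == "group2"] <- v[grp == "group2"] * spec$group_effects[[nm]]
      if (nm %in% vary)
        v <- v * a_fac[animal_row, nm] * c_fac[, nm]
      cells[[nm]] <- v
    }
    cells
  }
  cells <- withr::with_seed(spec$seed, draw())

  trace_list <- NULL
  if (traces) {
    trace_list <- vector("list", nrow(cells))
    names(trace_list) <- cells$cell_id
    for (i in seq_len(nrow(cells))) {
      pars <- myocyte_params(
        k_serca = cells$k_serca[i], k_ncx = cells$k_ncx[i],
        c_rest = cells$c_rest[i], beta = cells$beta[i], fr = cells$fr[i],
        k_caff = cells$k_caff[i], sr_init = cells$sr_init[i],
        stim_influx = NULL)
      sim <- simulate_myocyte(pars, protocol)
      cell_noise <- noise_spec(noise$channel_sd,
                               seed = (spec$seed * 10007L + i) %% .Machine$integer.max)
      trace_list[[i]] <- render_fluorescence(sim, curve, cell_noise,
                                             sample_hz = sample_hz)
    }
  }
  list(cells = cells, traces = trace_list)
}
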